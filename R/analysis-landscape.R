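# Rotation-dihedral distributions, Boltzmann-inverted free-energy
# surfaces with minimax transition paths, center-of-mass distance series
# and 3D occupancy density maps.

# Boltzmann constant times 298 K, in kJ/mol.
KT_298 <- 2.478

ca_index <- function(structure, resno, chain = NULL) {
  at <- structure$atoms
  hit <- which(at$name == "CA" & at$resno == resno &
                 (if (is.null(chain)) TRUE else at$chain == chain))
  if (!length(hit)) stopf("no CA atom for residue %d", resno)
  if (length(hit) > 1) warnf("residue %d has %d CA atoms; using the first",
                             resno, length(hit))
  hit[1]
}

#' Interdomain rotation dihedral across an ensemble
#'
#' Per-member dihedral angle over four C-alpha atoms (two residues at the
#' center of each domain, oriented perpendicular to the interdomain
#' axis - the convention used to monitor the rotation of one domain
#' relative to another), plus a circular histogram and its local maxima.
#'
#' @param ensemble an [ensemble3d()] (a single [structure3d()] is
#'   accepted).
#' @param resnos four residue numbers defining the dihedral, in chain
#'   order (two in the first domain, two in the second).
#' @param chain optional chain id.
#' @param bin_width histogram bin width in degrees (default 5).
#' @param smooth odd circular moving-average window (in bins) applied
#'   before peak detection only, suppressing single-bin sampling noise
#'   (default 3; 1 disables). Reported counts stay raw.
#' @return List of class `dihedral_series`: `angles` (degrees, per
#'   member), `breaks`, `counts`, `peaks` (data.frame `center`, `count`,
#'   sorted by height: circular local maxima of the histogram).
#' @export
dihedral_series <- function(ensemble, resnos, chain = NULL, bin_width = 5,
                            smooth = 3) {
  if (inherits(ensemble, "structure3d")) ensemble <- ensemble3d(ensemble)
  if (length(resnos) != 4) stopf("need exactly 4 residue numbers")
  idx <- vapply(resnos, ca_index, integer(1),
                structure = ensemble$members[[1]], chain = chain)
  ang <- vapply(ensemble$members, function(s)
    dihedral(s$xyz[idx, , drop = FALSE]), numeric(1))
  breaks <- seq(-180, 180, by = bin_width)
  # right-closed bins so the (-180, 180] convention maps cleanly
  bin <- findInterval(ang, breaks, left.open = TRUE, rightmost.closed = FALSE)
  bin[bin == 0] <- 1
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(counts)
  sm <- as.numeric(counts)
  if (smooth > 1) {
    h <- (smooth - 1) %/% 2
    sm <- vapply(seq_len(nb), function(i)
      mean(counts[((i - h - 1):(i + h - 1)) %% nb + 1]), numeric(1))
  }
  prv <- sm[c(nb, seq_len(nb - 1))]
  nxt <- sm[c(seq_len(nb - 1) + 1, 1)]
  is_peak <- sm > 0 & sm >= prv & sm >= nxt & (sm > prv | sm > nxt)
  peaks <- data.frame(center = centers[is_peak], count = sm[is_peak])
  peaks <- peaks[order(-peaks$count, peaks$center), , drop = FALSE]
  out <- list(angles = ang, breaks = breaks, counts = counts,
              centers = centers, peaks = peaks, resnos = resnos)
  class(out) <- "dihedral_series"
  out
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("dihedral_series over residues (%s): %d members; top peaks at %s deg\n",
              paste(x$resnos, collapse = ", "), length(x$angles),
              paste(utils::head(x$peaks$center, 3), collapse = ", ")))
  invisible(x)
}

#' Free-energy surface over two collective variables
#'
#' Boltzmann inversion of the 2D sample histogram:
#' `F = -kT ln(rho / rho_max)`, so the most populated bin sits at F = 0
#' and bin-to-bin differences reproduce the count ratios exactly. Empty
#' bins are masked (NA) rather than given a pseudo-count, leaving
#' unexplored regions blank.
#'
#' @param projections numeric matrix or data.frame with >= 2 columns
#'   (e.g. PC1, PC2 from [pca_project()]).
#' @param bins number of bins per axis (scalar or length 2; default 40).
#' @param kT thermal energy in kJ/mol (default 2.478, i.e. 298 K).
#' @param edges optional list of two break vectors overriding the
#'   automatic data-spanning bins.
#' @return List of class `fes2d`: `F` (kJ/mol matrix, min over occupied
#'   bins = 0, NA = unexplored), `counts`, `xedges`, `yedges`, `kT`.
#' @export
free_energy_surface <- function(projections, bins = 40, kT = KT_298,
                                edges = NULL) {
  P <- as.matrix(projections)[, 1:2, drop = FALSE]
  if (nrow(P) < 1) stopf("no samples")
  if (kT <= 0) stopf("kT must be positive")
  if (length(bins) == 1) bins <- c(bins, bins)
  mk_edges <- function(x, nb) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2] + diff(r) * 1e-9, length.out = nb + 1)
  }
  xe <- edges[[1]] %||% mk_edges(P[, 1], bins[1])
  ye <- edges[[2]] %||% mk_edges(P[, 2], bins[2])
  bx <- pmin(pmax(findInterval(P[, 1], xe, rightmost.closed = TRUE), 1),
             length(xe) - 1)
  by <- pmin(pmax(findInterval(P[, 2], ye, rightmost.closed = TRUE), 1),
             length(ye) - 1)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  for (k in seq_len(nrow(P))) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  FF <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  FF[occ] <- -kT * log(counts[occ] / max(counts))
  out <- list(F = FF, counts = counts, xedges = xe, yedges = ye, kT = kT)
  class(out) <- "fes2d"
  out
}

#' @export
print.fes2d <- function(x, ...) {
  cat(sprintf("fes2d: %d x %d bins, %d occupied, F range [0, %.3g] kJ/mol (kT = %.3f)\n",
              nrow(x$F), ncol(x$F), sum(!is.na(x$F)),
              max(x$F, na.rm = TRUE), x$kT))
  invisible(x)
}

#' @export
plot.fes2d <- function(x, ...) {
  cx <- (x$xedges[-1] + x$xedges[-length(x$xedges)]) / 2
  cy <- (x$yedges[-1] + x$yedges[-length(x$yedges)]) / 2
  graphics::image(cx, cy, x$F, xlab = "PC1", ylab = "PC2",
                  main = "free energy (kJ/mol)", ...)
  invisible(x)
}

#' Minimum free-energy (minimax) path between two basins
#'
#' The transition path over the occupied bins of a [free_energy_surface()]
#' that minimises the maximum free energy encountered, on the 8-connected
#' bin graph; the barrier is that maximum minus the free energy of the
#' starting basin. This is the landscape analogue of the lowest saddle
#' between two minima.
#'
#' @param surface a `fes2d`.
#' @param basin_a,basin_b bin indices `c(ix, iy)` of the two basins
#'   (both must be occupied).
#' @return List: `path` (two-column matrix of bin indices), `barrier`
#'   (kJ/mol), `F_path` (free energies along the path).
#' @export
min_free_energy_path <- function(surface, basin_a, basin_b) {
  FF <- surface$F
  nx <- nrow(FF); ny <- ncol(FF)
  id <- function(ij) (ij[2] - 1L) * nx + ij[1]
  a <- id(basin_a); b <- id(basin_b)
  if (is.na(FF[a]) || is.na(FF[b])) stopf("basin bin is unoccupied")
  if (a == b)
    return(list(path = matrix(basin_a, 1, 2), barrier = 0,
                F_path = FF[a]))
  key <- rep(Inf, nx * ny)
  parent <- rep(NA_integer_, nx * ny)
  done <- rep(FALSE, nx * ny)
  key[a] <- FF[a]
  repeat {
    avail <- replace(key, done, Inf)
    u <- which.min(avail)
    if (!is.finite(avail[u])) break  # frontier exhausted: disconnected
    if (u == b) break
    done[u] <- TRUE
    ui <- ((u - 1L) %% nx) + 1L
    uj <- ((u - 1L) %/% nx) + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- ui + di; vj <- uj + dj
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      v <- (vj - 1L) * nx + vi
      if (done[v] || is.na(FF[v])) next
      nk <- max(key[u], FF[v])
      if (nk < key[v]) { key[v] <- nk; parent[v] <- u }
    }
  }
  if (!is.finite(key[b]))
    stopf("basins are disconnected through occupied bins (%d occupied of %d)",
          sum(!is.na(FF)), nx * ny)
  path <- b
  while (path[1] != a) path <- c(parent[path[1]], path)
  ij <- cbind(((path - 1L) %% nx) + 1L, ((path - 1L) %/% nx) + 1L)
  list(path = ij, barrier = key[b] - FF[a], F_path = FF[path])
}

#' Locate occupied local minima of a free-energy surface
#'
#' @param surface a `fes2d`.
#' @param k number of minima to return (by depth).
#' @return Matrix of bin indices, one row per basin, deepest first.
#' @export
fes_minima <- function(surface, k = 2) {
  FF <- surface$F
  nx <- nrow(FF); ny <- ncol(FF)
  mins <- NULL
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (is.na(FF[i, j])) next
    nb <- FF[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
    if (FF[i, j] <= min(nb, na.rm = TRUE)) mins <- rbind(mins, c(i, j))
  }
  mins[order(FF[mins]), , drop = FALSE][seq_len(min(k, nrow(mins))), ,
                                        drop = FALSE]
}

#' Center-of-mass distance of a mobile domain from a reference position
#'
#' Each member is superposed on the fit selection onto a reference
#' structure (e.g. a crystal structure, fitted over the rigid core of the
#' static domain); the series is the Euclidean distance between the
#' member's mobile-domain center of mass and the reference position -
#' the degree-of-opening coordinate of a relocating domain.
#'
#' @param ensemble an [ensemble3d()].
#' @param mobile_indices atoms of the mobile domain (in ensemble
#'   topology).
#' @param fit_indices atoms of the fitting core, present with the same
#'   meaning in members and reference.
#' @param reference a [structure3d()] sharing the fit selection geometry.
#' @param reference_fit_indices fit atoms in the reference (default: the
#'   same indices as `fit_indices`).
#' @param reference_com reference position (nm); default: the mobile
#'   domain's center of mass in the reference.
#' @param weighting COM weighting, `"mass"` or `"uniform"`.
#' @return List of class `distance_series`: `d` (nm, per member),
#'   `reference_com`, `label`.
#' @export
com_distance_series <- function(ensemble, mobile_indices, fit_indices,
                                reference,
                                reference_fit_indices = fit_indices,
                                reference_com = NULL,
                                weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(fit_indices) != length(reference_fit_indices))
    stopf("fit selections differ in size between ensemble and reference")
  ref_fit <- reference$xyz[reference_fit_indices, , drop = FALSE]
  if (is.null(reference_com))
    reference_com <- center_of_mass(reference, mobile_indices, weighting)
  d <- vapply(ensemble$members, function(s) {
    tr <- superpose(s$xyz[fit_indices, , drop = FALSE], ref_fit)
    com <- center_of_mass(apply_transform(s, tr), mobile_indices, weighting)
    sqrt(sum((com - reference_com)^2))
  }, numeric(1))
  structure(list(d = d, reference_com = reference_com,
                 label = reference$source),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series: %d members, d in [%.3g, %.3g] nm\n",
              length(x$d), min(x$d), max(x$d)))
  invisible(x)
}

#' 3D density map of a mobile domain's center of mass
#'
#' After superposing every member on the fit selection (the static-domain
#' frame), the mobile-domain centers of mass are histogrammed on a
#' regular 3D grid and normalised to sum to 1 - the occupancy cloud of a
#' relocating domain relative to its anchor.
#'
#' @inheritParams com_distance_series
#' @param reference frame-defining [structure3d()]; default the first
#'   member.
#' @param spacing grid spacing in nm (default 0.2).
#' @param pad padding added around the COM cloud, nm.
#' @return List of class `density_map3d`: `density` (3D array summing to
#'   1), `origin` (nm), `spacing`, `coms`.
#' @export
density_map <- function(ensemble, mobile_indices, fit_indices,
                        reference = NULL, spacing = 0.2, pad = 0.3,
                        weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  if (!length(ensemble$members)) stopf("empty ensemble")
  reference <- reference %||% ensemble$members[[1]]
  ref_fit <- reference$xyz[fit_indices, , drop = FALSE]
  coms <- t(vapply(ensemble$members, function(s) {
    tr <- superpose(s$xyz[fit_indices, , drop = FALSE], ref_fit)
    center_of_mass(apply_transform(s, tr), mobile_indices, weighting)
  }, numeric(3)))
  origin <- apply(coms, 2, min) - pad
  dims <- pmax(ceiling((apply(coms, 2, max) + pad - origin) / spacing), 1)
  idx <- pmin(floor(sweep(coms, 2, origin) / spacing) + 1,
              matrix(dims, nrow(coms), 3, byrow = TRUE))
  dens <- array(0, dim = dims)
  for (k in seq_len(nrow(idx)))
    dens[idx[k, 1], idx[k, 2], idx[k, 3]] <-
      dens[idx[k, 1], idx[k, 2], idx[k, 3]] + 1
  dens <- dens / sum(dens)
  structure(list(density = dens, origin = origin, spacing = spacing,
                 coms = coms),
            class = "density_map3d")
}

#' @export
print.density_map3d <- function(x, ...) {
  cat(sprintf("density_map3d: %s grid, spacing %.3g nm, max density %.3g\n",
              paste(dim(x$density), collapse = "x"), x$spacing,
              max(x$density)))
  invisible(x)
}

#' Isosurface levels as fractions of the density maximum
#'
#' @param map a `density_map3d`.
#' @param fractions fractions of the maximum (default `c(0.1, 0.001)`,
#'   i.e. one tenth and one thousandth).
#' @return Named numeric vector of density levels.
#' @export
iso_levels <- function(map, fractions = c(0.1, 0.001)) {
  stats::setNames(fractions * max(map$density),
                  paste0("frac", fractions))
}
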