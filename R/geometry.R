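# Rigid-body geometry kernel: least-squares superposition, RMSD,
# dihedrals, centers of mass and gyration/inertia tensors. All lengths nm,
# all angles degrees.

coords_of <- function(x, indices = NULL) {
  xyz <- if (inherits(x, "structure3d")) x$xyz else as.matrix(x)
  if (!is.null(indices)) xyz <- xyz[indices, , drop = FALSE]
  xyz
}

element_masses <- function(symbols) {
  tab <- bio3d::elements
  m <- tab$mass[match(toupper(symbols), toupper(tab$symb))]
  bad <- is.na(m) | toupper(symbols) == "XX" | symbols == "unknown"
  if (any(bad))
    stopf("unknown element(s) for mass weighting: %s",
          paste(unique(symbols[bad]), collapse = ", "))
  m
}

atom_weights <- function(structure, indices, weighting) {
  n <- if (is.null(indices)) nrow(coords_of(structure)) else length(indices)
  if (weighting == "uniform" || !inherits(structure, "structure3d"))
    return(rep(1, n))
  el <- structure$atoms$element
  if (!is.null(indices)) el <- el[indices]
  element_masses(el)
}

#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) squared deviation of `mobile` onto `target` over the fit
#' atoms, via the SVD construction with a reflection guard so that
#' `det(rotation) = +1`. This is the operation behind "superposed at the
#' shared domain" in the fragment-recombination workflow and behind all
#' fitted analytics.
#'
#' @param mobile,target [structure3d()] objects or `n x 3` matrices (nm).
#' @param fit_indices atom indices used for the fit (same atoms, same
#'   order, in both inputs); at least 3 non-collinear atoms. `NULL` uses
#'   all atoms.
#' @param weights optional per-fit-atom weights.
#' @return A list of class `rigid_transform`: `rotation` (3x3),
#'   `translation` (length-3, nm) and `rmsd` (fit RMSD, nm). Apply with
#'   [apply_transform()].
#' @export
superpose <- function(mobile, target, fit_indices = NULL, weights = NULL) {
  X <- coords_of(mobile, fit_indices)
  Y <- coords_of(target, fit_indices)
  if (nrow(X) != nrow(Y))
    stopf("fit selections differ in size (%d vs %d)", nrow(X), nrow(Y))
  if (nrow(X) < 3) stopf("need at least 3 fit atoms, got %d", nrow(X))
  w <- weights %||% rep(1, nrow(X))
  if (length(w) != nrow(X)) stopf("weights length mismatch")
  w <- w / sum(w)
  mx <- colSums(X * w); my <- colSums(Y * w)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  # degenerate (collinear) fit sets leave the rotation under-determined
  for (Z in list(Xc, Yc)) {
    sv <- svd(Z)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-30))
      stopf("degenerate (collinear) fit atom set")
  }
  C <- crossprod(Xc * w, Yc)
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dev <- Xc %*% t(R) - Yc
  out <- list(rotation = R,
              translation = as.numeric(my - R %*% mx),
              rmsd = sqrt(sum(w * rowSums(dev^2))))
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform (fit RMSD %.4g nm)\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure or coordinate matrix
#'
#' @param x a [structure3d()] or `n x 3` matrix.
#' @param transform a `rigid_transform` from [superpose()].
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  f <- function(xyz) sweep(xyz %*% t(transform$rotation), 2,
                           transform$translation, `+`)
  if (inherits(x, "structure3d")) {
    x$xyz <- f(x$xyz)
    x
  } else f(as.matrix(x))
}

#' Root-mean-square deviation between two conformers
#'
#' @param a,b [structure3d()] objects or coordinate matrices.
#' @param analysis_indices atoms over which the RMSD is computed
#'   (default: all).
#' @param fit_indices if given, `a` is first superposed onto `b` over
#'   these atoms; `NULL` compares coordinates as-is.
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b, analysis_indices = NULL, fit_indices = NULL) {
  if (!is.null(fit_indices)) a <- apply_transform(a, superpose(a, b, fit_indices))
  A <- coords_of(a, analysis_indices)
  B <- coords_of(b, analysis_indices)
  if (!nrow(A)) stopf("empty analysis selection")
  if (nrow(A) != nrow(B)) stopf("selection size mismatch")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention, degrees in (-180, 180] (exactly opposed
#' arrangements report +180). Used e.g. for the interdomain rotation
#' dihedral defined on four C-alpha atoms spanning two domains.
#'
#' @param p1,p2,p3,p4 length-3 coordinates (nm), or a single 4x3 matrix
#'   as `p1`.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL) {
  if (is.matrix(p1) && is.null(p2)) {
    p4 <- p1[4, ]; p3 <- p1[3, ]; p2 <- p1[2, ]; p1 <- p1[1, ]
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (min(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2))) < 1e-12)
    stopf("coincident consecutive points in dihedral")
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stopf("collinear point triplet in dihedral")
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  if (ang == -180) ang <- 180
  ang
}

#' Center of mass of a selection
#'
#' @param structure a [structure3d()] (or coordinate matrix, in which
#'   case weighting must be `"uniform"`).
#' @param indices atom indices (default all).
#' @param weighting `"mass"` (standard atomic masses by element; unknown
#'   elements are an error) or `"uniform"`.
#' @return Length-3 numeric, nm.
#' @export
center_of_mass <- function(structure, indices = NULL,
                           weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  X <- coords_of(structure, indices)
  if (!nrow(X)) stopf("empty selection")
  w <- atom_weights(structure, indices, weighting)
  colSums(X * w) / sum(w)
}

#' Gyration tensor summary of a selection
#'
#' Eigen-decomposition of the (weighted) gyration tensor: the radius of
#' gyration Rg (with Rg^2 equal to the eigenvalue sum), the eigenvalues
#' in descending order (nm^2) and the orthonormal principal axes, i.e.
#' the inertia-ellipsoid description of a domain.
#'
#' @inheritParams center_of_mass
#' @return List of class `gyration_summary`: `Rg` (nm), `eigenvalues`
#'   (descending, nm^2), `axes` (columns), `degenerate` (near-equal or
#'   all-zero eigenvalue flag), `com`.
#' @export
gyration_summary <- function(structure, indices = NULL,
                             weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  X <- coords_of(structure, indices)
  if (nrow(X) < 2) stopf("gyration tensor needs at least 2 atoms")
  w <- atom_weights(structure, indices, weighting)
  com <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, com)
  S <- crossprod(Xc * w, Xc) / sum(w)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  out <- list(Rg = sqrt(sum(ev)), eigenvalues = ev, axes = e$vectors,
              degenerate = (ev[1] - ev[3]) <= 1e-12 * max(ev[1], 1e-12) ||
                ev[1] <= 1e-24,
              com = com)
  class(out) <- "gyration_summary"
  out
}

#' @export
print.gyration_summary <- function(x, ...) {
  cat(sprintf("Rg = %.4f nm; gyration eigenvalues (nm^2): %s%s\n", x$Rg,
              paste(signif(x$eigenvalues, 4), collapse = ", "),
              if (x$degenerate) " [degenerate axes]" else ""))
  invisible(x)
}
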