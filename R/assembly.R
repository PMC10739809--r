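# Fragment-pair recombination: cross-combine fragment conformers sharing a
# common domain, superpose at the shared domain, count interdomain steric
# clashes, filter at a clash-count threshold, and stitch accepted pairs
# into full-length conformers.

#' Assembly configuration
#'
#' Parameters of the fragment-recombination step. Pairs are kept when the
#' interdomain clash count is strictly below `threshold` (the published
#' bookkeeping: pairs with *fewer than* the threshold survive, pairs with
#' at least that many are discarded). The clash criterion itself is a
#' heavy-atom cross-pair distance below `cutoff` nm; a fixed small cutoff
#' flags genuine steric overlap (mainly surface side chains) rather than
#' mere contact.
#'
#' @param shared [domain_def()] of the domain present in both fragment
#'   pools (superposition anchor; C-SH2 analogue).
#' @param moving [domain_def()] of the clash-tested domain carried by the
#'   first pool (N-SH2 analogue).
#' @param static [domain_def()] of the clash-tested domain carried by the
#'   second pool (PTP analogue).
#' @param cutoff clash distance cutoff in nm (default 0.20).
#' @param threshold clash-count threshold (default 100): keep iff
#'   `count < threshold`.
#' @param junction residue number of the stitching seam; must lie inside
#'   the shared domain so that chain continuity is inherited from the
#'   shared-domain fit.
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(shared, moving, static, cutoff = 0.20,
                            threshold = 100, junction) {
  stopifnot(inherits(shared, "domain_def"), inherits(moving, "domain_def"),
            inherits(static, "domain_def"))
  if (cutoff <= 0) stopf("cutoff must be positive")
  if (!is_count(threshold) || threshold < 0) stopf("threshold must be >= 0")
  inside <- any(junction >= shared$ranges[, 1] & junction <= shared$ranges[, 2])
  if (!inside) stopf("junction residue %d is not inside the shared domain",
                     junction)
  structure(list(shared = shared, moving = moving, static = static,
                 cutoff = cutoff, threshold = threshold, junction = junction),
            class = "assembly_config")
}

#' Count interatomic clashes between two atom sets
#'
#' Number of cross pairs (one atom from each selection, both structures
#' already in a common frame) at distance strictly below `cutoff`.
#' Computed with a cell-list spatial grid; the result is identical to the
#' all-pairs brute force.
#'
#' @param a,b [structure3d()] objects or coordinate matrices (nm).
#' @param indices_a,indices_b atom selections (default all atoms).
#' @param cutoff distance cutoff, nm.
#' @return Integer clash count.
#' @export
count_clashes <- function(a, b, indices_a = NULL, indices_b = NULL,
                          cutoff = 0.20) {
  A <- coords_of(a, indices_a)
  B <- coords_of(b, indices_b)
  if (!nrow(A) || !nrow(B)) stopf("empty selection in clash count")
  if (cutoff <= 0) stopf("cutoff must be positive")
  # cell list with cell edge = cutoff; pad one empty layer so neighbor
  # arithmetic cannot alias across grid rows
  lo <- pmin(apply(A, 2, min), apply(B, 2, min))
  ca <- floor(sweep(A, 2, lo) / cutoff) + 1
  cb <- floor(sweep(B, 2, lo) / cutoff) + 1
  nd <- pmax(apply(ca, 2, max), apply(cb, 2, max)) + 2
  enc <- function(cc) cc[, 1] + nd[1] * (cc[, 2] + nd[2] * cc[, 3])
  codes_b <- enc(cb)
  bmap <- split(seq_len(nrow(B)), codes_b)
  amap <- split(seq_len(nrow(A)), enc(ca))
  noff <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  noff_code <- noff[, 1] + nd[1] * (noff[, 2] + nd[2] * noff[, 3])
  cut2 <- cutoff^2
  total <- 0L
  for (key in names(amap)) {
    cand <- unlist(bmap[as.character(as.numeric(key) + noff_code)],
                   use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    ai <- amap[[key]]
    d2 <- outer(rowSums(A[ai, , drop = FALSE]^2),
                rowSums(B[cand, , drop = FALSE]^2), `+`) -
      2 * tcrossprod(A[ai, , drop = FALSE], B[cand, , drop = FALSE])
    total <- total + sum(d2 < cut2)
  }
  as.integer(total)
}

#' Clash-filter a grid of fragment-pair combinations
#'
#' For every pair (i, j) of representatives from the two fragment pools:
#' superpose member i of `reps_a` onto member j of `reps_b` at the shared
#' domain's C-alpha atoms, count heavy-atom clashes between the moving
#' domain of i and the static domain of j, and flag the pair as passed
#' when the count is strictly below the configured threshold. With 20
#' representatives per pool this is the published 20 x 20 = 400-pair
#' screen.
#'
#' @param reps_a [ensemble3d()] of representatives carrying shared +
#'   moving domains.
#' @param reps_b [ensemble3d()] of representatives carrying shared +
#'   static domains.
#' @param config an [assembly_config()].
#' @return A list of class `clash_report`: `pairs` (data.frame `i`, `j`,
#'   `clashes`, `passed`), `summary` (counts of zero-clash, passing and
#'   failing pairs), `threshold`, `cutoff`.
#' @export
pair_filter <- function(reps_a, reps_b, config) {
  stopifnot(inherits(config, "assembly_config"))
  sa <- reps_a$members; sb <- reps_b$members
  fit_a <- select_atoms(sa[[1]], config$shared, atom_names = "CA")
  fit_b <- select_atoms(sb[[1]], config$shared, atom_names = "CA")
  if (length(fit_a) != length(fit_b))
    stopf("shared-domain CA selections differ between pools (%d vs %d)",
          length(fit_a), length(fit_b))
  mov <- select_atoms(sa[[1]], config$moving, heavy_only = TRUE)
  sta <- select_atoms(sb[[1]], config$static, heavy_only = TRUE)
  grid <- expand.grid(i = seq_along(sa), j = seq_along(sb))
  counts <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    i <- grid$i[r]; j <- grid$j[r]
    tr <- tryCatch(
      superpose(sa[[i]]$xyz[fit_a, , drop = FALSE],
                sb[[j]]$xyz[fit_b, , drop = FALSE]),
      error = function(e) stopf("superposition failed for pair (%d, %d): %s",
                                i, j, conditionMessage(e)))
    mov_xyz <- apply_transform(sa[[i]]$xyz[mov, , drop = FALSE], tr)
    counts[r] <- count_clashes(mov_xyz, sb[[j]]$xyz[sta, , drop = FALSE],
                               cutoff = config$cutoff)
  }
  pairs <- data.frame(i = grid$i, j = grid$j, clashes = counts,
                      passed = counts < config$threshold)
  out <- list(pairs = pairs,
              summary = c(zero = sum(counts == 0),
                          pass = sum(pairs$passed),
                          fail = sum(!pairs$passed)),
              threshold = config$threshold, cutoff = config$cutoff)
  class(out) <- "clash_report"
  out
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf(
    "clash_report: %d pairs | zero-clash %d, pass (< %d clashes) %d, fail %d\n",
    nrow(x$pairs), x$summary["zero"], x$threshold, x$summary["pass"],
    x$summary["fail"]))
  invisible(x)
}

#' Stitch an accepted fragment pair into a full-length conformer
#'
#' Superposes fragment `a` onto fragment `b` at the shared domain's
#' C-alpha atoms and merges the chains at the junction residue: residues
#' before the junction come from `a` (transformed), residues from the
#' junction onward come from `b`. Because the junction lies inside the
#' superposed rigid shared domain, backbone continuity across the seam is
#' inherited from the fit quality; the report carries the seam bond
#' length (C(junction-1)--N(junction), or the C-alpha pseudo-bond for
#' bead models) and the shared-domain fit RMSD.
#'
#' @param a,b [structure3d()] fragment conformers.
#' @param config an [assembly_config()].
#' @param check_clashes if `TRUE` (default), re-count clashes and refuse
#'   pairs at or above the threshold unless `override = TRUE`.
#' @param override assemble even a failing pair.
#' @return List of class `assembly_result`: `structure` (merged
#'   conformer), `junction` (residue), `seam_distance` (nm),
#'   `fit_rmsd` (nm), `clashes`.
#' @export
assemble_full_length <- function(a, b, config, check_clashes = TRUE,
                                 override = FALSE) {
  stopifnot(inherits(config, "assembly_config"))
  fit_a <- select_atoms(a, config$shared, atom_names = "CA")
  fit_b <- select_atoms(b, config$shared, atom_names = "CA")
  tr <- superpose(a$xyz[fit_a, , drop = FALSE], b$xyz[fit_b, , drop = FALSE])
  at <- apply_transform(a, tr)

  clashes <- NA_integer_
  if (check_clashes) {
    mov <- select_atoms(at, config$moving, heavy_only = TRUE)
    sta <- select_atoms(b, config$static, heavy_only = TRUE)
    clashes <- count_clashes(at$xyz[mov, , drop = FALSE],
                             b$xyz[sta, , drop = FALSE],
                             cutoff = config$cutoff)
    if (clashes >= config$threshold && !override)
      stopf("pair fails the clash filter (%d >= %d); use override = TRUE",
            clashes, config$threshold)
  }

  ia <- which(at$atoms$resno < config$junction)
  ib <- which(b$atoms$resno >= config$junction)
  if (!any(at$atoms$resno == config$junction - 1) &&
      !any(at$atoms$resno >= config$junction))
    stopf("junction region missing from fragment a")
  if (!any(b$atoms$resno == config$junction))
    stopf("junction residue %d missing from fragment b", config$junction)
  if (!length(ia)) stopf("no residues below the junction in fragment a")
  merged <- structure3d(rbind(at$atoms[ia, ], b$atoms[ib, ]),
                        rbind(at$xyz[ia, , drop = FALSE],
                              b$xyz[ib, , drop = FALSE]),
                        source = sprintf("assembled at residue %d",
                                         config$junction))

  seam <- seam_distance(at, b, config$junction)
  out <- list(structure = merged, junction = config$junction,
              seam_distance = seam, fit_rmsd = tr$rmsd, clashes = clashes)
  class(out) <- "assembly_result"
  out
}

# Peptide-bond distance across the stitching seam: C of the last a-side
# residue to N of the first b-side residue; bead models without backbone
# C/N fall back to the CA-CA pseudo-bond.
seam_distance <- function(a_fitted, b, junction) {
  pick <- function(s, resno, name) {
    i <- which(s$atoms$resno == resno & s$atoms$name == name)
    if (length(i)) s$xyz[i[1], ] else NULL
  }
  pc <- pick(a_fitted, junction - 1, "C")
  pn <- pick(b, junction, "N")
  if (is.null(pc) || is.null(pn)) {
    pc <- pick(a_fitted, junction - 1, "CA")
    pn <- pick(b, junction, "CA")
  }
  if (is.null(pc) || is.null(pn)) return(NA_real_)
  sqrt(sum((pc - pn)^2))
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf(
    "assembled conformer: %d atoms; seam at residue %d (%.3f nm), fit RMSD %.4g nm\n",
    nrow(x$structure$atoms), x$junction, x$seam_distance, x$fit_rmsd))
  invisible(x)
}

#' Write a clash-report matrix as CSV
#'
#' @param report a `clash_report` from [pair_filter()].
#' @param path output CSV path (columns i, j, clashes, passed).
#' @return `path`, invisibly.
#' @export
write_clash_csv <- function(report, path) {
  utils::write.csv(report$pairs, path, row.names = FALSE)
  invisible(path)
}
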