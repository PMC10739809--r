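#' Atomic structure container
#'
#' A `structure3d` holds one conformer: an atom table (name, element,
#' author residue number, residue name, chain) plus an `n x 3` coordinate
#' matrix in nanometres. Residue numbers are kept exactly as authored in
#' the source file (never renumbered), so published residue identifiers
#' such as Glu139 address atoms directly. All geometric and scattering
#' operations in the package consume this type.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`,
#'   `resid`, `chain` (one row per atom). `element` may be `"unknown"`
#'   for atoms whose element could not be resolved; such atoms are
#'   rejected later by mass- or form-factor-dependent operations.
#' @param xyz numeric matrix, `n x 3`, coordinates in nm.
#' @param source free-text provenance label (file, model number, ...).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz, source = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "resno", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stopf("xyz must have 3 columns")
  if (nrow(xyz) != nrow(atoms)) stopf("atom table (%d) and xyz (%d) differ",
                                      nrow(atoms), nrow(xyz))
  if (nrow(atoms) == 0) stopf("structure has zero atoms")
  if (!all(is.finite(xyz))) stopf("non-finite coordinates")
  # residue numbers must be non-decreasing within each chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r)) stopf("residue numbers not non-decreasing in chain '%s'", ch)
  }
  structure(list(atoms = atoms, xyz = xyz, source = source),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ", ")))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

#' Weighted conformer ensemble
#'
#' An ordered collection of [structure3d()] members sharing one atom
#' topology (same atom count, names and residue numbering), with
#' non-negative weights normalised to sum to one. This is the object the
#' fragment-recombination workflow builds, filters against clash counts
#' and validates against SAXS data.
#'
#' @param members list of `structure3d` objects with identical topology.
#' @param weights non-negative numeric weights; default uniform. They are
#'   normalised internally.
#' @return An object of class `ensemble3d`.
#' @export
ensemble3d <- function(members, weights = NULL) {
  if (inherits(members, "structure3d")) members <- list(members)
  if (!length(members)) stopf("ensemble needs at least one member")
  n0 <- n_atoms(members[[1]])
  for (k in seq_along(members)) {
    if (!inherits(members[[k]], "structure3d"))
      stopf("member %d is not a structure3d", k)
    if (n_atoms(members[[k]]) != n0)
      stopf("member %d has %d atoms, expected %d", k,
            n_atoms(members[[k]]), n0)
    if (!identical(members[[k]]$atoms$resno, members[[1]]$atoms$resno) ||
        !identical(members[[k]]$atoms$name, members[[1]]$atoms$name))
      stopf("member %d topology (atom names/residue numbers) differs", k)
  }
  if (is.null(weights)) weights <- rep(1, length(members))
  if (length(weights) != length(members))
    stopf("length(weights) != number of members")
  if (any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be non-negative with positive sum")
  structure(list(members = members, weights = weights / sum(weights)),
            class = "ensemble3d")
}

#' @export
print.ensemble3d <- function(x, ...) {
  cat(sprintf("ensemble3d: %d members x %d atoms\n",
              length(x$members), n_atoms(x$members[[1]])))
  invisible(x)
}

#' @export
length.ensemble3d <- function(x) length(x$members)

#' Domain definition by author residue ranges
#'
#' Names a domain (e.g. N-SH2, C-SH2, PTP) as a set of inclusive,
#' non-overlapping author-numbering residue intervals on one chain, the
#' way constructs are quoted in the structural literature (e.g. the
#' tandem SH2 fragment as residues 1--220).
#'
#' @param name domain name.
#' @param ranges two-column matrix or list of `c(lo, hi)` inclusive
#'   residue-number intervals; a single `c(lo, hi)` vector is accepted.
#' @param chain optional chain id; `NULL` matches any chain.
#' @return An object of class `domain_def`.
#' @export
domain_def <- function(name, ranges, chain = NULL) {
  if (is.numeric(ranges) && is.null(dim(ranges))) {
    if (length(ranges) != 2) stopf("a range vector must be c(lo, hi)")
    ranges <- matrix(ranges, ncol = 2)
  }
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2) stopf("ranges must have two columns (lo, hi)")
  if (any(ranges[, 1] > ranges[, 2])) stopf("range lo > hi in domain '%s'", name)
  ord <- order(ranges[, 1])
  ranges <- ranges[ord, , drop = FALSE]
  if (nrow(ranges) > 1 &&
      any(ranges[-1, 1] <= ranges[-nrow(ranges), 2]))
    stopf("overlapping residue ranges in domain '%s'", name)
  structure(list(name = name, ranges = ranges, chain = chain),
            class = "domain_def")
}

#' @export
print.domain_def <- function(x, ...) {
  rng <- apply(x$ranges, 1, function(r) paste0(r[1], "-", r[2]))
  cat(sprintf("domain '%s': residues %s%s\n", x$name,
              paste(rng, collapse = ", "),
              if (is.null(x$chain)) "" else paste0(" (chain ", x$chain, ")")))
  invisible(x)
}

#' Select atom indices by domain and atom-name filter
#'
#' Deterministically returns the sorted indices of the atoms of
#' `structure` falling inside the residue intervals of `domain`,
#' optionally restricted to named atoms (e.g. `"CA"`) or to heavy atoms.
#' If an atom-name filter removes every atom of a residue that lies in
#' the range, a warning names the residue.
#'
#' @param structure a [structure3d()].
#' @param domain a [domain_def()], or `NULL` for all residues.
#' @param atom_names optional character vector of atom names to keep
#'   (e.g. `"CA"` for the C-alpha trace).
#' @param heavy_only if `TRUE`, drop hydrogens (element `"H"`).
#' @return Sorted integer vector of atom indices (error if empty).
#' @export
select_atoms <- function(structure, domain = NULL, atom_names = NULL,
                         heavy_only = FALSE) {
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(domain)) {
    if (!inherits(domain, "domain_def")) stopf("domain must be a domain_def")
    inr <- rep(FALSE, nrow(at))
    for (k in seq_len(nrow(domain$ranges)))
      inr <- inr | (at$resno >= domain$ranges[k, 1] &
                    at$resno <= domain$ranges[k, 2])
    if (!is.null(domain$chain)) inr <- inr & at$chain == domain$chain
    keep <- keep & inr
  }
  pre <- keep
  if (heavy_only) keep <- keep & toupper(at$element) != "H"
  if (!is.null(atom_names)) {
    keep <- keep & at$name %in% atom_names
    lost <- unique(at$resno[pre & !at$resno %in% at$resno[keep]])
    if (length(lost))
      warnf("residue(s) %s contribute no atoms under filter {%s}",
            paste(utils::head(lost, 5), collapse = ","),
            paste(atom_names, collapse = ","))
  }
  idx <- sort(which(keep))
  if (!length(idx)) {
    rng <- if (is.null(domain)) "all residues" else
      paste(apply(domain$ranges, 1, function(r) paste0(r[1], "-", r[2])),
            collapse = ",")
    stopf("empty atom selection for %s", rng)
  }
  idx
}
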