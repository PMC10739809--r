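#' Read a (multi-model) PDB file into an ensemble
#'
#' Parses PDB v3.x ATOM/HETATM records (via bio3d), resolving alternate
#' locations by highest occupancy with an alphabetical tie-break, and
#' converts coordinates from Angstrom to the package's internal unit,
#' nanometre. Residue numbers are taken verbatim from the file (author
#' numbering, negative numbers allowed). Hydrogens are retained; they can
#' be excluded downstream with `heavy_only` selections.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` (default) reads only the first MODEL;
#'   `"all"` returns one ensemble member per MODEL.
#' @return An [ensemble3d()]; single-model files give a one-member
#'   ensemble (see [first_member()]).
#' @export
read_pdb <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stopf("cannot parse PDB '%s': %s", path,
                              conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stopf("PDB '%s' contains zero atoms", path)

  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]

  xyz_all <- pdb$xyz
  if (is.null(dim(xyz_all))) xyz_all <- matrix(xyz_all, nrow = 1)
  n_models <- nrow(xyz_all)
  col_keep <- as.numeric(t(outer(keep, 1:3, function(i, k) (i - 1) * 3 + k)))
  xyz_all <- xyz_all[, col_keep, drop = FALSE]

  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- "unknown"
  atoms <- data.frame(name = at$elety, element = elem, resno = at$resno,
                      resid = at$resid,
                      chain = ifelse(is.na(at$chain), " ", at$chain),
                      stringsAsFactors = FALSE)

  models <- if (model_policy == "first") 1L else seq_len(n_models)
  members <- lapply(models, function(m) {
    structure3d(atoms, unflatten_coords(xyz_all[m, ]) / 10,
                source = sprintf("%s model %d", basename(path), m))
  })
  ensemble3d(members)
}

# Alternate-location policy: per (chain, resno, insert, atom name) keep the
# single record with the highest occupancy; ties go to the alphabetically
# first altloc code.
resolve_altloc <- function(at) {
  alt <- at$alt
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  has_alt <- !is.na(alt) & alt != ""
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    best <- rows[order(-occ[rows], alt[rows])][1]
    keep[setdiff(rows, best)] <- FALSE
  }
  which(keep)
}

#' First member of an ensemble
#'
#' @param ensemble an [ensemble3d()].
#' @return The first [structure3d()] member.
#' @export
first_member <- function(ensemble) ensemble$members[[1]]

#' Write an ensemble as a (multi-model) PDB file
#'
#' Coordinates are converted nm to Angstrom and written with the standard
#' fixed-width ATOM records (0.001 A precision); multi-member ensembles
#' produce one MODEL/ENDMDL block per member, the interchange format used
#' for conformer ensembles. Values that do not fit the fixed-width fields
#' (residue numbers outside -999..9999, coordinates beyond +-9999.999 A)
#' raise an error instead of being silently truncated.
#'
#' @param ensemble an [ensemble3d()] or single [structure3d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ensemble, path) {
  if (inherits(ensemble, "structure3d")) ensemble <- ensemble3d(ensemble)
  if (!inherits(ensemble, "ensemble3d")) stopf("need an ensemble3d")
  at <- ensemble$members[[1]]$atoms
  if (any(at$resno > 9999 | at$resno < -999))
    stopf("residue number outside the PDB field range (-999..9999)")
  multi <- length(ensemble$members) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$members)) {
    s <- ensemble$members[[m]]
    ang <- s$xyz * 10
    if (any(abs(ang) > 9999.999))
      stopf("coordinate exceeds the PDB fixed-width field (|x| > 9999.999 A)")
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    nm <- s$atoms$name
    nm <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), nm)
    el <- ifelse(s$atoms$element == "unknown", "", s$atoms$element)
    serial <- seq_len(nrow(s$atoms))
    if (max(serial) > 99999) stopf("more than 99999 atoms")
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm, substr(s$atoms$resid, 1, 3), substr(s$atoms$chain, 1, 1),
      s$atoms$resno, ang[, 1], ang[, 2], ang[, 3], 1, 0, el)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
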