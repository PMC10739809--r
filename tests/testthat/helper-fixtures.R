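# Fixtures built in code: tiny PDB texts, bead structures, and the
# brute-force oracles the implementation is checked against.

toy_atoms <- function(n, resno = seq_len(n), name = "CA", element = "C") {
  data.frame(name = name, element = element, resno = resno, resid = "ALA",
             chain = "A", stringsAsFactors = FALSE)
}

toy_structure <- function(xyz, resno = seq_len(nrow(xyz)), name = "CA",
                          element = "C") {
  structure3d(toy_atoms(nrow(xyz), resno, name, element), xyz)
}

# Self-avoiding-ish random coil of n beads (nm), fixed step length.
random_coil <- function(n, step = 0.13, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  steps <- matrix(rnorm(n * 3), n, 3)
  steps <- steps / sqrt(rowSums(steps^2)) * step
  toy_structure(apply(steps, 2, cumsum))
}

# Quasi-uniform solid-sphere bead cloud: equal-volume radial shells,
# each a Fibonacci sphere (deterministic; for the analytic form-factor
# oracle).
sphere_cloud <- function(radius, n_shells = 60, per_shell = 60) {
  r <- radius * (((seq_len(n_shells)) - 0.5) / n_shells)^(1 / 3)
  xyz <- do.call(rbind, lapply(seq_len(n_shells), function(k)
    saxsemble:::fibonacci_sphere(per_shell) * r[k]))
  toy_structure(xyz)
}

# Analytic solid-sphere form factor, normalised to I(0) = 1.
sphere_form_factor <- function(q, R) {
  x <- q * R
  ifelse(x == 0, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# O(N^2) brute-force clash oracle.
brute_clashes <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sum(d2 < cutoff^2)
}

# Minimal hand-written PDB text (coordinates in Angstrom).
pdb_lines <- function(xyz_ang, resno = seq_len(nrow(xyz_ang)), name = "CA",
                      element = "C", altloc = " ", occ = 1,
                      resid = "ALA", chain = "A") {
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), name)
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(xyz_ang)), nm, altloc, resid, chain, resno,
          xyz_ang[, 1], xyz_ang[, 2], xyz_ang[, 3], occ, 0, element)
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# Small synthetic spec used across tests (fast).
small_spec <- function(seed = 7, ...) {
  synthetic_spec(seed = seed, n_members = c(ab = 25, bc = 25),
                 gt_pairs = 8, ...)
}
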