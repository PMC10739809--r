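# X-ray atomic form factors: 4-Gaussian + constant (Cromer-Mann)
# parameterisation, f(s) = c + sum_i a_i exp(-b_i s^2) with
# s = sin(theta)/lambda = q/(4*pi) in 1/Angstrom, plus effective
# displaced-solvent volumes per element (Fraser-style dummy atoms).

.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

# Displaced solvent volumes (A^3), Fraser/CRYSOL convention, stored in nm^3.
.displaced_volume_nm3 <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13,
                           P = 5.73, S = 19.86) * 1e-3

#' Elements covered by the form-factor table
#' @return Character vector of element symbols.
#' @export
form_factor_elements <- function() names(.cromer_mann)

#' Atomic X-ray form factor f(q)
#'
#' Vacuum scattering factor of a neutral element on a q grid in nm^-1,
#' from the 4-Gaussian + constant coefficients; `f(0)` equals the
#' element's electron count.
#'
#' @param element element symbol (must be in [form_factor_elements()]).
#' @param q scattering vector magnitudes, nm^-1.
#' @return Numeric vector `f(q)` in electrons.
#' @export
atomic_form_factor <- function(element, q) {
  cm <- .cromer_mann[[toupper(element)]]
  if (is.null(cm))
    stopf("element '%s' not in the form-factor table (%s)", element,
          paste(form_factor_elements(), collapse = ", "))
  s2 <- (q / 10 / (4 * pi))^2  # q [nm^-1] -> s [1/A], squared
  drop(cm$c + vapply(seq_len(length(q)), function(k)
    sum(cm$a * exp(-cm$b * s2[k])), numeric(1)))
}

displaced_volume <- function(element) {
  v <- .displaced_volume_nm3[toupper(element)]
  if (is.na(v)) stopf("no displaced-solvent volume for element '%s'", element)
  unname(v)
}

#' Per-scatterer contrast amplitudes with excluded-volume correction
#'
#' Contrast amplitude of every atom on the configured q grid:
#' `g_a(q) = f_a(q) - rho_s * V_a * exp(-q^2 * V_a^(2/3) / (4*pi))`,
#' the Gaussian dummy-atom model of the solvent displaced by the atom
#' (a Gaussian of integrated volume `V_a`, so that
#' `g_a(0) = Z_a - rho_s * V_a` exactly). With excluded-volume mode
#' `"none"` the vacuum amplitudes `f_a(q)` are returned; in uniform-bead
#' mode every scatterer has unit amplitude.
#'
#' @param structure a [structure3d()].
#' @param config a [saxs_config()].
#' @return Numeric matrix, atoms x length(q), of amplitudes (electrons).
#' @export
excluded_volume_correction <- function(structure, config) {
  amp <- amplitude_table(structure, config)
  unname(amp$g[amp$type, , drop = FALSE])
}

# Amplitudes grouped by scatterer type (one row per distinct element),
# plus the per-atom type index - the compact form the forward models use.
amplitude_table <- function(structure, config) {
  if (config$scatterer == "uniform-bead") {
    return(list(g = matrix(1, 1, length(config$q)),
                type = rep(1L, n_atoms(structure))))
  }
  el <- toupper(structure$atoms$element)
  types <- sort(unique(el))
  bad <- setdiff(types, form_factor_elements())
  if (length(bad))
    stopf("element(s) without form factors in atomic mode: %s",
          paste(bad, collapse = ", "))
  q <- config$q
  g <- t(vapply(types, function(e) {
    f <- atomic_form_factor(e, q)
    if (config$excluded_volume == "gaussian-dummy") {
      V <- displaced_volume(e)
      f <- f - config$rho_solvent * V * exp(-q^2 * V^(2 / 3) / (4 * pi))
    }
    f
  }, numeric(length(q))))
  list(g = g, type = match(el, types))
}
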