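# Guinier analysis and curve comparison.

#' Guinier fit of the low-q region
#'
#' Iterative linear fit of `ln I` versus `q^2`: fit, derive Rg from the
#' slope (`slope = -Rg^2/3`), truncate the window to `q * Rg <= qmax_rg`,
#' and refit until the window is stable. Returns the radius of gyration,
#' the forward intensity I(0), the fitted window and the goodness of fit.
#'
#' @param curve a [saxs_curve()].
#' @param qmax_rg Guinier validity bound on `qmax * Rg` (default 1.3, the
#'   usual convention for globular scatterers).
#' @param min_points minimum number of points in the fit window
#'   (default 5).
#' @return List of class `guinier_fit`: `Rg` (nm), `I0`, `q_window`,
#'   `n_points`, `qmax_rg` (achieved), `r_squared`.
#' @export
guinier_fit <- function(curve, qmax_rg = 1.3, min_points = 5) {
  ok <- which(curve$q > 0 & curve$I > 0)
  if (length(ok) < min_points)
    stopf("fewer than %d usable low-q points (q > 0, I > 0)", min_points)
  q2 <- curve$q[ok]^2
  lnI <- log(curve$I[ok])

  fit_window <- function(idx) {
    co <- stats::coef(stats::lm(lnI[idx] ~ q2[idx]))
    if (!is.finite(co[2]) || co[2] >= 0)
      stopf("Guinier fit has non-negative slope (no decaying low-q region)")
    list(Rg = unname(sqrt(-3 * co[2])), I0 = unname(exp(co[1])))
  }

  idx <- seq_len(min(length(ok), max(min_points, 15L)))
  prev <- integer(0)
  converged <- FALSE
  for (it in 1:100) {
    f <- fit_window(idx)
    new_idx <- which(curve$q[ok] * f$Rg <= qmax_rg)
    if (length(new_idx) < min_points)
      stopf("Guinier window shrank below %d points (qmax*Rg <= %.2f)",
            min_points, qmax_rg)
    if (identical(new_idx, idx)) { converged <- TRUE; break }
    if (identical(new_idx, prev)) {  # 2-cycle: keep the smaller window
      idx <- if (length(new_idx) < length(idx)) new_idx else idx
      f <- fit_window(idx)
      converged <- TRUE
      break
    }
    prev <- idx
    idx <- new_idx
  }
  if (!converged) stopf("Guinier window did not converge")
  r2 <- stats::cor(q2[idx], lnI[idx])^2
  out <- list(Rg = f$Rg, I0 = f$I0,
              q_window = range(curve$q[ok][idx]),
              n_points = length(idx),
              qmax_rg = max(curve$q[ok][idx]) * f$Rg,
              r_squared = r2)
  class(out) <- "guinier_fit"
  out
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.4f nm, I0 = %.4g (%d pts, q in [%.3g, %.3g], qmax*Rg = %.2f, r^2 = %.4f)\n",
    x$Rg, x$I0, x$n_points, x$q_window[1], x$q_window[2], x$qmax_rg,
    x$r_squared))
  invisible(x)
}

#' Fixed hydration-layer Rg offset
#'
#' Adds the configured constant (default 0.076 nm) to a bare-model radius
#' of gyration, the device by which implicit-solvent model Rg values are
#' made comparable to experimental ones that include the ordered
#' hydration shell.
#'
#' @param rg_bare bare radius of gyration, nm (> 0).
#' @param config a [saxs_config()] (uses `hydration_dRg`), or a number
#'   taken directly as the offset in nm.
#' @return Corrected Rg, nm.
#' @export
apply_hydration_offset <- function(rg_bare, config = saxs_config()) {
  if (any(rg_bare <= 0)) stopf("Rg must be positive")
  d <- if (is.numeric(config)) config else config$hydration_dRg
  rg_bare + d
}

#' Scale (and background) fit of a calculated curve to an experimental one
#'
#' Analytic weighted least squares for the scale factor (and an optional
#' constant background) mapping a calculated curve onto an experimental
#' curve with errors, plus the reduced chi-squared on the shared grid.
#' The calculated curve is interpolated linearly in q onto the
#' experimental grid over the overlapping range.
#'
#' @param calc calculated [saxs_curve()].
#' @param exp experimental [saxs_curve()] with `sigma`.
#' @param fit_background also fit a constant offset (default `FALSE`).
#' @return List: `scale`, `background` (0 when not fitted), `chi2_reduced`,
#'   `residuals` (sigma-weighted, on the experimental grid), `q`, `n`.
#' @export
fit_scale_and_compare <- function(calc, exp, fit_background = FALSE) {
  if (is.null(exp$sigma)) stopf("experimental curve needs errors (sigma)")
  keep <- exp$q >= min(calc$q) & exp$q <= max(calc$q)
  if (!any(keep)) stopf("no overlap between calculated and experimental q ranges")
  qe <- exp$q[keep]
  Ie <- exp$I[keep]
  se <- exp$sigma[keep]
  Ic <- stats::approx(calc$q, calc$I, xout = qe)$y
  w <- 1 / se^2
  if (fit_background) {
    X <- cbind(Ic, 1)
    A <- crossprod(X * w, X)
    beta <- solve(A, crossprod(X * w, Ie))
    scale <- beta[1]; bg <- beta[2]
  } else {
    scale <- sum(w * Ic * Ie) / sum(w * Ic^2)
    bg <- 0
  }
  res <- (Ie - scale * Ic - bg) / se
  p <- if (fit_background) 2 else 1
  list(scale = scale, background = bg,
       chi2_reduced = sum(res^2) / (length(res) - p),
       residuals = res, q = qe, n = length(res))
}
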