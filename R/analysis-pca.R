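# Essential-dynamics PCA of interdomain motion.

# Superpose every member onto a reference over fit_indices; returns the
# list of transformed coordinate matrices.
fit_members <- function(ensemble, ref_xyz, fit_indices) {
  lapply(ensemble$members, function(s) {
    tr <- superpose(s$xyz[fit_indices, , drop = FALSE],
                    ref_xyz[fit_indices, , drop = FALSE])
    apply_transform(s$xyz, tr)
  })
}

#' Principal component analysis of an ensemble
#'
#' Essential-dynamics PCA: members are least-squares superposed on the
#' fit selection onto an iteratively refined ensemble mean (two passes:
#' first onto member 1, then onto the resulting mean), and the covariance
#' of the analysis-selection coordinates is diagonalised. Separating the
#' fit selection (a rigid core used as the frame of reference) from the
#' analysis selection (the mobile part) isolates interdomain motion from
#' overall tumbling.
#'
#' @param ensemble an [ensemble3d()] with at least 2 members.
#' @param fit_indices atom indices defining the superposition frame.
#' @param analysis_indices atom indices whose fluctuations are analysed.
#' @return List of class `pca_model`: `eigenvalues` (descending, nm^2),
#'   `eigenvectors` (columns, orthonormal, over flattened analysis
#'   coordinates), `cumulative` variance fractions, `mean` (flattened
#'   analysis-coordinate mean), `fit_ref` (full reference coordinates),
#'   `fit_indices`, `analysis_indices`, `n_atoms`.
#' @export
pca_fit <- function(ensemble, fit_indices, analysis_indices) {
  if (length(ensemble$members) < 2) stopf("PCA needs at least 2 members")
  # pass 1: fit onto member 1, take the mean; pass 2: fit onto that mean
  f1 <- fit_members(ensemble, ensemble$members[[1]]$xyz, fit_indices)
  ref <- Reduce(`+`, f1) / length(f1)
  f2 <- fit_members(ensemble, ref, fit_indices)
  X <- do.call(rbind, lapply(f2, function(m)
    flatten_coords(m[analysis_indices, , drop = FALSE])))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (nrow(X) - 1)
  tot <- sum(ev)
  out <- list(eigenvalues = ev,
              eigenvectors = sv$v,
              cumulative = if (tot > 0) cumsum(ev) / tot else rep(NA_real_,
                                                                  length(ev)),
              mean = ctr, fit_ref = ref,
              fit_indices = fit_indices, analysis_indices = analysis_indices,
              n_atoms = n_atoms(ensemble$members[[1]]))
  class(out) <- "pca_model"
  out
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat(sprintf("pca_model: %d modes; top-%d variance fractions: %s\n",
              length(x$eigenvalues), k,
              paste(signif(x$cumulative[1:k], 3), collapse = ", ")))
  invisible(x)
}

#' Project conformers onto principal components
#'
#' Members are superposed onto the model's fitting reference over the fit
#' selection, centred with the stored mean and dotted with the
#' eigenvectors. Projecting the training ensemble reproduces the
#' eigenvalues as per-component variances.
#'
#' @param model a [pca_model] from [pca_fit()].
#' @param ensemble an [ensemble3d()] (or a single [structure3d()]) with
#'   the training topology.
#' @param n_components number of components to return (default all).
#' @return Numeric matrix, members x components.
#' @export
pca_project <- function(model, ensemble, n_components = NULL) {
  if (inherits(ensemble, "structure3d")) ensemble <- ensemble3d(ensemble)
  if (n_atoms(ensemble$members[[1]]) != model$n_atoms)
    stopf("topology mismatch: %d atoms vs model's %d",
          n_atoms(ensemble$members[[1]]), model$n_atoms)
  k <- n_components %||% ncol(model$eigenvectors)
  fitted <- fit_members(ensemble, model$fit_ref, model$fit_indices)
  X <- do.call(rbind, lapply(fitted, function(m)
    flatten_coords(m[model$analysis_indices, , drop = FALSE])))
  proj <- sweep(X, 2, model$mean) %*% model$eigenvectors[, seq_len(k),
                                                         drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  proj
}
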