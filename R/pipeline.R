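# Configuration-driven orchestration of the full workflow: load or
# generate fragment pools, cluster each pool, recombine top
# representatives under the clash filter, stitch survivors into
# full-length conformers, validate with SAXS/Guinier, and run the
# ensemble analytics.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_spec()] to generate the fragment pools,
#'   or `NULL` to read them from `ab_path`/`bc_path`.
#' @param ab_path,bc_path multi-model PDB paths of the two fragment
#'   pools (used when `synthetic` is `NULL`).
#' @param domains list with [domain_def()]s `A` (moving), `B` (shared),
#'   `C` (static); filled automatically for synthetic input.
#' @param junction stitching residue (inside domain B); automatic for
#'   synthetic input.
#' @param n_representatives representatives taken per fragment pool
#'   (default 20, giving the 20 x 20 pair grid).
#' @param cluster_cutoff RMSD cutoff for the pool clustering, nm;
#'   default 0.10, about a quarter of the bead spacing, which resolves
#'   the default synthetic pools into more clusters than representatives
#'   are requested (all-atom ensembles typically use ~0.3).
#' @param clash_cutoff,clash_threshold clash criterion and pass
#'   threshold (defaults 0.38 nm - the residue-bead overlap criterion
#'   matching the default synthetic input; use ~0.20 nm for all-atom
#'   heavy-atom structures - and 100).
#' @param saxs a [saxs_config()]; default uses uniform beads on a
#'   0--3 nm^-1 grid (appropriate for the bead-model toys; switch to
#'   atomic mode for all-atom input).
#' @param dihedral_resnos four residue numbers of the rotation dihedral;
#'   automatic for synthetic input.
#' @param experimental_curve optional path to a measured SAXS curve for
#'   the chi-squared comparison.
#' @param fes_bins,density_spacing analytics bin parameters; the default
#'   12 bins per axis keeps free-energy bins populated at the few-hundred
#'   conformer scale of the default run.
#' @param out_dir output directory for the report and artifacts.
#' @param seed integer seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            ab_path = NULL, bc_path = NULL,
                            domains = NULL, junction = NULL,
                            n_representatives = 20,
                            cluster_cutoff = 0.10,
                            clash_cutoff = 0.38, clash_threshold = 100,
                            saxs = saxs_config(scatterer = "uniform-bead"),
                            dihedral_resnos = NULL,
                            experimental_curve = NULL,
                            fes_bins = 12, density_spacing = 0.2,
                            out_dir = tempfile("saxsemble_run_"),
                            seed = 1) {
  if (is.null(synthetic) && (is.null(ab_path) || is.null(bc_path)))
    stopf("provide either a synthetic spec or both fragment PDB paths")
  if (!is.null(experimental_curve) && !file.exists(experimental_curve))
    stopf("experimental curve not found: %s", experimental_curve)
  if (n_representatives < 1) stopf("n_representatives must be >= 1")
  structure(list(synthetic = synthetic, ab_path = ab_path, bc_path = bc_path,
                 domains = domains, junction = junction,
                 n_representatives = n_representatives,
                 cluster_cutoff = cluster_cutoff,
                 clash_cutoff = clash_cutoff,
                 clash_threshold = clash_threshold,
                 saxs = saxs, dihedral_resnos = dihedral_resnos,
                 experimental_curve = experimental_curve,
                 fes_bins = fes_bins, density_spacing = density_spacing,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[saxsemble] ", fmt), ...))
}

#' Run the full fragment-recombination + validation pipeline
#'
#' Stages, in order: load or generate the fragment pools; cluster each
#' pool and take the most-populated-cluster representatives; clash-filter
#' all pairwise recombinations; stitch the passing pairs into full-length
#' conformers; per-conformer SAXS with Guinier Rg and the hydration
#' offset; ensemble-averaged SAXS (plus chi-squared against an
#' experimental curve when provided); ensemble analytics (PCA of the
#' mobile domain in the static-domain frame, free-energy surface on
#' PC1/PC2, rotation-dihedral distribution, mobile-domain COM distances
#' and 3D density map). All artifacts are written under
#' `config$out_dir`; the machine-readable `report.json` carries the seed
#' and configuration echo for provenance.
#'
#' @param config a [pipeline_config()].
#' @param verbose stage-level progress messages (default `TRUE`).
#' @return The report, invisibly also written as JSON: a nested list with
#'   elements `pairs`, `assembly`, `saxs`, `clusters`, `analytics`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]

  # -- stage 1: fragment pools -------------------------------------------
  if (!is.null(config$synthetic)) {
    gen <- generate_fragment_ensembles(config$synthetic)
    ab <- gen$ab; bc <- gen$bc
    domains <- config$domains %||% gen$ground_truth$domains
    junction <- config$junction %||% gen$ground_truth$junction
    dihedral_resnos <- config$dihedral_resnos %||%
      gen$ground_truth$dihedral_resnos
  } else {
    ab <- read_pdb(config$ab_path, model_policy = "all")
    bc <- read_pdb(config$bc_path, model_policy = "all")
    domains <- config$domains
    junction <- config$junction
    dihedral_resnos <- config$dihedral_resnos
    if (is.null(domains) || is.null(junction))
      stopf("domains and junction are required for PDB input")
  }
  stage_msg(verbose, "fragments: %d AB + %d BC members (%.1f s)",
            length(ab), length(bc), proc.time()[3] - t0)

  # -- stage 2: per-pool clustering and representatives ------------------
  ca_b_ab <- select_atoms(ab$members[[1]], domains$B, atom_names = "CA")
  ca_b_bc <- select_atoms(bc$members[[1]], domains$B, atom_names = "CA")
  ca_all_ab <- select_atoms(ab$members[[1]], NULL, atom_names = "CA")
  ca_all_bc <- select_atoms(bc$members[[1]], NULL, atom_names = "CA")
  cl_ab <- cluster_gromos(ab, ca_all_ab, fit_indices = ca_b_ab,
                          cutoff = config$cluster_cutoff)
  cl_bc <- cluster_gromos(bc, ca_all_bc, fit_indices = ca_b_bc,
                          cutoff = config$cluster_cutoff)
  k <- config$n_representatives
  reps_ab <- cluster_representatives(cl_ab, ab, k)
  reps_bc <- cluster_representatives(cl_bc, bc, k)
  ks <- unique(pmin(c(1, 5, 10, 20), nrow(cl_ab$clusters)))
  stage_msg(verbose,
            "clustering: %d + %d clusters; using %d + %d representatives (%.1f s)",
            nrow(cl_ab$clusters), nrow(cl_bc$clusters), length(reps_ab),
            length(reps_bc), proc.time()[3] - t0)

  # -- stage 3: pairwise clash filter ------------------------------------
  acfg <- assembly_config(shared = domains$B, moving = domains$A,
                          static = domains$C, cutoff = config$clash_cutoff,
                          threshold = config$clash_threshold,
                          junction = junction)
  report_pairs <- pair_filter(reps_ab, reps_bc, acfg)
  write_clash_csv(report_pairs, file.path(config$out_dir, "clash_matrix.csv"))
  stage_msg(verbose, "pair filter: %d pairs, %d pass, %d zero-clash (%.1f s)",
            nrow(report_pairs$pairs), report_pairs$summary["pass"],
            report_pairs$summary["zero"], proc.time()[3] - t0)

  # -- stage 4: assembly of passing pairs --------------------------------
  passing <- report_pairs$pairs[report_pairs$pairs$passed, , drop = FALSE]
  if (nrow(passing) == 0)
    warnf("no pair passed the clash filter; the assembled ensemble is empty")
  assembled <- vector("list", nrow(passing))
  seams <- numeric(nrow(passing))
  for (r in seq_len(nrow(passing))) {
    ar <- assemble_full_length(reps_ab$members[[passing$i[r]]],
                               reps_bc$members[[passing$j[r]]],
                               acfg, check_clashes = FALSE)
    assembled[[r]] <- ar$structure
    seams[r] <- ar$seam_distance
  }
  full <- if (nrow(passing)) ensemble3d(assembled) else NULL
  if (!is.null(full))
    write_pdb(full, file.path(config$out_dir, "ensemble.pdb"))
  stage_msg(verbose, "assembled %d full-length conformers (%.1f s)",
            length(assembled), proc.time()[3] - t0)

  # -- stage 5/6: SAXS + Guinier -----------------------------------------
  saxs_block <- NULL
  if (!is.null(full)) {
    curves <- lapply(full$members, saxs_debye, config = config$saxs)
    rgs <- vapply(curves, function(cv)
      guinier_fit(cv)$Rg, numeric(1))
    rgs_corr <- apply_hydration_offset(rgs, config$saxs)
    ens_curve <- ensemble_saxs(full, config$saxs, member_curves = curves)
    write_saxs_curve(ens_curve,
                     file.path(config$out_dir, "ensemble_saxs.dat"))
    ens_rg <- apply_hydration_offset(guinier_fit(ens_curve)$Rg, config$saxs)
    utils::write.csv(data.frame(i = passing$i, j = passing$j,
                                clashes = passing$clashes,
                                seam_nm = seams, rg_bare = rgs,
                                rg_hydrated = rgs_corr),
                     file.path(config$out_dir, "conformers.csv"),
                     row.names = FALSE)
    chi2 <- NULL
    if (!is.null(config$experimental_curve)) {
      expc <- read_saxs_curve(config$experimental_curve)
      cmp <- fit_scale_and_compare(ens_curve, expc)
      chi2 <- cmp$chi2_reduced
    }
    saxs_block <- list(rg_bare_range = range(rgs),
                       rg_hydrated_range = range(rgs_corr),
                       rg_ensemble = ens_rg, chi2_reduced = chi2)
    stage_msg(verbose,
              "SAXS: ensemble Rg %.3f nm; model Rg (hydrated) %.2f-%.2f nm (%.1f s)",
              ens_rg, min(rgs_corr), max(rgs_corr), proc.time()[3] - t0)
  }

  # -- stage 7: ensemble analytics ---------------------------------------
  # 7a: landscape of the shared-to-static domain roto-translation,
  # computed on the BC pool (shared-domain core analysed in the
  # static-domain frame), with the rotation-dihedral distribution
  idx_B_bc <- select_atoms(bc$members[[1]], domains$B, atom_names = "CA")
  idx_C_bc <- select_atoms(bc$members[[1]], domains$C, atom_names = "CA")
  pca_bc <- pca_fit(bc, fit_indices = idx_C_bc, analysis_indices = idx_B_bc)
  proj_bc <- pca_project(pca_bc, bc, n_components = 2)
  fes <- free_energy_surface(proj_bc, bins = config$fes_bins)
  utils::write.table(fes$F, file.path(config$out_dir, "fes.txt"),
                     row.names = FALSE, col.names = FALSE)
  barrier <- NA_real_
  basins <- fes_minima(fes, 2)
  if (nrow(basins) == 2) {
    mp <- tryCatch(min_free_energy_path(fes, basins[1, ], basins[2, ]),
                   error = function(e) NULL)
    if (!is.null(mp)) barrier <- mp$barrier
  }
  dih <- dihedral_series(bc, dihedral_resnos)

  # 7b: mobile-domain analytics on the assembled full-length ensemble
  analytics_full <- NULL
  if (!is.null(full) && length(full) >= 2) {
    s1 <- full$members[[1]]
    idx_A <- select_atoms(s1, domains$A)
    idx_C_ca <- select_atoms(s1, domains$C, atom_names = "CA")
    pca <- pca_fit(full, fit_indices = idx_C_ca, analysis_indices = idx_A)
    proj <- pca_project(pca, full, n_components = min(5, length(full) - 1))
    utils::write.csv(as.data.frame(proj),
                     file.path(config$out_dir, "projections.csv"),
                     row.names = FALSE)
    dser <- com_distance_series(full, idx_A, idx_C_ca, reference = s1,
                                weighting = "uniform")
    dmap <- density_map(full, idx_A, idx_C_ca,
                        spacing = config$density_spacing,
                        weighting = "uniform")
    write_density_text(dmap, file.path(config$out_dir, "density_map.txt"))
    analytics_full <- list(
      pca_top5_fraction = pca$cumulative[min(5, length(pca$cumulative))],
      pc1_fraction = pca$cumulative[1],
      d_com_range = range(dser$d),
      density_iso = iso_levels(dmap))
  }
  analytics <- c(list(
    bc_pc2_fraction = pca_bc$cumulative[min(2, length(pca_bc$cumulative))],
    fes_barrier = barrier,
    dihedral_peaks = utils::head(dih$peaks$center, 3)),
    analytics_full)
  stage_msg(verbose, "analytics done (%.1f s)", proc.time()[3] - t0)

  report <- list(
    provenance = list(seed = config$seed,
                      n_representatives = config$n_representatives,
                      clash_cutoff = config$clash_cutoff,
                      clash_threshold = config$clash_threshold,
                      cluster_cutoff = config$cluster_cutoff),
    clusters = list(
      ab = list(n = nrow(cl_ab$clusters),
                cumulative_fraction = cumulative_cluster_fraction(cl_ab, ks)),
      bc = list(n = nrow(cl_bc$clusters),
                cumulative_fraction = cumulative_cluster_fraction(cl_bc, ks))),
    pairs = list(n = nrow(report_pairs$pairs),
                 zero = unname(report_pairs$summary["zero"]),
                 pass = unname(report_pairs$summary["pass"]),
                 fail = unname(report_pairs$summary["fail"]),
                 threshold = report_pairs$threshold),
    assembly = list(n = length(assembled),
                    seam_max_nm = if (length(assembled)) max(seams) else NA),
    saxs = saxs_block,
    analytics = analytics)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(report)
}

# Plain-text 3D density grid: header lines then one voxel per line.
write_density_text <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin_nm %g %g %g", map$origin[1], map$origin[2],
                     map$origin[3]), con)
  writeLines(sprintf("# spacing_nm %g", map$spacing), con)
  writeLines(sprintf("# dims %d %d %d", dim(map$density)[1],
                     dim(map$density)[2], dim(map$density)[3]), con)
  idx <- which(map$density > 0, arr.ind = TRUE)
  writeLines(sprintf("%d %d %d %.10g", idx[, 1], idx[, 2], idx[, 3],
                     map$density[idx]), con)
  invisible(path)
}
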