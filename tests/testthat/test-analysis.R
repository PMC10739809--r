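test_that("PCA recovers planted modes and degenerate limits", {
  # identical members: all eigenvalues zero
  s <- toy_structure(matrix(rnorm(30), 10, 3))
  same <- ensemble3d(list(s, s, s))
  pm0 <- pca_fit(same, 1:10, 1:10)
  expect_lt(max(pm0$eigenvalues), 1e-20)
  expect_error(pca_fit(ensemble3d(list(s)), 1:10, 1:10), "at least 2")

  # single planted hinge rotation: PC1 dominates
  sp <- synthetic_spec(seed = 13, n_members = c(ab = 80, bc = 2),
                       clash_fraction = 0, hinge_open_sd_deg = 8)
  g <- generate_fragment_ensembles(sp)
  gt <- g$ground_truth
  fitB <- select_atoms(g$ab$members[[1]], gt$domains$B, atom_names = "CA")
  idxA <- select_atoms(g$ab$members[[1]], gt$domains$A)
  pm <- pca_fit(g$ab, fitB, idxA)
  expect_gt(pm$cumulative[1], 0.95)
  expect_equal(pm$cumulative[length(pm$cumulative)], 1, tolerance = 1e-9)
  # eigenvector orthonormality
  V <- pm$eigenvectors[, 1:5]
  expect_equal(crossprod(V), diag(5), tolerance = 1e-8)
  # eigenvalue sum equals the total variance of the fitted coordinates
  pr_all <- pca_project(pm, g$ab)
  expect_equal(sum(apply(pr_all, 2, var)), sum(pm$eigenvalues),
               tolerance = 1e-8)

  # two independent planted translation modes with variance ratio 2:1
  sp2 <- synthetic_spec(seed = 17, n_members = c(ab = 1500, bc = 2),
                        clash_fraction = 0, hinge_open_sd_deg = 0,
                        extra_modes = list(
                          list(type = "translation", axis = c(1, 0, 0),
                               sd = 0.2 * sqrt(2)),
                          list(type = "translation", axis = c(0, 1, 0),
                               sd = 0.2)))
  g2 <- generate_fragment_ensembles(sp2)
  pm2 <- pca_fit(g2$ab,
                 select_atoms(g2$ab$members[[1]],
                              g2$ground_truth$domains$B, atom_names = "CA"),
                 select_atoms(g2$ab$members[[1]],
                              g2$ground_truth$domains$A))
  expect_equal(pm2$eigenvalues[1] / pm2$eigenvalues[2], 2, tolerance = 0.1)
})

test_that("projections reproduce eigenvalues and planted displacements", {
  sp <- synthetic_spec(seed = 13, n_members = c(ab = 40, bc = 2),
                       clash_fraction = 0, hinge_open_sd_deg = 8)
  g <- generate_fragment_ensembles(sp)
  gt <- g$ground_truth
  fitB <- select_atoms(g$ab$members[[1]], gt$domains$B, atom_names = "CA")
  idxA <- select_atoms(g$ab$members[[1]], gt$domains$A)
  pm <- pca_fit(g$ab, fitB, idxA)
  pr <- pca_project(pm, g$ab)
  expect_equal(var(pr[, 1]), pm$eigenvalues[1], tolerance = 1e-8)
  expect_equal(colMeans(pr)[1:3], c(PC1 = 0, PC2 = 0, PC3 = 0),
               tolerance = 1e-8)

  # held-out member: reference mean + c * eigenvector projects to (c, 0, ...)
  ref <- pm$fit_ref
  held <- ref
  cshift <- 0.37
  held[idxA, ] <- saxsemble:::unflatten_coords(
    pm$mean + cshift * pm$eigenvectors[, 1])
  hs <- g$ab$members[[1]]
  hs$xyz <- held
  prh <- pca_project(pm, hs, n_components = 3)
  expect_equal(as.numeric(prh), c(cshift, 0, 0), tolerance = 1e-6)
  # topology mismatch errors
  expect_error(pca_project(pm, toy_structure(matrix(rnorm(9), 3, 3))),
               "topology")
})

test_that("neighbor-counting clustering recovers planted partitions", {
  set.seed(23)
  base1 <- matrix(rnorm(30), 10, 3)
  base2 <- base1 + 5
  mk <- function(base, eps) toy_structure(base + matrix(rnorm(30, 0, eps),
                                                        10, 3))
  members <- c(lapply(1:7, function(i) mk(base1, 0.005)),
               lapply(1:3, function(i) mk(base2, 0.005)))
  ens <- ensemble3d(members)
  cl <- cluster_gromos(ens, 1:10, cutoff = 0.05)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$size, c(7, 3))
  expect_true(all(cl$labels[1:7] == 1) && all(cl$labels[8:10] == 2))
  # giant cutoff: one cluster; tiny cutoff: all singletons
  expect_equal(nrow(cluster_gromos(ens, 1:10, cutoff = 1e6)$clusters), 1)
  expect_equal(nrow(cluster_gromos(ens, 1:10, cutoff = 1e-9)$clusters), 10)
})

test_that("clustering is permutation-stable up to relabeling", {
  set.seed(29)
  members <- lapply(1:12, function(i)
    toy_structure(matrix(rnorm(30, sd = 0.6), 10, 3)))
  ens <- ensemble3d(members)
  cl1 <- cluster_gromos(ens, 1:10, cutoff = 1.2)
  perm <- sample(12)
  cl2 <- cluster_gromos(ensemble3d(members[perm]), 1:10, cutoff = 1.2)
  # same partition of members after undoing the permutation
  part1 <- split(seq_len(12), cl1$labels)
  part2 <- split(perm, cl2$labels[order(seq_len(12))])
  norm <- function(p) unname(lapply(p, sort))
  expect_setequal(vapply(norm(part1), paste, "", collapse = ","),
                  vapply(norm(part2), paste, "", collapse = ","))
})

test_that("cumulative cluster fractions behave like a CDF", {
  labels <- rep(1:3, times = c(50, 30, 20))
  fake <- list(labels = labels,
               clusters = data.frame(label = 1:3, size = c(50, 30, 20),
                                     representative = 1:3),
               cutoff = 0.1)
  class(fake) <- "cluster_result"
  expect_equal(unname(cumulative_cluster_fraction(fake, c(1, 2))),
               c(0.5, 0.8))
  expect_equal(unname(cumulative_cluster_fraction(fake, 3)), 1)
  expect_error(cumulative_cluster_fraction(fake, 0), ">= 1")
  # monotonicity over random partitions
  set.seed(31)
  for (r in 1:100) {
    sizes <- sort(sample(1:30, sample(2:8, 1)), decreasing = TRUE)
    fk <- list(labels = rep(seq_along(sizes), times = sizes),
               clusters = data.frame(label = seq_along(sizes), size = sizes,
                                     representative = seq_along(sizes)))
    class(fk) <- "cluster_result"
    fr <- cumulative_cluster_fraction(fk, seq_along(sizes))
    expect_true(all(diff(fr) >= 0))
    expect_equal(unname(fr[length(fr)]), 1)
  }
})

test_that("dihedral series recovers planted values and mixture peaks", {
  # single-member ensemble: one angle, one occupied bin
  sp <- small_spec()
  g <- generate_fragment_ensembles(sp)
  gt <- g$ground_truth
  one <- ensemble3d(g$bc$members[[1]])
  d1 <- dihedral_series(one, gt$dihedral_resnos)
  expect_equal(sum(d1$counts), 1)
  # per-member angles equal the planted spin exactly
  ds <- dihedral_series(g$bc, gt$dihedral_resnos)
  expect_equal(saxsemble:::wrap_angle(ds$angles - gt$dihedral_deg),
               rep(0, length(ds$angles)), tolerance = 1e-9)
  # planted mixture at -100 / -30 degrees: top two peaks within one bin
  gbig <- generate_fragment_ensembles(
    synthetic_spec(seed = 41, n_members = c(ab = 2, bc = 2000)))
  db <- dihedral_series(gbig$bc, gbig$ground_truth$dihedral_resnos)
  top2 <- sort(db$peaks$center[1:2])
  expect_lte(abs(top2[1] - (-100)), 7.5)
  expect_lte(abs(top2[2] - (-30)), 7.5)
  expect_error(dihedral_series(g$bc, c(1, 2, 3, 99999)), "no CA")
})

test_that("free-energy surfaces Boltzmann-invert histogram ratios exactly", {
  # all samples in one bin: F = 0 there, everything else masked
  p1 <- matrix(rep(c(0.5, 0.5), 10), ncol = 2, byrow = TRUE)
  f1 <- free_energy_surface(p1, bins = 4)
  expect_equal(sum(!is.na(f1$F)), 1)
  expect_equal(min(f1$F, na.rm = TRUE), 0)
  # two occupied bins: delta F = -kT log(n1/n2) exactly
  kT <- 2.478
  pts <- rbind(matrix(rep(c(0.1, 0.1), 50), ncol = 2, byrow = TRUE),
               matrix(rep(c(0.9, 0.9), 20), ncol = 2, byrow = TRUE))
  f2 <- free_energy_surface(pts, bins = 2, kT = kT)
  occ <- sort(f2$F[!is.na(f2$F)])
  expect_equal(occ[2] - occ[1], -kT * log(20 / 50), tolerance = 1e-12)
  # two planted 2D Gaussians with 10:1 weights: basin depth ~ kT ln 10
  set.seed(43)
  n <- 1e5
  pick <- runif(n) < 10 / 11
  xy <- cbind(rnorm(n, ifelse(pick, -2, 2), 0.4),
              rnorm(n, 0, 0.4))
  fg <- free_energy_surface(xy, bins = 40, kT = kT)
  mins <- fes_minima(fg, 2)
  dF <- abs(fg$F[mins[1, 1], mins[1, 2]] - fg$F[mins[2, 1], mins[2, 2]])
  expect_equal(dF, kT * log(10), tolerance = 0.15 * kT * log(10))
  expect_error(free_energy_surface(xy[0, , drop = FALSE]), "samples")
})

test_that("minimax path finds the planted saddle barrier", {
  kT <- 2.478
  # 1D double well embedded in 2D, built from deterministic bin counts:
  # F(x) profile 0 .. 4 .. 0.5 kJ/mol across 9 bins
  Fprof <- c(0, 0.5, 1.5, 3, 4, 3, 1.5, 1, 0.5)
  counts <- round(4000 * exp(-Fprof / kT))
  xs <- rep(seq_along(Fprof) - 0.5, times = counts)
  pts <- cbind(xs, 0.5)
  fes <- free_energy_surface(pts, edges = list(0:9, 0:1), kT = kT)
  expect_equal(dim(fes$F), c(9, 1))
  mp <- min_free_energy_path(fes, c(1, 1), c(9, 1))
  # barrier equals the planted saddle up to count rounding
  expect_equal(mp$barrier, 4, tolerance = 0.05)
  expect_equal(nrow(mp$path), 9)
  # flat surface: zero barrier; equal endpoints: empty path
  flat <- free_energy_surface(cbind(rep(1:4, each = 25) + 0.5, 0.5),
                              edges = list(1:5, 0:1), kT = kT)
  expect_equal(min_free_energy_path(flat, c(1, 1), c(4, 1))$barrier, 0)
  expect_equal(min_free_energy_path(flat, c(2, 1), c(2, 1))$barrier, 0)
  # disconnected basins error
  gap <- free_energy_surface(rbind(cbind(rep(0.5, 10), 0.5),
                                   cbind(rep(8.5, 10), 0.5)),
                             edges = list(0:9, 0:1), kT = kT)
  expect_error(min_free_energy_path(gap, c(1, 1), c(9, 1)), "disconnected")
})

test_that("COM distance series measures planted displacements", {
  gen <- generate_fragment_ensembles(small_spec())
  gt <- gen$ground_truth
  s <- gen$ab$members[[1]]
  idxA <- select_atoms(s, gt$domains$A)
  fitB <- select_atoms(s, gt$domains$B, atom_names = "CA")
  # member vs itself: zero distance
  d0 <- com_distance_series(ensemble3d(s), idxA, fitB, reference = s,
                            weighting = "uniform")
  expect_lt(d0$d, 1e-9)
  # mobile domain rigidly shifted 2 nm with the fit region untouched
  s2 <- s
  s2$xyz[idxA, ] <- s2$xyz[idxA, ] + matrix(c(2, 0, 0), length(idxA), 3,
                                            byrow = TRUE)
  d2 <- com_distance_series(ensemble3d(s2), idxA, fitB, reference = s,
                            weighting = "uniform")
  expect_equal(d2$d, 2, tolerance = 1e-9)
  # invariance under a global rigid motion of the member
  tr <- list(rotation = saxsemble:::rotation_about_axis(c(0, 1, 1), 2),
             translation = c(1, 2, 3))
  class(tr) <- "rigid_transform"
  d3 <- com_distance_series(ensemble3d(apply_transform(s2, tr)), idxA, fitB,
                            reference = s, weighting = "uniform")
  expect_equal(d3$d, d2$d, tolerance = 1e-9)
})

test_that("density maps localise planted COM clouds and normalise", {
  gen <- generate_fragment_ensembles(small_spec())
  gt <- gen$ground_truth
  s <- gen$ab$members[[1]]
  idxA <- select_atoms(s, gt$domains$A)
  fitB <- select_atoms(s, gt$domains$B, atom_names = "CA")
  # all members identical: a single occupied voxel of density 1
  ens_same <- ensemble3d(rep(list(s), 5))
  m1 <- density_map(ens_same, idxA, fitB, weighting = "uniform")
  expect_equal(sum(m1$density > 0), 1)
  expect_equal(max(m1$density), 1)
  # planted Gaussian cloud of shifted copies: density max within one
  # voxel of the planted mean
  set.seed(47)
  mu <- c(1.2, -0.8, 0.5)
  members <- lapply(1:200, function(i) {
    sh <- s
    sh$xyz[idxA, ] <- sh$xyz[idxA, ] +
      matrix(mu + rnorm(3, 0, 0.15), length(idxA), 3, byrow = TRUE)
    sh
  })
  m2 <- density_map(ensemble3d(members), idxA, fitB, reference = s,
                    spacing = 0.2, weighting = "uniform")
  expect_equal(sum(m2$density), 1, tolerance = 1e-12)
  peak <- which(m2$density == max(m2$density), arr.ind = TRUE)[1, ]
  peak_center <- m2$origin + (peak - 0.5) * m2$spacing
  planted <- center_of_mass(s, idxA, weighting = "uniform") + mu
  expect_lt(max(abs(peak_center - planted)), 1.5 * m2$spacing)
  lv <- iso_levels(m2)
  expect_equal(unname(lv[1] / lv[2]), 100, tolerance = 1e-9)
})
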