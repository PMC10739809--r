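test_that("clash counting matches the closed-form cases", {
  A <- matrix(c(0, 0, 0), 1, 3)
  B <- matrix(c(100, 0, 0), 1, 3)
  expect_identical(count_clashes(A, B, cutoff = 0.2), 0L)
  # one exact overlap among otherwise distant atoms
  A2 <- rbind(c(0, 0, 0), c(5, 5, 5))
  B2 <- rbind(c(0, 0, 0), c(-7, 3, 9))
  expect_identical(count_clashes(A2, B2, cutoff = 0.2), 1L)
  expect_error(count_clashes(A2[0, , drop = FALSE], B2, cutoff = 0.2),
               "empty")
})

test_that("grid-based clash count equals the brute force on random fixtures", {
  set.seed(21)
  for (rep in 1:200) {
    nA <- sample(5:40, 1); nB <- sample(5:40, 1)
    cutoff <- runif(1, 0.1, 0.6)
    A <- matrix(rnorm(nA * 3, 0, runif(1, 0.3, 2)), nA, 3)
    B <- matrix(rnorm(nB * 3, sample(c(0, 0.5), 1), runif(1, 0.3, 2)), nB, 3)
    expect_identical(count_clashes(A, B, cutoff = cutoff),
                     as.integer(brute_clashes(A, B, cutoff)))
  }
})

test_that("clash counts are monotone in the cutoff", {
  set.seed(22)
  A <- matrix(rnorm(60), 20, 3)
  B <- matrix(rnorm(60, 0.3), 20, 3)
  cuts <- c(0.1, 0.2, 0.4, 0.8, 1.5)
  counts <- vapply(cuts, function(cc) count_clashes(A, B, cutoff = cc),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

make_pair_fixture <- function() {
  # shared domain: 4 non-coplanar CA beads (residues 10-13); a clash-test
  # bead stack follows at a higher residue number
  shared <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5))
  build <- function(extra_xyz, extra_res) {
    toy_structure(rbind(shared, extra_xyz), resno = c(10:13, extra_res))
  }
  list(shared_def = domain_def("S", c(10, 13)),
       build = build)
}

test_that("pair_filter reports every pair with threshold-consistent flags", {
  fx <- make_pair_fixture()
  # planted per-pair counts {0, 50, 150} via bead stacks at the cutoff
  mk_moving <- function(n_at) {
    # n_at near-coincident beads produce n_at cross pairs with a single
    # static bead placed on top of them
    fx$build(matrix(rep(c(2, 0, 0), n_at), ncol = 3, byrow = TRUE) +
               cbind(0, 0, seq(0, 0.001, length.out = n_at)),
             rep(20, n_at))
  }
  statics <- fx$build(rbind(c(2, 0, 0)), 30)
  far <- fx$build(rbind(c(50, 0, 0)), 20)
  cfgf <- assembly_config(fx$shared_def, domain_def("M", c(20, 20)),
                          domain_def("X", c(30, 30)), cutoff = 0.2,
                          threshold = 100, junction = 12)
  planted <- c(0, 50, 150)
  for (k in seq_along(planted)) {
    memb <- if (planted[k] == 0) far else mk_moving(planted[k])
    rep1 <- pair_filter(ensemble3d(list(memb)), ensemble3d(list(statics)),
                        cfgf)
    expect_equal(rep1$pairs$clashes, planted[k])
    expect_equal(rep1$pairs$passed, planted[k] < 100)
  }
})

test_that("pair_filter is invariant to rigid pre-transformations", {
  gen <- generate_fragment_ensembles(small_spec())
  gt <- gen$ground_truth
  cfg <- assembly_config(gt$domains$B, gt$domains$A, gt$domains$C,
                         cutoff = gt$clash$cutoff, threshold = 100,
                         junction = gt$junction)
  reps_a <- ensemble3d(gen$ab$members[1:4])
  reps_b <- ensemble3d(gen$bc$members[1:4])
  r1 <- pair_filter(reps_a, reps_b, cfg)
  tr <- list(rotation = saxsemble:::rotation_about_axis(c(1, 2, 3), 0.7),
             translation = c(5, -3, 2))
  class(tr) <- "rigid_transform"
  reps_a2 <- ensemble3d(lapply(reps_a$members, apply_transform, transform = tr))
  r2 <- pair_filter(reps_a2, reps_b, cfg)
  expect_identical(r1$pairs$clashes, r2$pairs$clashes)
})

test_that("planted pair clash counts are reproduced exactly", {
  gen <- generate_fragment_ensembles(small_spec())
  gt <- gen$ground_truth
  k <- nrow(gt$clash$counts)
  cfg <- assembly_config(gt$domains$B, gt$domains$A, gt$domains$C,
                         cutoff = gt$clash$cutoff, threshold = 100,
                         junction = gt$junction)
  rep <- pair_filter(ensemble3d(gen$ab$members[seq_len(k)]),
                     ensemble3d(gen$bc$members[seq_len(k)]), cfg)
  expect_identical(matrix(rep$pairs$clashes, k, k), gt$clash$counts,
                   ignore_attr = TRUE)
  expect_equal(sum(rep$summary[c("pass", "fail")]), k * k,
               ignore_attr = TRUE)
})

test_that("raising the threshold never loses passing pairs", {
  gen <- generate_fragment_ensembles(small_spec())
  gt <- gen$ground_truth
  mk <- function(thr) {
    cfg <- assembly_config(gt$domains$B, gt$domains$A, gt$domains$C,
                           cutoff = gt$clash$cutoff, threshold = thr,
                           junction = gt$junction)
    sum(pair_filter(ensemble3d(gen$ab$members[1:6]),
                    ensemble3d(gen$bc$members[1:6]), cfg)$pairs$passed)
  }
  passes <- vapply(c(1, 10, 100, 1000), mk, numeric(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("carved fragments reassemble into the parent", {
  cp <- carve_parent(small_spec())
  cfg <- assembly_config(cp$domains$B, cp$domains$A, cp$domains$C,
                         junction = cp$junction)
  res <- assemble_full_length(cp$ab, cp$bc, cfg, check_clashes = FALSE)
  expect_lt(max(abs(res$structure$xyz - cp$parent$xyz)), 1e-6)
  expect_lt(res$fit_rmsd, 1e-9)
  # the seam distance is the parent's own junction pseudo-bond
  expect_equal(res$seam_distance, cp$junction_bond, tolerance = 1e-9)
  # atom conservation across the seam
  expect_equal(nrow(res$structure$atoms),
               sum(cp$ab$atoms$resno < cp$junction) +
                 sum(cp$bc$atoms$resno >= cp$junction))
})

test_that("assembly enforces the clash filter unless overridden", {
  gen <- generate_fragment_ensembles(small_spec())
  gt <- gen$ground_truth
  fail_idx <- which(gt$clash$counts >= 5, arr.ind = TRUE)
  expect_gt(nrow(fail_idx), 0)  # the default clash fraction plants failures
  i <- fail_idx[1, 1]; j <- fail_idx[1, 2]
  cfg <- assembly_config(gt$domains$B, gt$domains$A, gt$domains$C,
                         cutoff = gt$clash$cutoff, threshold = 5,
                         junction = gt$junction)
  expect_error(assemble_full_length(gen$ab$members[[i]], gen$bc$members[[j]],
                                    cfg), "clash filter")
  res <- assemble_full_length(gen$ab$members[[i]], gen$bc$members[[j]], cfg,
                              override = TRUE)
  expect_s3_class(res$structure, "structure3d")
})

test_that("assembly configuration validates the junction placement", {
  d <- domain_def("S", c(10, 20))
  m <- domain_def("M", c(1, 5)); s <- domain_def("X", c(30, 40))
  expect_error(assembly_config(d, m, s, junction = 25), "junction")
  expect_silent(assembly_config(d, m, s, junction = 15))
})
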