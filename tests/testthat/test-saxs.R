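test_that("Debye intensities match the closed forms", {
  cfg <- saxs_config(q = seq(0, 3, length.out = 41),
                     scatterer = "uniform-bead")
  # single scatterer of unit amplitude: I(q) = 1
  s1 <- toy_structure(rbind(c(0, 0, 0)))
  expect_equal(saxs_debye(s1, cfg)$I, rep(1, 41))
  # two unit scatterers at distance d: I(q) = 2 + 2 sin(qd)/(qd)
  d <- 1.3
  s2 <- toy_structure(rbind(c(0, 0, 0), c(0, 0, d)))
  cv <- saxs_debye(s2, cfg)
  expect_equal(cv$I, 2 + 2 * saxsemble:::sinc(cfg$q * d), tolerance = 1e-12)
  # I(0) = (sum of amplitudes)^2, I(q) >= 0
  expect_equal(cv$I[1], 4)
  expect_true(all(cv$I >= 0))
})

test_that("uniform sphere cloud reproduces the analytic form factor", {
  R <- 1
  sph <- sphere_cloud(R)
  q <- seq(0, 4.3, length.out = 33)  # first minimum at qR ~ 4.49
  cv <- saxs_debye(sph, saxs_config(q = q, scatterer = "uniform-bead"))
  rel <- abs(cv$I / cv$I[1] - sphere_form_factor(q, R)) /
    sphere_form_factor(q, R)
  expect_lt(max(rel), 0.02)
})

test_that("q-vector sampling agrees with the Debye oracle and converges", {
  coil <- random_coil(500, seed = 31)
  q <- seq(0, 3, length.out = 31)
  cfg <- function(n) saxs_config(q = q, n_orientations = n,
                                 scatterer = "uniform-bead")
  ref <- saxs_debye(coil, cfg(1))
  errs <- vapply(c(50, 200, 2000), function(n) {
    cv <- saxs_qvector(coil, cfg(n))
    max(abs(cv$I - ref$I) / ref$I)
  }, numeric(1))
  expect_lt(errs[3], 0.01)      # n = 2000 within 1 percent everywhere
  expect_true(all(diff(errs) < 0))  # error decays with direction count
})

test_that("single-direction sampling gives the axial closed form", {
  # centrosymmetric pair along the lone sampling direction:
  # |2 cos(q d / 2)|^2 exactly
  d <- 0.9
  u <- saxsemble:::fibonacci_sphere(1)[1, ]
  s <- toy_structure(rbind(-u * d / 2, u * d / 2))
  q <- seq(0, 3, length.out = 31)
  cv <- saxs_qvector(s, saxs_config(q = q, n_orientations = 1,
                                    scatterer = "uniform-bead"))
  expect_equal(cv$I, (2 * cos(q * d / 2))^2, tolerance = 1e-10)
})

test_that("SAXS curves are invariant under rigid motion", {
  coil <- random_coil(80, seed = 7)
  tr <- list(rotation = saxsemble:::rotation_about_axis(c(1, 0, 2), 1.1),
             translation = c(10, -5, 3))
  class(tr) <- "rigid_transform"
  cfg <- saxs_config(q = seq(0, 3, length.out = 21),
                     scatterer = "uniform-bead")
  # double-precision phase arithmetic limits agreement to ~1e-7 relative
  I1 <- saxs_debye(coil, cfg)$I
  I2 <- saxs_debye(apply_transform(coil, tr), cfg)$I
  expect_equal(I2, I1, tolerance = 1e-6)
  I3 <- saxs_qvector(coil, cfg)$I
  I4 <- saxs_qvector(apply_transform(coil, tr), cfg)$I
  expect_equal(I4, I3, tolerance = 1e-6)
})

test_that("excluded-volume contrast has the exact q = 0 limit", {
  cfg0 <- saxs_config(q = c(0, 1, 2), scatterer = "atomic")
  s <- structure3d(toy_atoms(2, name = c("C1", "O1"),
                             element = c("C", "O")),
                   rbind(c(0, 0, 0), c(0, 0, 0.3)))
  g <- excluded_volume_correction(s, cfg0)
  # g(0) = Z - rho_s * V exactly
  expect_equal(g[1, 1], atomic_form_factor("C", 0) - 334 * 16.44e-3,
               tolerance = 1e-9)
  expect_equal(g[2, 1], atomic_form_factor("O", 0) - 334 * 9.13e-3,
               tolerance = 1e-9)
  # the correction reduces the vacuum amplitude for carbon
  expect_lt(g[1, 1], atomic_form_factor("C", 0))
  # mode "none" reduces to vacuum form factors; rho_s = 0 equivalent
  cfg_v <- saxs_config(q = c(0, 1, 2), scatterer = "atomic",
                       excluded_volume = "none")
  gv <- excluded_volume_correction(s, cfg_v)
  expect_equal(gv[1, ], atomic_form_factor("C", c(0, 1, 2)),
               tolerance = 1e-12)
  # unknown element in atomic mode is an error
  su <- structure3d(toy_atoms(1, element = "Xq"), rbind(c(0, 0, 0)))
  expect_error(saxs_debye(su, cfg0), "form factor")
})

test_that("form factors reproduce electron counts at q = 0 and decay", {
  for (el in form_factor_elements()) {
    f <- atomic_form_factor(el, seq(0, 30, length.out = 60))
    z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)[[el]]
    expect_equal(f[1], z, tolerance = 0.005 * z)
    expect_true(all(diff(f) <= 1e-9))
  }
})

test_that("ensemble curves are weighted means of member curves", {
  cfg <- saxs_config(q = seq(0, 2, length.out = 21),
                     scatterer = "uniform-bead")
  a <- random_coil(40, seed = 1)
  b <- random_coil(40, seed = 2)
  ens1 <- ensemble3d(list(a))
  expect_equal(ensemble_saxs(ens1, cfg)$I, saxs_debye(a, cfg)$I)
  # identical members, uneven weights: same curve
  ens2 <- ensemble3d(list(a, a), weights = c(0.3, 0.7))
  expect_equal(ensemble_saxs(ens2, cfg)$I, saxs_debye(a, cfg)$I,
               tolerance = 1e-12)
  # distinct members, equal weights: arithmetic mean
  ens3 <- ensemble3d(list(a, b))
  expect_equal(ensemble_saxs(ens3, cfg)$I,
               (saxs_debye(a, cfg)$I + saxs_debye(b, cfg)$I) / 2,
               tolerance = 1e-12)
})

test_that("curve text round-trips through the data-bank dialect", {
  cv <- saxs_curve(seq(0.1, 2, length.out = 20),
                   exp(-seq(0.1, 2, length.out = 20)),
                   sigma = rep(0.01, 20), label = "toy")
  f <- tempfile(fileext = ".dat")
  write_saxs_curve(cv, f)
  back <- read_saxs_curve(f)
  expect_equal(back$q, cv$q, tolerance = 1e-7)
  expect_equal(back$I, cv$I, tolerance = 1e-9)
  expect_equal(back$sigma, cv$sigma, tolerance = 1e-9)
  # Angstrom q units convert on read
  back_a <- read_saxs_curve(f, q_unit = "angstrom")
  expect_equal(back_a$q, cv$q * 10, tolerance = 1e-6)
})
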