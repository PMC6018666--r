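# SAXS forward model: form factors, Debye sum, representative-intensity
# preparation, scale estimation, Rg and Dmax.

test_that("form factors reproduce electron counts at q = 0", {
  f0 <- form_factors(c("H", "C", "N", "O", "P", "S"), 0,
                     solvent_correction = FALSE)
  expect_equal(as.vector(f0), c(1, 6, 7, 8, 15, 16), tolerance = 2e-3)
  # solvent correction reduces the q = 0 value by rho_s * V
  fc <- form_factors("C", 0)
  expect_lt(fc[1, 1], 6)
  expect_error(form_factors("C", -0.1), "non-negative")
  expect_error(form_factors("Xx", 0.1), "coefficients")
})

test_that("Debye intensity matches closed forms for 1 and 2 atoms", {
  one <- atomic_model(data.frame(
    serial = 1, name = "C1", elem = "C", resno = 1, resname = "ALA",
    chain = "A", x = 0, y = 0, z = 0), roles = c(A = "protein"))
  q <- seq(0, 0.5, 0.05)
  f <- form_factors("C", q)[, 1]
  expect_equal(debye_intensity(one, q)$I, f^2, tolerance = 1e-12)

  d <- 4.2
  two <- atomic_model(data.frame(
    serial = 1:2, name = c("C1", "C2"), elem = "C", resno = 1:2,
    resname = "ALA", chain = "A", x = c(0, d), y = 0, z = 0),
    roles = c(A = "protein"))
  qd <- q * d
  sinc <- ifelse(qd == 0, 1, sin(qd) / ifelse(qd == 0, 1, qd))
  expect_equal(debye_intensity(two, q)$I, 2 * f^2 * (1 + sinc),
               tolerance = 1e-12)
  expect_equal(debye_intensity(two, 0)$I, 4 * f[1]^2)
  expect_error(debye_intensity(two, c(-0.1, 0.2)), "non-negative")
})

test_that("compiled Debye equals the naive double-loop oracle", {
  for (seed in 1:3) {
    m <- random_model(50, seed = seed)
    q <- seq(0, 0.6, length.out = 15)
    expect_equal(debye_intensity(m, q)$I, naive_debye(m, q),
                 tolerance = 1e-8)
    # and the packaged plain-R reference agrees too
    expect_equal(debye_reference(m, q)$I, debye_intensity(m, q)$I,
                 tolerance = 1e-10)
  }
})

test_that("representative-intensity grid reproduces the restraint count", {
  toy <- toy_fixture()
  crv <- simulate_saxs(toy$truth, seq(0.01, 0.55, length.out = 150),
                       noise_frac = 0.01, seed = 2)
  rep <- prepare_representative_intensities(crv)
  expect_equal(nrow(rep), 43)
  expect_equal(rep$q, seq(0.03, 0.45, 0.01))
})

test_that("polynomial inputs are interpolated exactly and idempotently", {
  q <- seq(0.0, 0.55, length.out = 140)
  coef <- c(13, -2, 0.5, 4, -1)
  poly_fn <- function(x) {
    # the fit range is q <= fit_qmax; rescaling must match the fit's own
    qf <- q[q <= 0.5]
    t <- 2 * (x - min(qf)) / diff(range(qf)) - 1
    drop(outer(t, 0:4, "^") %*% coef)
  }
  crv <- scattering_curve(q, poly_fn(q))
  rep1 <- prepare_representative_intensities(crv, poly_degree = 8)
  expect_equal(rep1$I, poly_fn(rep1$q), tolerance = 1e-8)
  # idempotence on its own output for polynomial inputs
  rep2 <- prepare_representative_intensities(
    scattering_curve(rep1$q, rep1$I), fit_qmax = 0.45, poly_degree = 8,
    grid_min = 0.03, grid_max = 0.45, grid_step = 0.01)
  expect_equal(rep2$I, rep1$I, tolerance = 1e-7)
})

test_that("representative intensities beat raw noisy samples", {
  toy <- toy_fixture()
  q <- seq(0.01, 0.55, length.out = 150)
  truth <- debye_intensity(toy$truth, q)
  noisy <- simulate_saxs(toy$truth, q, noise_frac = 0.02, seed = 5)
  rep <- prepare_representative_intensities(noisy)
  truth_at <- approx(q, truth$I, xout = rep$q)$y
  raw_at <- approx(q, noisy$I, xout = rep$q)$y
  rms_rep <- sqrt(mean((rep$I - truth_at)^2))
  rms_raw <- sqrt(mean((raw_at - truth_at)^2))
  expect_lt(rms_rep, rms_raw)
})

test_that("grid outside the fitted range and over-high degree error", {
  crv <- scattering_curve(seq(0.05, 0.4, 0.01), rexp(36) + 1)
  expect_error(prepare_representative_intensities(crv),
               "outside the fitted")
  expect_error(prepare_representative_intensities(
    crv, poly_degree = 50, grid_min = 0.06, grid_max = 0.3), "degree")
})

test_that("scale estimation is the mean experimental/calculated ratio", {
  q <- seq(0.02, 0.4, 0.02)
  set.seed(11)
  I <- rexp(length(q)) + 0.5
  a <- scattering_curve(q, I)
  expect_equal(estimate_scale(a, a), 1)
  expect_equal(estimate_scale(scattering_curve(q, 2 * I), a), 2)
  # property: estimate_scale(c*a, a) = c
  for (c0 in c(0.25, 3, 40)) {
    expect_equal(estimate_scale(scattering_curve(q, c0 * I), a), c0,
                 tolerance = 1e-12)
  }
  b <- scattering_curve(q, rexp(length(q)) + 0.5)
  expect_equal(estimate_scale(a, b), mean(a$I / b$I))
  expect_error(estimate_scale(a, scattering_curve(q, rep(0, length(q)))),
               "zero")
})

test_that("uniform sphere Rg matches the analytic value within 1%", {
  set.seed(7)
  n <- 10000
  pts <- matrix(runif(3 * n * 3, -10, 10), ncol = 3)
  keep <- rowSums(pts^2) <= 100
  pts <- pts[keep, ][seq_len(n), ]
  m <- atomic_model(data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)), elem = "C",
    resno = seq_len(n), resname = "ALA", chain = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3]), roles = c(A = "protein"))
  expect_equal(model_rg(m), sqrt(3 / 5) * 10, tolerance = 0.01)
})

test_that("Dmax is the maximum interatomic distance", {
  two <- atomic_model(data.frame(
    serial = 1:2, name = c("C1", "C2"), elem = "C", resno = 1:2,
    resname = "ALA", chain = "A", x = c(0, 30), y = 0, z = 0),
    roles = c(A = "protein"))
  expect_equal(model_dmax(two), 30)
})

test_that("Guinier Rg of the toy Debye curve matches the model Rg", {
  toy <- toy_fixture()
  crv <- debye_intensity(toy$truth, seq(0.005, 0.2, 0.005))
  g <- guinier_rg(crv)
  expect_equal(g$rg, model_rg(toy$truth), tolerance = 0.03)
  expect_error(guinier_rg(scattering_curve(c(0.01, 0.02, 0.03),
                                           c(3, 2.9, 2.8))), "fewer than 5")
})

test_that("Debye curves are positive and finite including q = 0", {
  toy <- toy_fixture()
  crv <- debye_intensity(toy$truth, c(0, 10^seq(-3, -0.3, length.out = 20)))
  expect_true(all(is.finite(crv$I)))
  expect_true(all(crv$I > 0))
})

test_that("scattering curves survive the .dat round trip", {
  crv <- scattering_curve(seq(0.01, 0.1, 0.01), 10:1, sigma = rep(0.5, 10))
  p <- tempfile(fileext = ".dat")
  write_curve(crv, p)
  back <- read_curve(p)
  expect_equal(back$q, crv$q, tolerance = 1e-8)
  expect_equal(back$I, crv$I, tolerance = 1e-8)
  expect_equal(back$sigma, crv$sigma, tolerance = 1e-8)
})
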