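# Alignment-tensor fitting and the correlation restraint.

# Random unit bond vectors packed into a minimal two-atom-per-bond model.
make_bond_model <- function(B) {
  n <- nrow(B)
  at <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- c(4 * i, 0, 0)
    data.frame(serial = c(2 * i - 1, 2 * i), name = c("N", "H"),
               elem = c("N", "H"), resno = i, resname = "ALA",
               chain = "A",
               x = c(base[1], base[1] + B[i, 1]),
               y = c(base[2], base[2] + B[i, 2]),
               z = c(base[3], base[3] + B[i, 3]))
  }))
  atomic_model(at, roles = c(A = "protein"))
}

random_units <- function(n, seed) {
  set.seed(seed)
  B <- matrix(rnorm(3 * n), ncol = 3)
  B / sqrt(rowSums(B^2))
}

random_saupe <- function(seed) {
  set.seed(seed)
  v <- rnorm(5, sd = 3)
  matrix(c(v[1], v[3], v[4],
           v[3], v[2], v[5],
           v[4], v[5], -v[1] - v[2]), 3, 3, byrow = TRUE)
}

test_that("noiseless couplings recover the tensor exactly", {
  B <- random_units(20, seed = 1)
  S <- random_saupe(2)
  m <- make_bond_model(B)
  D <- rowSums((B %*% S) * B)
  rdcs <- rdc_set("A", 1:20, "N", "H", D)
  fit <- fit_tensor_svd(m, rdcs)
  expect_equal(fit$tensor$S, S, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$Q, 0, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_equal(sum(diag(fit$tensor$S)), 0, tolerance = 1e-10)
  expect_equal(sum(fit$tensor$eigenvalues), 0, tolerance = 1e-10)
})

test_that("noisy couplings recover components within 3 standard errors", {
  B <- random_units(30, seed = 3)
  S <- random_saupe(4)
  m <- make_bond_model(B)
  D0 <- rowSums((B %*% S) * B)
  sd_noise <- 0.05 * sd(D0)
  set.seed(5)
  D <- D0 + rnorm(length(D0), 0, sd_noise)
  fit <- fit_tensor_svd(m, rdc_set("A", 1:30, "N", "H", D))
  # standard errors of the linear LS problem
  A <- cbind(B[, 1]^2 - B[, 3]^2, B[, 2]^2 - B[, 3]^2,
             2 * B[, 1] * B[, 2], 2 * B[, 1] * B[, 3],
             2 * B[, 2] * B[, 3])
  se <- sd_noise * sqrt(diag(solve(crossprod(A))))
  truth <- c(S[1, 1], S[2, 2], S[1, 2], S[1, 3], S[2, 3])
  est <- c(fit$tensor$S[1, 1], fit$tensor$S[2, 2], fit$tensor$S[1, 2],
           fit$tensor$S[1, 3], fit$tensor$S[2, 3])
  expect_true(all(abs(est - truth) <= 3 * se))
  expect_gt(fit$Q, 0)
})

test_that("under-determined bond sets are rejected", {
  B <- random_units(4, seed = 6)
  m <- make_bond_model(B)
  expect_error(fit_tensor_svd(m, rdc_set("A", 1:4, "N", "H", rnorm(4))),
               "at least 5")
  # 6 bonds all along z: rank-deficient design
  Bz <- matrix(rep(c(0, 0, 1), each = 6), ncol = 3)
  mz <- make_bond_model(Bz)
  expect_error(fit_tensor_svd(mz, rdc_set("A", 1:6, "N", "H", rnorm(6))),
               "rank")
  expect_error(fit_tensor_svd(make_bond_model(random_units(6, 1)),
                              rdc_set("B", 1:6, "N", "H", rnorm(6))),
               "not resolvable")
})

test_that("SVD residual beats random tensors", {
  B <- random_units(15, seed = 8)
  m <- make_bond_model(B)
  set.seed(9)
  D <- rnorm(15)
  fit <- fit_tensor_svd(m, rdc_set("A", 1:15, "N", "H", D))
  for (k in 1:200) {
    Sr <- random_saupe(100 + k)
    resid <- sum((rowSums((B %*% Sr) * B) - D)^2)
    expect_gte(resid, fit$residual - 1e-9)
  }
})

test_that("Q and r are invariant under global rotation with refit", {
  toy <- toy_fixture()
  rdcs <- simulate_rdc(toy$truth, noise_hz = 0.5, seed = 11)
  f1 <- fit_tensor_svd(toy$truth, rdcs)
  rot <- toy$truth
  R <- rotation_about_axis(c(1, 2, 0.5), 1.1)
  rot$atoms[c("x", "y", "z")] <- coords(rot) %*% t(R)
  f2 <- fit_tensor_svd(rot, rdcs)
  expect_equal(f2$Q, f1$Q, tolerance = 1e-8)
  expect_equal(f2$r, f1$r, tolerance = 1e-8)
})

test_that("replica averaging is the element-wise mean", {
  x <- c(1.2, -0.5, 3)
  expect_equal(replica_average(x, x), x)
  expect_equal(replica_average(x, -x), c(0, 0, 0))
  set.seed(12)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(replica_average(a, b), (a + b) / 2)
  expect_error(replica_average(a, b[1:5]), "differ")
  toy <- toy_fixture()
  r1 <- simulate_rdc(toy$truth, noise_hz = 0.2, seed = 1)
  r2 <- simulate_rdc(toy$truth, noise_hz = 0.2, seed = 2)
  avg <- replica_average(r1, r2)
  expect_s3_class(avg, "RDCSet")
  expect_equal(avg$D, (r1$D + r2$D) / 2)
})

test_that("correlation restraint energy follows the Pearson correlation", {
  v <- c(1, 3, -2, 0.5, 4)
  expect_equal(rdc_correlation_energy(v, v), -20000)
  expect_equal(rdc_correlation_energy(-v, v), 20000)
  set.seed(13)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rdc_correlation_energy(a, b, slope = -500),
               -500 * cor(a, b))
  # invariance under affine rescaling of the calculated couplings
  expect_equal(rdc_correlation_energy(3 * a + 7, b),
               rdc_correlation_energy(a, b), tolerance = 1e-12)
  expect_error(rdc_correlation_energy(rep(1, 5), v), "variance")
  expect_error(rdc_correlation_energy(v[1:2], v[1:2]), "3 bonds")
})

test_that("RDC tables survive the text round trip", {
  toy <- toy_fixture()
  rdcs <- simulate_rdc(toy$truth, noise_hz = 0.3, seed = 14)
  p <- tempfile(fileext = ".txt")
  write_rdc(rdcs, p)
  back <- read_rdc(p)
  expect_equal(back$D, rdcs$D, tolerance = 1e-6)
  expect_equal(back$resno, rdcs$resno)
  expect_equal(back$atom1, rdcs$atom1)
})
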