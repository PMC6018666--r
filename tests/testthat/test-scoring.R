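# Hybrid energy: upper walls, metainference likelihood, restraints,
# surrogate physics, and term composition.

test_that("upper wall is one-sided and quadratic above the center", {
  expect_equal(upper_wall(3.0, 3.5, 1000), 0)
  expect_equal(upper_wall(3.5, 3.5, 1000), 0)
  expect_equal(upper_wall(4.5, 3.5, 1000), 1000)
  set.seed(1)
  v <- runif(50, 0, 8)
  oracle <- ifelse(v > 3.5, 1000 * (v - 3.5)^2, 0)
  expect_equal(upper_wall(v, 3.5, 1000), oracle)
  # continuity and flat interior near the wall
  eps <- 1e-8
  expect_lt(upper_wall(3.5 + eps, 3.5, 1000), 1e-10)
  expect_error(upper_wall(1, 1, -5), "k must be")
})

test_that("metainference energy follows the Gaussian per-point form", {
  d <- c(2, 4, 6)
  sg <- c(0.5, 1, 2)
  lam <- 1.05
  # perfect forward agreement leaves only the log-sigma part
  expect_equal(metainference_energy(d / lam, d, sg, lam), sum(log(sg)))
  # doubling sigma quarters the misfit part and adds n log 2
  f <- c(2.5, 3.1, 7)
  e1 <- metainference_energy(f, d, sg, 1)
  e2 <- metainference_energy(f, d, 2 * sg, 1)
  misfit1 <- e1 - sum(log(sg))
  misfit2 <- e2 - sum(log(2 * sg))
  expect_equal(misfit2, misfit1 / 4)
  # random-case oracle
  set.seed(2)
  f <- rnorm(20, 10); d2 <- rnorm(20, 10); s2 <- runif(20, 0.5, 2)
  expect_equal(metainference_energy(f, d2, s2, 1.02),
               sum((1.02 * f - d2)^2 / (2 * s2^2) + log(s2)))
  expect_error(metainference_energy(f, d2, s2, 1.2), "bounds")
  expect_error(metainference_energy(f, d2, -s2, 1), "sigma")
})

test_that("metainference energy is convex with minimum at f = d/lambda", {
  d <- c(5, 7)
  sg <- 0.3
  lam <- 0.95
  f0 <- d / lam
  e0 <- metainference_energy(f0, d, sg, lam)
  set.seed(3)
  for (k in 1:25) {
    expect_gt(metainference_energy(f0 + rnorm(2, 0, 0.5), d, sg, lam), e0)
  }
})

test_that("toy truth satisfies every restraint and energies add", {
  toy <- toy_fixture()
  re <- restraint_energy(toy$truth, toy$restraints)
  expect_equal(re$total, 0)
  expect_true(all(re$breakdown == 0))
  expect_equal(length(re$breakdown), 8)  # 4 interface + 2 salt + 2 ss

  # pulling one ring pair to 4.5 A raises the total by exactly k (1.0)^2
  pulled <- toy$truth
  ri <- toy$restraints$interface[1, ]
  c1 <- ring_center(pulled, ri$chain1, ri$resno1)
  c2 <- ring_center(pulled, ri$chain2, ri$resno2)
  u <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
  d_now <- sqrt(sum((c2 - c1)^2))
  shift <- (4.5 - d_now) * u
  idx <- which(pulled$atoms$chain == ri$chain2 &
                 pulled$atoms$resno == ri$resno2)
  pulled$atoms[idx, c("x", "y", "z")] <-
    sweep(coords(pulled, idx), 2, shift, "+")
  re2 <- restraint_energy(pulled, toy$restraints)
  expect_equal(re2$total - re$total, ri$k * 1.0^2, tolerance = 1e-6)

  # random perturbation: total equals the sum of the breakdown
  re3 <- restraint_energy(toy$start, toy$restraints)
  expect_equal(re3$total, sum(re3$breakdown))
  expect_gt(re3$total, 0)
})

test_that("total energy composes additively from its terms", {
  toy <- toy_fixture()
  q <- seq(0.02, 0.5, length.out = 100)
  saxs_exp <- simulate_saxs(toy$truth, q, noise_frac = 0.02, seed = 4)
  rdc_exp <- simulate_rdc(toy$truth, noise_hz = 0.3, seed = 4)
  saxs_term <- prepare_saxs_term(saxs_exp, toy$start, fit_qmax = 0.5,
                                 grid_max = 0.4)
  rdc_term <- prepare_rdc_term(rdc_exp)
  phys <- physical_term(toy$truth)

  expect_equal(total_energy(toy$start, hybrid_energy_model())$total, 0)

  hem1 <- hybrid_energy_model(rdc_term = rdc_term)
  e1 <- total_energy(toy$start, hem1)
  expect_equal(e1$total, unname(e1$breakdown["rdc"]))

  hem <- hybrid_energy_model(saxs_term = saxs_term, rdc_term = rdc_term,
                             restraints = toy$restraints, physical = phys)
  e_all <- total_energy(toy$start, hem)
  expect_equal(e_all$total, sum(e_all$breakdown), tolerance = 1e-12)
  parts <- c(
    metainference_energy(debye_intensity(toy$start, saxs_term$q)$I,
                         saxs_term$d, saxs_term$sigma, 1),
    rdc_correlation_energy(
      back_calc_rdc(toy$start, rdc_exp, rdc_term$tensor_calc), rdc_exp$D),
    restraint_energy(toy$start, toy$restraints)$total,
    physical_energy(toy$start, phys))
  expect_equal(unname(e_all$breakdown), parts, tolerance = 1e-9)
})

test_that("metainference prefers the truth over rigid perturbations", {
  toy <- toy_fixture()
  q <- seq(0.03, 0.45, 0.01)
  saxs_exp <- simulate_saxs(toy$truth, q, noise_frac = 0, seed = 1)
  FF <- form_factors(toy$truth$atoms$elem, q)
  d <- saxs_exp$I
  sg <- 0.02 * d
  e_truth <- metainference_energy(debye_intensity(toy$truth, q)$I, d, sg, 1)
  set.seed(6)
  worse <- 0
  for (k in 1:100) {
    pert <- apply_move(toy$truth, toy$partition, group = "dom2",
                       rotation = rotation_about_axis(rnorm(3),
                                                      runif(1, 0.3, 1.2)),
                       translation = rnorm(3, 0, 2))
    if (backbone_rmsd(pert, toy$truth) < 2) next
    e_p <- metainference_energy(debye_intensity(pert, q)$I, d, sg, 1)
    worse <- worse + (e_p > e_truth)
    expect_gt(e_p, e_truth)
  }
  expect_gt(worse, 50)  # most draws actually exceeded the 2 A floor
})

test_that("surrogate physical term penalizes chain breaks and clashes", {
  toy <- toy_fixture()
  phys <- physical_term(toy$truth)
  e0 <- physical_energy(toy$truth, phys)
  expect_lt(e0, 10)  # truth is near the physical minimum
  # breaking the chain by translating domain 2 raises the bond energy
  moved <- apply_move(toy$truth, toy$partition, group = "dom2",
                      translation = c(8, 0, 0))
  expect_gt(physical_energy(moved, phys), e0 + 1000)
  # squashing two atoms together triggers the repulsion
  clash <- toy$truth
  i_from <- which(clash$atoms$chain == "A" & clash$atoms$resno == 30 &
                    clash$atoms$name == "CA")
  i_to <- which(clash$atoms$chain == "A" & clash$atoms$resno == 5 &
                  clash$atoms$name == "CA")
  clash$atoms[i_from, c("x", "y", "z")] <-
    clash$atoms[i_to, c("x", "y", "z")] + 0.3
  expect_gt(physical_energy(clash, phys), e0 + 10)
})
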