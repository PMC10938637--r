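test_that("fixture structures: composition identical, geometries differ", {
  fx <- make_fixture_structures(10, "extended", seed = 4)
  expect_equal(fx$A$beads$name, fx$B$beads$name)
  expect_equal(fx$A$beads$residue_index, fx$B$beads$residue_index)
  bbA <- select_backbone(fx$A); bbB <- select_backbone(fx$B)
  nA <- length(build_network(bbA)); nB <- length(build_network(bbB))
  expect_gt(nA, nB)  # compact coil has more contacts than the extended chain

  # determinism
  fx2 <- make_fixture_structures(10, "extended", seed = 4)
  expect_identical(fx$A$beads, fx2$A$beads)

  # degenerate but legal
  tiny <- make_fixture_structures(3, "random", seed = 1)
  expect_s3_class(tiny$A, "bead_structure")
})

test_that("sampling at the same lambda yields exactly zero work", {
  sys <- toy_oscillators(2, 500, 1000)
  run <- sample_window(sys, 0.4, sampler_config(n_samples = 50, burn_in = 50,
                                                seed = 3),
                       neighbor_lams = 0.4)
  expect_true(all(run$works == 0))
})

test_that("sampler is deterministic under a fixed seed", {
  sys <- toy_oscillators(3, 500, 1000)
  cfg <- sampler_config(n_samples = 200, burn_in = 100, seed = 12)
  r1 <- sample_window(sys, 0.5, cfg, neighbor_lams = c(0.4, 0.6))
  r2 <- sample_window(sys, 0.5, cfg, neighbor_lams = c(0.4, 0.6))
  expect_identical(r1$works, r2$works)
  expect_identical(r1$final, r2$final)
})

test_that("sampled marginals match the analytic Gaussian (equipartition)", {
  kA <- 500; kB <- 1000
  sys <- toy_oscillators(1, kA, kB, c_A = 0.2, c_B = 0.8)
  cfg <- sampler_config(n_samples = 6000, burn_in = 800, stride = 3, seed = 41)
  kT <- K_BOLTZMANN * 310
  for (lam in c(0, 0.5, 1)) {
    run <- sample_window(sys, lam, cfg, record_positions = TRUE)
    x <- run$positions[, 1]
    k_lam <- (1 - lam) * kA + lam * kB
    c_lam <- (1 - lam) * 0.2 + lam * 0.8
    var_true <- kT / k_lam
    n_eff <- length(x) / 10
    expect_lt(abs(mean(x) - c_lam), 3 * sqrt(var_true / n_eff))
    expect_lt(abs(var(x) - var_true), 3 * var_true * sqrt(2 / n_eff))
    expect_gt(run$acceptance_rate, 0.2)
    expect_lt(run$acceptance_rate, 0.8)
  }
})

test_that("analytic_dG implements the Gaussian partition-function result", {
  kT <- K_BOLTZMANN * 310
  # pure b0 shift is free
  expect_equal(analytic_dG(toy_oscillators(3, 500, 500, c_A = 0, c_B = 1)), 0)
  one <- analytic_dG(toy_oscillators(1, 500, 1000))
  expect_equal(one, kT / 2 * log(2), tolerance = 1e-12)
  expect_equal(one, 0.8933, tolerance = 1e-3)
  expect_equal(analytic_dG(toy_oscillators(5, 500, 1000)), 5 * one)

  # cross-check against numerical quadrature of the partition integral
  z <- function(k) integrate(function(x) exp(-k * x^2 / (2 * kT)),
                             -Inf, Inf)$value
  expect_equal(one, -kT * log(z(1000) / z(500)), tolerance = 1e-8)

  # unsupported: coupled pair systems
  coupled <- toy_system(
    2, dim = 1,
    tethers = data.frame(bead = 1L, k_A = 100, k_B = 100, cA1 = 0, cB1 = 0),
    pairs = data.frame(i = 1L, j = 2L, b0_A = 1, k_A = 100, b0_B = 1,
                       k_B = 200))
  expect_error(analytic_dG(coupled), class = "enmix_unsupported_system")
})

test_that("unbounded systems are rejected by the divergence guard", {
  expect_error(
    toy_system(2, dim = 1,
               pairs = data.frame(i = 1L, j = 2L, b0_A = 1, k_A = 100,
                                  b0_B = 1, k_B = 100)),
    class = "enmix_unbounded_system"
  )
  # bounded at lambda 0 but unbounded at lambda 1
  expect_error(
    toy_system(1, dim = 1,
               tethers = data.frame(bead = 1L, k_A = 100, k_B = 0,
                                    cA1 = 0, cB1 = 0)),
    class = "enmix_unbounded_system"
  )
})

test_that("gaussian_work_pair stores the implied truth and obeys Crooks", {
  w <- gaussian_work_pair(5, 2, 5e4, seed = 8, temperature = 310)
  beta <- 1 / (K_BOLTZMANN * 310)
  expect_equal(attr(w, "true_dG"), 5 - beta * 4 / 2)
  expect_equal(mean(w$forward$w), 5, tolerance = 0.05)
  expect_equal(mean(w$reverse$w), -5 + beta * 4, tolerance = 0.05)
})

test_that("full pipeline on 1-D oscillators recovers the analytic answer", {
  sys <- toy_oscillators(5, 500, 1000)
  truth <- analytic_dG(sys)
  cfg <- sampler_config(n_samples = 1500, burn_in = 300, stride = 2, seed = 71)
  sim <- simulate_windows(sys, lambda_schedule_uniform(11), cfg)
  est <- bar_estimate(sim$windows)
  expect_lt(abs(est$dG - truth), 3 * est$err)
  ti <- ti_estimate(sim$dhdl, sim$schedule)
  expect_lt(abs(ti$dG - truth), 4 * ti$err)
})

test_that("3-D structure-derived toy systems sample and estimate reversibly", {
  fx <- make_fixture_structures(8, "extended", seed = 19)
  bbA <- select_backbone(fx$A); bbB <- select_backbone(fx$B)
  tA <- topology_from_network(bbA, build_network(bbA), "fix")
  tB <- topology_from_network(bbB, build_network(bbB), "fix")
  ptAB <- mix_topologies(tA, tB)
  ptBA <- mix_topologies(tB, tA)
  sysAB <- toy_system_from_topology(ptAB, coords(bbA))
  sysBA <- toy_system_from_topology(ptBA, coords(bbB))
  cfg <- sampler_config(n_samples = 1500, burn_in = 400, seed = 55)
  fwd <- bar_estimate(simulate_windows(sysAB, lambda_schedule_uniform(13),
                                       cfg)$windows)
  cfg$seed <- 56
  rev <- bar_estimate(simulate_windows(sysBA, lambda_schedule_uniform(13),
                                       cfg)$windows)
  expect_lt(abs(fwd$dG + rev$dG), 3 * (fwd$err + rev$err))
})
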