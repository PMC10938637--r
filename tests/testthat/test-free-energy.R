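test_that("BAR solves the trivial symmetric cases exactly", {
  # all forward work c and reverse -c: both Fermi arguments vanish at dG = c
  w <- window_work(0, 1, forward = rep(2.5, 50), reverse = rep(-2.5, 50))
  expect_equal(bar_interval(w)$dG, 2.5, tolerance = 1e-9)
  w0 <- window_work(0, 1, forward = rep(0, 50), reverse = rep(0, 50))
  expect_equal(bar_interval(w0)$dG, 0, tolerance = 1e-12)
})

test_that("exchanging the forward and reverse sets negates the BAR estimate", {
  # the reverse-direction problem reuses the same samples with the roles
  # exchanged (each set already carries the sign convention of its own
  # ensemble), so its solution is exactly -dG
  for (seed in 1:5) {
    w <- gaussian_work_pair(runif(1, -4, 4), runif(1, 0.5, 3), 2000,
                            seed = seed)
    flipped <- window_work(0, 1, forward = w$reverse, reverse = w$forward,
                           temperature = w$temperature)
    expect_equal(bar_interval(flipped)$dG, -bar_interval(w)$dG,
                 tolerance = 1e-9)
  }
})

test_that("BAR recovers the analytic Gaussian work identity", {
  beta <- 1 / (K_BOLTZMANN * 310)
  for (ms in list(c(1, 1), c(5, 2), c(-3, 4))) {
    w <- gaussian_work_pair(ms[1], ms[2], 1e5, seed = 17 + ms[1])
    r <- bar_interval(w)
    truth <- ms[1] - beta * ms[2]^2 / 2
    expect_equal(attr(w, "true_dG"), truth)
    expect_lt(abs(r$dG - truth), 3 * r$err_asymptotic)
  }
})

test_that("sigma = 0 work data returns mu exactly and seeds reproduce", {
  w <- gaussian_work_pair(3.2, 0, 100, seed = 1)
  expect_equal(bar_interval(w)$dG, 3.2, tolerance = 1e-9)
  w2 <- gaussian_work_pair(3.2, 0.7, 100, seed = 9)
  w3 <- gaussian_work_pair(3.2, 0.7, 100, seed = 9)
  expect_identical(w2$forward$w, w3$forward$w)
})

test_that("empty reverse set triggers the exponential-averaging fallback", {
  w <- window_work(0, 1, forward = rnorm(500, 2, 0.5),
                   reverse = numeric(0))
  expect_warning(r <- bar_interval(w), "exponential")
  expect_true(r$exp_fallback)
  expect_equal(r$method, "EXP")
  expect_true(is.finite(r$dG))
})

test_that("non-overlapping work distributions raise a typed error", {
  w <- window_work(0, 1, forward = rnorm(100, 500, 0.01),
                   reverse = rnorm(100, 500, 0.01))
  expect_error(bar_interval(w), class = "enmix_non_overlap")
})

test_that("block_error reproduces hand arithmetic on engineered blocks", {
  # five blocks whose per-block BAR estimates are exactly 1..5
  m <- 40
  w <- window_work(0, 1,
                   forward = rep(1:5, each = m),
                   reverse = -rep(1:5, each = m))
  err <- block_error(w, n_blocks = 5)
  expect_equal(err, sqrt(2.5) / sqrt(5), tolerance = 1e-9)  # ~0.7071
  # identical blocks give zero error
  w2 <- window_work(0, 1, forward = rep(c(1, 2), 50), reverse = -rep(c(1, 2), 50))
  expect_equal(block_error(w2, n_blocks = 5), 0, tolerance = 1e-9)
  expect_error(block_error(w, n_blocks = 1), class = "enmix_parameter_error")
})

test_that("chained block errors are stable for 2..10 blocks on stationary data", {
  # the per-window block error is noisy for very few blocks, but the
  # path-summed error (the quantity actually reported) averages that
  # noise over the windows and plateaus for fewer than ~10 blocks
  set.seed(23)
  wins <- lapply(1:28, function(i) {
    gaussian_work_pair(runif(1, -2, 2), runif(1, 0.5, 2), 4000,
                       seed = 5000 + i)
  })
  tot <- vapply(2:10, function(nb) {
    sum(vapply(wins, function(w) block_error(w, n_blocks = nb), numeric(1)))
  }, numeric(1))
  expect_lt((max(tot) - min(tot)) / mean(tot), 0.5)
})

test_that("chain_intervals sums contributions and errors over the path", {
  one <- data.frame(lambda_low = 0, lambda_high = 1, dG = 4.2, err = 0.3)
  est <- chain_intervals(one)
  expect_equal(est$dG, 4.2)
  expect_equal(est$err, 0.3)

  two <- data.frame(lambda_low = c(0, 0.5), lambda_high = c(0.5, 1),
                    dG = c(1, 2), err = c(0.1, 0.2))
  est2 <- chain_intervals(two)
  expect_equal(est2$dG, 3)
  expect_equal(est2$err, 0.3)
  expect_equal(chain_intervals(two, error_combination = "quadrature")$err,
               sqrt(0.05), tolerance = 1e-12)

  lam <- as.numeric(lambda_schedule_dense29())
  zeros <- data.frame(lambda_low = lam[-29], lambda_high = lam[-1],
                      dG = 0, err = 0)
  est3 <- chain_intervals(zeros)
  expect_equal(est3$dG, 0)
  expect_equal(est3$err, 0)
  expect_equal(nrow(est3$per_interval), 28L)

  gap <- data.frame(lambda_low = c(0, 0.6), lambda_high = c(0.5, 1),
                    dG = 0, err = 0)
  expect_error(chain_intervals(gap), class = "enmix_coverage_error")
})

test_that("the estimate total always equals the sum of interval values", {
  sys <- toy_oscillators(2, 500, 800)
  sim <- simulate_windows(sys, lambda_schedule_uniform(6),
                          sampler_config(n_samples = 400, burn_in = 200,
                                         seed = 2))
  est <- bar_estimate(sim$windows)
  expect_equal(est$dG, sum(est$per_interval$dG), tolerance = 1e-9)
})

test_that("TI handles constant integrands and matches the trapezoid rule", {
  sched <- lambda_schedule_uniform(5)
  zero <- replicate(5, rep(0, 50), simplify = FALSE)
  expect_equal(ti_estimate(zero, sched)$dG, 0)
  const <- replicate(5, rep(3.7, 50), simplify = FALSE)
  expect_equal(ti_estimate(const, sched)$dG, 3.7, tolerance = 1e-12)
  expect_error(ti_estimate(const[1:4], sched), class = "enmix_parameter_error")

  # non-uniform schedule: literal trapezoid over the means
  sched2 <- lambda_schedule(c(0, 0.1, 0.6, 1))
  means <- c(1, 2, -1, 4)
  dhdl <- lapply(means, function(m) rep(m, 20))
  lam <- as.numeric(sched2)
  expected <- sum(diff(lam) * (means[-4] + means[-1]) / 2)
  expect_equal(ti_estimate(dhdl, sched2)$dG, expected, tolerance = 1e-12)
})

test_that("autocorrelation: normalization, white noise and AR(1) closed form", {
  set.seed(77)
  x <- rnorm(1e5)
  ac <- autocorrelation(x, 20)
  expect_equal(ac$acf[1], 1)
  expect_true(all(abs(ac$acf[-1]) < 0.02))

  phi <- 0.8
  n <- 1e5
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n = n))
  ac2 <- autocorrelation(ar, 10)
  expect_lt(max(abs(ac2$acf - phi^(0:10))), 0.02)
  expect_gt(ac2$tau_int, 1)

  expect_error(autocorrelation(rep(1, 100), 5),
               class = "enmix_parameter_error")
})

test_that("convergence profile is flat on stationary data, flags drift", {
  # drifting data: concatenation of two Gaussian work streams with
  # different underlying means (an unequilibrated first half)
  beta <- 1 / (K_BOLTZMANN * 310)
  mk_windows <- function(drift) {
    lapply(1:2, function(i) {
      set.seed(100 + i + drift * 7)
      n <- 800
      mu <- if (drift) c(rep(8, n / 2), rep(1, n / 2)) else rep(1, n)
      window_work((i - 1) / 2, i / 2,
                  forward = rnorm(n, mu, 0.8),
                  reverse = rnorm(n, -mu + beta * 0.8^2, 0.8))
    })
  }
  flat <- convergence_profile(mk_windows(FALSE))
  expect_true(flat$converged)
  expect_equal(flat$profile$dG[nrow(flat$profile)],
               bar_estimate(mk_windows(FALSE))$dG)
  drifty <- convergence_profile(mk_windows(TRUE))
  expect_false(drifty$converged)

  single <- convergence_profile(mk_windows(FALSE), fractions = 1)
  expect_equal(nrow(single$profile), 1L)
  expect_error(
    convergence_profile(mk_windows(FALSE), fractions = c(0.001, 1)),
    class = "enmix_insufficient_data"
  )
})

test_that("ddg arithmetic, antisymmetry and error conventions", {
  mk_est <- function(dG, err) {
    chain_intervals(data.frame(lambda_low = 0, lambda_high = 1,
                               dG = dG, err = err))
  }
  x <- mk_est(-1.0, 0.1)
  y <- mk_est(-7.65, 0.2)
  r <- ddg(x, y)
  expect_equal(r$ddG, -6.65)
  expect_equal(r$err, 0.3)
  expect_equal(ddg(y, x)$ddG, -r$ddG)
  expect_equal(ddg(x, x)$ddG, 0)
  expect_equal(ddg(x, y, error_combination = "quadrature")$err,
               sqrt(0.01 + 0.04))
})

test_that("thermodynamic cycle closure", {
  expect_equal(cycle_absolute(0, 0, 0)$dG_AB_Y, 0)
  # a condition change blind to conformation leaves dG_AB unchanged
  expect_equal(cycle_absolute(-3.1, 2.2, 2.2)$dG_AB_Y, -3.1)
  r <- cycle_absolute(5, 1, 2, dG_AB_Y_independent = 6.05)
  expect_equal(r$dG_AB_Y, 6)
  expect_equal(r$closure_residual, 0.05)
})

test_that("work-file ingestion: authored fixture, dialect equivalence, errors", {
  sys <- toy_oscillators(3, 500, 900)
  sim <- simulate_windows(sys, lambda_schedule(c(0, 0.5, 1)),
                          sampler_config(n_samples = 300, burn_in = 150,
                                         seed = 6))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p_xvg <- write_window_files(sim, d1, "xvg")
  p_tsv <- write_window_files(sim, d2, "tsv")
  w_xvg <- read_work_data(p_xvg, sim$schedule)
  w_tsv <- read_work_data(p_tsv, sim$schedule)
  expect_length(w_xvg, 2L)
  expect_equal(nrow(w_xvg[[1]]$forward), 300L)
  expect_equal(bar_estimate(w_xvg)$dG, bar_estimate(w_tsv)$dG,
               tolerance = 1e-9)
  expect_equal(bar_estimate(w_xvg)$dG, bar_estimate(sim$windows)$dG,
               tolerance = 1e-9)

  empty <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# only", "@ comments"), empty)
  expect_error(read_work_data(c(p_xvg[1:2], empty), sim$schedule),
               class = "enmix_empty_input")
  # interior file missing its second neighbour column
  broken <- withr::local_tempfile(fileext = ".xvg")
  writeLines("0 1.0", broken)
  expect_error(read_work_data(c(p_xvg[1], broken, p_xvg[3]), sim$schedule),
               "neighbour", class = "enmix_format_error")
})
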