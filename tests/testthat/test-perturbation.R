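test_that("lambda schedules: 29-point production list and uniform grids", {
  s <- lambda_schedule_dense29()
  expect_length(s, 29L)
  expect_equal(as.numeric(s)[1:4], c(0, 0.0167, 0.033, 0.05))
  expect_equal(as.numeric(s)[22:29],
               c(0.85, 0.875, 0.9, 0.925, 0.95, 0.967, 0.983, 1))
  expect_equal(diff(as.numeric(s)[9:21]), rep(0.05, 12))
  # near-symmetry about one half (printed precision breaks exactness)
  v <- as.numeric(s)
  expect_lt(max(abs(v + rev(v) - 1)), 1e-3)

  expect_equal(as.numeric(lambda_schedule_uniform(2)), c(0, 1))
  expect_equal(as.numeric(lambda_schedule_uniform(3)), c(0, 0.5, 1))
  expect_equal(diff(as.numeric(lambda_schedule_uniform(21))),
               rep(0.05, 20))
  expect_error(lambda_schedule_uniform(1), class = "enmix_parameter_error")
  expect_error(lambda_schedule(c(0, 0.5, 0.4, 1)),
               class = "enmix_parameter_error")
})

test_that("mix_topologies reproduces the set-algebra partition", {
  fx <- mix_fixture_pair()
  pt <- mix_topologies(fx$A, fx$B)
  expect_equal(nrow(pt$perturbed), fx$n_changed + fx$n_a_only + fx$n_b_only)
  static_harm <- pt$static$bonded[pt$static$bonded$section_tag == "rubber_band", ]
  expect_equal(nrow(static_harm), fx$n_identical)

  # one-sided terms get a zero force constant and a copied minimum
  a_only <- pt$perturbed[pt$perturbed$k_B == 0, ]
  expect_equal(nrow(a_only), fx$n_a_only)
  expect_equal(a_only$b0_B, a_only$b0_A)
  expect_equal(a_only$b0_A, rep(0.62, fx$n_a_only))
  expect_equal(a_only$k_A, rep(500, fx$n_a_only))
  b_only <- pt$perturbed[pt$perturbed$k_A == 0, ]
  expect_equal(nrow(b_only), fx$n_b_only)
  expect_equal(b_only$b0_A, b_only$b0_B)

  # identical inputs give a lambda-independent system
  pt0 <- mix_topologies(fx$A, fx$A)
  expect_equal(nrow(pt0$perturbed), 0L)
})

test_that("mix_topologies validates atoms, charges and non-harmonic terms", {
  fx <- mix_fixture_pair()
  tB <- fx$B
  tB$atoms$bead_name[3] <- "SC1"
  expect_error(mix_topologies(fx$A, tB), "atom 3",
               class = "enmix_incompatible_atoms")

  tQ <- fx$B
  tQ$atoms$charge[2] <- 1
  expect_error(mix_topologies(fx$A, tQ), class = "enmix_incompatible_atoms")
  expect_s3_class(mix_topologies(fx$A, tQ, allow_charge_diff = TRUE),
                  "perturbed_topology")

  tAng <- fx$B
  tAng$bonded <- rbind(tAng$bonded, data.frame(
    ai = 1L, aj = 2L, ak = 3L, funct = 2L, c0 = 120, c1 = 25,
    c2 = NA_real_, c3 = NA_real_, section_tag = "angles"))
  expect_error(mix_topologies(fx$A, tAng), class = "enmix_unmixable_term")
})

test_that("k_scale multiplies elastic-network force constants of both states", {
  fx <- mix_fixture_pair()
  pt1 <- mix_topologies(fx$A, fx$B)
  pt2 <- mix_topologies(fx$A, fx$B, k_scale = 2)
  expect_equal(pt2$perturbed$k_A, 2 * pt1$perturbed$k_A)
  expect_equal(pt2$perturbed$k_B, 2 * pt1$perturbed$k_B)
  st1 <- pt1$static$bonded; st2 <- pt2$static$bonded
  rb <- st1$section_tag == "rubber_band"
  expect_equal(st2$c1[rb], 2 * st1$c1[rb])
})

test_that("restraint energy: minima, midpoint interpolation, lambda bounds", {
  mk_pt <- function(b0A, kA, b0B, kB) {
    fx <- random_perturbed_system(1, n_beads = 2, n_terms = 1)
    fx$pt$perturbed <- data.frame(i = 1L, j = 2L, funct = 6L, b0_A = b0A,
                                  k_A = kA, b0_B = b0B, k_B = kB,
                                  section_tag = "rubber_band")
    fx$pt
  }
  pos_at <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  expect_equal(restraint_energy(mk_pt(0.5, 500, 0.7, 500), pos_at(0.5), 0), 0)
  # interpolated minimum at the midpoint
  expect_equal(restraint_energy(mk_pt(0.5, 500, 0.7, 500), pos_at(0.6), 0.5), 0)
  expect_error(restraint_energy(mk_pt(0.5, 500, 0.7, 500), pos_at(0.5), 1.2),
               class = "enmix_parameter_error")
})

test_that("restraint energy matches an independent transcription of the formula", {
  set.seed(20)
  for (rep in 1:5) {
    fx <- random_perturbed_system(rep, n_beads = 10, n_terms = 10)
    for (lam in runif(4)) {
      expect_equal(
        restraint_energy(fx$pt, fx$pos, lam),
        oracle_restraint_energy(fx$pt$perturbed, fx$pos, lam),
        tolerance = 1e-12
      )
    }
  }
})

test_that("endpoint identity and swap antisymmetry hold", {
  pure_energy <- function(pt, pos, which) {
    p <- pt$perturbed
    d <- sqrt(rowSums((pos[p$i, , drop = FALSE] - pos[p$j, , drop = FALSE])^2))
    if (which == "A") sum(0.5 * p$k_A * (d - p$b0_A)^2)
    else sum(0.5 * p$k_B * (d - p$b0_B)^2)
  }
  for (seed in 1:20) {
    fx <- random_perturbed_system(seed)
    eA <- pure_energy(fx$pt, fx$pos, "A")
    eB <- pure_energy(fx$pt, fx$pos, "B")
    expect_equal(restraint_energy(fx$pt, fx$pos, 0), eA, tolerance = 1e-10)
    expect_equal(restraint_energy(fx$pt, fx$pos, 1), eB, tolerance = 1e-10)
    swapped <- swap_roles(fx$pt)
    for (lam in c(0.25, 0.7)) {
      expect_equal(restraint_energy(fx$pt, fx$pos, lam),
                   restraint_energy(swapped, fx$pos, 1 - lam),
                   tolerance = 1e-10)
    }
  }
})

test_that("restraint energy is an exact cubic polynomial in lambda", {
  # k(lambda) is linear and the squared displacement quadratic, so for a
  # fixed configuration the energy is a polynomial of degree three,
  # pinned down exactly by four points
  fx <- random_perturbed_system(33)
  lam4 <- c(0.1, 0.35, 0.6, 0.9)
  e4 <- vapply(lam4, function(l) restraint_energy(fx$pt, fx$pos, l), numeric(1))
  coefs <- solve(outer(lam4, 0:3, `^`), e4)
  pred <- function(l) sum(coefs * l^(0:3))
  for (l in c(0.05, 0.5, 0.77)) {
    expect_equal(restraint_energy(fx$pt, fx$pos, l), pred(l),
                 tolerance = 1e-8)
  }
})

test_that("energy-linear mixing mode averages the endpoint energies", {
  fx <- random_perturbed_system(5)
  eA <- restraint_energy(fx$pt, fx$pos, 0)
  eB <- restraint_energy(fx$pt, fx$pos, 1)
  expect_equal(restraint_energy(fx$pt, fx$pos, 0.3, mode = "energy"),
               0.7 * eA + 0.3 * eB, tolerance = 1e-12)
})

test_that("restraint_dhdl matches a numerical lambda derivative", {
  fx <- random_perturbed_system(12)
  h <- 1e-6
  for (lam in c(0.2, 0.5, 0.8)) {
    num <- (restraint_energy(fx$pt, fx$pos, lam + h) -
              restraint_energy(fx$pt, fx$pos, lam - h)) / (2 * h)
    expect_equal(restraint_dhdl(fx$pt, fx$pos, lam), num, tolerance = 1e-5)
  }
})

test_that("perturbed topology write/read round trip preserves all terms", {
  fx <- mix_fixture_pair()
  pt <- mix_topologies(fx$A, fx$B)
  path <- withr::local_tempfile(fileext = ".itp")
  write_perturbed_topology(pt, path)
  pt2 <- read_perturbed_topology(path)
  expect_equal(nrow(pt2$perturbed), nrow(pt$perturbed))
  expect_equal(pt2$perturbed[, c("i", "j", "b0_A", "k_A", "b0_B", "k_B")],
               pt$perturbed[, c("i", "j", "b0_A", "k_A", "b0_B", "k_B")],
               tolerance = 1e-9)
  # one-sided terms carry an explicit zero k column in the file
  lines <- readLines(path)
  one_sided <- grep("^\\s*1\\s+6\\s+6", lines, value = TRUE)
  expect_length(one_sided, 1L)
  expect_match(one_sided, "0\\.0\\s*$")
  # count of four-parameter lines equals the perturbed term count
  body <- lines[grepl("^\\s*\\d+\\s+\\d+\\s+\\d+(\\s+-?\\d+\\.?\\d*){4}\\s*$", lines)]
  expect_length(body, nrow(pt$perturbed))
})
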