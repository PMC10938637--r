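# Toy systems and a Metropolis sampler: everything needed to exercise the
# full pipeline (networks -> mixed topology -> per-window work data ->
# BAR/TI) without a molecular dynamics engine, plus analytic Gaussian
# free-energy references for validation.

#' Construct a toy harmonic system
#'
#' A toy system lives in `dim` dimensions (1 for analytic oscillator
#' checks, 3 for structure-derived systems) and carries two kinds of
#' lambda-perturbed harmonic terms: per-bead tethers
#' `1/2 k(lam) |r_i - c(lam)|^2` and pair distance restraints
#' `1/2 k(lam) (|r_i - r_j| - b0(lam))^2`, with endpoint parameter sets A
#' and B interpolated linearly. The energy must be bounded below at both
#' endpoints: every connected component (via pair terms) must contain at
#' least one bead with a positive-k tether, or — for pure pair systems in
#' 3-D — the component is only bounded up to rigid motions, which is
#' rejected unless at least one tether anchors it.
#'
#' @param n_beads number of beads.
#' @param dim spatial dimension, 1 or 3.
#' @param tethers data frame `bead`, `k_A`, `k_B` plus center columns
#'   `cA1..cAdim`, `cB1..cBdim` (or `c_A`/`c_B` for `dim = 1`).
#' @param pairs data frame `i`, `j`, `b0_A`, `k_A`, `b0_B`, `k_B` (e.g.
#'   the `perturbed` table of a [mix_topologies()] result, possibly plus
#'   static terms with equal A/B parameters).
#' @param temperature kelvin.
#' @param positions optional starting coordinate matrix (`n_beads x dim`).
#' @return Object of class `toy_system`.
#' @export
toy_system <- function(n_beads, dim = 1, tethers = NULL, pairs = NULL,
                       temperature = DEFAULT_TEMPERATURE, positions = NULL) {
  stopifnot(n_beads >= 1, dim %in% c(1L, 3L), temperature > 0)
  if (is.null(tethers)) {
    tethers <- data.frame(bead = integer(0), k_A = numeric(0),
                          k_B = numeric(0))
  }
  if (!is.null(tethers) && nrow(tethers) > 0) {
    if ("c_A" %in% names(tethers) && dim == 1) {
      tethers$cA1 <- tethers$c_A
      tethers$cB1 <- tethers$c_B
    }
    for (d in seq_len(dim)) {
      for (side in c("A", "B")) {
        col <- paste0("c", side, d)
        if (!col %in% names(tethers)) tethers[[col]] <- 0
      }
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(0), j = integer(0), b0_A = numeric(0),
                        k_A = numeric(0), b0_B = numeric(0), k_B = numeric(0))
  }
  sys <- structure(
    list(n_beads = as.integer(n_beads), dim = as.integer(dim),
         tethers = tethers, pairs = pairs, temperature = temperature,
         positions = positions),
    class = "toy_system"
  )
  check_bounded(sys)
  sys
}

check_bounded <- function(sys) {
  # at each endpoint, every pair-connected component must contain a
  # positive-k tether, otherwise the chain can drift without energy cost
  for (lam_end in c(0, 1)) {
    kk <- if (lam_end == 0) "k_A" else "k_B"
    parent <- seq_len(sys$n_beads)
    findp <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    pr <- sys$pairs[sys$pairs[[kk]] > 0, , drop = FALSE]
    if (nrow(pr) > 0) {
      for (r in seq_len(nrow(pr))) {
        ra <- findp(pr$i[r]); rb <- findp(pr$j[r])
        if (ra != rb) parent[ra] <- rb
      }
    }
    te <- sys$tethers[sys$tethers[[kk]] > 0, , drop = FALSE]
    anchored_roots <- if (nrow(te) > 0) {
      unique(vapply(as.integer(te$bead), findp, integer(1)))
    } else integer(0)
    roots <- vapply(seq_len(sys$n_beads), findp, integer(1))
    if (!all(roots %in% anchored_roots)) {
      abort_enmix(sprintf(
        "toy system unbounded at lambda = %d: a connected component has no positive-k tether",
        lam_end), "enmix_unbounded_system")
    }
  }
  invisible(TRUE)
}

#' Independent one-dimensional oscillators
#'
#' Convenience constructor for the analytic validation system: `n`
#' independent 1-D beads, each tethered with force constant `k_A` at
#' lambda 0 and `k_B` at lambda 1 (centers `c_A`, `c_B`).
#'
#' @param n number of oscillators.
#' @param k_A,k_B endpoint force constants (kJ/mol/nm^2), recycled.
#' @param c_A,c_B endpoint centers (nm), recycled.
#' @param temperature kelvin.
#' @return A [toy_system()] with `dim = 1`.
#' @export
toy_oscillators <- function(n, k_A = 500, k_B = 1000, c_A = 0, c_B = 0,
                            temperature = DEFAULT_TEMPERATURE) {
  toy_system(
    n_beads = n, dim = 1,
    tethers = data.frame(bead = seq_len(n),
                         k_A = rep_len(k_A, n), k_B = rep_len(k_B, n),
                         cA1 = rep_len(c_A, n), cB1 = rep_len(c_B, n)),
    temperature = temperature
  )
}

#' Build a 3-D toy system from a perturbed topology
#'
#' Takes the perturbed pair terms (and static harmonic bonds) of a
#' [mix_topologies()] result as distance restraints and anchors the first
#' bead with a stiff lambda-independent tether so the system is bounded.
#'
#' @param pt a `perturbed_topology`.
#' @param positions starting coordinates (e.g. state-A backbone coordinates).
#' @param temperature kelvin.
#' @param anchor_k tether force constant for the anchor bead.
#' @return A [toy_system()] with `dim = 3`.
#' @export
toy_system_from_topology <- function(pt, positions,
                                     temperature = DEFAULT_TEMPERATURE,
                                     anchor_k = 1000) {
  stopifnot(inherits(pt, "perturbed_topology"))
  positions <- coords(positions)
  b <- pt$static$bonded
  h <- b[b$section_tag %in% c("bonds", "rubber_band") & b$funct %in% c(1L, 6L), ,
         drop = FALSE]
  pairs <- rbind(
    pt$perturbed[, c("i", "j", "b0_A", "k_A", "b0_B", "k_B")],
    if (nrow(h) > 0) data.frame(i = h$ai, j = h$aj, b0_A = h$c0, k_A = h$c1,
                                b0_B = h$c0, k_B = h$c1)
  )
  n <- nrow(positions)
  anchor <- data.frame(bead = 1L, k_A = anchor_k, k_B = anchor_k,
                       cA1 = positions[1, 1], cA2 = positions[1, 2],
                       cA3 = positions[1, 3],
                       cB1 = positions[1, 1], cB2 = positions[1, 2],
                       cB3 = positions[1, 3])
  toy_system(n_beads = n, dim = 3, tethers = anchor, pairs = pairs,
             temperature = temperature, positions = positions)
}

#' Sampler configuration
#'
#' @param n_samples production samples to record per window.
#' @param burn_in equilibration sweeps discarded before recording; the
#'   proposal width is auto-tuned here toward a 30-60% acceptance rate and
#'   then frozen, preserving detailed balance in production.
#' @param stride sweeps between recorded samples.
#' @param step_size initial Gaussian proposal width (nm); `NULL` picks a
#'   thermal guess from the stiffest force constant.
#' @param seed RNG seed for the window.
#' @param dt_ps nominal time between recorded samples (used for the time
#'   column of emitted work files).
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 2000, burn_in = 500, stride = 2,
                           step_size = NULL, seed = 1, dt_ps = 50) {
  stopifnot(n_samples >= 1, burn_in >= 1, stride >= 1)
  structure(
    list(n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
         stride = as.integer(stride), step_size = step_size,
         seed = as.integer(seed), dt_ps = dt_ps),
    class = "sampler_config"
  )
}

default_step <- function(sys) {
  ks <- c(sys$tethers$k_A, sys$tethers$k_B, sys$pairs$k_A, sys$pairs$k_B)
  kmax <- max(ks[ks > 0], 1)
  sqrt(kBT(sys$temperature) / kmax)
}

start_positions <- function(sys) {
  if (!is.null(sys$positions)) return(as.matrix(sys$positions))
  pos <- matrix(0, sys$n_beads, sys$dim)
  if (nrow(sys$tethers) > 0) {
    for (r in seq_len(nrow(sys$tethers))) {
      b <- sys$tethers$bead[r]
      pos[b, ] <- as.numeric(sys$tethers[r, paste0("cA", seq_len(sys$dim))])
    }
  }
  pos
}

#' Sample one lambda window
#'
#' Runs a Metropolis chain (single-bead Gaussian displacement proposals,
#' acceptance `min(1, exp(-beta dU))`) at coupling value `lam`. After
#' burn-in, every `stride`-th sweep records the energy difference
#' `U(lambda') - U(lambda)` to each requested neighbour, the
#' dH/dlambda value at `lam`, and optionally the configuration.
#'
#' @param sys a [toy_system()].
#' @param lam coupling value in \[0, 1\].
#' @param cfg a [sampler_config()].
#' @param neighbor_lams numeric vector of neighbouring lambda values.
#' @param record_positions keep sampled configurations (memory-heavy).
#' @return List: `works` (matrix, one column per neighbour), `dhdl`,
#'   `times` (ps), `acceptance_rate`, `step_size`, optionally `positions`.
#' @export
sample_window <- function(sys, lam, cfg, neighbor_lams = numeric(0),
                          record_positions = FALSE) {
  stopifnot(inherits(sys, "toy_system"), inherits(cfg, "sampler_config"))
  if (lam < 0 || lam > 1) {
    abort_enmix("lambda must be in [0, 1]", "enmix_parameter_error")
  }
  step0 <- cfg$step_size %||% default_step(sys)
  te <- sys$tethers; pr <- sys$pairs
  dimn <- sys$dim
  cA <- as.matrix(if (nrow(te) > 0) te[, paste0("cA", seq_len(dimn)), drop = FALSE]
                  else matrix(0, 0, dimn))
  cB <- as.matrix(if (nrow(te) > 0) te[, paste0("cB", seq_len(dimn)), drop = FALSE]
                  else matrix(0, 0, dimn))
  set.seed(cfg$seed)
  out <- .mc_sample_cpp(
    start_positions(sys), dimn,
    as.integer(te$bead - 1L), cA, cB, as.numeric(te$k_A), as.numeric(te$k_B),
    as.integer(pr$i - 1L), as.integer(pr$j - 1L),
    as.numeric(pr$b0_A), as.numeric(pr$b0_B),
    as.numeric(pr$k_A), as.numeric(pr$k_B),
    lam, as.numeric(neighbor_lams), 1 / kBT(sys$temperature),
    cfg$n_samples, cfg$burn_in, cfg$stride, step0,
    is.null(cfg$step_size), TRUE, record_positions
  )
  out$times <- seq_len(cfg$n_samples) * cfg$dt_ps
  colnames(out$works) <- as.character(neighbor_lams)
  if (!record_positions) out$positions <- NULL
  out
}

#' Simulate work data over a full lambda schedule
#'
#' Runs [sample_window()] at every schedule point (recording energy
#' differences to the adjacent points) and assembles the per-interval
#' [window_work()] list the estimators consume. Per-window seeds are
#' derived deterministically from `cfg$seed`.
#'
#' @param sys a [toy_system()].
#' @param schedule a [lambda_schedule()] or preset.
#' @param cfg a [sampler_config()]; `cfg$seed` seeds the whole scan.
#' @return List: `windows` (list of `window_work`), `dhdl` (per-lambda
#'   samples for TI), `acceptance_rates`.
#' @export
simulate_windows <- function(sys, schedule, cfg) {
  schedule <- resolve_schedule(schedule)
  lam <- as.numeric(schedule)
  n <- length(lam)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    neigh <- c(if (i > 1) lam[i - 1], if (i < n) lam[i + 1])
    wcfg <- cfg
    wcfg$seed <- (cfg$seed + 7919L * i) %% 2147483647L
    runs[[i]] <- sample_window(sys, lam[i], wcfg, neighbor_lams = neigh)
  }
  windows <- lapply(seq_len(n - 1L), function(i) {
    up_col <- if (i == 1) 1L else 2L
    window_work(
      lam[i], lam[i + 1L],
      forward = data.frame(time = runs[[i]]$times,
                           w = runs[[i]]$works[, up_col]),
      reverse = data.frame(time = runs[[i + 1L]]$times,
                           w = runs[[i + 1L]]$works[, 1L]),
      temperature = sys$temperature
    )
  })
  list(
    windows = windows,
    dhdl = lapply(runs, `[[`, "dhdl"),
    acceptance_rates = vapply(runs, `[[`, numeric(1), "acceptance_rate"),
    schedule = schedule
  )
}

#' Analytic free energy of independent 1-D oscillators
#'
#' Closed-form Gaussian partition-function result for a [toy_system()]
#' made of independent 1-D tethered oscillators with positive force
#' constants at both endpoints:
#' `dG = (k_B T / 2) * sum_i log(k_B,i / k_A,i)`. Shifts of the tether
#' center contribute nothing. Systems with pair terms (shared
#' coordinates, Jacobian effects) are rejected; use the sampler there.
#'
#' @param sys a [toy_system()].
#' @return dG in kJ/mol for the lambda 0 -> 1 transformation.
#' @export
analytic_dG <- function(sys) {
  stopifnot(inherits(sys, "toy_system"))
  if (nrow(sys$pairs) > 0 || sys$dim != 1) {
    abort_enmix(
      "analytic result available only for independent 1-D tethered oscillators",
      "enmix_unsupported_system"
    )
  }
  te <- sys$tethers
  if (anyDuplicated(te$bead)) {
    abort_enmix("analytic result requires one tether per bead",
                "enmix_unsupported_system")
  }
  if (any(te$k_A <= 0 | te$k_B <= 0)) {
    abort_enmix("analytic result requires positive k at both endpoints",
                "enmix_unsupported_system")
  }
  kBT(sys$temperature) / 2 * sum(log(te$k_B / te$k_A))
}

#' Crooks-consistent Gaussian work data
#'
#' Draws forward work from `Normal(mu, sigma^2)` and reverse work from
#' `Normal(-mu + beta sigma^2, sigma^2)`, the unique Gaussian pair
#' satisfying the work fluctuation theorem; the implied true free energy
#' difference `mu - beta sigma^2 / 2` is stored as attribute `true_dG`.
#'
#' @param mu forward-work mean (kJ/mol).
#' @param sigma work standard deviation (kJ/mol).
#' @param n samples per direction.
#' @param seed RNG seed.
#' @param temperature kelvin.
#' @return A [window_work()] spanning \[0, 1\] with attribute `true_dG`.
#' @export
gaussian_work_pair <- function(mu, sigma, n, seed = 1,
                               temperature = DEFAULT_TEMPERATURE) {
  stopifnot(sigma >= 0, n >= 1)
  beta <- 1 / kBT(temperature)
  set.seed(seed)
  wF <- stats::rnorm(n, mu, sigma)
  wR <- stats::rnorm(n, -mu + beta * sigma^2, sigma)
  w <- window_work(0, 1,
                   forward = data.frame(time = seq_len(n), w = wF),
                   reverse = data.frame(time = seq_len(n), w = wR),
                   temperature = temperature)
  attr(w, "true_dG") <- mu - beta * sigma^2 / 2
  w
}

#' Generate a pair of fixture bead structures
#'
#' Builds two coarse-grained chains with identical bead composition
#' (one backbone bead per residue plus a seeded, variable number of
#' side-chain beads) but different geometries, standing in for the
#' experimentally determined A and B conformations: A compact
#' (helix-like coil, ~0.35 nm backbone spacing), B extended (or `random`,
#' a self-avoiding-ish random walk).
#'
#' @param n_residues chain length (>= 3).
#' @param mode geometry of structure B: `"extended"` or `"random"`
#'   (structure A is always the compact helix-like coil).
#' @param seed RNG seed (controls side-chain composition and the random
#'   walk).
#' @return List with elements `A` and `B`, two [bead_structure()] objects.
#' @export
make_fixture_structures <- function(n_residues, mode = c("extended", "random"),
                                    seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_residues >= 3)
  set.seed(seed)
  n_sc <- sample(0:2, n_residues, replace = TRUE)
  resnames <- sample(c("ALA", "LEU", "GLU", "LYS", "PHE"), n_residues,
                     replace = TRUE)

  build <- function(bb_xyz) {
    rows <- list()
    idx <- 0L
    for (r in seq_len(n_residues)) {
      idx <- idx + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, name = "BB", residue_index = r,
        residue_name = resnames[r],
        x = bb_xyz[r, 1], y = bb_xyz[r, 2], z = bb_xyz[r, 3])
      if (n_sc[r] > 0) {
        for (s in seq_len(n_sc[r])) {
          idx <- idx + 1L
          off <- 0.3 * s
          rows[[length(rows) + 1L]] <- data.frame(
            index = idx, name = paste0("SC", s), residue_index = r,
            residue_name = resnames[r],
            x = bb_xyz[r, 1] + off, y = bb_xyz[r, 2] + 0.1,
            z = bb_xyz[r, 3] - 0.1)
        }
      }
    }
    do.call(rbind, rows)
  }

  # compact helix-like coil: ~100 degrees per residue, 0.15 nm rise,
  # 0.23 nm radius -> backbone neighbour spacing ~0.35 nm
  ang <- (seq_len(n_residues) - 1) * 100 * pi / 180
  helix <- cbind(0.23 * cos(ang), 0.23 * sin(ang),
                 (seq_len(n_residues) - 1) * 0.15)
  bb_B <- if (mode == "extended") {
    cbind((seq_len(n_residues) - 1) * 0.35, 0, 0)
  } else {
    steps <- matrix(stats::rnorm(3 * (n_residues - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 0.35
    apply(rbind(c(0, 0, 0), steps), 2, cumsum)
  }
  list(
    A = bead_structure(build(helix), title = sprintf("fixture A (helix-like, n=%d)", n_residues)),
    B = bead_structure(build(bb_B), title = sprintf("fixture B (%s, n=%d)", mode, n_residues))
  )
}

#' Write simulated window data as per-lambda work files
#'
#' Emits one file per schedule point in the layout [read_work_data()]
#' expects: a time column followed by the energy difference to each
#' neighbouring lambda (ascending). Formats: `"xvg"` (with `@`/`#` header
#' comments) or `"tsv"`.
#'
#' @param sim a [simulate_windows()] result.
#' @param dir output directory (created if needed).
#' @param format `"xvg"` or `"tsv"`.
#' @return Character vector of file paths, in schedule order.
#' @export
write_window_files <- function(sim, dir, format = c("xvg", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lam <- as.numeric(sim$schedule)
  n <- length(lam)
  windows <- sim$windows
  paths <- character(n)
  for (i in seq_len(n)) {
    cols <- list()
    if (i > 1) cols$down <- windows[[i - 1L]]$reverse$w
    if (i < n) cols$up <- windows[[i]]$forward$w
    times <- if (i < n) windows[[i]]$forward$time else windows[[i - 1L]]$reverse$time
    tab <- do.call(cbind, c(list(time = times), cols))
    ext <- if (format == "xvg") "xvg" else "tsv"
    path <- file.path(dir, sprintf("window_%03d.%s", i, ext))
    hdr <- if (format == "xvg") {
      c(sprintf("# lambda = %g", lam[i]),
        sprintf("@ s%d legend \"dU to lambda %g\"",
                seq_along(cols) - 1L,
                c(if (i > 1) lam[i - 1L], if (i < n) lam[i + 1L])))
    } else {
      sprintf("# lambda = %g", lam[i])
    }
    writeLines(c(hdr, apply(tab, 1, function(r)
      paste(formatC(r, format = "g", digits = 12), collapse = "\t"))), path)
    paths[i] <- path
  }
  paths
}
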