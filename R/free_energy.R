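# Free energy estimation from per-window work data: Bennett acceptance
# ratio (BAR) and thermodynamic integration (TI), block-averaging errors,
# autocorrelation and convergence diagnostics, and combination of
# estimates into relative free energies (ddG) and thermodynamic cycles.
#
# Sign conventions: for a window (lambda_low, lambda_high), forward work
# samples are w_F = U(lambda_high) - U(lambda_low) evaluated on
# configurations from the lambda_low ensemble; reverse samples are
# w_R = U(lambda_low) - U(lambda_high) on the lambda_high ensemble.
# The interval dG is the free energy at lambda_high minus at lambda_low.

#' Construct per-window work data
#'
#' @param lambda_low,lambda_high window endpoints, `lambda_low < lambda_high`.
#' @param forward data frame (`time`, `w`) of forward energy differences
#'   (kJ/mol) on the low-lambda ensemble.
#' @param reverse data frame (`time`, `w`) of reverse energy differences on
#'   the high-lambda ensemble; may have zero rows (exponential-averaging
#'   fallback only).
#' @param temperature kelvin.
#' @return Object of class `window_work`.
#' @export
window_work <- function(lambda_low, lambda_high, forward, reverse,
                        temperature = DEFAULT_TEMPERATURE) {
  stopifnot(lambda_low < lambda_high, temperature > 0)
  as_wdf <- function(x) {
    if (is.numeric(x)) x <- data.frame(time = seq_along(x), w = x)
    stopifnot(is.data.frame(x), all(c("time", "w") %in% names(x)))
    x[, c("time", "w")]
  }
  structure(
    list(lambda_low = lambda_low, lambda_high = lambda_high,
         forward = as_wdf(forward), reverse = as_wdf(reverse),
         temperature = temperature),
    class = "window_work"
  )
}

#' @export
print.window_work <- function(x, ...) {
  cat(sprintf("<window_work> [%g, %g]: %d forward, %d reverse samples, T = %g K\n",
              x$lambda_low, x$lambda_high, nrow(x$forward), nrow(x$reverse),
              x$temperature))
  invisible(x)
}

fermi <- function(x) stats::plogis(-x)  # 1 / (1 + exp(x)), overflow-safe

bar_residual <- function(dG, wF, wR, beta) {
  M <- log(length(wF) / length(wR))
  sum(fermi(M + beta * (wF - dG))) - sum(fermi(-M + beta * (wR + dG)))
}

solve_bar <- function(wF, wR, beta) {
  nF <- length(wF); nR <- length(wR)
  tol <- 1e-10 * (nF + nR)
  bound <- max(abs(c(wF, wR)), 0) + 50 / beta
  # residual is monotonically increasing in dG; expand bracket by doubling
  lo <- -1 / beta; hi <- 1 / beta
  g <- function(x) bar_residual(x, wF, wR, beta)
  while (g(lo) > 0 && lo > -bound) lo <- lo * 2
  while (g(hi) < 0 && hi < bound) hi <- hi * 2
  if (g(lo) > 0 || g(hi) < 0) {
    abort_enmix(
      "no BAR root bracket: forward and reverse work distributions do not overlap; add lambda points",
      "enmix_non_overlap"
    )
  }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-12, maxiter = 1000)
  # polish: uniroot's tol is on x; verify residual tolerance
  dG <- r$root
  if (abs(g(dG)) > tol) {
    r <- stats::uniroot(g, c(dG - 1e-6, dG + 1e-6), extendInt = "upX",
                        tol = .Machine$double.eps^0.75)
    dG <- r$root
  }
  dG
}

#' Bennett acceptance ratio estimate for one lambda interval
#'
#' Solves the self-consistent acceptance-ratio equation
#' `sum_F f(ln(n_F/n_R) + beta (w_F - dG)) =
#'  sum_R f(ln(n_R/n_F) + beta (w_R + dG))`, `f(x) = 1/(1 + e^x)`,
#' with a bracketing root finder. The error is a block-averaging standard
#' error ([block_error()], default 5 blocks). With an empty reverse set
#' the estimator falls back to one-sided exponential averaging and flags
#' the result.
#'
#' @param w a [window_work()].
#' @param n_blocks blocks for the error estimate.
#' @return List: `dG`, `err` (kJ/mol), `n_F`, `n_R`, `method`,
#'   `exp_fallback` flag.
#' @export
bar_interval <- function(w, n_blocks = 5) {
  stopifnot(inherits(w, "window_work"))
  beta <- 1 / kBT(w$temperature)
  wF <- w$forward$w; wR <- w$reverse$w
  if (length(wF) == 0) {
    abort_enmix("forward work set is empty", "enmix_parameter_error")
  }
  if (length(wR) == 0) {
    warning("empty reverse work set: falling back to one-sided exponential averaging")
    dG <- -log(mean(exp(-beta * (wF - min(wF))))) / beta + min(wF)
    blocks <- split_blocks(wF, n_blocks)
    est <- vapply(blocks, function(b) {
      -log(mean(exp(-beta * (b - min(b))))) / beta + min(b)
    }, numeric(1))
    return(list(dG = dG, err = stats::sd(est) / sqrt(length(est)),
                n_F = length(wF), n_R = 0L, method = "EXP",
                exp_fallback = TRUE))
  }
  dG <- solve_bar(wF, wR, beta)
  M <- log(length(wF) / length(wR))
  fF <- fermi(M + beta * (wF - dG))
  fR <- fermi(-M + beta * (wR + dG))
  if (mean(fF) < 1e-10 || mean(fR) < 1e-10) {
    abort_enmix(
      "forward and reverse work distributions carry no statistical overlap; add lambda points",
      "enmix_non_overlap"
    )
  }
  err <- block_error(w, n_blocks = n_blocks, estimator = "BAR")
  list(dG = dG, err = err,
       err_asymptotic = bar_asymptotic_err(w, dG),
       n_F = length(wF), n_R = length(wR),
       method = "BAR", exp_fallback = FALSE)
}

#' Asymptotic standard error of a BAR estimate
#'
#' The estimator's large-sample standard error from the Fermi-weight
#' variance formula, evaluated at the solved free energy difference. This
#' is stable even when few blocks make the block-averaging error itself
#' noisy; it assumes uncorrelated samples, so it is a cross-check, not the
#' default error.
#'
#' @param w a [window_work()].
#' @param dG the solved BAR estimate (kJ/mol).
#' @return Standard error in kJ/mol.
#' @export
bar_asymptotic_err <- function(w, dG) {
  stopifnot(inherits(w, "window_work"))
  kT <- kBT(w$temperature)
  beta <- 1 / kT
  wF <- w$forward$w; wR <- w$reverse$w
  M <- log(length(wF) / length(wR))
  fF <- fermi(M + beta * (wF - dG))
  fR <- fermi(-M + beta * (wR + dG))
  kT * sqrt((mean(fF^2) / mean(fF)^2 - 1) / length(wF) +
              (mean(fR^2) / mean(fR)^2 - 1) / length(wR))
}

split_blocks <- function(x, n_blocks) {
  n <- length(x)
  if (n_blocks < 2) abort_enmix("n_blocks must be >= 2", "enmix_parameter_error")
  if (n < n_blocks) {
    abort_enmix("series shorter than the number of blocks", "enmix_parameter_error")
  }
  size <- n %/% n_blocks
  lapply(seq_len(n_blocks), function(b) x[((b - 1) * size + 1):(b * size)])
}

#' Block-averaging error estimate
#'
#' Splits the forward and reverse work series (or a dH/dlambda series)
#' into `n_blocks` contiguous equal-length blocks, re-estimates the
#' quantity on each block, and returns the standard error of the block
#' estimates (sample standard deviation divided by `sqrt(n_blocks)`),
#' treating blocks as independent. Five blocks is the conventional
#' default; estimates are insensitive to the exact count below ~10 blocks
#' for stationary data.
#'
#' @param w a [window_work()] (estimator `"BAR"`) or numeric vector of
#'   dH/dlambda samples (estimator `"TI"`, block means).
#' @param n_blocks number of blocks (>= 2).
#' @param estimator `"BAR"` or `"TI"`.
#' @return Standard error (kJ/mol).
#' @export
block_error <- function(w, n_blocks = 5, estimator = c("BAR", "TI")) {
  estimator <- match.arg(estimator)
  if (estimator == "BAR") {
    stopifnot(inherits(w, "window_work"))
    beta <- 1 / kBT(w$temperature)
    bF <- split_blocks(w$forward$w, n_blocks)
    bR <- split_blocks(w$reverse$w, n_blocks)
    est <- vapply(seq_len(n_blocks), function(b) {
      solve_bar(bF[[b]], bR[[b]], beta)
    }, numeric(1))
  } else {
    stopifnot(is.numeric(w))
    est <- vapply(split_blocks(w, n_blocks), mean, numeric(1))
  }
  stats::sd(est) / sqrt(length(est))
}

#' Chain per-interval estimates along the lambda path
#'
#' Sums contiguous interval estimates covering \[0, 1\] into a total dG.
#' Errors combine by linear summation by default (the engine's reporting
#' convention for chained BAR intervals); quadrature combination is
#' available behind `error_combination = "quadrature"`.
#'
#' @param intervals data frame with columns `lambda_low`, `lambda_high`,
#'   `dG`, `err` (or a list of `bar_interval` results plus window
#'   metadata).
#' @param error_combination `"linear"` or `"quadrature"`.
#' @param method label stored on the estimate.
#' @param n_blocks block count used upstream, stored for provenance.
#' @return Object of class `free_energy_estimate`: `dG`, `err`,
#'   `per_interval`, `method`, `n_blocks`.
#' @export
chain_intervals <- function(intervals,
                            error_combination = c("linear", "quadrature"),
                            method = "BAR", n_blocks = 5) {
  error_combination <- match.arg(error_combination)
  stopifnot(is.data.frame(intervals),
            all(c("lambda_low", "lambda_high", "dG", "err") %in%
                  names(intervals)))
  iv <- intervals[order(intervals$lambda_low), , drop = FALSE]
  lo <- iv$lambda_low; hi <- iv$lambda_high
  if (abs(lo[1]) > 1e-9 || abs(hi[length(hi)] - 1) > 1e-9 ||
      (length(lo) > 1 && any(abs(hi[-length(hi)] - lo[-1]) > 1e-9))) {
    abort_enmix("intervals do not tile [0, 1] contiguously",
                "enmix_coverage_error")
  }
  err <- if (error_combination == "linear") sum(iv$err)
         else sqrt(sum(iv$err^2))
  structure(
    list(dG = sum(iv$dG), err = err, per_interval = iv, method = method,
         n_blocks = n_blocks, error_combination = error_combination),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate> dG = %.4f +/- %.4f kJ/mol (%s, %d intervals, %d blocks)\n",
              x$dG, x$err, x$method, nrow(x$per_interval), x$n_blocks))
  invisible(x)
}

#' BAR estimate over a full window chain
#'
#' Applies [bar_interval()] to every window and chains the results.
#'
#' @param windows list of [window_work()] covering \[0, 1\].
#' @param n_blocks blocks for errors.
#' @param error_combination see [chain_intervals()].
#' @return A `free_energy_estimate`.
#' @export
bar_estimate <- function(windows, n_blocks = 5,
                         error_combination = c("linear", "quadrature")) {
  error_combination <- match.arg(error_combination)
  per <- lapply(windows, function(w) {
    r <- bar_interval(w, n_blocks = n_blocks)
    data.frame(lambda_low = w$lambda_low, lambda_high = w$lambda_high,
               dG = r$dG, err = r$err)
  })
  chain_intervals(do.call(rbind, per), error_combination = error_combination,
                  method = "BAR", n_blocks = n_blocks)
}

#' Thermodynamic integration estimate
#'
#' Trapezoidal quadrature of per-lambda mean `dH/dlambda` over the
#' schedule. Per-interval errors propagate the block standard errors of
#' the two endpoint means through the trapezoid weights (combined
#' linearly, matching the chained-interval convention).
#'
#' @param dhdl list of numeric vectors of dH/dlambda samples, one per
#'   schedule point, in schedule order.
#' @param schedule a [lambda_schedule()] (or preset accepted by the
#'   estimators).
#' @param n_blocks blocks for per-lambda mean errors.
#' @param error_combination see [chain_intervals()].
#' @return A `free_energy_estimate` with method `"TI"`.
#' @export
ti_estimate <- function(dhdl, schedule, n_blocks = 5,
                        error_combination = c("linear", "quadrature")) {
  error_combination <- match.arg(error_combination)
  schedule <- resolve_schedule(schedule)
  lam <- as.numeric(schedule)
  if (length(dhdl) != length(lam)) {
    abort_enmix(sprintf("need one dH/dlambda series per lambda point (%d vs %d)",
                        length(dhdl), length(lam)), "enmix_parameter_error")
  }
  m <- vapply(dhdl, mean, numeric(1))
  se <- vapply(dhdl, function(x) {
    if (length(x) >= n_blocks * 2) block_error(x, n_blocks, estimator = "TI")
    else stats::sd(x) / sqrt(length(x))
  }, numeric(1))
  n <- length(lam)
  h <- diff(lam)
  iv <- data.frame(
    lambda_low = lam[-n], lambda_high = lam[-1],
    dG = h * (m[-n] + m[-1]) / 2,
    err = h * (se[-n] + se[-1]) / 2
  )
  chain_intervals(iv, error_combination = error_combination, method = "TI",
                  n_blocks = n_blocks)
}

#' Normalized autocorrelation function and integrated correlation time
#'
#' Returns the normalized autocovariance (1 at lag zero) up to `max_lag`
#' and the integrated autocorrelation time, summed until the first
#' nonpositive ACF value (the simple truncation rule; no windowing).
#'
#' @param series numeric vector (e.g. dH/dlambda samples).
#' @param max_lag largest lag, `< length(series)`.
#' @return List: `acf` (length `max_lag + 1`), `tau_int` (in sampling
#'   intervals).
#' @export
autocorrelation <- function(series, max_lag) {
  stopifnot(is.numeric(series), length(series) > max_lag, max_lag >= 0)
  if (stats::sd(series) == 0) {
    abort_enmix("constant series: autocorrelation normalization undefined",
                "enmix_parameter_error")
  }
  ac <- as.numeric(stats::acf(series, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  first_np <- which(ac <= 0)[1]
  upto <- if (is.na(first_np)) length(ac) else first_np - 1L
  tau_int <- 1 + 2 * sum(ac[seq_len(upto)][-1])
  list(acf = ac, tau_int = tau_int)
}

#' Convergence profile of the chained estimate
#'
#' Re-estimates the total dG using only the first fraction of every
#' window's samples, for each requested fraction. The estimate is flagged
#' converged when the last two profile points differ by less than `tol`
#' (default: twice the final chained block error).
#'
#' @param windows list of [window_work()] covering \[0, 1\].
#' @param fractions increasing fractions in (0, 1\], last must be 1.
#' @param tol convergence tolerance in kJ/mol. The default is twice the
#'   path-summed asymptotic error of the full estimate: unlike the block
#'   error, the asymptotic error is blind to slow drifts, so drifting data
#'   cannot loosen the tolerance that is supposed to expose them.
#' @param n_blocks blocks for errors.
#' @return List: `profile` (data frame `fraction`, `dG`), `converged`,
#'   `tol`.
#' @export
convergence_profile <- function(windows, fractions = c(0.25, 0.5, 0.75, 1),
                                tol = NULL, n_blocks = 5) {
  stopifnot(!is.unsorted(fractions, strictly = TRUE),
            fractions[length(fractions)] == 1, all(fractions > 0))
  est <- lapply(fractions, function(f) {
    trimmed <- lapply(windows, function(w) {
      nF <- max(1L, floor(nrow(w$forward) * f))
      nR <- max(1L, floor(nrow(w$reverse) * f))
      if (nF < 10 || nR < 10) {
        abort_enmix(sprintf(
          "fraction %.3g leaves fewer than 10 samples in window [%g, %g]",
          f, w$lambda_low, w$lambda_high), "enmix_insufficient_data")
      }
      window_work(w$lambda_low, w$lambda_high,
                  w$forward[seq_len(nF), ], w$reverse[seq_len(nR), ],
                  w$temperature)
    })
    bar_estimate(trimmed, n_blocks = n_blocks)
  })
  dGs <- vapply(est, `[[`, numeric(1), "dG")
  final <- est[[length(est)]]
  if (is.null(tol)) {
    tol <- 2 * sum(vapply(windows, function(w) {
      r <- bar_interval(w, n_blocks = n_blocks)
      r$err_asymptotic %||% r$err
    }, numeric(1)))
  }
  n <- length(dGs)
  converged <- n >= 2 && abs(dGs[n] - dGs[n - 1]) < tol
  list(profile = data.frame(fraction = fractions, dG = dGs),
       converged = converged, tol = tol, final = final)
}

#' Relative free energy between two condition sets
#'
#' `ddG = dG_AB(Y) - dG_AB(X)`: how changing the conditions from X to Y
#' shifts the A/B conformational equilibrium. Errors add linearly (the
#' summation convention used when both legs carry block errors);
#' quadrature is available via `error_combination`.
#'
#' @param est_X,est_Y `free_energy_estimate` objects for the reference (X)
#'   and modified (Y) conditions.
#' @param error_combination `"linear"` or `"quadrature"`.
#' @return Object of class `cycle_result` with `ddG`, `err`, and a
#'   `provenance_warning` flag when the two estimates do not share an A/B
#'   definition.
#' @export
ddg <- function(est_X, est_Y, error_combination = c("linear", "quadrature")) {
  error_combination <- match.arg(error_combination)
  stopifnot(inherits(est_X, "free_energy_estimate"),
            inherits(est_Y, "free_energy_estimate"))
  pw <- FALSE
  pX <- attr(est_X, "provenance"); pY <- attr(est_Y, "provenance")
  if (!is.null(pX) && !is.null(pY) && !identical(pX, pY)) {
    warning("free energy estimates carry different A/B provenance labels")
    pw <- TRUE
  }
  err <- if (error_combination == "linear") est_X$err + est_Y$err
         else sqrt(est_X$err^2 + est_Y$err^2)
  structure(
    list(ddG = est_Y$dG - est_X$dG, err = err, dG_X = est_X$dG,
         dG_Y = est_Y$dG, provenance_warning = pw),
    class = "cycle_result"
  )
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> ddG = %.4f +/- %.4f kJ/mol\n", x$ddG, x$err))
  invisible(x)
}

#' Close a thermodynamic cycle for an absolute leg
#'
#' Given the conformational leg under conditions X and the two
#' condition-change legs at fixed conformation, returns
#' `dG_AB(Y) = dG_AB(X) - dG_A(XY) + dG_B(XY)`. When an independently
#' computed `dG_AB(Y)` is supplied, the cycle-closure residual is
#' reported alongside.
#'
#' @param dG_AB_X conformational A to B free energy under X (kJ/mol).
#' @param dG_A_XY,dG_B_XY condition-change free energies at fixed
#'   conformation A and B.
#' @param dG_AB_Y_independent optional independent estimate of the result.
#' @return List: `dG_AB_Y`, and `closure_residual` when the independent
#'   value is given.
#' @export
cycle_absolute <- function(dG_AB_X, dG_A_XY, dG_B_XY,
                           dG_AB_Y_independent = NULL) {
  val <- dG_AB_X - dG_A_XY + dG_B_XY
  out <- list(dG_AB_Y = val)
  if (!is.null(dG_AB_Y_independent)) {
    out$closure_residual <- abs(dG_AB_Y_independent - val)
  }
  out
}

#' Read per-window work data from per-lambda tabular files
#'
#' One file per schedule point, xvg-like (lines starting with `#` or `@`
#' are comments) or plain TSV. Columns: time, then the energy difference
#' `U(lambda') - U(lambda)` to each neighbouring lambda in ascending
#' order (interior points: lower neighbour, then upper neighbour;
#' endpoints: the single neighbour).
#'
#' @param paths character vector of file paths, one per schedule point in
#'   schedule order.
#' @param schedule a [lambda_schedule()] or preset.
#' @param temperature kelvin.
#' @return List of [window_work()], one per adjacent schedule interval.
#' @export
read_work_data <- function(paths, schedule, temperature = DEFAULT_TEMPERATURE) {
  schedule <- resolve_schedule(schedule)
  lam <- as.numeric(schedule)
  if (length(paths) != length(lam)) {
    abort_enmix(sprintf("need one file per lambda point (%d files, %d points)",
                        length(paths), length(lam)), "enmix_format_error")
  }
  tabs <- lapply(seq_along(paths), function(i) {
    lines <- readLines(paths[[i]], warn = FALSE)
    lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0) {
      abort_enmix(paste0("no data rows in ", paths[[i]]), "enmix_empty_input")
    }
    tab <- utils::read.table(text = lines, header = FALSE)
    n_neigh <- if (i == 1 || i == length(lam)) 1L else 2L
    if (ncol(tab) < 1 + n_neigh) {
      abort_enmix(sprintf(
        "%s: expected %d neighbour column(s) after time, found %d",
        paths[[i]], n_neigh, ncol(tab) - 1), "enmix_format_error")
    }
    tab
  })
  up_col <- function(i) if (i == 1) 2L else 3L   # column of dU to upper neighbour
  lapply(seq_len(length(lam) - 1L), function(i) {
    fw <- tabs[[i]]
    rv <- tabs[[i + 1L]]
    window_work(
      lam[i], lam[i + 1L],
      forward = data.frame(time = fw[, 1], w = fw[, up_col(i)]),
      reverse = data.frame(time = rv[, 1], w = rv[, 2]),
      temperature = temperature
    )
  })
}

#' Write a free energy estimate as TSV and JSON summaries
#'
#' @param est a `free_energy_estimate`.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @param converged optional convergence flag recorded in the JSON.
#' @return Invisibly, the summary list.
#' @export
write_estimate <- function(est, tsv_path = NULL, json_path = NULL,
                           converged = NA) {
  stopifnot(inherits(est, "free_energy_estimate"))
  if (!is.null(tsv_path)) {
    utils::write.table(est$per_interval, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  summary <- list(dG = est$dG, err = est$err, method = est$method,
                  n_blocks = est$n_blocks,
                  error_combination = est$error_combination,
                  converged = converged,
                  per_interval = est$per_interval)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(summary)
}
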