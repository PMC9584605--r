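# Train-based quantal analysis: RRP size and release probability estimators.

.new_quantal <- function(method, rrp, pr, replenishment = NA_real_,
                         diagnostics = list(), q = NA_real_) {
  if (!is.finite(rrp) || rrp <= 0) {
    abort(sprintf("%s estimation failed: non-positive pool estimate.", method))
  }
  structure(list(method = method, rrp = rrp, pr = pr,
                 replenishment = replenishment, q = q,
                 diagnostics = diagnostics),
            class = "quantal_estimate")
}

#' @export
print.quantal_estimate <- function(x, ...) {
  cat(sprintf("<quantal_estimate [%s]> RRP %.5g (amplitude units)%s, P_r %.4g%s\n",
              x$method, x$rrp,
              if (is.finite(x$q)) sprintf(" = %.5g SVs", x$rrp / x$q) else "",
              x$pr,
              if (is.finite(x$replenishment)) sprintf(", refill fraction %.4g", x$replenishment) else ""))
  invisible(x)
}

#' @export
tidy.quantal_estimate <- function(x, ...) {
  tibble(method = x$method, rrp = x$rrp,
         rrp_sv = if (is.finite(x$q)) x$rrp / x$q else NA_real_,
         pr = x$pr, replenishment = x$replenishment)
}

#' @export
glance.quantal_estimate <- function(x, ...) {
  as_tibble(c(list(method = x$method), x$diagnostics))
}

#' Elmqvist-Quastel (EQ) pool estimate
#'
#' Regresses the amplitude of each of the first `n_points` EPSCs against the
#' cumulative amplitude released before it. For a depleting train the points
#' fall on a line whose x-intercept is the initial pool (in amplitude units)
#' and whose negative slope is the release fraction; `pr` is reported as
#' `EPSC1 / RRP`.
#'
#' @param train An `epsc_train`.
#' @param n_points Number of initial stimuli used in the regression (3-6
#'   sensible; default 4, the near-linear depletion segment).
#' @return A `quantal_estimate` (`method = "EQ"`); `rrp` is in amplitude units
#'   (divide by `q`, kept from the train, for vesicle counts — see `tidy()`).
#' @export
eq_estimate <- function(train, n_points = 4) {
  a <- train$amplitude_nA
  if (length(a) < n_points + 1) abort("train too short for the requested EQ fit.")
  idx <- seq_len(n_points)
  cum_before <- cumsum(c(0, a))[idx]
  fit <- lm(a[idx] ~ cum_before)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0) {
    abort("EQ estimation requires a depressing train (negative initial slope).")
  }
  rrp <- -coef(fit)[[1]] / slope
  .new_quantal("EQ", rrp, pr = a[1] / rrp,
               diagnostics = list(slope = slope, intercept = coef(fit)[[1]],
                                  # noiseless depletion fits are exact; the
                                  # perfect-fit warning from summary.lm is moot
                                  r_squared = suppressWarnings(summary(fit)$r.squared),
                                  n_points = n_points),
               q = attr(train, "q") %||% NA_real_)
}

#' SMN back-extrapolation pool estimate
#'
#' Fits a line to the last `ss_window` points of the cumulative-amplitude
#' curve and back-extrapolates to stimulus index 0; the intercept is the pool
#' estimate. The corrected variant iteratively removes the replenishment
#' accumulated before steady state: each cumulative point is reduced by the
#' steady-state refill rate weighted by the fraction of the pool already
#' vacated (refill is proportional to empty sites), and the line is refit
#' until the intercept stabilises (tolerance 1e-6, at most 10 iterations).
#'
#' @param train An `epsc_train`.
#' @param ss_window Number of final stimuli defining steady state.
#' @param corrected Apply the occupancy-weighted replenishment correction.
#' @return A `quantal_estimate` (`method = "SMN"`).
#' @export
smn_estimate <- function(train, ss_window = 10, corrected = TRUE) {
  a <- train$amplitude_nA
  n <- length(a)
  if (n < ss_window + 2) abort("train too short for the SMN fit.")
  j <- seq_len(n)
  cum <- cumsum(a)
  tail_idx <- (n - ss_window + 1):n
  fit <- lm(cum[tail_idx] ~ j[tail_idx])
  slope <- coef(fit)[[2]]
  if (slope < 0) abort("SMN estimation requires a non-negative steady-state slope.")
  rrp <- coef(fit)[[1]]
  iterations <- 0L
  if (corrected && slope > 0) {
    for (it in seq_len(10)) {
      iterations <- it
      # replenishment between stimuli i-1 and i scales with the vacated
      # fraction of the pool just before stimulus i
      vac <- pmin(pmax(cumsum(c(0, a))[seq_len(n)] / max(rrp, a[1]), 0), 1)
      refill <- slope * cumsum(c(0, vac[-n]))
      cum_corr <- cum - refill
      fit2 <- lm(cum_corr[tail_idx] ~ j[tail_idx])
      new_rrp <- coef(fit2)[[1]]
      done <- is.finite(new_rrp) && abs(new_rrp - rrp) <= 1e-6 * max(abs(rrp), 1)
      rrp <- new_rrp
      if (done) break
    }
    if (rrp <= 0) abort("SMN correction collapsed the pool estimate; train may not depress.")
  }
  .new_quantal("SMN", rrp, pr = a[1] / rrp,
               diagnostics = list(ss_slope = slope, corrected = corrected,
                                  iterations = iterations, ss_window = ss_window),
               q = attr(train, "q") %||% NA_real_)
}

# forward recursion of the pool/release-fraction/refill model
.nprf_predict <- function(theta, n_stim) {
  N <- theta[1]; p <- theta[2]; R <- theta[3]
  a <- numeric(n_stim)
  pool <- N
  for (j in seq_len(n_stim)) {
    a[j] <- p * pool
    rem <- pool - a[j]
    pool <- rem + R * (N - rem)
  }
  a
}

#' NpRf pool estimate
#'
#' Least-squares fit of the three-parameter recursion `a_j = p * n_j`,
#' `n_{j+1} = n_j - a_j + R * (N - (n_j - a_j))`: a pool of `N` sites releases
#' the fraction `p` per stimulus and a fixed fraction `R` of the vacated sites
#' is refilled in each inter-stimulus interval. Deterministic multi-start
#' bounded optimisation.
#'
#' @param train An `epsc_train` with at least 10 stimuli.
#' @return A `quantal_estimate` (`method = "NpRf"`) with the refill fraction
#'   in `replenishment`.
#' @export
nprf_estimate <- function(train) {
  a <- train$amplitude_nA
  n <- length(a)
  if (n < 10) abort("NpRf requires at least 10 stimuli.")
  if (diff(range(a)) < 1e-12 * max(abs(a), 1)) {
    abort("NpRf is degenerate on a flat train (p unidentifiable).")
  }
  total <- sum(a)
  obj <- function(theta) sum((.nprf_predict(theta, n) - a)^2)
  starts <- expand.grid(N = c(total * 0.5, total, total * 2),
                        p = c(0.05, 0.15, 0.4),
                        R = c(0.05, 0.3, 0.7))
  lower <- c(a[1], 1e-6, 0); upper <- c(total * 20, 1, 1)
  fits <- apply(starts, 1, function(s) {
    tryCatch(nlminb(pmin(pmax(as.numeric(s), lower), upper), obj,
                    lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("NpRf optimisation failed from every start.")
  best <- fits[[which.min(purrr::map_dbl(fits, "objective"))]]
  if (!is.finite(best$objective)) {
    abort("NpRf optimisation did not converge; inspect the train.")
  }
  th <- best$par
  .new_quantal("NpRf", rrp = th[1], pr = th[2], replenishment = th[3],
               diagnostics = list(rss = best$objective,
                                  convergence = best$convergence,
                                  message = best$message),
               q = attr(train, "q") %||% NA_real_)
}

#' Descriptive train metrics
#'
#' @param train An `epsc_train` with >= 2 stimuli.
#' @param ss_window Number of final stimuli averaged for the steady state
#'   (default 10, i.e. EPSC 41-50 of a 50-AP train).
#' @return One-row tibble: `epsc1`, `ppr` (EPSC2/EPSC1), `epsc_ss`,
#'   `depression_ratio` (EPSC_ss/EPSC1).
#' @export
train_metrics <- function(train, ss_window = 10) {
  a <- train$amplitude_nA
  if (length(a) < 2) abort("train metrics need at least 2 stimuli.")
  ss <- mean(tail(a, min(ss_window, length(a))))
  tibble(epsc1 = a[1], ppr = a[2] / a[1], epsc_ss = ss,
         depression_ratio = ss / a[1])
}

#' Effective EPSC duration
#'
#' Charge divided by peak amplitude: the width (ms) of a square pulse with
#' the same amplitude and charge, a proxy for release synchronicity.
#'
#' @param charge_pC EPSC charge, pC (vectorised).
#' @param amplitude_nA EPSC peak amplitude, nA (> 0).
#' @return Duration(s) in ms (pC / nA = ms).
#' @export
effective_duration <- function(charge_pC, amplitude_nA) {
  if (any(amplitude_nA <= 0)) abort("`amplitude_nA` must be > 0.")
  charge_pC / amplitude_nA
}
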