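# Core kinetic simulators: single-pool and sequential two-step priming/fusion.
#
# Internal unit system: time s, concentrations nM, rates 1/s. The user-facing
# Michaelis parameters (sigma, k_half) are per uM and converted here, once.

.rate_at <- function(dca_nM, rest, sigma_uM, khalf_uM) {
  dca_um <- dca_nM / 1000
  (rest + sigma_uM * dca_um) / (1 + dca_um / khalf_uM)
}

# derivative functions for deSolve; `p` carries dca0 (elevation above rest at
# segment start, nM) so effective Ca2+ is evaluated in closed form at any t
.deriv_single_pool <- function(t, y, p) {
  kf <- .rate_at(p$dca0 * exp(-p$k_ca * t), p$kf_rest, p$sigma, p$k_half)
  flux <- kf * y[1] - p$kb * y[2]
  list(c(-flux, flux))
}

.deriv_two_step <- function(t, y, p) {
  dca <- p$dca0 * exp(-p$k_ca * t)
  k1 <- .rate_at(dca, p$k1_rest, p$sigma1, p$k1_half)
  k2 <- .rate_at(dca, p$k2_rest, p$sigma2, p$k2_half)
  f1 <- k1 * y[1] - p$b1 * y[2]   # ES -> LS
  f2 <- k2 * y[2] - p$b2 * y[3]   # LS -> TS
  list(c(-f1, f1 - f2, f2))
}

.ode_parms <- function(params, calcium, dca0) {
  c(params[setdiff(names(params), c("n_total", "q"))],
    list(k_ca = calcium$k_ca, dca0 = dca0))
}

.integrate_segment <- function(occ, dt, params, calcium, dca0,
                               rtol = 1e-8, atol = 1e-10) {
  if (dt <= 0) return(occ)
  deriv <- if (inherits(params, "single_pool_params")) .deriv_single_pool else .deriv_two_step
  sol <- deSolve::ode(occ, c(0, dt), deriv, parms = .ode_parms(params, calcium, dca0),
                      method = deSolve::rkMethod("rk45f"), rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE integration failed over a %.6g s segment.", dt))
  }
  setNames(as.numeric(sol[nrow(sol), -1]), names(occ))
}

#' Resting state of a priming model
#'
#' Analytic steady state of the occupancy equations at resting \[Ca2+\], with
#' facilitation/depression variables at 1.
#'
#' @param params A [single_pool_params()] or [two_step_params()] object.
#' @param calcium A [calcium_dynamics()] object.
#' @return An `stp_state` list: `t`, `ca` (nM), `y`, `z` and a named
#'   `occupancy` vector (`n_e`, `n_o`, or `es`, `ls`, `ts`) summing to
#'   `n_total`.
#' @examples
#' p <- single_pool_params(1000, kf_rest = 0.2, sigma = 10, k_half = 2,
#'                         kb = 0.2)
#' resting_state(p, calcium_dynamics())$occupancy  # 500/500 split
#' @export
resting_state <- function(params, calcium = calcium_dynamics()) {
  UseMethod("resting_state")
}

#' @export
resting_state.single_pool_params <- function(params, calcium = calcium_dynamics()) {
  if (params$kf_rest + params$kb <= 0) {
    abort("resting state undefined when kf_rest = kb = 0; supply an explicit state.")
  }
  n_o <- params$n_total * params$kf_rest / (params$kf_rest + params$kb)
  .new_state(0, calcium$ca_rest, c(n_e = params$n_total - n_o, n_o = n_o))
}

#' @export
resting_state.two_step_params <- function(params, calcium = calcium_dynamics()) {
  N <- params$n_total
  if (params$b2 == 0) {
    occ <- c(es = 0, ls = 0, ts = N)
  } else if (params$b1 == 0) {
    # ES drains completely; LS/TS split by detailed balance of step 2
    r2 <- params$k2_rest / params$b2
    ls <- N / (1 + r2)
    occ <- c(es = 0, ls = ls, ts = N - ls)
  } else {
    r1 <- params$k1_rest / params$b1
    r2 <- params$k2_rest / params$b2
    es <- N / (1 + r1 + r1 * r2)
    occ <- c(es = es, ls = es * r1, ts = es * r1 * r2)
  }
  .new_state(0, calcium$ca_rest, occ)
}

.new_state <- function(t, ca, occupancy, y = 1, z = 1) {
  structure(list(t = t, ca = ca, y = y, z = z, occupancy = occupancy),
            class = "stp_state")
}

#' Construct an explicit model state
#'
#' Mainly useful to start [simulate_train()] away from rest, e.g. with a
#' prescribed occupied pool and replenishment switched off.
#'
#' @param occupancy Named vector: `c(n_e=, n_o=)` (single pool) or
#'   `c(es=, ls=, ts=)` (two-step).
#' @param ca Effective \[Ca2+\], nM.
#' @param y,z Facilitation/depression variables.
#' @param t State time, s.
#' @return An `stp_state`.
#' @export
model_state <- function(occupancy, ca = 50, y = 1, z = 1, t = 0) {
  ok <- identical(sort(names(occupancy)), c("n_e", "n_o")) ||
    identical(sort(names(occupancy)), c("es", "ls", "ts"))
  if (!ok) abort("`occupancy` must be named c(n_e=, n_o=) or c(es=, ls=, ts=).")
  if (any(occupancy < 0)) abort("occupancies must be >= 0.")
  .new_state(t, ca, occupancy[intersect(c("n_e", "n_o", "es", "ls", "ts"),
                                        names(occupancy))], y, z)
}

#' @export
print.stp_state <- function(x, ...) {
  cat(sprintf("<stp_state> t = %g s, ca = %g nM, y = %g, z = %g\n  occupancy: %s\n",
              x$t, x$ca, x$y, x$z,
              paste(sprintf("%s = %.6g", names(x$occupancy), x$occupancy),
                    collapse = ", ")))
  invisible(x)
}

#' Per-AP release probability sequence
#'
#' Applies the facilitation/depression recursion of [pr_dynamics()] along a
#' protocol: P_r is evaluated from the current `(y, z)`, the per-AP increments
#' are applied, and both variables then relax exponentially towards 1 over the
#' inter-stimulus interval. Probabilities exceeding 1 are clipped with a
#' warning.
#'
#' @param protocol A [stim_protocol()].
#' @param dyn A [pr_dynamics()] object.
#' @return A tibble with `stimulus_index`, `ap_time_s`, `pr`, `y`, `z`.
#' @export
pr_sequence <- function(protocol, dyn) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(dyn, "pr_dynamics"))
  if (dyn$pr1 * dyn$y_max^dyn$facilitation_exponent > 1) {
    warn("pr1 * y_max^exponent exceeds 1; release probabilities will be clipped at 1.")
  }
  times <- protocol$ap_time_s
  n <- length(times)
  pr <- yv <- zv <- numeric(n)
  y <- 1; z <- 1
  for (j in seq_len(n)) {
    yv[j] <- y; zv[j] <- z
    pr[j] <- min(dyn$pr1 * y^dyn$facilitation_exponent * z, 1)
    y <- y + dyn$y_inc1 * (dyn$y_max - y)
    z <- z - dyn$z_dec1 * (z - dyn$z_min)
    if (j < n) {
      dt <- times[j + 1] - times[j]
      y <- 1 + (y - 1) * exp(-dyn$k_y * dt)
      z <- 1 + (z - 1) * exp(-dyn$k_z * dt)
    }
  }
  tibble(stimulus_index = protocol$stimulus_index, ap_time_s = times,
         pr = pr, y = yv, z = zv)
}

.fusion_component <- function(params) {
  if (inherits(params, "single_pool_params")) "n_o" else "ts"
}

#' Simulate an EPSC train
#'
#' Event-driven simulation of AP-evoked release: at each AP the release
#' probability is evaluated from the facilitation/depression state, the
#' quantal content is drawn from the fusion-competent pool (mean-field in
#' deterministic mode, binomial in stochastic mode), vacated sites return to
#' the empty pool, effective \[Ca2+\] jumps by `delta_ca_ap`, and the
#' occupancy ODEs are integrated to the next AP with an adaptive
#' Runge-Kutta-Fehlberg 4(5) scheme (interval-by-interval, so AP events are
#' handled exactly).
#'
#' @param protocol A [stim_protocol()].
#' @param params [single_pool_params()] or [two_step_params()].
#' @param calcium A [calcium_dynamics()] object.
#' @param pr_dyn A [pr_dynamics()] object.
#' @param mode `"deterministic"` (continuous occupancies) or `"stochastic"`
#'   (binomial release at APs; inter-AP kinetics stay mean-field).
#' @param seed RNG seed; required in stochastic mode.
#' @param init_state Optional `stp_state` to start from (default:
#'   [resting_state()]).
#' @param rtol,atol Integrator tolerances.
#' @return An `epsc_train` tibble with columns `stimulus_index`, `ap_time_s`,
#'   `amplitude_nA`, `m_j`, `pr_j`, `pool_before`; the state trajectory
#'   (pre/post each AP) is attached as attribute `"trajectory"` and the final
#'   state as `"final_state"`.
#' @examples
#' p <- single_pool_params(2000, kf_rest = 0.3, sigma = 10, k_half = 2,
#'                         kb = 0.1, q = 0.01)
#' tr <- simulate_train(gen_regular_protocol(10, 100), p,
#'                      calcium_dynamics(delta_ca_ap = 150),
#'                      pr_dynamics(pr1 = 0.1))
#' tr$amplitude_nA
#' @export
simulate_train <- function(protocol, params, calcium, pr_dyn,
                           mode = c("deterministic", "stochastic"),
                           seed = NULL, init_state = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(calcium, "calcium_dynamics"),
            inherits(pr_dyn, "pr_dynamics"))
  if (mode == "stochastic") {
    if (is.null(seed)) abort("stochastic mode requires a `seed`.")
    set.seed(seed)
  }
  state <- init_state %||% resting_state(params, calcium)
  stopifnot(inherits(state, "stp_state"))
  fuse <- .fusion_component(params)
  times <- protocol$ap_time_s
  n <- length(times)
  exponent <- pr_dyn$facilitation_exponent
  clip_warned <- FALSE

  occ <- state$occupancy
  ca <- state$ca; y <- state$y; z <- state$z
  m <- pr <- pool <- numeric(n)
  traj <- vector("list", 2 * n)

  for (j in seq_len(n)) {
    pr_j <- pr_dyn$pr1 * y^exponent * z
    if (pr_j > 1) {
      if (!clip_warned) {
        warn("release probability exceeded 1 and was clipped.")
        clip_warned <- TRUE
      }
      pr_j <- 1
    }
    pool[j] <- occ[[fuse]]
    m[j] <- if (mode == "deterministic") {
      pr_j * pool[j]
    } else {
      rbinom(1, max(0L, as.integer(round(pool[j]))), pr_j)
    }
    pr[j] <- pr_j
    traj[[2 * j - 1]] <- c(t = times[j], ca = ca, y = y, z = z, occ, phase = 0)
    # release: vacated sites become empty and immediately available
    occ[[fuse]] <- occ[[fuse]] - m[j]
    occ[[1]] <- occ[[1]] + m[j]
    ca <- ca + calcium$delta_ca_ap
    y <- y + pr_dyn$y_inc1 * (pr_dyn$y_max - y)
    z <- z - pr_dyn$z_dec1 * (z - pr_dyn$z_min)
    traj[[2 * j]] <- c(t = times[j], ca = ca, y = y, z = z, occ, phase = 1)
    if (j < n) {
      dt <- times[j + 1] - times[j]
      occ <- .integrate_segment(occ, dt, params, calcium, ca - calcium$ca_rest,
                                rtol, atol)
      ca <- ca_after(ca, dt, calcium)
      y <- 1 + (y - 1) * exp(-pr_dyn$k_y * dt)
      z <- 1 + (z - 1) * exp(-pr_dyn$k_z * dt)
    }
  }

  traj <- as_tibble(do.call(rbind, traj))
  names(traj) <- c("t_s", "ca_nM", "y", "z", names(occ), "phase")
  traj$phase <- ifelse(traj$phase == 0, "pre", "post")

  out <- tibble(stimulus_index = protocol$stimulus_index,
                ap_time_s = times,
                amplitude_nA = m * params$q,
                m_j = m, pr_j = pr, pool_before = pool)
  attr(out, "mode") <- mode
  attr(out, "q") <- params$q
  attr(out, "trajectory") <- traj
  attr(out, "final_state") <- .new_state(times[n], ca, occ, y, z)
  class(out) <- c("epsc_train", class(out))
  out
}

#' Construct an EPSC train from measured amplitudes
#'
#' @param amplitudes Per-stimulus peak amplitudes, nA.
#' @param ap_times AP times, s (default: indices as a unit-rate train).
#' @param charges Optional per-stimulus charges, pC.
#' @param q Optional quantal amplitude, nA.
#' @param mode Provenance tag.
#' @return An `epsc_train` tibble.
#' @export
epsc_train <- function(amplitudes, ap_times = seq_along(amplitudes) - 1,
                       charges = NULL, q = NA_real_, mode = "experimental") {
  if (length(ap_times) != length(amplitudes)) {
    abort("`amplitudes` and `ap_times` must have equal length.")
  }
  if (any(!is.finite(amplitudes))) abort("`amplitudes` must be finite.")
  out <- tibble(stimulus_index = seq_along(amplitudes),
                ap_time_s = as.numeric(ap_times),
                amplitude_nA = as.numeric(amplitudes))
  if (!is.null(charges)) {
    if (length(charges) != length(amplitudes)) {
      abort("`charges` must match `amplitudes` in length.")
    }
    out$charge_pC <- as.numeric(charges)
  }
  attr(out, "mode") <- mode
  attr(out, "q") <- q
  class(out) <- c("epsc_train", class(out))
  out
}

#' Evolve a model state through a silent period
#'
#' Integrates the occupancy ODEs (with decaying effective \[Ca2+\]) over `dt`
#' seconds and relaxes the facilitation/depression variables in closed form.
#'
#' @param state An `stp_state`.
#' @param dt Duration, s.
#' @inheritParams simulate_train
#' @return The evolved `stp_state`.
#' @export
evolve_state <- function(state, dt, params, calcium, pr_dyn,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state, "stp_state"))
  if (dt < 0) abort("`dt` must be >= 0.")
  occ <- .integrate_segment(state$occupancy, dt, params, calcium,
                            state$ca - calcium$ca_rest, rtol, atol)
  .new_state(state$t + dt, ca_after(state$ca, dt, calcium), occ,
             y = 1 + (state$y - 1) * exp(-pr_dyn$k_y * dt),
             z = 1 + (state$z - 1) * exp(-pr_dyn$k_z * dt))
}

#' Simulate a paired-train recovery experiment
#'
#' Runs a conditioning train, carries the depleted state through each silent
#' recovery interval, then simulates the test train from that state.
#'
#' @inheritParams simulate_train
#' @param cond_protocol Conditioning [stim_protocol()].
#' @param intervals Recovery intervals, s (> 0).
#' @param test_protocol Test [stim_protocol()] with times relative to its
#'   onset.
#' @param ss_window Number of final conditioning stimuli averaged for the
#'   steady-state amplitude.
#' @return A `recovery_dataset`: list with the conditioning train and summary
#'   amplitudes plus a `points` tibble (`interval_s`, `epsc_test1`,
#'   `frac_recovery`, list-column `test_train`).
#' @export
recovery_curve <- function(params, calcium, pr_dyn, cond_protocol, intervals,
                           test_protocol, mode = "deterministic", seed = NULL,
                           ss_window = 10, rtol = 1e-8, atol = 1e-10) {
  if (any(intervals <= 0)) abort("`intervals` must be > 0 (protocols must not overlap).")
  intervals <- sort(as.numeric(intervals))
  cond <- simulate_train(cond_protocol, params, calcium, pr_dyn, mode = mode,
                         seed = seed, rtol = rtol, atol = atol)
  state0 <- attr(cond, "final_state")
  cond_end <- max(cond_protocol$ap_time_s)
  test_rel <- test_protocol$ap_time_s - test_protocol$ap_time_s[1]
  cond_epsc1 <- cond$amplitude_nA[1]
  cond_ss <- mean(tail(cond$amplitude_nA, ss_window))

  points <- purrr::map_dfr(seq_along(intervals), function(i) {
    iv <- intervals[i]
    st <- evolve_state(state0, iv, params, calcium, pr_dyn, rtol, atol)
    prot <- stim_protocol(cond_end + iv + test_rel)
    test <- simulate_train(prot, params, calcium, pr_dyn, mode = mode,
                           seed = if (is.null(seed)) NULL else seed + i,
                           init_state = st, rtol = rtol, atol = atol)
    tibble(interval_s = iv, epsc_test1 = test$amplitude_nA[1],
           frac_recovery = fractional_recovery(test$amplitude_nA[1],
                                               cond_epsc1, cond_ss),
           test_train = list(test))
  })

  structure(list(cond_train = cond, cond_epsc1 = cond_epsc1,
                 cond_epsc_ss = cond_ss, points = points),
            class = "recovery_dataset")
}

#' @export
print.recovery_dataset <- function(x, ...) {
  cat(sprintf("<recovery_dataset> conditioning EPSC1 %.4g nA, steady state %.4g nA; %d recovery intervals (%.3g - %.3g s)\n",
              x$cond_epsc1, x$cond_epsc_ss, nrow(x$points),
              min(x$points$interval_s), max(x$points$interval_s)))
  invisible(x)
}
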