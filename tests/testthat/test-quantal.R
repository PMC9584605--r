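# Quantal analysis: EQ, SMN, NpRf estimators, train metrics, effective
# duration and Boltzmann onset delay.

test_that("EQ recovers pool and release probability exactly on pure depletion", {
  q <- 0.012
  tr <- geom_depletion_train(pr = 0.165, pool = 2532, n_stim = 40, q = q)
  est <- eq_estimate(tr, n_points = 4)
  expect_equal(est$pr, 0.165, tolerance = 1e-9)
  expect_equal(est$rrp / q, 2532, tolerance = 1e-9)
  # internal consistency: pr = EPSC1 / RRP by construction
  expect_equal(est$pr, tr$amplitude_nA[1] / est$rrp)
  # unit invariance: rescaling amplitudes rescales rrp, not pr
  tr_pA <- epsc_train(tr$amplitude_nA * 1000, tr$ap_time_s)
  est_pA <- eq_estimate(tr_pA)
  expect_equal(est_pA$pr, est$pr, tolerance = 1e-9)
  expect_equal(est_pA$rrp, est$rrp * 1000, tolerance = 1e-6)
})

test_that("EQ rejects non-depressing trains and is biased up by replenishment", {
  flat <- epsc_train(rep(1, 10))
  expect_error(eq_estimate(flat), "depressing")
  cfg <- demo_single_pool()
  tr <- simulate_train(gen_regular_protocol(40, 500), cfg$params, cfg$calcium,
                       cfg$pr_dyn)
  true_pool_amp <- resting_state(cfg$params, cfg$calcium)$occupancy[["n_o"]] *
    cfg$params$q
  est <- eq_estimate(tr)
  expect_gt(est$rrp, true_pool_amp)  # replenishment inflates the intercept
})

test_that("SMN back-extrapolation matches the geometric series total", {
  tr <- geom_depletion_train(pr = 0.25, pool = 1500, n_stim = 120, q = 1)
  est <- smn_estimate(tr, corrected = FALSE)
  expect_equal(est$rrp, 1500, tolerance = 1e-9)
  # identical amplitudes: replenishment-dominated limit, intercept ~ 0
  flat <- epsc_train(rep(2, 40))
  est_flat <- tryCatch(smn_estimate(flat, corrected = FALSE),
                       error = function(e) e)
  if (inherits(est_flat, "quantal_estimate")) {
    expect_lt(abs(est_flat$rrp), 1e-6)
  } else {
    expect_s3_class(est_flat, "error")  # intercept 0 fails the rrp > 0 guard
  }
})

test_that("the SMN correction moves the estimate towards the true pool", {
  cfg <- demo_single_pool()
  tr <- simulate_train(gen_regular_protocol(50, 500), cfg$params, cfg$calcium,
                       cfg$pr_dyn)
  truth <- resting_state(cfg$params, cfg$calcium)$occupancy[["n_o"]] *
    cfg$params$q
  un <- smn_estimate(tr, corrected = FALSE)
  co <- smn_estimate(tr, corrected = TRUE)
  expect_lt(abs(co$rrp - truth), abs(un$rrp - truth))
})

test_that("NpRf recovers its own generating parameters and degenerates properly", {
  a <- stpkit:::.nprf_predict(c(2000, 0.1, 0.3), 30)
  est <- nprf_estimate(epsc_train(a))
  expect_equal(est$rrp, 2000, tolerance = 1e-3)
  expect_equal(est$pr, 0.1, tolerance = 1e-3)
  expect_equal(est$replenishment, 0.3, tolerance = 1e-3)
  # R = 0 reduces to geometric depletion; p matches the EQ slope
  tr0 <- geom_depletion_train(pr = 0.2, pool = 1000, n_stim = 20, q = 1)
  est0 <- nprf_estimate(tr0)
  eq0 <- eq_estimate(tr0)
  expect_equal(est0$pr, eq0$pr, tolerance = 1e-4)
  expect_equal(est0$replenishment, 0, tolerance = 1e-4)
  expect_error(nprf_estimate(epsc_train(rep(1, 20))), "flat")
  expect_error(nprf_estimate(epsc_train(c(2, 1))), "10 stimuli")
})

test_that("train metrics report PPR, steady state and depression ratio", {
  m <- train_metrics(epsc_train(c(2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)))
  expect_equal(m$ppr, 0.5)
  m2 <- train_metrics(epsc_train(rep(3, 20)))
  expect_equal(m2$depression_ratio, 1)
  # geometric depletion decays towards zero steady state
  tr <- geom_depletion_train(pr = 0.2, pool = 1000, n_stim = 50, q = 1)
  m3 <- train_metrics(tr)
  expect_equal(m3$ppr, 0.8, tolerance = 1e-9)
  expect_equal(m3$epsc_ss / m3$epsc1,
               mean(0.8^(40:49)), tolerance = 1e-9)
})

test_that("effective duration equals charge over amplitude with exponential identities", {
  expect_equal(effective_duration(1.5, 3), 0.5)  # square pulse width
  # mono-exponential EPSC: charge = A * tau, so duration = tau
  A <- 2; tau <- 0.4
  expect_equal(effective_duration(A * tau, A), tau)
  # bi-exponential waveform: numeric-integration oracle
  k <- mepsc_kernel(tau_rise_ms = 0.1, tau_decay_ms = 0.5, amplitude_nA = -1)
  t <- seq(0, 20, by = 1e-4)
  w <- k$eval(t)
  charge <- sum(w) * 1e-4   # pC if nA * ms
  peak <- min(w)
  expect_equal(effective_duration(abs(charge), abs(peak)),
               (0.5 - 0.1) / (exp(-k$t_peak_ms / 0.5) - exp(-k$t_peak_ms / 0.1)),
               tolerance = 1e-3)
  expect_error(effective_duration(1, 0), "amplitude")
})

test_that("Boltzmann onset delay matches the analytic extreme-curvature point", {
  tr <- boltzmann_trace(A = 1, t50 = 1, k = 0.1)
  d <- onset_delay(tr, stim_time_ms = 0)
  expect_equal(d, (1 - 0.1 * log(2 + sqrt(3))) * 1000, tolerance = 1e-3)
  # oracle: numeric extremum of the second derivative of the fitted sigmoid
  tt <- seq(0.2, 1.8, by = 1e-5)
  b <- 1 / (1 + exp((1 - tt) / 0.1))
  d2 <- diff(b, differences = 2)
  t_num <- tt[which.max(d2) + 1]
  expect_equal(d / 1000, t_num, tolerance = 1e-3)
  # translation equivariance and amplitude invariance
  d_shift <- onset_delay(boltzmann_trace(shift = 0.5), stim_time_ms = 0.5)
  expect_equal(d_shift, d, tolerance = 1e-6)
  d_scaled <- onset_delay(boltzmann_trace(A = 25), stim_time_ms = 0)
  expect_equal(d_scaled, d, tolerance = 1e-6)
  flat <- tibble::tibble(time_ms = seq(0, 3, 0.01),
                         current_nA = rep(0, 301))
  expect_error(onset_delay(flat, 0), "deflection")
})
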