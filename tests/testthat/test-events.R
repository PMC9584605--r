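# Event analysis: mEPSC detection/metrics, spike matching, delay/jitter,
# preceding activity and binned statistics.

test_that("a single injected event is detected with its template amplitude", {
  k <- mepsc_kernel(0.2, 1.5, amplitude_nA = -0.08)
  t <- seq(0, 1000, by = 0.05)
  cur <- numeric(length(t))
  sel <- t >= 400 & t <= 430
  cur[sel] <- k$eval(t[sel] - 400)
  det <- detect_minis(tibble::tibble(time_ms = t, current_nA = cur),
                      min_separation_ms = 2)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$amplitude_nA, -0.08, tolerance = 0.01)
  expect_equal(det$events$t_peak_ms, 400 + k$t_peak_ms, tolerance = 0.1)
  expect_error(detect_minis(tibble::tibble(time_ms = numeric(),
                                           current_nA = numeric())),
               "short")
})

test_that("Poisson event rates are recovered within counting error", {
  lam <- 10; dur <- 60
  tr <- gen_mepsc_trace(dur, lam, mepsc_kernel(0.2, 1.5, -0.08),
                        noise_sd_nA = 0.01, fs_khz = 10, seed = 21)
  # event-free baseline stretch taken from the ground-truth sidecar
  ev <- ground_truth(tr)$event_times_ms
  gaps <- which(diff(c(0, ev)) > 120)
  base_start <- c(0, ev)[gaps[1]] + 10
  det <- detect_minis(tr, threshold_sd = 5, min_separation_ms = 2,
                      baseline_window_ms = base_start + c(0, 100))
  expect_lt(abs(det$frequency_hz - lam), 3 * sqrt(lam / dur))
})

test_that("overlapping events are excluded, not merged", {
  k <- mepsc_kernel(0.1, 0.5, amplitude_nA = -0.05)
  t <- seq(0, 500, by = 0.02)
  set.seed(3)
  cur <- rnorm(length(t), 0, 0.001)
  for (t0 in c(300, 301)) {  # two events 1 ms apart
    sel <- t >= t0 & t <= t0 + 6
    cur[sel] <- cur[sel] + k$eval(t[sel] - t0)
  }
  det <- detect_minis(tibble::tibble(time_ms = t, current_nA = cur),
                      min_separation_ms = 5)
  expect_equal(nrow(det$events), 0)
  expect_equal(det$n_excluded_overlap, 2)
})

test_that("false positives on pure noise are rare at a 5 SD threshold", {
  fp <- vapply(1:5, function(s) {
    tr <- gen_mepsc_trace(60, rate_hz = 0, noise_sd_nA = 0.01, fs_khz = 10,
                          seed = s)
    nrow(detect_minis(tr, threshold_sd = 5, min_separation_ms = 2)$events)
  }, 0)
  expect_lt(mean(fp), 1)
})

test_that("event metrics match triangles and the bi-exponential oracle", {
  dt <- 0.001
  up <- seq(0, 1, by = dt); down <- seq(1 - dt, 0, by = -dt)
  wf <- tibble::tibble(time_ms = seq(0, by = dt,
                                     length.out = length(up) + length(down) + 600),
                       current_nA = c(rep(0, 400), up, down, rep(0, 200)))
  m <- event_metrics(wf, direction = "positive")
  expect_equal(m$rise_10_90_ms, 0.8, tolerance = 1e-3)
  expect_equal(m$fwhm_ms, 1, tolerance = 1e-3)
  expect_equal(m$amplitude_nA, 1, tolerance = 1e-6)
  # bi-exponential template: oracle = root finding on the analytic kernel
  k <- mepsc_kernel(0.1, 0.5, amplitude_nA = -1)
  t <- seq(0, 12, by = 1e-4)
  wf2 <- tibble::tibble(time_ms = t, current_nA = k$eval(t - 2))
  m2 <- event_metrics(wf2)
  f <- function(x) -k$eval(x)  # positive-going for root finding
  cross <- function(level, lo, hi) uniroot(function(x) f(x) - level, c(lo, hi),
                                           tol = 1e-10)$root
  rise_oracle <- cross(0.9, k$t_peak_ms * 0.2, k$t_peak_ms) - cross(0.1, 0, k$t_peak_ms)
  fwhm_oracle <- cross(0.5, k$t_peak_ms, 10) - cross(0.5, 0, k$t_peak_ms)
  expect_equal(m2$rise_10_90_ms, rise_oracle, tolerance = 0.01)
  expect_equal(m2$fwhm_ms, fwhm_oracle, tolerance = 0.01)
  expect_error(event_metrics(wf2[1:which.min(wf2$current_nA), ]),
               "down-crossing")
  expect_error(event_metrics(tibble::tibble(time_ms = seq(0, 1, 0.01),
                                            current_nA = rep(0, 101))),
               "peak")
})

test_that("AP success counts greedy matches inside the window", {
  stim <- seq(0, 90, by = 10)
  expect_equal(ap_success(stim, stim + 0.5, window_ms = 2), 1)
  expect_equal(ap_success(stim, numeric(0), window_ms = 2), 0)
  # constructed 30% deletion
  set.seed(5)
  keep <- sample(c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_equal(ap_success(stim, (stim + 0.5)[keep], window_ms = 2), 0.7)
  # invariance under global time translation
  expect_equal(ap_success(stim + 123, (stim + 0.5)[keep] + 123, 2), 0.7)
  # each AP consumed once: one AP cannot serve two stimuli (window wider than
  # the ISI here, hence the suppressed guard warning)
  expect_equal(suppressWarnings(ap_success(c(0, 1), c(0.5), window_ms = 2)), 0.5)
})

test_that("delay and jitter are the moments of matched latencies", {
  stim <- seq(0, 90, by = 10)
  dj <- delay_jitter(stim, stim + 0.5, window_ms = 2)
  expect_equal(dj$mean_delay_us, 500)
  expect_equal(dj$jitter_us, 0)
  dj2 <- delay_jitter(c(0, 10), c(0.1, 10.3), window_ms = 2)
  expect_equal(dj2$mean_delay_us, 200)
  expect_equal(dj2$jitter_us, sd(c(100, 300)))
  expect_error(delay_jitter(c(0, 10), c(0.1), window_ms = 2), "2 successful")
  # large-sample SD recovery
  set.seed(13)
  n <- 1e4
  stim <- seq(0, by = 10, length.out = n)
  aps <- stim + rnorm(n, 300, 65) / 1000
  dj3 <- delay_jitter(stim, aps, window_ms = 2)
  expect_lt(abs(dj3$jitter_us / 65 - 1), 0.03)
})

test_that("preceding activity follows the exponential-kernel series", {
  expect_equal(preceding_activity(c(0))[1], 0)
  expect_equal(preceding_activity(c(0, 30))[2], exp(-1))
  # regular 100 Hz train converges to the geometric limit r/(1-r), r = e^(-1/3)
  tt <- seq(0, by = 10, length.out = 201)
  act <- preceding_activity(tt, tau_ms = 30)
  r <- exp(-10 / 30)
  expect_equal(act[201], r / (1 - r), tolerance = 1e-6)
  # brute-force oracle at an arbitrary index
  idx <- 37
  expect_equal(act[idx], sum(exp(-(tt[idx] - tt[1:(idx - 1)]) / 30)),
               tolerance = 1e-12)
  # monotone in tau for a fixed history
  a10 <- preceding_activity(tt, tau_ms = 10)
  a100 <- preceding_activity(tt, tau_ms = 100)
  expect_true(all(a100[-1] > a10[-1]))
})

test_that("binned statistics use half-open bins and flag empty ones", {
  df <- data.frame(v = c(1, 2, 3, 10), x = c(0.5, 1.0, 1.5, 5))
  b <- binned_stats(df, "v", "x", bin_edges = c(0, 1, 2, 3))
  expect_equal(b$n, c(1, 2, 0))
  expect_equal(b$mean[1:2], c(1, 2.5))       # x = 1.0 joins [1, 2)
  expect_true(b$empty[3])
  one <- binned_stats(df, "v", "x", bin_edges = c(0, 100))
  expect_equal(one$mean, mean(df$v))
  expect_equal(one$sd, sd(df$v))
  expect_error(binned_stats(df, "v", "x", c(3, 1)), "increasing")
})
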