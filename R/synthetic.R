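# Synthetic-data generators: every input the analysis chain consumes can be
# produced here with known ground truth, so the whole pipeline is testable
# without recordings. All generators take a mandatory seed and attach their
# generating parameters as a `ground_truth` attribute (the "sidecar").

.with_truth <- function(x, truth) {
  attr(x, "ground_truth") <- truth
  x
}

#' Ground truth attached to a synthetic object
#' @param x A generator output.
#' @return The generating parameters (list), or NULL.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Add Gaussian amplitude noise to a simulated train
#'
#' @param train An `epsc_train`.
#' @param amp_noise_sd Amplitude noise SD, nA (>= 0; 0 returns the input
#'   unchanged).
#' @param seed RNG seed (mandatory).
#' @return An `epsc_train` with perturbed `amplitude_nA`.
#' @export
gen_noisy_train <- function(train, amp_noise_sd, seed) {
  if (amp_noise_sd < 0) abort("`amp_noise_sd` must be >= 0.")
  if (amp_noise_sd == 0) return(train)
  set.seed(seed)
  out <- train
  out$amplitude_nA <- train$amplitude_nA + rnorm(nrow(train), 0, amp_noise_sd)
  .with_truth(out, list(amp_noise_sd = amp_noise_sd, seed = seed,
                        clean_amplitudes = train$amplitude_nA))
}

#' Bi-exponential mEPSC kernel
#'
#' Difference-of-exponentials waveform normalised so its extremum equals
#' `amplitude_nA` (negative for inward events).
#'
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants, ms
#'   (`tau_decay_ms > tau_rise_ms`).
#' @param amplitude_nA Peak amplitude, nA (negative = inward; default -0.05).
#' @return A `mepsc_kernel` list with an `eval(t_ms)` closure.
#' @export
mepsc_kernel <- function(tau_rise_ms = 0.1, tau_decay_ms = 0.5,
                         amplitude_nA = -0.05) {
  if (tau_rise_ms <= 0 || tau_decay_ms <= tau_rise_ms) {
    abort("need 0 < tau_rise_ms < tau_decay_ms.")
  }
  # peak time and normalisation of exp(-t/td) - exp(-t/tr)
  tpk <- log(tau_decay_ms / tau_rise_ms) /
    (1 / tau_rise_ms - 1 / tau_decay_ms)
  pk <- exp(-tpk / tau_decay_ms) - exp(-tpk / tau_rise_ms)
  structure(list(tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 amplitude_nA = amplitude_nA, t_peak_ms = tpk,
                 eval = function(t_ms) {
                   out <- numeric(length(t_ms))
                   pos <- t_ms >= 0
                   out[pos] <- amplitude_nA / pk *
                     (exp(-t_ms[pos] / tau_decay_ms) - exp(-t_ms[pos] / tau_rise_ms))
                   out
                 }),
            class = "mepsc_kernel")
}

#' Synthetic mEPSC trace
#'
#' Homogeneous Poisson event times convolved with a bi-exponential kernel plus
#' Gaussian baseline noise.
#'
#' @param duration_s Trace duration, s.
#' @param rate_hz Event rate, Hz (0 gives pure noise).
#' @param kernel A [mepsc_kernel()].
#' @param noise_sd_nA Gaussian noise SD, nA.
#' @param fs_khz Sampling rate, kHz.
#' @param seed RNG seed (mandatory).
#' @return Tibble trace (`time_ms`, `current_nA`) with `ground_truth` carrying
#'   the event times and parameters.
#' @export
gen_mepsc_trace <- function(duration_s, rate_hz, kernel = mepsc_kernel(),
                            noise_sd_nA = 0.005, fs_khz = 20, seed) {
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  if (rate_hz < 0) abort("`rate_hz` must be >= 0.")
  set.seed(seed)
  n_ev <- rpois(1, rate_hz * duration_s)
  ev_ms <- sort(runif(n_ev, 0, duration_s * 1000))
  t_ms <- seq(0, duration_s * 1000, by = 1 / fs_khz)
  cur <- rnorm(length(t_ms), 0, noise_sd_nA)
  span_ms <- 10 * kernel$tau_decay_ms
  for (ev in ev_ms) {
    sel <- t_ms >= ev & t_ms <= ev + span_ms
    cur[sel] <- cur[sel] + kernel$eval(t_ms[sel] - ev)
  }
  .with_truth(tibble(time_ms = t_ms, current_nA = cur),
              list(event_times_ms = ev_ms, rate_hz = rate_hz,
                   noise_sd_nA = noise_sd_nA, fs_khz = fs_khz, seed = seed,
                   kernel = kernel[c("tau_rise_ms", "tau_decay_ms", "amplitude_nA")]))
}

#' Sinusoidally amplitude-modulated (SAM) spike pattern
#'
#' Inhomogeneous Poisson process with intensity
#' `carrier_rate_hz * (1 + depth * sin(2 * pi * mod_freq_hz * t))`, generated
#' by thinning, with an absolute refractory period enforced.
#'
#' @param duration_s Duration, s.
#' @param carrier_rate_hz Mean rate, Hz.
#' @param mod_freq_hz Modulation frequency, Hz (a warning is issued outside
#'   the physiological 20-2000 Hz range).
#' @param depth Modulation depth in \[0, 1\].
#' @param seed RNG seed (mandatory).
#' @param refractory_ms Absolute refractory period, ms.
#' @return A [stim_protocol()] with `ground_truth`.
#' @export
gen_sam_spike_pattern <- function(duration_s, carrier_rate_hz, mod_freq_hz,
                                  depth, seed, refractory_ms = 1) {
  if (carrier_rate_hz <= 0) abort("`carrier_rate_hz` must be > 0.")
  if (depth < 0 || depth > 1) abort("`depth` must lie in [0, 1].")
  if (mod_freq_hz < 20 || mod_freq_hz > 2000) {
    warn("`mod_freq_hz` outside the 20-2000 Hz range used experimentally.")
  }
  set.seed(seed)
  lam_max <- carrier_rate_hz * (1 + depth)
  t <- 0; last <- -Inf; out <- numeric(0)
  repeat {
    t <- t + stats::rexp(1, lam_max)
    if (t > duration_s) break
    lam <- carrier_rate_hz * (1 + depth * sin(2 * pi * mod_freq_hz * t))
    if (runif(1) <= lam / lam_max && (t - last) * 1000 >= refractory_ms) {
      out <- c(out, t)
      last <- t
    }
  }
  if (length(out) == 0) abort("no spikes generated; increase duration or rate.")
  .with_truth(stim_protocol(out, label = sprintf("SAM %g Hz mod", mod_freq_hz)),
              list(duration_s = duration_s, carrier_rate_hz = carrier_rate_hz,
                   mod_freq_hz = mod_freq_hz, depth = depth, seed = seed,
                   refractory_ms = refractory_ms))
}

#' Synthetic postsynaptic AP responses to a stimulus protocol
#'
#' Each stimulus triggers an AP with probability `success_p`; the latency is
#' `delay_mean_us + activity_slope_us * preceding_activity` plus Gaussian
#' jitter, so spike timing can be made to degrade with preceding activity.
#'
#' @param protocol A [stim_protocol()] (times in s).
#' @param success_p Per-stimulus success probability.
#' @param delay_mean_us Mean stimulus-to-AP delay, microseconds.
#' @param jitter_sd_us Gaussian latency SD, microseconds.
#' @param activity_slope_us Added delay per unit of exponential-kernel
#'   weighted preceding activity (tau 30 ms), microseconds.
#' @param seed RNG seed (mandatory).
#' @param tau_ms Kernel time constant for the activity dependence.
#' @return List (`spike_record`): `stim_times_ms`, `ap_times_ms`, plus
#'   `ground_truth`.
#' @export
gen_ap_responses <- function(protocol, success_p, delay_mean_us,
                             jitter_sd_us, activity_slope_us = 0, seed,
                             tau_ms = 30) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (success_p < 0 || success_p > 1) abort("`success_p` must lie in [0, 1].")
  if (jitter_sd_us < 0) abort("`jitter_sd_us` must be >= 0.")
  set.seed(seed)
  stim_ms <- protocol$ap_time_s * 1000
  act <- preceding_activity(stim_ms, tau_ms = tau_ms)
  n <- length(stim_ms)
  fired <- runif(n) < success_p
  delay_us <- delay_mean_us + activity_slope_us * act +
    rnorm(n, 0, jitter_sd_us)
  ap_ms <- stim_ms[fired] + pmax(delay_us[fired], 1) / 1000
  rec <- structure(list(stim_times_ms = stim_ms, ap_times_ms = sort(ap_ms)),
                   class = "spike_record")
  .with_truth(rec, list(success_p = success_p, delay_mean_us = delay_mean_us,
                        jitter_sd_us = jitter_sd_us,
                        activity_slope_us = activity_slope_us,
                        tau_ms = tau_ms, seed = seed, fired = fired,
                        activity = act))
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d stimuli, %d APs\n",
              length(x$stim_times_ms), length(x$ap_times_ms)))
  invisible(x)
}
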