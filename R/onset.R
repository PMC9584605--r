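#' EPSC onset delay from a Boltzmann fit of the rising flank
#'
#' Fits `B(t) = A / (1 + exp((t50 - t) / k))` to the rising flank of the first
#' EPSC after `stim_time_ms` and reports the point of extreme curvature of the
#' fitted sigmoid on its leading edge, `t_onset = t50 - k * log(2 + sqrt(3))`
#' (the extremum of the second time-derivative, which is unit-independent).
#' The flank is analysed on the baseline-subtracted, sign-normalised current,
#' so inward (negative) EPSCs are handled transparently and the delay is
#' invariant under amplitude scaling.
#'
#' @param trace Tibble/data frame with columns `time_ms` and `current_nA`,
#'   uniformly sampled.
#' @param stim_time_ms Stimulus time, ms.
#' @param fit_window_ms Window after the stimulus searched for the peak
#'   (default 5 ms).
#' @return Onset delay in microseconds.
#' @export
onset_delay <- function(trace, stim_time_ms, fit_window_ms = 5) {
  .check_trace(trace)
  seg <- trace[trace$time_ms >= stim_time_ms &
               trace$time_ms <= stim_time_ms + fit_window_ms, ]
  if (nrow(seg) < 6) abort("too few samples after `stim_time_ms` for an onset fit.")
  base <- seg$current_nA[1]
  dev <- seg$current_nA - base
  sgn <- sign(dev[which.max(abs(dev))])
  if (sgn == 0) abort("no deflection after the stimulus; cannot fit an onset.")
  yy <- dev * sgn
  ipk <- which.max(yy)
  if (ipk < 4) abort("rising flank too short for a Boltzmann fit.")
  flank <- seg[seq_len(ipk), ]
  tt <- flank$time_ms
  yv <- yy[seq_len(ipk)]
  amp0 <- max(yv)
  t50_0 <- tt[which.min(abs(yv - amp0 / 2))]
  k0 <- max((tt[ipk] - tt[1]) / 10, diff(tt)[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(yv ~ A / (1 + exp((t50 - tt) / k)),
                      start = list(A = amp0, t50 = t50_0, k = k0),
                      lower = c(A = 0, t50 = tt[1] - fit_window_ms, k = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("Boltzmann onset fit failed: ", conditionMessage(e))))
  cf <- coef(fit)
  t_onset <- cf[["t50"]] - cf[["k"]] * log(2 + sqrt(3))
  (t_onset - stim_time_ms) * 1000
}
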