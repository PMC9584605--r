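#' Build a stimulation protocol from AP times
#'
#' A protocol is a tibble with columns `stimulus_index` and `ap_time_s`.
#'
#' @param ap_times Strictly increasing AP times in seconds (non-empty).
#' @param label Optional free-text label stored as an attribute.
#' @return A tibble of class `stim_protocol`.
#' @export
stim_protocol <- function(ap_times, label = NULL) {
  if (length(ap_times) == 0) abort("`ap_times` must be non-empty.")
  if (any(!is.finite(ap_times))) abort("`ap_times` must be finite.")
  if (length(ap_times) > 1 && any(diff(ap_times) <= 0)) {
    abort("`ap_times` must be strictly increasing.")
  }
  out <- tibble(stimulus_index = seq_along(ap_times), ap_time_s = as.numeric(ap_times))
  attr(out, "label") <- label
  class(out) <- c("stim_protocol", class(out))
  out
}

#' Regular stimulus train
#'
#' @param n_stimuli Number of APs (>= 1).
#' @param rate_hz Stimulation frequency in Hz (> 0).
#' @param start_s Time of the first AP, s.
#' @param label Optional label.
#' @return A [stim_protocol()] tibble; `(50, 50)` ends at 0.98 s,
#'   `(50, 500)` at 98 ms.
#' @export
gen_regular_protocol <- function(n_stimuli, rate_hz, start_s = 0, label = NULL) {
  if (n_stimuli < 1) abort("`n_stimuli` must be >= 1.")
  if (rate_hz <= 0) abort("`rate_hz` must be > 0.")
  stim_protocol(start_s + (seq_len(n_stimuli) - 1) / rate_hz,
                label = label %||% sprintf("%d AP @ %g Hz", n_stimuli, rate_hz))
}

#' Paired conditioning/test protocols for recovery experiments
#'
#' For each recovery interval, the test protocol (given with times relative to
#' its own first AP) is appended after the end of the conditioning train plus
#' the interval.
#'
#' @param cond Conditioning [stim_protocol()].
#' @param intervals Recovery intervals in s (> 0).
#' @param test Test-train [stim_protocol()] (times relative to its onset).
#' @return A tibble with one row per interval and a list-column `protocol`
#'   holding the combined paired protocol; attributes keep the pieces.
#' @export
gen_recovery_protocols <- function(cond, intervals, test) {
  stopifnot(inherits(cond, "stim_protocol"), inherits(test, "stim_protocol"))
  if (length(intervals) == 0) abort("`intervals` must be non-empty.")
  if (any(intervals <= 0)) abort("`intervals` must be > 0.")
  cond_end <- max(cond$ap_time_s)
  test_rel <- test$ap_time_s - test$ap_time_s[1]
  tibble(
    interval_s = as.numeric(intervals),
    protocol = purrr::map(intervals, function(iv) {
      stim_protocol(c(cond$ap_time_s, cond_end + iv + test_rel),
                    label = sprintf("paired, interval %g s", iv))
    })
  )
}

#' Logarithmic recovery-interval grid
#'
#' Default sweep used for recovery experiments: log-spaced intervals between
#' 20 ms and 16 s.
#'
#' @param n Number of intervals.
#' @param from,to Range in seconds.
#' @return Numeric vector of intervals, s.
#' @export
recovery_intervals <- function(n = 12, from = 0.02, to = 16) {
  exp(seq(log(from), log(to), length.out = n))
}
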