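# Event-level analysis: mEPSC detection and metrics, spike-timing statistics.

.check_trace <- function(trace) {
  if (!all(c("time_ms", "current_nA") %in% names(trace))) {
    abort("trace needs columns `time_ms` and `current_nA`.")
  }
  if (nrow(trace) < 2) abort("trace is empty or too short.")
  dt <- diff(trace$time_ms)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    abort("trace must be uniformly sampled.")
  }
  invisible(dt[1])
}

#' Detect miniature EPSCs in a current trace
#'
#' Events are threshold crossings of the baseline-subtracted current at
#' `threshold_sd` times the baseline standard deviation (the baseline is
#' estimated from `baseline_window_ms`, which should be event-free).
#' Contiguous supra-threshold segments are reduced to their peak; peaks closer
#' together than `min_separation_ms` are treated as overlapping events and all
#' members of the overlapping group are excluded. Metrics per retained event
#' come from [event_metrics()].
#'
#' @param trace Tibble with `time_ms`, `current_nA`, uniform sampling.
#' @param threshold_sd Threshold multiplier on the baseline SD (4-6 sensible;
#'   default 5).
#' @param min_separation_ms Minimum inter-peak distance; closer events are
#'   excluded as overlapping.
#' @param baseline_window_ms Length-2 window (ms) used for baseline mean/SD.
#' @param direction `"negative"` for inward currents (default) or
#'   `"positive"`.
#' @param metric_window_ms Half-window around each peak used to measure the
#'   event waveform.
#' @param smooth_ms Width of the moving-average filter applied before
#'   threshold detection (peaks and metrics still use the raw trace); prevents
#'   baseline noise from splitting one event into several threshold
#'   crossings.
#' @return A `mini_detection` list: `events` tibble (`t_peak_ms`,
#'   `amplitude_nA`, `rise_10_90_ms`, `fwhm_ms`), `frequency_hz`,
#'   `threshold_nA`, `baseline_sd_nA`, `n_excluded_overlap`.
#' @export
detect_minis <- function(trace, threshold_sd = 5, min_separation_ms = 5,
                         baseline_window_ms = c(0, 100),
                         direction = c("negative", "positive"),
                         metric_window_ms = 10, smooth_ms = 0.5) {
  direction <- match.arg(direction)
  dt <- .check_trace(trace)
  if (threshold_sd < 4 || threshold_sd > 6) {
    warn("`threshold_sd` outside the conventional 4-6 range.")
  }
  sgn <- if (direction == "negative") -1 else 1
  y <- sgn * trace$current_nA
  tms <- trace$time_ms
  in_base <- tms >= baseline_window_ms[1] & tms <= baseline_window_ms[2]
  if (!any(in_base)) abort("baseline window contains no samples.")
  mu <- mean(y[in_base]); s <- sd(y[in_base])
  if (s == 0) s <- .Machine$double.eps
  thr <- mu + threshold_sd * s
  if (any(y[in_base] > thr)) {
    warn("baseline window contains supra-threshold samples; SD estimate may be inflated.")
  }
  w <- max(1L, round(smooth_ms / dt))
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  above <- ys > thr
  if (!any(above)) {
    return(structure(list(events = tibble(t_peak_ms = numeric(), amplitude_nA = numeric(),
                                          rise_10_90_ms = numeric(), fwhm_ms = numeric()),
                          frequency_hz = 0, threshold_nA = sgn * thr,
                          baseline_sd_nA = s, n_excluded_overlap = 0L),
                     class = "mini_detection"))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg_start <- starts[runs$values]
  seg_end <- ends[runs$values]
  # merge segments separated by brief sub-threshold dips (noise-scale gaps)
  if (length(seg_start) > 1) {
    gap <- seg_start[-1] - seg_end[-length(seg_end)]
    keep_break <- gap > 2 * w
    seg_start <- seg_start[c(TRUE, keep_break)]
    seg_end <- seg_end[c(keep_break, TRUE)]
  }
  # within a segment, distinct peaks must be separated by a valley at least
  # half the detection threshold deep (prominence rule); otherwise the lesser
  # maximum is a noise wiggle on the same event
  prom <- threshold_sd * s / 2
  peaks <- unlist(lapply(seq_along(seg_start), function(k) {
    idx <- seg_start[k]:seg_end[k]
    if (length(idx) < 3) {
      loc <- idx[which.max(ys[idx])]
    } else {
      d <- diff(sign(diff(ys[idx])))
      loc <- idx[which(d < 0) + 1]
      if (length(loc) == 0) loc <- idx[which.max(ys[idx])]
      while (length(loc) > 1) {
        valley <- vapply(seq_len(length(loc) - 1), function(i) {
          min(ys[loc[i]:loc[i + 1]])
        }, 0)
        depth <- pmin(ys[loc[-length(loc)]], ys[loc[-1]]) - valley
        if (all(depth >= prom)) break
        i <- which.min(depth)
        drop <- if (ys[loc[i]] <= ys[loc[i + 1]]) i else i + 1
        loc <- loc[-drop]
      }
    }
    vapply(loc, function(i) {
      lo <- max(1, i - w); hi <- min(length(y), i + w)
      as.integer(lo + which.max(y[lo:hi]) - 1)
    }, 0L)
  }))
  peaks <- sort(unique(peaks))
  # overlap exclusion: any peak within min_separation of a neighbour is dropped
  keep <- rep(TRUE, length(peaks))
  if (length(peaks) > 1) {
    gaps <- diff(tms[peaks])
    close_pairs <- which(gaps < min_separation_ms)
    keep[close_pairs] <- FALSE
    keep[close_pairs + 1] <- FALSE
  }
  n_excluded <- sum(!keep)
  peaks <- peaks[keep]
  half <- max(1L, round(metric_window_ms / dt))
  events <- purrr::map_dfr(peaks, function(ip) {
    lo <- max(1, ip - half); hi <- min(length(y), ip + half)
    wf <- tibble(time_ms = tms[lo:hi], current_nA = (y[lo:hi] - mu) * sgn)
    m <- tryCatch(event_metrics(wf, direction = direction),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    m$t_peak_ms <- tms[ip]
    m
  })
  if (nrow(events) > 0) {
    events <- events[, c("t_peak_ms", "amplitude_nA", "rise_10_90_ms", "fwhm_ms")]
  }
  duration_s <- (tms[length(tms)] - tms[1]) / 1000
  structure(list(events = events, frequency_hz = nrow(events) / duration_s,
                 threshold_nA = sgn * thr, baseline_sd_nA = s,
                 n_excluded_overlap = n_excluded),
            class = "mini_detection")
}

#' @export
print.mini_detection <- function(x, ...) {
  cat(sprintf("<mini_detection> %d events (%.3g Hz), threshold %.4g nA, %d excluded as overlapping\n",
              nrow(x$events), x$frequency_hz, x$threshold_nA, x$n_excluded_overlap))
  invisible(x)
}

#' @export
tidy.mini_detection <- function(x, ...) x$events

#' @export
glance.mini_detection <- function(x, ...) {
  tibble(n_events = nrow(x$events), frequency_hz = x$frequency_hz,
         threshold_nA = x$threshold_nA, baseline_sd_nA = x$baseline_sd_nA,
         n_excluded_overlap = x$n_excluded_overlap)
}

#' Metrics of a single event waveform
#'
#' Amplitude relative to the local baseline (mean of the leading samples),
#' 10-90% rise time and full width at half maximum, both by linear
#' interpolation of the threshold crossings.
#'
#' @param waveform Tibble with `time_ms`, `current_nA`, containing one peak.
#' @param direction `"negative"` (inward, default) or `"positive"`.
#' @param baseline_frac Fraction of leading samples averaged as baseline.
#' @return One-row tibble: `amplitude_nA` (signed), `rise_10_90_ms`,
#'   `fwhm_ms`.
#' @export
event_metrics <- function(waveform, direction = c("negative", "positive"),
                          baseline_frac = 0.05) {
  direction <- match.arg(direction)
  .check_trace(waveform)
  sgn <- if (direction == "negative") -1 else 1
  tms <- waveform$time_ms
  y <- sgn * waveform$current_nA
  nb <- max(1L, floor(length(y) * baseline_frac))
  base <- mean(y[seq_len(nb)])
  yy <- y - base
  ip <- which.max(yy)
  amp <- yy[ip]
  if (amp <= 0) abort("waveform has no peak above its baseline.")
  cross_up <- function(level) {
    pre <- yy[seq_len(ip)]
    if (!any(pre <= level)) abort("waveform does not start below the crossing level.")
    i <- max(which(pre <= level))
    if (i == ip) return(tms[ip])
    approx(pre[i:(i + 1)], tms[i:(i + 1)], xout = level)$y
  }
  cross_down <- function(level) {
    post <- yy[ip:length(yy)]
    below <- which(post <= level)
    if (length(below) == 0) abort("no down-crossing within the waveform window.")
    i <- min(below)
    if (i == 1) return(tms[ip])
    idx <- (ip + i - 2):(ip + i - 1)
    approx(yy[idx], tms[idx], xout = level)$y
  }
  rise <- cross_up(0.9 * amp) - cross_up(0.1 * amp)
  fwhm <- cross_down(0.5 * amp) - cross_up(0.5 * amp)
  tibble(amplitude_nA = sgn * amp, rise_10_90_ms = rise, fwhm_ms = fwhm)
}

#' Match postsynaptic APs to presynaptic stimuli
#'
#' Greedy earliest-AP matching: each stimulus takes the first unconsumed AP in
#' `(stim, stim + window_ms]`.
#'
#' @param stim_times_ms Stimulus times, ms.
#' @param ap_times_ms AP times, ms.
#' @param window_ms Matching window (> 0; must be shorter than the minimal
#'   inter-stimulus interval).
#' @return Tibble `stim_ms`, `ap_ms` (NA on failure), `delay_us`, `success`.
#' @export
match_spikes <- function(stim_times_ms, ap_times_ms, window_ms = 2) {
  if (window_ms <= 0) abort("`window_ms` must be > 0.")
  if (length(stim_times_ms) > 1 && window_ms > min(diff(sort(stim_times_ms)))) {
    warn("matching window exceeds the minimal inter-stimulus interval.")
  }
  aps <- sort(ap_times_ms)
  used <- rep(FALSE, length(aps))
  ap_hit <- rep(NA_real_, length(stim_times_ms))
  for (i in seq_along(stim_times_ms)) {
    cand <- which(!used & aps > stim_times_ms[i] &
                    aps <= stim_times_ms[i] + window_ms)
    if (length(cand) > 0) {
      used[cand[1]] <- TRUE
      ap_hit[i] <- aps[cand[1]]
    }
  }
  tibble(stim_ms = stim_times_ms, ap_ms = ap_hit,
         delay_us = (ap_hit - stim_times_ms) * 1000,
         success = !is.na(ap_hit))
}

#' Fraction of stimuli that trigger an AP
#'
#' @inheritParams match_spikes
#' @return Fraction in \[0, 1\].
#' @export
ap_success <- function(stim_times_ms, ap_times_ms, window_ms = 2) {
  mean(match_spikes(stim_times_ms, ap_times_ms, window_ms)$success)
}

#' Mean AP delay and jitter
#'
#' Jitter is the standard deviation of stimulus-to-AP latencies over
#' successful matches.
#'
#' @inheritParams match_spikes
#' @return One-row tibble: `mean_delay_us`, `jitter_us`, `n_success`.
#' @export
delay_jitter <- function(stim_times_ms, ap_times_ms, window_ms = 2) {
  d <- match_spikes(stim_times_ms, ap_times_ms, window_ms)$delay_us
  d <- d[!is.na(d)]
  if (length(d) < 2) abort("need >= 2 successful matches to estimate jitter.")
  tibble(mean_delay_us = mean(d), jitter_us = sd(d), n_success = length(d))
}

#' Exponential-kernel weighted preceding activity
#'
#' For each spike, the sum over all earlier spikes of
#' `exp(-(t_i - t_k) / tau_ms)`: recent activity counts almost fully, remote
#' activity decays away. Computed in one pass with the recursion
#' `s_i = (s_{i-1} + 1) * exp(-dt_i / tau)`.
#'
#' @param ap_times_ms Sorted spike times, ms.
#' @param tau_ms Weighting time constant (default 30 ms; 10 and 100 ms are
#'   common robustness choices).
#' @return Numeric vector, one value per spike (0 for the first).
#' @export
preceding_activity <- function(ap_times_ms, tau_ms = 30) {
  if (tau_ms <= 0) abort("`tau_ms` must be > 0.")
  n <- length(ap_times_ms)
  if (n == 0) return(numeric(0))
  if (any(diff(ap_times_ms) < 0)) abort("`ap_times_ms` must be sorted.")
  s <- numeric(n)
  for (i in seq_len(n)[-1]) {
    s[i] <- (s[i - 1] + 1) * exp(-(ap_times_ms[i] - ap_times_ms[i - 1]) / tau_ms)
  }
  s
}

#' Binned summary statistics
#'
#' Bins `values` by `covariate` using half-open `[left, right)` bins; a value
#' exactly on an edge joins the bin to its right.
#'
#' @param data Data frame.
#' @param values,covariate Column names (strings) of the response and the
#'   binning covariate.
#' @param bin_edges Sorted, strictly increasing bin edges.
#' @return Tibble with one row per bin: `left`, `right`, `n`, `mean`, `sd`,
#'   `empty`.
#' @export
binned_stats <- function(data, values, covariate, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.")
  }
  v <- data[[values]]; x <- data[[covariate]]
  if (length(v) != length(x)) abort("`values` and `covariate` must have equal length.")
  bin <- findInterval(x, bin_edges, rightmost.closed = FALSE, left.open = FALSE)
  nb <- length(bin_edges) - 1
  purrr::map_dfr(seq_len(nb), function(b) {
    sel <- bin == b
    tibble(left = bin_edges[b], right = bin_edges[b + 1], n = sum(sel),
           mean = if (any(sel)) mean(v[sel]) else NA_real_,
           sd = if (sum(sel) > 1) sd(v[sel]) else NA_real_,
           empty = !any(sel))
  })
}
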