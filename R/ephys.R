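# Evoked synaptic current metrics: baseline, peak amplitude, half-time
# decay, charge integral, peak-normalized traces.

#' Pre-stimulus baseline current
#'
#' Mean current over the `pre_window` ms immediately before stimulus onset.
#' Note that a linearly drifting baseline of slope `s` biases the estimate by
#' `s * pre_window / 2`; drift correction is out of scope.
#'
#' @param trace A [current_trace()].
#' @param pre_window Baseline window length, ms (default 20).
#' @return Baseline current, nA (attribute `n` = samples used).
#' @export
estimate_baseline <- function(trace, pre_window = 20) {
  stopifnot(inherits(trace, "current_trace"))
  check_num(pre_window, "pre_window", lower = 0, strict_lower = TRUE)
  sel <- trace$time_ms >= trace$stimulus_onset_ms - pre_window &
    trace$time_ms < trace$stimulus_onset_ms
  if (sum(sel) < 2) {
    stop(sprintf("insufficient pre-stimulus samples (%d) for a %g ms baseline window",
                 sum(sel), pre_window), call. = FALSE)
  }
  structure(mean(trace$current_nA[sel]), n = sum(sel))
}

#' Peak amplitude of the evoked response
#'
#' Maximum absolute deviation from baseline within the post-stimulus search
#' window. The amplitude is reported as a positive magnitude; the polarity of
#' the deflection is recorded separately.
#'
#' @param trace A [current_trace()].
#' @param baseline Baseline current, nA (from [estimate_baseline()]).
#' @param search_window Length of the search window after onset, ms
#'   (default 50).
#' @param detection_sd Multiple of the pre-stimulus noise sd below which the
#'   response is flagged sub-threshold (default 4).
#' @return List: `amplitude` (nA, >= 0), `peak_time` (ms), `polarity`
#'   (`"inward"`/`"outward"`), `sub_threshold` (logical), `flags`
#'   (character; notes a peak at the window edge, i.e. possible truncation).
#' @export
peak_amplitude <- function(trace, baseline, search_window = 50, detection_sd = 4) {
  stopifnot(inherits(trace, "current_trace"))
  sel <- which(trace$time_ms >= trace$stimulus_onset_ms &
                 trace$time_ms <= trace$stimulus_onset_ms + search_window)
  if (length(sel) < 2) stop("search window contains fewer than 2 samples", call. = FALSE)
  dev <- trace$current_nA[sel] - baseline
  i <- which.max(abs(dev))
  flags <- character(0)
  if (i == length(sel)) flags <- c(flags, "peak_at_window_edge")
  pre <- trace$time_ms < trace$stimulus_onset_ms
  noise <- if (sum(pre) >= 4) stats::sd(trace$current_nA[pre]) else 0
  amp <- abs(dev[i])
  t_pk <- trace$time_ms[sel[i]]
  # parabolic refinement of the peak between samples; skipped when the peak
  # sits at the first sample (instantaneous rise, nothing to interpolate)
  if (i > 1 && i < length(sel)) {
    y0 <- abs(dev[i - 1]); y1 <- amp; y2 <- abs(dev[i + 1])
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      d <- 0.5 * (y0 - y2) / den
      if (abs(d) <= 0.5) {
        dt <- 1 / trace$sampling_rate_khz
        t_pk <- t_pk + d * dt
        amp <- y1 - 0.25 * (y0 - y2) * d
      }
    }
  }
  list(amplitude = amp,
       peak_time = t_pk,
       polarity = if (dev[i] < 0) "inward" else "outward",
       sub_threshold = amp < detection_sd * noise,
       flags = flags)
}

#' Half-time decay of the evoked response
#'
#' Time elapsed from the response peak to the first subsequent crossing of
#' 50% of the signed peak deviation from baseline, with linear interpolation
#' between the bracketing samples — the standard synaptic t-half convention
#' (measured from the peak, not from the stimulus).
#'
#' @param trace A [current_trace()].
#' @param baseline Baseline current, nA.
#' @param amplitude Peak amplitude magnitude, nA.
#' @param peak_time Peak time, ms.
#' @return Half-decay time, ms.
#' @export
half_decay_time <- function(trace, baseline, amplitude, peak_time) {
  stopifnot(inherits(trace, "current_trace"))
  check_num(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  sel <- which(trace$time_ms >= peak_time)
  dev <- abs(trace$current_nA[sel] - baseline)
  # on noisy traces, a 5-sample moving average stabilizes the crossing
  # (sample-level jitter would otherwise dominate); on clean traces raw
  # interpolation keeps the closed forms exact
  pre <- trace$time_ms < trace$stimulus_onset_ms
  noisy <- sum(pre) >= 4 && stats::sd(trace$current_nA[pre]) > 0.005 * amplitude
  if (noisy && length(dev) > 7) {
    sm <- stats::filter(dev, rep(1 / 5, 5), sides = 2)
    keep <- !is.na(sm)
    dev[keep] <- sm[keep]
  }
  half <- amplitude / 2
  below <- which(dev <= half)
  below <- below[below > 1]
  if (length(below) == 0) {
    stop("decay truncated: trace ends before the 50% crossing", call. = FALSE)
  }
  j <- below[1]
  t0 <- trace$time_ms[sel[j - 1]]; t1 <- trace$time_ms[sel[j]]
  d0 <- dev[j - 1]; d1 <- dev[j]
  tc <- if (d0 == d1) t1 else t0 + (d0 - half) / (d0 - d1) * (t1 - t0)
  tc - peak_time
}

#' Evoked charge integral
#'
#' Magnitude of the trapezoidal integral of the baseline-subtracted current
#' over the response window `[onset, t_end]`, in pC (nA x ms). `t_end` is the
#' first time after the peak at which the absolute deviation falls below
#' `return_fraction` of the amplitude and stays below it for at least
#' `persistence_ms`, capped at `max_window` after onset. If the response
#' never returns to baseline before the cap, the integral runs to the cap
#' and the result is flagged.
#'
#' @param trace A [current_trace()].
#' @param baseline Baseline current, nA.
#' @param amplitude Peak amplitude magnitude, nA (used for the return
#'   threshold); pass the [peak_amplitude()] value.
#' @param peak_time Peak time, ms.
#' @param return_fraction Return-to-baseline threshold as a fraction of
#'   amplitude (default 0.05).
#' @param persistence_ms How long the deviation must stay below threshold,
#'   ms (default 2).
#' @param max_window Integration cap after onset, ms (default 200).
#' @return Charge magnitude in pC, with attributes `window` (`c(onset,
#'   t_end)` in ms) and `flags`.
#' @export
charge_integral <- function(trace, baseline, amplitude, peak_time,
                            return_fraction = 0.05, persistence_ms = 2,
                            max_window = 200) {
  stopifnot(inherits(trace, "current_trace"))
  onset <- trace$stimulus_onset_ms
  t_cap <- min(onset + max_window, trace$time_ms[length(trace$time_ms)])
  sel <- which(trace$time_ms >= peak_time & trace$time_ms <= t_cap)
  dev <- abs(trace$current_nA[sel] - baseline)
  thr <- return_fraction * amplitude
  dt <- 1 / trace$sampling_rate_khz
  need <- max(1L, ceiling(persistence_ms / dt))
  below <- dev < thr
  t_end <- NA_real_
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  for (g in seq_along(run$lengths)) {
    if (run$values[g] && (run$lengths[g] >= need || ends[g] == length(below))) {
      t_end <- trace$time_ms[sel[starts[g]]]
      break
    }
  }
  flags <- character(0)
  if (is.na(t_end)) {
    t_end <- t_cap
    flags <- c(flags, "no_return_to_baseline_before_cap")
  }
  isel <- which(trace$time_ms >= onset & trace$time_ms <= t_end)
  tt <- trace$time_ms[isel]
  ii <- trace$current_nA[isel] - baseline
  # include the partial segments at the window edges by linear interpolation
  if (tt[1] > onset) {
    i0 <- stats::approx(trace$time_ms, trace$current_nA, onset)$y - baseline
    tt <- c(onset, tt); ii <- c(i0, ii)
  }
  if (tt[length(tt)] < t_end) {
    i1 <- stats::approx(trace$time_ms, trace$current_nA, t_end)$y - baseline
    tt <- c(tt, t_end); ii <- c(ii, i1)
  }
  q <- abs(sum(diff(tt) * (ii[-1] + ii[-length(ii)]) / 2))
  structure(q, window = c(onset, t_end), flags = flags)
}

#' Peak-normalize an evoked trace
#'
#' Returns `(I - baseline) / (signed peak deviation)`: a dimensionless trace
#' whose peak value is exactly 1, regardless of response polarity. Used to
#' compare response kinetics across genotypes independent of amplitude.
#'
#' @param trace A [current_trace()].
#' @param baseline Baseline current, nA.
#' @param amplitude Peak amplitude magnitude, nA (> 0); used only to reject
#'   zero-amplitude traces. The divisor is the extreme sample deviation
#'   itself, so the normalized peak sample is exactly 1.
#' @return A data frame `time_ms`, `normalized` with peak exactly 1.
#' @export
normalize_trace <- function(trace, baseline, amplitude) {
  stopifnot(inherits(trace, "current_trace"))
  if (amplitude <= 0) stop("amplitude must be > 0 to normalize", call. = FALSE)
  dev <- trace$current_nA - baseline
  peak <- dev[which.max(abs(dev))]
  data.frame(time_ms = trace$time_ms, normalized = dev / peak)
}

#' All evoked-response metrics of a trace
#'
#' Convenience wrapper running [estimate_baseline()], [peak_amplitude()],
#' [half_decay_time()], [charge_integral()] and [normalize_trace()].
#'
#' @param trace A [current_trace()].
#' @param pre_window Baseline window, ms.
#' @param ... Further arguments to [charge_integral()].
#' @return An `evoked_metrics` object: list with `baseline`, `amplitude`,
#'   `peak_time`, `polarity`, `half_decay`, `charge`, `response_window`,
#'   `normalized` (data frame), `sub_threshold`, `flags`.
#' @export
evoked_metrics <- function(trace, pre_window = 20, ...) {
  baseline <- estimate_baseline(trace, pre_window)
  pk <- peak_amplitude(trace, baseline)
  flags <- pk$flags
  if (pk$sub_threshold) {
    return(structure(list(baseline = as.numeric(baseline), amplitude = pk$amplitude,
                          peak_time = pk$peak_time, polarity = pk$polarity,
                          half_decay = NA_real_, charge = 0,
                          response_window = c(NA_real_, NA_real_),
                          normalized = NULL, sub_threshold = TRUE,
                          flags = c(flags, "sub_threshold")),
                     class = "evoked_metrics"))
  }
  hd <- half_decay_time(trace, baseline, pk$amplitude, pk$peak_time)
  q <- charge_integral(trace, baseline, pk$amplitude, pk$peak_time, ...)
  structure(list(baseline = as.numeric(baseline), amplitude = pk$amplitude,
                 peak_time = pk$peak_time, polarity = pk$polarity,
                 half_decay = hd, charge = as.numeric(q),
                 response_window = attr(q, "window"),
                 normalized = normalize_trace(trace, baseline, pk$amplitude),
                 sub_threshold = FALSE,
                 flags = c(flags, attr(q, "flags"))),
            class = "evoked_metrics")
}

#' @export
print.evoked_metrics <- function(x, ...) {
  cat(sprintf(
    "<evoked_metrics> amplitude %.3f nA (%s) at %.2f ms, t1/2 %.3f ms, charge %.3f pC%s\n",
    x$amplitude, x$polarity, x$peak_time, x$half_decay, x$charge,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}
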