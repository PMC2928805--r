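#' Generate a synthetic evoked current trace
#'
#' Simulates a voltage-clamp evoked postsynaptic current on a uniform time
#' grid: flat baseline before stimulus onset, then a kinetic term
#' `exp(-t/tau_decay) - exp(-t/tau_rise)` (pure `exp(-t/tau_decay)` when
#' `tau_rise = 0`) rescaled so the analytic peak deviation equals
#' `spec$amplitude` exactly. Inward responses deflect negative from baseline.
#'
#' The ground-truth sidecar carries the analytic amplitude, peak time,
#' half-decay time (time from peak to 50% of the peak deviation; `tau_decay *
#' log(2)` for monoexponential decay, a numerical root of the kinetic form
#' otherwise) and charge `amplitude * (tau_decay - tau_rise) / g_peak` in pC,
#' where `g_peak` is the peak of the unit-amplitude kernel. If the trace ends
#' before the response has decayed to 5% of peak, the sidecar records a
#' `"decay truncated"` flag.
#'
#' @param spec A [trace_spec()].
#' @return A list with `trace` (a `current_trace`) and `truth`
#'   (`ground_truth`).
#' @examples
#' tr <- make_trace(trace_spec(amplitude = 2, tau_rise = 0, tau_decay = 5))
#' tr$truth$half_decay_ms  # 5 * log(2)
#' @export
make_trace <- function(spec) {
  if (!inherits(spec, "trace_spec")) stop("`spec` must be a trace_spec", call. = FALSE)
  dt <- 1 / spec$sampling_rate
  # sample grid anchored at stimulus onset (acquisition is TTL-triggered, so
  # a sample falls exactly on the stimulus)
  t0 <- spec$onset - dt * floor(spec$onset / dt)
  time <- seq(t0, spec$duration, by = dt)
  tau_r <- spec$tau_rise; tau_d <- spec$tau_decay

  kern <- function(tt) {
    if (tau_r > 0) exp(-tt / tau_d) - exp(-tt / tau_r) else exp(-tt / tau_d)
  }
  if (tau_r > 0) {
    t_peak <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  } else {
    t_peak <- 0
  }
  g_peak <- kern(t_peak)

  sgn <- if (spec$polarity == "inward") -1 else 1
  rel <- time - spec$onset
  resp <- ifelse(rel >= 0, kern(pmax(rel, 0)), 0)
  current <- spec$baseline_current + sgn * spec$amplitude / g_peak * resp
  current <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) current + rnorm(length(current), 0, spec$noise_sd) else current
  })

  # analytic half-decay: first t > t_peak with kern(t) = g_peak / 2
  half_decay <- if (tau_r > 0) {
    f <- function(tt) kern(tt) - g_peak / 2
    uniroot(f, c(t_peak, t_peak + 50 * tau_d), tol = 1e-10)$root - t_peak
  } else {
    tau_d * log(2)
  }
  # time (after peak) to decay to 5% of peak
  t05 <- if (tau_r > 0) {
    f <- function(tt) kern(tt) - 0.05 * g_peak
    uniroot(f, c(t_peak, t_peak + 100 * tau_d), tol = 1e-10)$root
  } else {
    tau_d * log(20)
  }
  flags <- character(0)
  if (spec$onset + t05 > spec$duration) flags <- c(flags, "decay truncated")

  trace <- current_trace(time_ms = time, current_nA = current,
                         sampling_rate_khz = spec$sampling_rate,
                         stimulus_onset_ms = spec$onset,
                         holding_mv = spec$holding_mv)
  truth <- structure(list(
    modality = "evoked_trace",
    amplitude_nA = spec$amplitude,
    polarity = spec$polarity,
    baseline_nA = spec$baseline_current,
    peak_time_ms = spec$onset + t_peak,
    half_decay_ms = half_decay,
    charge_pC = spec$amplitude * (tau_d - tau_r) / g_peak,
    decay05_time_ms = spec$onset + t05,
    noise_sd = spec$noise_sd,
    flags = flags,
    seed = spec$seed
  ), class = "ground_truth")
  list(trace = trace, truth = truth)
}

#' Construct a current trace object
#'
#' Container for a sampled voltage-clamp current: a uniform time grid in ms,
#' current in nA, plus acquisition metadata.
#'
#' @param time_ms Time stamps, ms (uniform grid).
#' @param current_nA Current samples, nA.
#' @param sampling_rate_khz Sampling rate, kHz; inferred from `time_ms` if
#'   omitted.
#' @param stimulus_onset_ms Stimulus onset, ms; must lie within the time range.
#' @param holding_mv Holding potential metadata (default -60).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time_ms, current_nA, sampling_rate_khz = NULL,
                          stimulus_onset_ms, holding_mv = -60) {
  if (length(time_ms) != length(current_nA)) {
    stop("`time_ms` and `current_nA` must have equal length", call. = FALSE)
  }
  if (length(time_ms) < 3) stop("trace needs at least 3 samples", call. = FALSE)
  dts <- diff(time_ms)
  if (any(dts <= 0)) stop("`time_ms` must be strictly increasing", call. = FALSE)
  if (diff(range(dts)) > 1e-6 * mean(dts)) {
    stop("`time_ms` must be a uniform grid (within 1 ppm)", call. = FALSE)
  }
  rate <- sampling_rate_khz %||% (1 / mean(dts))
  check_num(stimulus_onset_ms, "stimulus_onset_ms",
            lower = time_ms[1], upper = time_ms[length(time_ms)])
  structure(list(time_ms = as.numeric(time_ms),
                 current_nA = as.numeric(current_nA),
                 sampling_rate_khz = rate,
                 stimulus_onset_ms = stimulus_onset_ms,
                 holding_mv = holding_mv),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %.4g kHz, %.4g-%.4g ms, onset %.4g ms, holding %g mV\n",
              length(x$time_ms), x$sampling_rate_khz, x$time_ms[1],
              x$time_ms[length(x$time_ms)], x$stimulus_onset_ms, x$holding_mv))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  plot(x$time_ms, x$current_nA, type = "l", xlab = "time (ms)",
       ylab = "current (nA)", ...)
  abline(v = x$stimulus_onset_ms, lty = 2, col = "grey50")
  invisible(x)
}
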