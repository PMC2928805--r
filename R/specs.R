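#' Specification of a synthetic crawling worm
#'
#' Describes a single sinuous worm translating across the field of view, used
#' by [make_centerline()] and [render_movie()]. All geometry is in micrometres;
#' the rendered pixel grid is controlled by `pixel_size`.
#'
#' The body is built from cumulative turning angles over equal arc-length
#' steps. The head bend is injected as an extra tangent offset over the first
#' body twelfth, so that the first supplementary angle computed from the 13
#' equidistant midline points equals `head_bend_angle` by construction (exact
#' ground truth, not a fitted quantity). Undulation is suppressed over the two
#' most anterior twelfths for the same reason.
#'
#' @param body_length Worm length along the midline, um. Adult hermaphrodites
#'   are about 1 mm long.
#' @param max_half_width Maximal body half-width, um (default 40; the width
#'   profile tapers to zero at nose and tail).
#' @param width_profile Optional function mapping normalized arc position
#'   `u` in \[0, 1\] to half-width in um. Default: elliptical taper
#'   `max_half_width * sqrt(1 - (2 u - 1)^2)`.
#' @param undulation_amplitude Amplitude of the sinusoidal body-tangent
#'   oscillation, degrees (0 <= a < 90).
#' @param undulation_wavelength Undulation wavelength as a fraction of body
#'   length (default 0.65, typical of crawling).
#' @param undulation_freq Temporal frequency of the travelling body wave, Hz.
#' @param head_bend_angle Ground-truth first supplementary angle, degrees.
#' @param head_bend_freq If > 0, the head bend oscillates as
#'   `head_bend_angle * cos(2 pi f t)` (peak magnitude `head_bend_angle`,
#'   attained at t = 0 and every 1/f s); if 0 the bend is constant.
#' @param speed Centroid translation speed, um/s.
#' @param heading Direction of travel, degrees (nose leads).
#' @param pixel_size um per pixel of the rendered frames.
#' @param frame_interval Time between frames, s (default 0.5, i.e. 2 fps).
#' @param n_frames Number of frames.
#' @param foreground,background Mean worm and plate intensity (arbitrary
#'   camera units; the worm is brighter than the plate by default).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed for the generator's private RNG stream.
#'
#' @return An object of class `worm_spec`.
#' @seealso [make_centerline()], [render_movie()]
#' @export
worm_spec <- function(body_length = 1000,
                      max_half_width = 40,
                      width_profile = NULL,
                      undulation_amplitude = 25,
                      undulation_wavelength = 0.65,
                      undulation_freq = 0.3,
                      head_bend_angle = 0,
                      head_bend_freq = 0,
                      speed = 0,
                      heading = 0,
                      pixel_size = 5,
                      frame_interval = 0.5,
                      n_frames = 1L,
                      foreground = 1200,
                      background = 400,
                      noise_sd = 0,
                      seed = 1L) {
  check_num(body_length, "body_length", lower = 0, strict_lower = TRUE)
  check_num(max_half_width, "max_half_width", lower = 0, strict_lower = TRUE)
  check_num(undulation_amplitude, "undulation_amplitude", lower = 0, upper = 90 - 1e-9)
  check_num(undulation_wavelength, "undulation_wavelength", lower = 0, strict_lower = TRUE)
  check_num(undulation_freq, "undulation_freq", lower = 0)
  check_num(head_bend_angle, "head_bend_angle", lower = -179, upper = 179)
  check_num(head_bend_freq, "head_bend_freq", lower = 0)
  check_num(speed, "speed", lower = 0)
  check_num(heading, "heading")
  check_num(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_num(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_num(n_frames, "n_frames", lower = 1)
  if (n_frames != round(n_frames)) stop_field("n_frames", "must be an integer count")
  check_num(foreground, "foreground")
  check_num(background, "background")
  if (foreground <= background) {
    stop_field("foreground", "must exceed `background` (worm must contrast with plate)")
  }
  check_num(noise_sd, "noise_sd", lower = 0)
  check_num(seed, "seed")
  if (!is.null(width_profile) && !is.function(width_profile)) {
    stop_field("width_profile", "must be a function(u) -> half-width in um, or NULL")
  }
  structure(list(
    body_length = body_length, max_half_width = max_half_width,
    width_profile = width_profile,
    undulation_amplitude = undulation_amplitude,
    undulation_wavelength = undulation_wavelength,
    undulation_freq = undulation_freq,
    head_bend_angle = head_bend_angle, head_bend_freq = head_bend_freq,
    speed = speed, heading = heading, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    foreground = foreground, background = background,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "worm_spec")
}

#' @export
print.worm_spec <- function(x, ...) {
  cat(sprintf(
    "<worm_spec> L=%g um, head bend %g deg%s, undulation %g deg, speed %g um/s,\n  %d frame(s) @ %g s, %g um/px, noise sd %g, seed %d\n",
    x$body_length, x$head_bend_angle,
    if (x$head_bend_freq > 0) sprintf(" (oscillating @ %g Hz)", x$head_bend_freq) else "",
    x$undulation_amplitude, x$speed, x$n_frames, x$frame_interval,
    x$pixel_size, x$noise_sd, x$seed))
  invisible(x)
}

# Half-width (um) at normalized arc position u in [0, 1].
worm_half_width <- function(spec, u) {
  if (!is.null(spec$width_profile)) return(spec$width_profile(u))
  spec$max_half_width * sqrt(pmax(0, 1 - (2 * u - 1)^2))
}

# Analytic body area in um^2: integral of 2 * half-width ds.
worm_body_area <- function(spec, n = 20001L) {
  u <- seq(0, 1, length.out = n)
  w <- 2 * worm_half_width(spec, u)
  spec$body_length * sum((w[-1] + w[-n]) / 2) * (u[2] - u[1])
}

#' Specification of a synthetic puncta image
#'
#' Describes a row of resolvable Gaussian fluorescence puncta on a noisy,
#' uniform background, emulating linescan substrates such as GFP-tagged
#' channel or dystrophin-complex puncta along a muscle membrane.
#'
#' @param n_puncta Number of puncta (0 allowed: background-only image).
#' @param spacing Center-to-center spacing along the row, px. Must exceed
#'   `4 * psf_sigma` so puncta are resolvable.
#' @param peak_heights Net peak height above background of each punctum
#'   (length 1 is recycled).
#' @param psf_sigma Gaussian spot sigma, px.
#' @param background_level Uniform background intensity.
#' @param noise_sd Additive Gaussian noise sd.
#' @param height Image height in px (default fits the spots comfortably).
#' @param seed Integer seed.
#' @return An object of class `puncta_spec`.
#' @seealso [render_puncta()]
#' @export
puncta_spec <- function(n_puncta = 5L,
                        spacing = 20,
                        peak_heights = 150,
                        psf_sigma = 2,
                        background_level = 100,
                        noise_sd = 0,
                        height = NULL,
                        seed = 1L) {
  check_num(n_puncta, "n_puncta", lower = 0)
  if (n_puncta != round(n_puncta)) stop_field("n_puncta", "must be an integer count")
  check_num(psf_sigma, "psf_sigma", lower = 0, strict_lower = TRUE)
  check_num(spacing, "spacing", lower = 0, strict_lower = TRUE)
  if (n_puncta > 1 && spacing <= 4 * psf_sigma) {
    stop_field("spacing", sprintf(
      "must exceed 4 * psf_sigma = %g px for resolvable puncta", 4 * psf_sigma))
  }
  if (n_puncta > 0) {
    if (!is.numeric(peak_heights) || anyNA(peak_heights) || any(peak_heights <= 0)) {
      stop_field("peak_heights", "must all be > 0")
    }
    peak_heights <- rep_len(peak_heights, n_puncta)
  } else {
    peak_heights <- numeric(0)
  }
  check_num(background_level, "background_level", lower = 0)
  check_num(noise_sd, "noise_sd", lower = 0)
  height <- height %||% max(32, ceiling(12 * psf_sigma))
  check_num(height, "height", lower = 8)
  check_num(seed, "seed")
  structure(list(
    n_puncta = as.integer(n_puncta), spacing = spacing,
    peak_heights = peak_heights, psf_sigma = psf_sigma,
    background_level = background_level, noise_sd = noise_sd,
    height = as.integer(height), seed = as.integer(seed)
  ), class = "puncta_spec")
}

#' @export
print.puncta_spec <- function(x, ...) {
  cat(sprintf(
    "<puncta_spec> %d puncta, spacing %g px, sigma %g px, background %g, noise sd %g, seed %d\n",
    x$n_puncta, x$spacing, x$psf_sigma, x$background_level, x$noise_sd, x$seed))
  invisible(x)
}

#' Specification of a synthetic evoked current trace
#'
#' Describes a voltage-clamp evoked postsynaptic current: flat baseline, then
#' a difference-of-exponentials response (monoexponential decay when
#' `tau_rise = 0`) scaled so the analytic peak deviation equals `amplitude`
#' exactly. Inward currents deflect negative from baseline, matching the
#' voltage-clamp convention at a -60 mV holding potential.
#'
#' @param amplitude Peak deviation from baseline, nA (positive magnitude).
#' @param tau_rise Rise time constant, ms (0 selects pure monoexponential
#'   decay).
#' @param tau_decay Decay time constant, ms; must exceed `tau_rise`.
#' @param onset Stimulus onset, ms from the start of the trace. Default 25 ms
#'   leaves the standard 20 ms pre-stimulus baseline window.
#' @param duration Total trace duration, ms.
#' @param sampling_rate Sampling rate, kHz (default 2.9, the digitization rate
#'   used for such recordings).
#' @param baseline_current Holding current, nA.
#' @param noise_sd Additive Gaussian current noise, nA.
#' @param polarity `"inward"` (negative deflection) or `"outward"`.
#' @param holding_mv Holding potential metadata, mV.
#' @param seed Integer seed.
#' @return An object of class `trace_spec`.
#' @seealso [make_trace()]
#' @export
trace_spec <- function(amplitude = 2,
                       tau_rise = 0,
                       tau_decay = 5,
                       onset = 25,
                       duration = 100,
                       sampling_rate = 2.9,
                       baseline_current = -0.1,
                       noise_sd = 0,
                       polarity = c("inward", "outward"),
                       holding_mv = -60,
                       seed = 1L) {
  polarity <- match.arg(polarity)
  check_num(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  check_num(tau_rise, "tau_rise", lower = 0)
  check_num(tau_decay, "tau_decay", lower = 0, strict_lower = TRUE)
  if (tau_decay <= tau_rise) stop_field("tau_decay", "must exceed tau_rise")
  check_num(onset, "onset", lower = 0)
  check_num(duration, "duration", lower = 0, strict_lower = TRUE)
  if (onset >= duration) stop_field("onset", "must lie within the trace duration")
  check_num(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_num(baseline_current, "baseline_current")
  check_num(noise_sd, "noise_sd", lower = 0)
  check_num(holding_mv, "holding_mv")
  check_num(seed, "seed")
  structure(list(
    amplitude = amplitude, tau_rise = tau_rise, tau_decay = tau_decay,
    onset = onset, duration = duration, sampling_rate = sampling_rate,
    baseline_current = baseline_current, noise_sd = noise_sd,
    polarity = polarity, holding_mv = holding_mv, seed = as.integer(seed)
  ), class = "trace_spec")
}

#' @export
print.trace_spec <- function(x, ...) {
  cat(sprintf(
    "<trace_spec> %g nA %s, tau_rise %g ms, tau_decay %g ms, onset %g ms, %g ms @ %g kHz, noise sd %g, seed %d\n",
    x$amplitude, x$polarity, x$tau_rise, x$tau_decay, x$onset, x$duration,
    x$sampling_rate, x$noise_sd, x$seed))
  invisible(x)
}
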