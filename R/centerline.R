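#' Analytic worm centerline at a given time
#'
#' Builds the worm midline as cumulative turning angles over equal arc-length
#' steps, in um coordinates. The head bend is a constant tangent offset over
#' the first body twelfth (the turn concentrated at the second of the 13
#' equidistant midline points), so the first supplementary angle of the 13
#' analytic points equals the spec's `head_bend_angle` exactly; undulation is
#' tapered in only beyond the second twelfth to preserve that identity. The
#' centroid of the returned polyline translates at exactly `spec$speed` along
#' `spec$heading` (nose leading), with the undulation's centroid wobble
#' removed by construction.
#'
#' @param spec A [worm_spec()].
#' @param t Time, s.
#' @param n_steps Number of equal arc-length steps (default 600; must be a
#'   multiple of 12 so the 13 nominal points fall on vertices).
#' @return A `centerline` object: an `(n_steps + 1) x 2` matrix of (x, y) um
#'   coordinates ordered nose to tail, with attributes `first_angle_deg`
#'   (analytic ground truth at time `t`), `points13` (the 13 equidistant
#'   points, um) and `body_length`.
#' @examples
#' cl <- make_centerline(worm_spec(head_bend_angle = 30, undulation_amplitude = 0), t = 0)
#' attr(cl, "first_angle_deg")
#' @export
make_centerline <- function(spec, t = 0, n_steps = 600L) {
  if (!inherits(spec, "worm_spec")) stop("`spec` must be a worm_spec", call. = FALSE)
  check_num(t, "t", lower = 0)
  if (n_steps %% 12L != 0L) stop_field("n_steps", "must be a multiple of 12")
  L <- spec$body_length
  ds <- L / n_steps
  s_mid <- (seq_len(n_steps) - 0.5) * ds

  # Body tangent points opposite to the direction of travel (nose leads).
  base <- deg2rad(spec$heading) + pi

  bend_now <- deg2rad(spec$head_bend_angle) *
    (if (spec$head_bend_freq > 0) cos(2 * pi * spec$head_bend_freq * t) else 1)
  bend <- ifelse(s_mid < L / 12, bend_now, 0)

  und <- deg2rad(spec$undulation_amplitude) *
    sin(2 * pi * (s_mid / (spec$undulation_wavelength * L)) -
          2 * pi * spec$undulation_freq * t)
  q <- pmin(pmax((s_mid - 2 * L / 12) / (L / 12), 0), 1)
  taper <- q * q * (3 - 2 * q)

  psi <- base + bend + und * taper
  x <- c(0, cumsum(ds * cos(psi)))
  y <- c(0, cumsum(ds * sin(psi)))

  # Re-center so the area-weighted body centroid (what a tracker's mask
  # centroid measures) translates uniformly at `speed` along `heading`:
  # vertices are weighted by the local body width.
  w <- worm_half_width(spec, seq(0, 1, length.out = n_steps + 1L))
  w <- w / sum(w)
  vx <- spec$speed * cos(deg2rad(spec$heading))
  vy <- spec$speed * sin(deg2rad(spec$heading))
  x <- x - sum(w * x) + vx * t
  y <- y - sum(w * y) + vy * t

  xy <- cbind(x = x, y = y)
  idx13 <- seq(1L, n_steps + 1L, by = n_steps / 12L)
  pts13 <- xy[idx13, , drop = FALSE]
  structure(xy,
            class = c("centerline", "matrix", "array"),
            first_angle_deg = abs(rad2deg(bend_now)),
            points13 = pts13,
            body_length = L,
            time_s = t)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d vertices, arc length %.1f um, first angle %.2f deg (t = %g s)\n",
              nrow(x), polyline_length(x), attr(x, "first_angle_deg"),
              attr(x, "time_s")))
  invisible(x)
}
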