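# Midline extraction, 13-point assignment, and the first supplementary angle.

# Bilinear interpolation of matrix m (row = y, col = x; pixel centers at
# (col - 0.5, row - 0.5)) at points (x, y). Outside values clamp to the edge.
bilinear_at <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  cx <- pmin(pmax(x + 0.5, 1), W)  # continuous column index
  ry <- pmin(pmax(y + 0.5, 1), H)
  c0 <- pmin(floor(cx), W - 1); r0 <- pmin(floor(ry), H - 1)
  fc <- cx - c0; fr <- ry - r0
  i00 <- (c0 - 1) * H + r0
  m[i00] * (1 - fc) * (1 - fr) + m[i00 + H] * fc * (1 - fr) +
    m[i00 + 1] * (1 - fc) * fr + m[i00 + H + 1] * fc * fr
}

#' Extract the worm midline from a binary mask
#'
#' Thins the mask to its topological skeleton, prunes it to the single
#' longest endpoint-to-endpoint geodesic path (discarding all spurs), fits a
#' smoothing spline to the path, re-centers each point at the local
#' mid-thickness of the mask (midpoint of the perpendicular foreground run,
#' estimated subpixel from the interpolated mask), and extends both ends
#' along the terminal tangents to the mask boundary so the midline reaches
#' the true nose and tail tips rather than the skeleton endpoints.
#'
#' @param mask A [segment_worm()] result (or any logical matrix).
#' @param frame Optional grayscale frame the mask came from. When supplied,
#'   re-centering and tip extension run on a normalized-intensity coverage
#'   map (intensity rescaled so the plate is 0 and the worm body 1) instead
#'   of the binary mask: the anti-aliased edge carries subpixel boundary
#'   position, which roughly halves the error of the three-point head angle.
#' @param expected_length Optional expected body length in px; if given, a
#'   midline whose arc length falls outside 0.8-1.2 times it raises an error.
#' @param smooth_df Smoothing-spline degrees of freedom for the skeleton-path
#'   fit; default scales with path length (one df per ~12 px of arc), chosen
#'   so that straight-worm angle noise stays below 1 degree while crawling
#'   wavelengths are preserved. The final re-centering pass is left
#'   unsmoothed so a sharp head bend is not rounded off.
#' @param n_out Number of equidistant vertices in the returned midline.
#' @return A `midline` object: `n_out x 2` matrix of (x, y) px, nose/tail
#'   orientation *unassigned* (see [assign_head()]), with attributes
#'   `arc_length` (px) and `head_confidence`.
#' @export
extract_midline <- function(mask, frame = NULL, expected_length = NULL,
                            smooth_df = NULL, n_out = 200L) {
  if (!is.logical(c(mask[1]))) mask <- mask > 0
  path <- skeleton_longest_path(thin_mask(mask))
  if (nrow(path) < 8) {
    frame_error("skeleton path too short to form a midline", "nemaphene_midline_error")
  }
  if (!is.null(frame)) {
    bg <- stats::median(frame[!mask]); fg <- stats::median(frame[mask])
    maskn <- pmin(pmax((frame - bg) / (fg - bg), 0), 1)
  } else {
    maskn <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  }
  mean_hw <- max(1, sum(mask) / (2 * polyline_length(path)))
  search <- 0.25 * ceiling(max(4, 3 * mean_hw) / 0.25)

  smooth_path <- function(p, df) {
    s <- c(0, cumsum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)))
    df <- min(df, nrow(p) - 1)
    if (df < 4 || nrow(p) < 8) return(p)
    fx <- stats::smooth.spline(s, p[, 1], df = df)
    fy <- stats::smooth.spline(s, p[, 2], df = df)
    sg <- seq(0, s[length(s)], length.out = max(200, nrow(p)))
    cbind(x = stats::predict(fx, sg)$y, y = stats::predict(fy, sg)$y)
  }

  # move each vertex to the midpoint of the perpendicular foreground run of
  # the coverage map, with subpixel 0.5-crossings of the profile
  recenter <- function(sm) {
    n <- nrow(sm)
    tang <- rbind(sm[2, ] - sm[1, ], sm[3:n, ] - sm[1:(n - 2), ], sm[n, ] - sm[n - 1, ])
    tl <- sqrt(rowSums(tang^2)); tang <- tang / pmax(tl, 1e-9)
    nrm <- cbind(-tang[, 2], tang[, 1])
    offs <- seq(-search, search, by = 0.25)
    prof <- vapply(seq_along(offs), function(j) {
      bilinear_at(maskn, sm[, 1] + offs[j] * nrm[, 1], sm[, 2] + offs[j] * nrm[, 2])
    }, numeric(n))
    inside <- prof >= 0.5
    zero <- which.min(abs(offs))
    out <- sm
    for (i in seq_len(n)) {
      if (!inside[i, zero]) next
      lo <- zero; while (lo > 1 && inside[i, lo - 1]) lo <- lo - 1
      hi <- zero; while (hi < length(offs) && inside[i, hi + 1]) hi <- hi + 1
      eL <- offs[lo]
      if (lo > 1) {
        p0 <- prof[i, lo - 1]; p1 <- prof[i, lo]
        if (p1 > p0) eL <- offs[lo - 1] + (0.5 - p0) / (p1 - p0) * 0.25
      }
      eR <- offs[hi]
      if (hi < length(offs)) {
        p0 <- prof[i, hi]; p1 <- prof[i, hi + 1]
        if (p0 > p1) eR <- offs[hi] + (p0 - 0.5) / (p0 - p1) * 0.25
      }
      out[i, ] <- sm[i, ] + (eL + eR) / 2 * nrm[i, ]
    }
    out
  }

  df0 <- smooth_df %||% min(30, max(6, round(polyline_length(path) / 12)))
  sm <- smooth_path(path, df0)
  sm <- interp_polyline(sm, seq(0, polyline_length(sm), length.out = n_out))
  sm <- recenter(sm)
  sm <- smooth_path(sm, df0 * 2)
  sm <- interp_polyline(sm, seq(0, polyline_length(sm), length.out = n_out))
  sm <- recenter(sm)  # final pass kept unsmoothed to preserve the head kink
  sm <- interp_polyline(sm, seq(0, polyline_length(sm), length.out = n_out))

  # extend both ends to the body tip: among rays fanned around the terminal
  # tangent, the apex of the rounded nose/tail cap is the farthest subpixel
  # 0.5-crossing of the coverage map (robust to small tangent errors, which
  # would otherwise exit through the side of the cap)
  cross_dist <- function(tip, dir) {
    steps <- seq(0.25, search, by = 0.25)
    vals <- bilinear_at(maskn, tip[1] + steps * dir[1], tip[2] + steps * dir[2])
    out <- match(TRUE, vals < 0.5)
    if (is.na(out) || out == 1) return(0)
    s0 <- steps[out - 1]; v0 <- vals[out - 1]; v1 <- vals[out]
    s0 + (v0 - 0.5) / max(v0 - v1, 1e-9) * 0.25
  }
  extend_end <- function(p, head) {
    k <- min(8, nrow(p) - 1)
    if (head) {
      tip <- p[1, ]; dir <- p[1, ] - p[1 + k, ]
    } else {
      tip <- p[nrow(p), ]; dir <- p[nrow(p), ] - p[nrow(p) - k, ]
    }
    th0 <- atan2(dir[2], dir[1])
    fan <- deg2rad(seq(-12, 12, by = 2))
    ds <- vapply(fan, function(dth) {
      cross_dist(tip, c(cos(th0 + dth), sin(th0 + dth)))
    }, numeric(1))
    b <- which.max(ds)
    # an interior maximum marks the apex of a rounded cap; a maximum at the
    # fan edge means a flat or cornered end (e.g. a cut-off mask), where the
    # diagonal is trivially longest -- keep the tangent ray there
    if (b == 1L || b == length(fan) || ds[b] == 0) b <- which(fan == 0)
    d <- c(cos(th0 + fan[b]), sin(th0 + fan[b]))
    tip + ds[b] * d
  }
  sm <- rbind(extend_end(sm, TRUE), sm, extend_end(sm, FALSE))
  sm <- interp_polyline(sm, seq(0, polyline_length(sm), length.out = n_out))
  L <- polyline_length(sm)

  if (!is.null(expected_length) &&
      (L < 0.8 * expected_length || L > 1.2 * expected_length)) {
    frame_error(sprintf(
      "midline arc length %.1f px outside 0.8-1.2 x expected %.1f px",
      L, expected_length), "nemaphene_midline_error")
  }
  structure(sm, class = c("midline", "matrix", "array"),
            arc_length = L, head_confidence = "unassigned")
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("<midline> %d vertices, arc length %.1f px, head: %s\n",
              nrow(x), attr(x, "arc_length"), attr(x, "head_confidence")))
  invisible(x)
}

#' Place equidistant body points along a midline
#'
#' Places `n` points at arc lengths `0, L/(n-1), ..., L` along the midline by
#' linear interpolation between polyline vertices. The default `n = 13`
#' reproduces the classic 13-point body-posture parameterization (point 1 =
#' nose, point 13 = tail tip).
#'
#' @param midline A [extract_midline()] result (or any ordered 2-column
#'   polyline matrix).
#' @param n Number of points (>= 3), default 13.
#' @return A `posture_points` object: `n x 2` matrix of (x, y) px with
#'   attribute `spacing` (the common arc-length spacing).
#' @export
assign_body_points <- function(midline, n = 13L) {
  check_num(n, "n", lower = 3)
  if (n != round(n)) stop_field("n", "must be an integer count")
  L <- polyline_length(midline)
  if (L <= 0) stop("midline arc length must be > 0", call. = FALSE)
  pts <- interp_polyline(midline, seq(0, L, length.out = n))
  structure(pts, class = c("posture_points", "matrix", "array"),
            spacing = L / (n - 1),
            head_confidence = attr(midline, "head_confidence") %||% "unassigned")
}

#' First supplementary angle of the head
#'
#' The head-bend statistic: 180 degrees minus the interior angle at the
#' second body point, formed by the three most anterior of the 13 midline
#' points. Equivalently, the turning angle between the segment from point 1
#' to point 2 and the segment from point 2 to point 3. Reported as an
#' unsigned magnitude in \[0, 180\]; the signed image-frame value (positive =
#' turn toward image-left of the nose-to-tail direction) is attached as
#' attribute `signed` (the image frame carries no dorsoventral information).
#'
#' @param points A [assign_body_points()] result, or any matrix with at
#'   least 3 (x, y) rows ordered from the nose.
#' @return Angle in degrees (numeric scalar, attribute `signed`).
#' @examples
#' first_supplementary_angle(rbind(c(0, 0), c(10, 0), c(20, 10)))  # 45
#' @export
first_supplementary_angle <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  p <- points[1:3, , drop = FALSE]
  v1 <- p[2, ] - p[1, ]
  v2 <- p[3, ] - p[2, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("coincident body points", call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  ang <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  structure(ang, signed = ang * sign(cross + (cross == 0)))
}
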