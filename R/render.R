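# Rendering of synthetic data: worm movies and puncta images.

#' Render a synthetic worm movie
#'
#' Rasterizes the analytic centerline of a [worm_spec()] into `n_frames`
#' grayscale frames. A pixel is body if its distance to the centerline is at
#' most the local half-width; masks are anti-aliased by 4x supersampling
#' followed by block averaging, so edges carry fractional coverage. Gaussian
#' noise of sd `noise_sd` is added from the spec's private seeded RNG stream.
#'
#' @param spec A [worm_spec()].
#' @param canvas Optional `c(height, width)` in px. By default the canvas is
#'   sized to contain the worm over all frames with a margin. If a canvas is
#'   supplied and the worm would leave it, an error asks for a larger canvas.
#' @return A list with components `stack` (an `image_stack`: list of numeric
#'   intensity matrices plus `pixel_size`, `frame_interval`) and `truth` (a
#'   `ground_truth` sidecar holding the analytic speed, per-frame first
#'   angles, 13-point coordinates, centroids in px and the analytic body
#'   area). Ground-truth values come from the analytic form, never from the
#'   rendered pixels. The noiseless coverage masks (`alpha > 0.5`) are kept in
#'   `stack$masks` for round-trip tests.
#' @export
render_movie <- function(spec, canvas = NULL) {
  if (!inherits(spec, "worm_spec")) stop("`spec` must be a worm_spec", call. = FALSE)
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval
  cls <- lapply(times, function(t) make_centerline(spec, t))

  px <- spec$pixel_size
  hw_max_px <- spec$max_half_width / px
  margin <- hw_max_px + 4
  all_xy <- do.call(rbind, lapply(cls, unclass))
  xr <- range(all_xy[, 1]) / px
  yr <- range(all_xy[, 2]) / px

  if (is.null(canvas)) {
    width <- ceiling(diff(xr) + 2 * margin)
    height <- ceiling(diff(yr) + 2 * margin)
    off_x <- margin - xr[1]
    off_y <- margin - yr[1]
  } else {
    height <- canvas[1]; width <- canvas[2]
    off_x <- width / 2 - mean(xr)
    off_y <- height / 2 - mean(yr)
    if (xr[1] + off_x < margin || xr[2] + off_x > width - margin ||
        yr[1] + off_y < margin || yr[2] + off_y > height - margin) {
      stop(sprintf(
        "worm leaves the %d x %d px field of view; use a larger canvas (>= %d x %d px)",
        height, width, ceiling(diff(yr) + 2 * margin), ceiling(diff(xr) + 2 * margin)),
        call. = FALSE)
    }
  }

  frames <- vector("list", spec$n_frames)
  masks <- vector("list", spec$n_frames)
  angles <- numeric(spec$n_frames)
  cents <- matrix(NA_real_, spec$n_frames, 2)
  pts13 <- vector("list", spec$n_frames)

  render_one <- function(cl) {
    xy_px <- cbind(cl[, 1] / px + off_x, cl[, 2] / px + off_y)
    alpha <- rasterize_tube(xy_px, spec, height, width)
    alpha
  }

  # analytic (width-weighted) body centroid, matching what a mask centroid
  # measures; this is the quantity the generator translates uniformly
  wts <- worm_half_width(spec, seq(0, 1, length.out = nrow(cls[[1]])))
  wts <- wts / sum(wts)

  out <- with_seed(spec$seed, {
    for (k in seq_len(spec$n_frames)) {
      alpha <- render_one(cls[[k]])
      img <- spec$background + alpha * (spec$foreground - spec$background)
      if (spec$noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
      }
      frames[[k]] <- img
      masks[[k]] <- alpha > 0.5
      angles[k] <- attr(cls[[k]], "first_angle_deg")
      cents[k, ] <- c(sum(wts * cls[[k]][, 1]), sum(wts * cls[[k]][, 2])) / px +
        c(off_x, off_y)
      p <- attr(cls[[k]], "points13")
      pts13[[k]] <- cbind(x = p[, 1] / px + off_x, y = p[, 2] / px + off_y)
    }
    list(frames = frames, masks = masks, angles = angles,
         cents = cents, pts13 = pts13)
  })

  stack <- image_stack(out$frames, pixel_size = px,
                       frame_interval = spec$frame_interval)
  stack$masks <- out$masks
  truth <- structure(list(
    modality = "worm_movie",
    speed_um_s = spec$speed,
    heading_deg = spec$heading,
    displacement_px_per_frame = spec$speed * spec$frame_interval / px,
    first_angle_deg = out$angles,
    time_s = times,
    centroid_px = out$cents,
    points13_px = out$pts13,
    body_area_um2 = worm_body_area(spec),
    body_length_px = spec$body_length / px,
    pixel_size = px,
    frame_interval = spec$frame_interval,
    seed = spec$seed
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

# Supersampled distance-to-polyline rasterization. xy_px: nose->tail polyline
# in px; returns an height x width coverage (alpha) matrix in [0, 1].
rasterize_tube <- function(xy_px, spec, height, width, ss = 4L, n_seg = 150L) {
  L <- polyline_length(xy_px)
  s <- seq(0, L, length.out = n_seg + 1L)
  P <- interp_polyline(xy_px, s)
  u <- s / L
  hw <- worm_half_width(spec, u) / spec$pixel_size  # half-width in px

  H <- height * ss; W <- width * ss
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(n_seg)) {
    A <- P[i, ]; B <- P[i + 1L, ]
    h0 <- hw[i]; h1 <- hw[i + 1L]
    hmax <- max(h0, h1)
    # candidate window in supersampled px indices (pixel centers at (j-0.5)/ss)
    c0 <- max(1L, floor((min(A[1], B[1]) - hmax - 0.5) * ss))
    c1 <- min(W, ceiling((max(A[1], B[1]) + hmax + 0.5) * ss))
    r0 <- max(1L, floor((min(A[2], B[2]) - hmax - 0.5) * ss))
    r1 <- min(H, ceiling((max(A[2], B[2]) + hmax + 0.5) * ss))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    xs <- (cols - 0.5) / ss; ys <- (rows - 0.5) / ss
    gx <- matrix(xs, length(rows), length(cols), byrow = TRUE)
    gy <- matrix(ys, length(rows), length(cols))
    dx <- B[1] - A[1]; dy <- B[2] - A[2]
    len2 <- dx * dx + dy * dy
    tt <- if (len2 > 0) pmin(pmax(((gx - A[1]) * dx + (gy - A[2]) * dy) / len2, 0), 1) else 0
    qx <- A[1] + tt * dx; qy <- A[2] + tt * dy
    d2 <- (gx - qx)^2 + (gy - qy)^2
    hloc <- h0 + tt * (h1 - h0)
    hit <- d2 <= hloc * hloc
    if (any(hit)) {
      sub <- mask[rows, cols, drop = FALSE]
      mask[rows, cols] <- sub | hit
    }
  }
  # block-average ss x ss -> coverage fraction
  m <- matrix(as.numeric(mask), H, W)
  m <- rowsum(m, rep(seq_len(height), each = ss))
  m <- t(rowsum(t(m), rep(seq_len(width), each = ss)))
  dimnames(m) <- NULL
  m / (ss * ss)
}

#' Render a synthetic puncta image
#'
#' Produces a 2-D image `background + sum of Gaussian spots + noise`, with the
#' puncta centered on a horizontal row, and an analytic ground-truth sidecar
#' listing each punctum's center and net height.
#'
#' @param spec A [puncta_spec()].
#' @return A list with `image` (numeric matrix), `path` (the linescan path
#'   through the punctum centers, a 2-column matrix of (x, y) px) and `truth`
#'   (`ground_truth` with `centers_px`, `net_heights`, `background_level`,
#'   `noise_sd`).
#' @export
render_puncta <- function(spec) {
  if (!inherits(spec, "puncta_spec")) stop("`spec` must be a puncta_spec", call. = FALSE)
  n <- spec$n_puncta
  width <- max(48, ceiling((n + 1) * spec$spacing))
  height <- spec$height
  # centers snapped to pixel centers (half-integer coordinates) so that a
  # profile sample at a punctum center reads the peak without interpolation
  y_mid <- floor(height / 2) + 0.5
  centers_x <- if (n > 0) {
    raw <- seq_len(n) * spec$spacing + (width - (n + 1) * spec$spacing) / 2
    floor(raw) + 0.5
  } else numeric(0)

  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  img <- matrix(spec$background_level, height, width)
  for (i in seq_len(n)) {
    gx <- exp(-0.5 * ((xs - centers_x[i]) / spec$psf_sigma)^2)
    gy <- exp(-0.5 * ((ys - y_mid) / spec$psf_sigma)^2)
    img <- img + spec$peak_heights[i] * outer(gy, gx)
  }
  img <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) img + matrix(rnorm(length(img), 0, spec$noise_sd), height) else img
  })
  path <- cbind(x = c(0.5, width - 0.5), y = c(y_mid, y_mid))
  truth <- structure(list(
    modality = "puncta_image",
    centers_px = centers_x,
    y_px = y_mid,
    net_heights = spec$peak_heights,
    psf_sigma = spec$psf_sigma,
    background_level = spec$background_level,
    noise_sd = spec$noise_sd,
    seed = spec$seed
  ), class = "ground_truth")
  list(image = img, path = path, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> modality: %s\n", x$modality))
  flds <- setdiff(names(x), "modality")
  for (f in flds) {
    v <- x[[f]]
    if (is.numeric(v) && length(v) <= 6) {
      cat(sprintf("  %s: %s\n", f, paste(signif(v, 6), collapse = ", ")))
    } else {
      cat(sprintf("  %s: <%s>\n", f, paste(class(v)[1], collapse = "/")))
    }
  }
  invisible(x)
}
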