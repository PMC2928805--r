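# Centroid tracking and average locomotory speed.

#' Track the worm centroid across frames
#'
#' Segments each frame and records the centroid of the worm mask. Frames that
#' fail segmentation are flagged invalid, never interpolated.
#'
#' @param stack An [image_stack()].
#' @param config Options passed to [segment_worm()].
#' @return A `worm_track`: data frame with `frame`, `time_s`, `x_px`, `y_px`,
#'   `valid`, `failure_reason`, plus attributes `pixel_size` (um/px, may be
#'   `NA`) and `frame_interval` (s).
#' @export
track_centroids <- function(stack, config = list()) {
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack", call. = FALSE)
  nf <- length(stack$frames)
  if (nf < 2) stop("need at least 2 frames to track", call. = FALSE)
  dt <- stack$frame_interval
  out <- data.frame(frame = seq_len(nf),
                    time_s = (seq_len(nf) - 1) * dt,
                    x_px = NA_real_, y_px = NA_real_,
                    valid = FALSE, failure_reason = NA_character_)
  for (k in seq_len(nf)) {
    res <- tryCatch(segment_worm(stack$frames[[k]], config),
                    nemaphene_frame_error = function(e) e)
    if (inherits(res, "condition")) {
      out$failure_reason[k] <- conditionMessage(res)
    } else {
      # coverage-weighted subpixel centroid: weight pixels near the mask by
      # normalized intensity, so anti-aliased edges contribute fractionally
      frame <- stack$frames[[k]]
      bg <- stats::median(frame[!res]); fg <- stats::median(frame[res])
      cov <- pmin(pmax((frame - bg) / (fg - bg), 0), 1)
      dil <- EBImage::imageData(EBImage::dilate(
        EBImage::Image(res * 1), EBImage::makeBrush(5, "disc"))) > 0
      idx <- which(dil)
      H <- nrow(res)
      w <- cov[idx]
      if (sum(w) <= 0) { w <- rep(1, length(idx)) }
      out$x_px[k] <- sum(w * ((idx - 1L) %/% H + 1L - 0.5)) / sum(w)
      out$y_px[k] <- sum(w * ((idx - 1L) %% H + 1L - 0.5)) / sum(w)
      out$valid[k] <- TRUE
    }
  }
  if (sum(out$valid) < 2) stop("fewer than 2 valid frames; cannot track", call. = FALSE)
  structure(out, class = c("worm_track", "data.frame"),
            pixel_size = stack$pixel_size, frame_interval = dt)
}

#' Average locomotory speed from a track
#'
#' Speed is the mean path length per unit time: the summed centroid
#' displacement over consecutive valid-frame pairs divided by the summed
#' elapsed time of those pairs. Pairs spanning an invalid frame are excluded
#' from both numerator and denominator. A head-bending worm with little net
#' displacement still shows locomotory speed under this definition, which is
#' what object-tracking packages report for crawling assays (the alternative,
#' net displacement over duration, measures dispersal instead).
#'
#' @param track A [track_centroids()] result, or a data frame with `time_s`,
#'   `x_px`, `y_px`, `valid`.
#' @param pixel_size um per px; defaults to the track's attribute. If `NA`,
#'   the speed is returned in px/s.
#' @return Average speed (um/s, or px/s when uncalibrated), with attributes
#'   `unit`, `n_pairs`, `path_px` and `time_s`.
#' @export
average_speed <- function(track, pixel_size = NULL) {
  stopifnot(all(c("time_s", "x_px", "y_px", "valid") %in% names(track)))
  pixel_size <- pixel_size %||% attr(track, "pixel_size")
  v <- which(track$valid)
  if (length(v) < 2) stop("need >= 2 valid frames", call. = FALSE)
  consec <- v[which(diff(v) == 1L)]
  if (length(consec) == 0) stop("no consecutive valid frame pairs", call. = FALSE)
  d <- sqrt((track$x_px[consec + 1L] - track$x_px[consec])^2 +
              (track$y_px[consec + 1L] - track$y_px[consec])^2)
  tt <- track$time_s[consec + 1L] - track$time_s[consec]
  speed_px <- sum(d) / sum(tt)
  if (is.null(pixel_size) || is.na(pixel_size)) {
    structure(speed_px, unit = "px/s", n_pairs = length(consec),
              path_px = sum(d), time_s = sum(tt))
  } else {
    structure(speed_px * pixel_size, unit = "um/s", n_pairs = length(consec),
              path_px = sum(d), time_s = sum(tt))
  }
}
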