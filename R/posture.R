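# Frame-to-angle posture pipeline and the maximal-extension statistic.

#' First angle at maximal head-swing extension
#'
#' Selects, among valid frames inside the analysis window, the frame where
#' the head swing reaches its maximal extension — i.e. the maximum of the
#' absolute first supplementary angle — and reports that angle. The default
#' window of 15-60 s after recording start targets the period when an animal
#' is stimulated to move forward rapidly and the head-bending phenotype is
#' most prominent.
#'
#' @param series Data frame with columns `frame`, `time_s`, `angle_deg`,
#'   `ok` (logical) and optionally `failure_reason` (as produced by
#'   [analyze_posture()]).
#' @param window `c(t_start, t_end)` in seconds, default `c(15, 60)`.
#' @return A `first_angle_result`: list with `angle` (degrees, unsigned),
#'   `frame_index`, `time`, and the per-frame `series`.
#' @export
max_extension_first_angle <- function(series, window = c(15, 60)) {
  stopifnot(is.data.frame(series),
            all(c("frame", "time_s", "angle_deg", "ok") %in% names(series)))
  check_num(window, "window", len = 2)
  if (window[2] < window[1]) stop_field("window", "t_end must be >= t_start")
  inwin <- series$time_s >= window[1] & series$time_s <= window[2]
  ok <- inwin & series$ok & is.finite(series$angle_deg)
  if (!any(ok)) {
    fails <- series[inwin & !series$ok, , drop = FALSE]
    msg <- if (nrow(fails)) {
      paste0("no valid frame in window [", window[1], ", ", window[2], "] s; failures: ",
             paste(sprintf("frame %d: %s", fails$frame,
                           fails$failure_reason %||% "unknown"), collapse = "; "))
    } else {
      paste0("no frames fall in window [", window[1], ", ", window[2], "] s")
    }
    stop(msg, call. = FALSE)
  }
  i <- which(ok)[which.max(abs(series$angle_deg[ok]))]
  structure(list(angle = abs(series$angle_deg[i]),
                 frame_index = series$frame[i],
                 time = series$time_s[i],
                 window = window,
                 series = series),
            class = "first_angle_result")
}

#' @export
print.first_angle_result <- function(x, ...) {
  cat(sprintf(
    "<first_angle_result> %.2f deg at frame %d (t = %.2f s; window %g-%g s; %d/%d frames valid)\n",
    x$angle, x$frame_index, x$time, x$window[1], x$window[2],
    sum(x$series$ok), nrow(x$series)))
  invisible(x)
}

#' Head-bend analysis of a worm movie
#'
#' Full posture pipeline: per frame, segment the worm, extract the midline,
#' then assign the nose across frames from motion, place the 13 equidistant
#' body points, compute the per-frame first supplementary angle, and report
#' it at the frame of maximal head-swing extension inside the window.
#' Per-frame failures (no object, coiled posture, out-of-bounds midline) are
#' recorded, not fatal.
#'
#' @param stack An [image_stack()].
#' @param window Analysis window in seconds (default `c(15, 60)`); clipped
#'   frames outside the recording are ignored.
#' @param n_points Number of body points (default 13).
#' @param config Options passed to [segment_worm()]; additionally
#'   `expected_length` and `smooth_df` for [extract_midline()], and
#'   `override` / `min_motion` for [assign_head()].
#' @return A `first_angle_result` (see [max_extension_first_angle()]) with an
#'   extra `points` element: a long data frame `frame,point_index,x_px,y_px`
#'   of the body-point coordinates of valid frames.
#' @export
analyze_posture <- function(stack, window = c(15, 60), n_points = 13L,
                            config = list()) {
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack", call. = FALSE)
  nf <- length(stack$frames)
  dt <- stack$frame_interval
  if (!is.finite(dt)) stop("stack has no frame interval; cannot place the time window", call. = FALSE)
  times <- (seq_len(nf) - 1) * dt

  midlines <- vector("list", nf)
  reasons <- rep(NA_character_, nf)
  for (k in seq_len(nf)) {
    midlines[[k]] <- tryCatch({
      m <- segment_worm(stack$frames[[k]], config)
      extract_midline(m, frame = stack$frames[[k]],
                      expected_length = config$expected_length,
                      smooth_df = config$smooth_df)
    }, nemaphene_frame_error = function(e) {
      reasons[k] <<- conditionMessage(e)
      NULL
    })
  }
  if (all(vapply(midlines, is.null, logical(1)))) {
    stop(paste0("no frame could be analyzed; first failure: ",
                reasons[which(!is.na(reasons))[1]]), call. = FALSE)
  }
  midlines <- assign_head(midlines, override = config$override,
                          min_motion = config$min_motion %||% 2)

  angle <- rep(NA_real_, nf)
  pts_rows <- list()
  for (k in seq_len(nf)) {
    if (is.null(midlines[[k]])) next
    pts <- assign_body_points(midlines[[k]], n = n_points)
    angle[k] <- as.numeric(first_supplementary_angle(pts))
    pts_rows[[length(pts_rows) + 1L]] <- data.frame(
      frame = k, point_index = seq_len(nrow(pts)),
      x_px = pts[, 1], y_px = pts[, 2])
  }
  series <- data.frame(frame = seq_len(nf), time_s = times,
                       angle_deg = angle,
                       ok = !is.na(angle),
                       failure_reason = reasons)
  res <- max_extension_first_angle(series, window = window)
  res$points <- do.call(rbind, pts_rows)
  res$head_confidence <- attr(midlines[[which(!vapply(midlines, is.null, logical(1)))[1]]],
                              "head_confidence")
  res
}
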