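# Worm segmentation: global threshold, polarity auto-detect, hole filling,
# largest connected component.

frame_error <- function(msg, class) {
  stop(structure(class = c(class, "nemaphene_frame_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Segment the worm in a single frame
#'
#' Global Otsu threshold (or a fixed numeric threshold) with automatic
#' polarity detection (the worm may be darker or brighter than the plate; the
#' smaller intensity class is taken as foreground), hole filling, and
#' selection of the largest connected component within configured area
#' bounds. Suits single-worm, clean-background assay plates.
#'
#' @param frame Numeric matrix (single-channel image, row = y, col = x).
#' @param config List of options: `threshold` (`"otsu"`, the default, or a
#'   numeric intensity), `min_area` / `max_area` (component area bounds in px;
#'   defaults 64 and half the frame), `fill_holes` (default `TRUE`).
#' @return An object of class `binary_mask`: a logical matrix with attributes
#'   `threshold`, `area` and `polarity` (`"bright"` or `"dark"` worm).
#'   Frames without a usable component raise a condition of class
#'   `nemaphene_segmentation_error` (callers processing stacks catch it and
#'   flag the frame rather than abort).
#' @export
segment_worm <- function(frame, config = list()) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("`frame` must be a numeric matrix", call. = FALSE)
  }
  min_area <- config$min_area %||% 64
  max_area <- config$max_area %||% (length(frame) / 2)
  fill_holes <- config$fill_holes %||% TRUE
  thr_cfg <- config$threshold %||% "otsu"

  rng <- range(frame)
  if (diff(rng) <= 0) {
    frame_error("uniform-intensity frame: no object to segment",
                "nemaphene_segmentation_error")
  }
  if (identical(thr_cfg, "otsu")) {
    norm <- (frame - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    thr <- as.numeric(thr_cfg)
  }

  above <- frame > thr
  polarity <- if (mean(above) <= 0.5) "bright" else "dark"
  fg <- if (polarity == "bright") above else !above

  img <- EBImage::Image(fg * 1)
  if (fill_holes) img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  labm <- EBImage::imageData(lab)
  if (max(labm) < 1) {
    frame_error("no foreground component found", "nemaphene_segmentation_error")
  }
  sizes <- tabulate(labm[labm > 0])
  best <- which.max(sizes)
  area <- sizes[best]
  if (area < min_area || area > max_area) {
    frame_error(sprintf(
      "largest component area %d px outside bounds [%g, %g]",
      area, min_area, max_area), "nemaphene_segmentation_error")
  }
  mask <- matrix(labm == best, nrow(frame), ncol(frame))
  structure(mask, class = c("binary_mask", "matrix", "array"),
            threshold = thr, area = area, polarity = polarity)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, area %d px, threshold %.4g (%s worm)\n",
              nrow(x), ncol(x), attr(x, "area"), attr(x, "threshold"),
              attr(x, "polarity")))
  invisible(x)
}
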