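# File formats: multi-page TIFF stacks with JSON sidecars, trace CSVs,
# ground-truth JSON sidecars.

#' Construct an image stack
#'
#' @param frames A single numeric matrix or a list of equally sized numeric
#'   matrices (row = y, column = x), intensities in arbitrary camera units.
#' @param pixel_size um per pixel.
#' @param frame_interval Time between frames, s.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size = NA_real_, frame_interval = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || !all(vapply(frames, is.matrix, logical(1)))) {
    stop("`frames` must be a matrix or a list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1 && (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px, %g um/px, %g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Write / read an image stack as 16-bit multi-page TIFF plus JSON sidecar
#'
#' Intensities are clamped to \[0, 65535\] and rounded to integers. The
#' sidecar `<path>.json` records `pixel_size_um` and `frame_interval_s`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack", call. = FALSE)
  scaled <- lapply(stack$frames, function(f) {
    round(pmin(pmax(f, 0), 65535)) / 65535
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval)
  meta <- meta[!vapply(meta, function(x) is.null(x) || is.na(x), logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) round(f * 65535))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  num_or_na <- function(x) {
    x <- suppressWarnings(as.numeric(x %||% NA_real_))
    if (length(x) != 1) NA_real_ else x
  }
  image_stack(frames,
              pixel_size = num_or_na(meta$pixel_size_um),
              frame_interval = num_or_na(meta$frame_interval_s))
}

#' Write / read a current trace as CSV plus JSON metadata
#'
#' The CSV has header `time_ms,current_nA`; `<path>.json` holds
#' `stimulus_onset_ms`, `sampling_rate_khz` and `holding_mv`.
#'
#' @param trace A [current_trace()].
#' @param path Output CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   [current_trace()].
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "current_trace")) stop("`trace` must be a current_trace", call. = FALSE)
  utils::write.csv(data.frame(time_ms = trace$time_ms, current_nA = trace$current_nA),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(stimulus_onset_ms = trace$stimulus_onset_ms,
         sampling_rate_khz = trace$sampling_rate_khz,
         holding_mv = trace$holding_mv),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, meta = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "current_nA") %in% names(df))) {
    stop("trace CSV must have columns `time_ms,current_nA`", call. = FALSE)
  }
  md <- if (file.exists(meta)) jsonlite::read_json(meta) else list()
  current_trace(df$time_ms, df$current_nA,
                sampling_rate_khz = as.numeric(md$sampling_rate_khz %||% NA) ,
                stimulus_onset_ms = as.numeric(md$stimulus_onset_ms %||% df$time_ms[1]),
                holding_mv = as.numeric(md$holding_mv %||% -60))
}

#' Write / read a ground-truth sidecar as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output path (conventionally `<dataset>.truth.json`).
#' @return `write_truth` returns `path` invisibly; `read_truth` a
#'   `ground_truth` list (matrices are restored as plain lists of rows).
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "ground_truth")) stop("`truth` must be a ground_truth", call. = FALSE)
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "ground_truth")
}
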