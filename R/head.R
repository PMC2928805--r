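# Nose/tail assignment across a sequence of midlines.

#' Assign the nose end of per-frame midlines
#'
#' The imaging itself does not distinguish nose from tail, so orientation is
#' assigned from motion: first, midlines are given a consistent orientation
#' across frames by endpoint-proximity matching; then the endpoint whose
#' offset from the centroid best aligns with the direction of centroid motion
#' over the sequence is labelled the nose (a crawling worm leads with its
#' nose). If net motion is below `min_motion` and no override is given, the
#' orientation is left as-is with `head_confidence = "unassigned"` (the angle
#' magnitude is still meaningful when the bend sits at one end, but which end
#' is anterior is unknown).
#'
#' @param midlines List of per-frame `midline` objects (`NULL` for frames
#'   whose extraction failed).
#' @param track Optional data frame with per-frame centroids (`x`, `y`,
#'   `valid`); defaults to midline vertex means.
#' @param override Optional user override instead of motion: one of
#'   `"left"`, `"right"`, `"up"`, `"down"` — the nose is the endpoint with
#'   the smaller x, larger x, smaller y, larger y respectively (applied per
#'   frame after orientation matching, decided on the first valid frame).
#' @param min_motion Net centroid displacement (px) below which motion-based
#'   assignment is refused (default 2).
#' @return The list of midlines, rows flipped where needed so row 1 is the
#'   nose, each with `head_confidence` attribute `"motion"`, `"user"` or
#'   `"unassigned"`.
#' @export
assign_head <- function(midlines, track = NULL, override = NULL, min_motion = 2) {
  valid <- which(!vapply(midlines, is.null, logical(1)))
  if (length(valid) == 0) stop("no valid midlines", call. = FALSE)
  if (is.null(override) && length(valid) < 2) {
    stop("need >= 2 frames with midlines for motion-based head assignment, or an override",
         call. = FALSE)
  }

  flip <- function(m) {
    structure(m[rev(seq_len(nrow(m))), , drop = FALSE], class = class(m),
              arc_length = attr(m, "arc_length"),
              head_confidence = attr(m, "head_confidence"))
  }

  # consistent orientation across frames: match endpoints to the previous
  # valid frame by proximity
  for (j in seq_along(valid)[-1]) {
    prev <- midlines[[valid[j - 1]]]
    cur <- midlines[[valid[j]]]
    pe <- rbind(prev[1, ], prev[nrow(prev), ])
    ce <- rbind(cur[1, ], cur[nrow(cur), ])
    keep <- sum((ce[1, ] - pe[1, ])^2) + sum((ce[2, ] - pe[2, ])^2)
    flp <- sum((ce[2, ] - pe[1, ])^2) + sum((ce[1, ] - pe[2, ])^2)
    if (flp < keep) midlines[[valid[j]]] <- flip(cur)
  }

  set_conf <- function(conf) {
    for (i in valid) attr(midlines[[i]], "head_confidence") <<- conf
  }

  if (!is.null(override)) {
    override <- match.arg(override, c("left", "right", "up", "down"))
    m1 <- midlines[[valid[1]]]
    ends <- rbind(m1[1, ], m1[nrow(m1), ])
    pick <- switch(override,
                   left = which.min(ends[, 1]), right = which.max(ends[, 1]),
                   up = which.min(ends[, 2]), down = which.max(ends[, 2]))
    if (pick == 2) for (i in valid) midlines[[i]] <- flip(midlines[[i]])
    set_conf("user")
    return(midlines)
  }

  cents <- if (!is.null(track)) {
    cbind(track$x, track$y)
  } else {
    t(vapply(midlines, function(m) {
      if (is.null(m)) c(NA_real_, NA_real_) else colMeans(m)
    }, numeric(2)))
  }
  cv <- cents[valid, , drop = FALSE]
  net <- sqrt(sum((cv[nrow(cv), ] - cv[1, ])^2))
  if (!is.finite(net) || net < min_motion) {
    set_conf("unassigned")
    return(midlines)
  }

  # score: alignment of (endpoint1 - endpoint2) with per-step motion
  score <- 0
  for (j in seq_along(valid)[-1]) {
    mv <- cv[j, ] - cv[j - 1, ]
    nm <- sqrt(sum(mv^2)); if (nm < 1e-9) next
    m <- midlines[[valid[j]]]
    axis <- m[1, ] - m[nrow(m), ]
    score <- score + sum(axis * mv) / nm
  }
  if (score < 0) for (i in valid) midlines[[i]] <- flip(midlines[[i]])
  set_conf("motion")
  midlines
}
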