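# Shared fixtures: small synthetic datasets built in code at test time.

# Default posture-test worm: 1 mm worm at 5 um/px with crawling undulation.
test_worm <- function(head_bend_angle = 0, noise_sd = 0, n_frames = 1L,
                      speed = 150, seed = 1L, ...) {
  worm_spec(head_bend_angle = head_bend_angle, undulation_amplitude = 25,
            speed = speed, n_frames = n_frames, noise_sd = noise_sd,
            seed = seed, ...)
}

# Arc positions of points `q` along a dense reference polyline `p`, found by
# nearest-point projection onto every segment: the independent arc-length
# oracle used for equidistance checks (the reference is sampled much more
# finely than the midline whose points are being checked).
oracle_arc_positions <- function(p, q) {
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cum <- c(0, cumsum(seg))
  ax <- p[-nrow(p), 1]; ay <- p[-nrow(p), 2]
  bx <- p[-1, 1]; by <- p[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx * dx + dy * dy, 1e-300)
  vapply(seq_len(nrow(q)), function(i) {
    tt <- pmin(pmax(((q[i, 1] - ax) * dx + (q[i, 2] - ay) * dy) / len2, 0), 1)
    d2 <- (ax + tt * dx - q[i, 1])^2 + (ay + tt * dy - q[i, 2])^2
    j <- which.min(d2)
    cum[j] + tt[j] * seg[j]
  }, numeric(1))
}

# Rectangle mask with a worm-like straight body (for midline symmetry tests).
rectangle_mask <- function(h = 40, w = 160, body_h = 10, body_w = 120) {
  m <- matrix(FALSE, h, w)
  r0 <- (h - body_h) / 2
  c0 <- (w - body_w) / 2
  m[(r0 + 1):(r0 + body_h), (c0 + 1):(c0 + body_w)] <- TRUE
  m
}

# Ring (annulus) mask: a closed loop with no skeleton endpoints.
ring_mask <- function(size = 80, r_out = 30, r_in = 22) {
  ctr <- size / 2
  d <- sqrt(outer((1:size - ctr)^2, (1:size - ctr)^2, "+"))
  d <= r_out & d >= r_in
}
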