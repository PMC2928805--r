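# Posture module: segmentation, midline extraction, 13-point placement,
# first supplementary angle, head assignment, maximal-extension statistic.

test_that("uniform frames fail segmentation with a frame-level condition", {
  expect_error(segment_worm(matrix(100, 50, 50)), "no object",
               class = "nemaphene_segmentation_error")
})

test_that("segmentation at the midpoint threshold reproduces the renderer mask", {
  mv <- render_movie(test_worm(head_bend_angle = 30, noise_sd = 0))
  sp <- test_worm()
  thr <- (sp$foreground + sp$background) / 2
  m <- segment_worm(mv$stack$frames[[1]], config = list(threshold = thr))
  expect_identical(unclass(m)[, ], mv$stack$masks[[1]])
})

test_that("segmentation handles both polarities and noisy frames", {
  mv <- render_movie(test_worm(noise_sd = 80, seed = 4))
  m <- segment_worm(mv$stack$frames[[1]])
  expect_equal(attr(m, "polarity"), "bright")
  truth_area <- mv$truth$body_area_um2 / 25
  expect_lt(abs(attr(m, "area") - truth_area) / truth_area, 0.05)
  # dark worm on bright plate
  inv <- 2000 - mv$stack$frames[[1]]
  m2 <- segment_worm(inv)
  expect_equal(attr(m2, "polarity"), "dark")
  expect_equal(sum(m2 != m) / sum(m), 0, tolerance = 0.02)
})

test_that("midline of a straight rectangle is its long axis", {
  ml <- extract_midline(rectangle_mask())
  L <- attr(ml, "arc_length")
  expect_gt(L, 110); expect_lt(L, 126)
  expect_lt(diff(range(ml[, 2])), 1.5)  # essentially horizontal
})

test_that("midline tracks the analytic centerline within 1 px RMS", {
  mv <- render_movie(test_worm(head_bend_angle = 30, noise_sd = 0))
  fr <- mv$stack$frames[[1]]
  ml <- extract_midline(segment_worm(fr), frame = fr)
  tp <- mv$truth$points13_px[[1]]
  if (sum((ml[1, ] - tp[1, ])^2) > sum((ml[nrow(ml), ] - tp[1, ])^2)) {
    ml <- ml[rev(seq_len(nrow(ml))), ]
  }
  pts <- assign_body_points(structure(ml, class = class(ml)))
  rms <- sqrt(mean(rowSums((pts - tp)^2)))
  expect_lt(rms, 1)
})

test_that("coiled (loop) masks raise a coiled-posture error", {
  expect_error(extract_midline(ring_mask()), "coiled",
               class = "nemaphene_coiled_error")
})

test_that("body points are equally spaced with exact endpoints", {
  # straight midline of length 120: points at 0, 10, ..., 120
  straight <- cbind(x = seq(0, 120, length.out = 50), y = rep(5, 50))
  pts <- assign_body_points(straight, n = 13)
  expect_equal(pts[, 1], seq(0, 120, by = 10), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(nrow(assign_body_points(straight)), 13)  # default is 13 points
  expect_error(assign_body_points(straight, n = 2), "n")
})

test_that("13-point spacing deviates < 2% from the dense arc-length oracle", {
  set.seed(7)
  for (rep in 1:10) {
    sp <- worm_spec(head_bend_angle = runif(1, 0, 60),
                    undulation_amplitude = runif(1, 5, 35),
                    undulation_wavelength = runif(1, 0.4, 0.9),
                    seed = rep)
    t_at <- runif(1, 0, 3)
    dense <- make_centerline(sp, t = t_at, n_steps = 2400L)
    # points are placed on a midline about as coarse as an extracted one;
    # the oracle measures their spacing along the dense reference curve
    coarse <- make_centerline(sp, t = t_at, n_steps = 60L)
    pts <- assign_body_points(coarse)
    s <- oracle_arc_positions(unclass(dense), unclass(pts))
    L <- max(s)
    expect_lt(max(abs(diff(s) - L / 12)) / (L / 12), 0.02)
  }
})

test_that("first supplementary angle matches analytic geometry", {
  expect_equal(as.numeric(first_supplementary_angle(
    rbind(c(0, 0), c(10, 0), c(20, 0)))), 0)
  a <- first_supplementary_angle(rbind(c(0, 0), c(10, 0), c(20, 10)))
  expect_equal(as.numeric(a), 45, tolerance = 1e-9)
  expect_error(first_supplementary_angle(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident")
})

test_that("the angle is invariant to rotation, translation and scale", {
  base <- rbind(c(0, 0), c(10, 0), c(20, 10), c(30, 12))
  a0 <- as.numeric(first_supplementary_angle(base))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(as.numeric(first_supplementary_angle(base %*% R)), a0,
               tolerance = 0.5)
  expect_equal(as.numeric(first_supplementary_angle(
    sweep(base, 2, c(55, -31), "+"))), a0, tolerance = 0.5)
  expect_equal(as.numeric(first_supplementary_angle(base * 2.7)), a0,
               tolerance = 0.5)
})

test_that("motion assigns the nose to the leading endpoint", {
  mv <- render_movie(test_worm(speed = 150, n_frames = 4, noise_sd = 0))
  mls <- lapply(mv$stack$frames, function(f) extract_midline(segment_worm(f), frame = f))
  oriented <- assign_head(mls)
  expect_true(all(vapply(oriented, function(m) attr(m, "head_confidence") == "motion",
                         logical(1))))
  for (k in seq_along(oriented)) {
    tp <- mv$truth$points13_px[[k]]
    d_nose <- sum((oriented[[k]][1, ] - tp[1, ])^2)
    d_tail <- sum((oriented[[k]][1, ] - tp[13, ])^2)
    expect_lt(d_nose, d_tail)
  }
  # reversing the frame order swaps nose and tail
  rev_or <- assign_head(rev(mls))
  expect_equal(unname(rev_or[[1]][1, ]),
               unname(oriented[[length(oriented)]][nrow(oriented[[1]]), ]),
               tolerance = 1e-6)
})

test_that("a stationary worm honors the user override and flags no motion", {
  mv <- render_movie(test_worm(speed = 0, n_frames = 2, noise_sd = 0, heading = 0))
  mls <- lapply(mv$stack$frames, function(f) extract_midline(segment_worm(f), frame = f))
  unass <- assign_head(mls)
  expect_equal(attr(unass[[1]], "head_confidence"), "unassigned")
  lft <- assign_head(mls, override = "left")
  expect_equal(attr(lft[[1]], "head_confidence"), "user")
  expect_lt(lft[[1]][1, 1], lft[[1]][nrow(lft[[1]]), 1])
  rgt <- assign_head(mls, override = "right")
  expect_gt(rgt[[1]][1, 1], rgt[[1]][nrow(rgt[[1]]), 1])
})

test_that("maximal-extension statistic picks the argmax frame in the window", {
  s <- data.frame(frame = 1:3, time_s = c(0, 0.5, 1), angle_deg = c(20, 20, 20),
                  ok = TRUE, failure_reason = NA)
  r <- max_extension_first_angle(s, window = c(0, 2))
  expect_equal(r$angle, 20)
  s2 <- data.frame(frame = 1:4, time_s = (0:3) * 0.5,
                   angle_deg = c(10, 25, 40, 33), ok = TRUE, failure_reason = NA)
  r2 <- max_extension_first_angle(s2, window = c(0, 2))
  expect_equal(r2$angle, 40)
  expect_equal(r2$frame_index, 3)
  expect_error(max_extension_first_angle(s2, window = c(10, 20)), "window")
})

test_that("the pipeline recovers a constant head bend end to end", {
  mv <- render_movie(test_worm(head_bend_angle = 30, n_frames = 3, noise_sd = 40,
                               seed = 5))
  res <- analyze_posture(mv$stack, window = c(0, 5))
  expect_equal(res$angle, 30, tolerance = 2)
  expect_equal(nrow(res$points), 13 * sum(res$series$ok))
})

test_that("an oscillating head bend reports its peak within 2 degrees", {
  # bend = 35 * cos(2 pi 0.25 t): peaks at t = 0 and 4 s; frames every 0.5 s
  sp <- test_worm(head_bend_angle = 35, n_frames = 10, noise_sd = 40, seed = 6)
  sp$head_bend_freq <- 0.25
  mv <- render_movie(sp)
  expect_equal(max(mv$truth$first_angle_deg), 35, tolerance = 1e-9)
  res <- analyze_posture(mv$stack, window = c(0, 5))
  expect_equal(res$angle, 35, tolerance = 2)
})
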