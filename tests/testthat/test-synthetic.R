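# Synthetic-data generators: analytic centerline, movie/puncta rendering,
# evoked-trace simulation, and their ground-truth sidecars.

polyline_length_test <- function(xy) sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))

test_that("spec constructors validate fields and name the offender", {
  expect_error(worm_spec(body_length = -1), "body_length")
  expect_error(worm_spec(undulation_amplitude = 95), "undulation_amplitude")
  expect_error(worm_spec(n_frames = 0), "n_frames")
  expect_error(worm_spec(frame_interval = 0), "frame_interval")
  expect_error(puncta_spec(peak_heights = -5), "peak_heights")
  expect_error(puncta_spec(psf_sigma = 0), "psf_sigma")
  expect_error(puncta_spec(n_puncta = 3, spacing = 6, psf_sigma = 2), "spacing")
  expect_error(trace_spec(tau_rise = 5, tau_decay = 3), "tau_decay")
  expect_error(trace_spec(sampling_rate = 0), "sampling_rate")
})

test_that("straight degenerate worm is a straight segment of full length", {
  cl <- make_centerline(worm_spec(head_bend_angle = 0, undulation_amplitude = 0))
  expect_equal(polyline_length_test(cl), 1000, tolerance = 1e-9)
  # all vertices collinear
  expect_lt(diff(range(cl[, 2])), 1e-9)
  expect_equal(attr(cl, "first_angle_deg"), 0)
})

test_that("head bend of the analytic 13 points matches the spec exactly", {
  for (ang in c(10, 30, 57)) {
    cl <- make_centerline(worm_spec(head_bend_angle = ang, undulation_amplitude = 0))
    p <- attr(cl, "points13")
    a <- first_supplementary_angle(p)
    expect_equal(as.numeric(a), ang, tolerance = 0.5)
    # with undulation on, the identity still holds by construction
    cl2 <- make_centerline(worm_spec(head_bend_angle = ang, undulation_amplitude = 30))
    a2 <- first_supplementary_angle(attr(cl2, "points13"))
    expect_equal(as.numeric(a2), ang, tolerance = 0.5)
  }
})

test_that("centerline arc length is conserved across time and bending", {
  sp <- worm_spec(head_bend_angle = 45, undulation_amplitude = 30, speed = 80,
                  n_frames = 5)
  for (t in c(0, 0.5, 1.7)) {
    cl <- make_centerline(sp, t)
    expect_equal(polyline_length_test(cl), 1000, tolerance = 1)  # within 0.1%
  }
})

test_that("stationary worm renders with a fixed centroid", {
  mv <- render_movie(worm_spec(speed = 0, undulation_amplitude = 20, n_frames = 3))
  cents <- t(vapply(mv$stack$masks, function(m) {
    idx <- which(m); H <- nrow(m)
    c(mean((idx - 1) %/% H), mean((idx - 1) %% H))
  }, numeric(2)))
  expect_lt(max(dist(cents)), 0.5)
})

test_that("ground-truth displacement follows the unit conversion", {
  sp <- worm_spec(speed = 100, frame_interval = 0.5, pixel_size = 5, n_frames = 4)
  mv <- render_movie(sp)
  expect_equal(mv$truth$displacement_px_per_frame, 10)
  d <- diff(mv$truth$centroid_px[, 1])
  expect_equal(d, rep(10, 3), tolerance = 1e-6)
})

test_that("noiseless mask area matches the analytic body area within 3%", {
  sp <- worm_spec(head_bend_angle = 25, undulation_amplitude = 25, noise_sd = 0)
  mv <- render_movie(sp)
  area_px <- sum(mv$stack$masks[[1]])
  area_truth <- mv$truth$body_area_um2 / sp$pixel_size^2
  expect_lt(abs(area_px - area_truth) / area_truth, 0.03)
})

test_that("a worm leaving a fixed canvas asks for a larger one", {
  sp <- worm_spec(speed = 200, n_frames = 10)
  expect_error(render_movie(sp, canvas = c(60, 60)), "larger canvas")
})

test_that("rendering is bit-reproducible under a fixed seed", {
  sp <- worm_spec(noise_sd = 50, n_frames = 2, seed = 42)
  a <- render_movie(sp); b <- render_movie(sp)
  expect_identical(a$stack$frames, b$stack$frames)
  c <- render_movie(worm_spec(noise_sd = 50, n_frames = 2, seed = 43))
  expect_false(identical(a$stack$frames[[1]], c$stack$frames[[1]]))
})

test_that("puncta image matches its closed form", {
  # no puncta: mean equals the background within the noise sd
  p0 <- render_puncta(puncta_spec(n_puncta = 0, background_level = 100, noise_sd = 4))
  expect_lt(abs(mean(p0$image) - 100), 4)
  # single noiseless punctum: max pixel = background + height
  p1 <- render_puncta(puncta_spec(n_puncta = 1, peak_heights = 150,
                                  background_level = 100, noise_sd = 0))
  expect_equal(max(p1$image), 250, tolerance = 1e-9)
  expect_equal(p1$truth$net_heights, 150)
})

test_that("puncta rendering is seed-deterministic", {
  s <- puncta_spec(noise_sd = 5, seed = 11)
  expect_identical(render_puncta(s)$image, render_puncta(s)$image)
})

test_that("trace ground truth carries the analytic closed forms", {
  tr <- make_trace(trace_spec(amplitude = 2, tau_rise = 0, tau_decay = 5))
  expect_equal(tr$truth$charge_pC, 10)            # A * tau
  expect_equal(tr$truth$half_decay_ms, 5 * log(2), tolerance = 1e-9)
  # difference of exponentials: peak at ln(5) * 5/4 after onset
  tr2 <- make_trace(trace_spec(tau_rise = 1, tau_decay = 5, onset = 25))
  expect_equal(tr2$truth$peak_time_ms - 25, log(5) * 5 / 4, tolerance = 1e-6)
})

test_that("trace baseline is flat before onset and polarity sets the sign", {
  tin <- make_trace(trace_spec(polarity = "inward", baseline_current = -0.1))$trace
  pre <- tin$time_ms < tin$stimulus_onset_ms
  expect_true(all(tin$current_nA[pre] == -0.1))
  expect_lt(min(tin$current_nA), -0.1)
  tout <- make_trace(trace_spec(polarity = "outward", baseline_current = -0.1))$trace
  expect_gt(max(tout$current_nA), -0.1)
})

test_that("too-short traces are flagged as truncated in the sidecar", {
  tr <- make_trace(trace_spec(tau_decay = 50, onset = 25, duration = 60))
  expect_true("decay truncated" %in% tr$truth$flags)
  ok <- make_trace(trace_spec(tau_decay = 5, onset = 25, duration = 100))
  expect_length(ok$truth$flags, 0)
})

test_that("trace generation is seed-deterministic", {
  s <- trace_spec(noise_sd = 0.05, seed = 9)
  expect_identical(make_trace(s)$trace$current_nA, make_trace(s)$trace$current_nA)
})
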