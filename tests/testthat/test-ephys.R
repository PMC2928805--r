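# Evoked-current metrics.

test_that("baseline is the pre-stimulus mean and demands enough samples", {
  tr <- current_trace(seq(0, 100, by = 1), rep(-0.1, 101), stimulus_onset_ms = 50)
  expect_equal(as.numeric(estimate_baseline(tr)), -0.1)
  expect_error(estimate_baseline(current_trace(seq(0, 100, by = 30),
                                               rep(0, 4), stimulus_onset_ms = 10)),
               "insufficient")
})

test_that("baseline noise averages down as the standard error predicts", {
  # 58 samples at 2.9 kHz in 20 ms; 3 * sd / sqrt(n) = 0.004
  set.seed(21)
  ok <- 0
  for (r in 1:50) {
    tr <- make_trace(trace_spec(baseline_current = -0.1, noise_sd = 0.01,
                                seed = r))$trace
    if (abs(as.numeric(estimate_baseline(tr)) + 0.1) < 3 * 0.01 / sqrt(58)) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.95)
})

test_that("a drifting baseline biases the estimate by slope * window / 2", {
  tt <- seq(0, 100, by = 1 / 2.9)
  slope <- 0.002  # nA per ms
  tr <- current_trace(tt, -0.1 + slope * tt, stimulus_onset_ms = 50)
  b <- as.numeric(estimate_baseline(tr, pre_window = 20))
  expect_equal(b, -0.1 + slope * 50 - slope * 20 / 2, tolerance = 0.02)
})

test_that("peak amplitude is exact for both kinetic forms", {
  m1 <- evoked_metrics(make_trace(trace_spec(amplitude = 2, tau_rise = 0,
                                             tau_decay = 5))$trace)
  expect_equal(m1$amplitude, 2, tolerance = 1e-6)
  expect_equal(m1$peak_time, 25, tolerance = 1e-6)  # at onset
  expect_equal(m1$polarity, "inward")
  m2 <- evoked_metrics(make_trace(trace_spec(amplitude = 2, tau_rise = 1,
                                             tau_decay = 5))$trace)
  expect_equal(m2$amplitude, 2, tolerance = 0.002)
  expect_equal(m2$peak_time - 25, log(5) * 5 / 4, tolerance = 0.05)
})

test_that("pure-noise traces are flagged sub-threshold", {
  set.seed(5)
  tt <- seq(0, 100, by = 1 / 2.9)
  tr <- current_trace(tt, -0.1 + rnorm(length(tt), 0, 0.01),
                      stimulus_onset_ms = 50)
  m <- evoked_metrics(tr)
  expect_true(m$sub_threshold)
  expect_lt(m$amplitude, 0.05)
  expect_equal(m$charge, 0)
})

test_that("half-decay matches tau * log(2) and the printed recovery values", {
  m <- evoked_metrics(make_trace(trace_spec(tau_rise = 0, tau_decay = 5))$trace)
  expect_equal(m$half_decay, 5 * log(2), tolerance = 0.01)
  # decay constants whose half-times match published gain-of-function and
  # suppressed-mutant values at the 2.9 kHz digitization rate
  m1 <- evoked_metrics(make_trace(trace_spec(tau_rise = 0, tau_decay = 4.660,
                                             duration = 150))$trace)
  expect_equal(round(m1$half_decay, 2), 3.23, tolerance = 0.005)
  m2 <- evoked_metrics(make_trace(trace_spec(tau_rise = 0, tau_decay = 9.536,
                                             duration = 150))$trace)
  expect_equal(round(m2$half_decay, 2), 6.61, tolerance = 0.005)
})

test_that("a trace ending before the 50% crossing errors as truncated", {
  tr <- make_trace(trace_spec(tau_decay = 80, onset = 25, duration = 27))$trace
  b <- estimate_baseline(tr)
  pk <- peak_amplitude(tr, b, search_window = 2)
  expect_error(half_decay_time(tr, b, pk$amplitude, pk$peak_time), "truncated")
})

test_that("charge approaches A * tau as the cutoff goes to zero", {
  tr <- make_trace(trace_spec(amplitude = 2, tau_rise = 0, tau_decay = 5,
                              duration = 200))$trace
  m_05 <- evoked_metrics(tr)
  m_0 <- evoked_metrics(tr, return_fraction = 0.0005)
  expect_lt(m_05$charge, 10)
  expect_equal(m_0$charge, 10, tolerance = 0.02)
  # closed form for the 5% truncation: integral to tau*ln(20) is A*tau*0.95
  expect_equal(m_05$charge, 2 * 5 * 0.95, tolerance = 0.05)
})

test_that("charge doubles with amplitude at fixed kinetics, zero without response", {
  m1 <- evoked_metrics(make_trace(trace_spec(amplitude = 1, tau_decay = 5))$trace)
  m2 <- evoked_metrics(make_trace(trace_spec(amplitude = 2, tau_decay = 5))$trace)
  expect_equal(m2$charge / m1$charge, 2, tolerance = 1e-6)
})

test_that("no return to baseline before the cap flags the charge window", {
  tr <- make_trace(trace_spec(tau_decay = 120, onset = 25, duration = 150))$trace
  b <- estimate_baseline(tr)
  pk <- peak_amplitude(tr, b)
  q <- charge_integral(tr, b, pk$amplitude, pk$peak_time, max_window = 100)
  expect_true("no_return_to_baseline_before_cap" %in% attr(q, "flags"))
})

test_that("normalized traces peak at exactly 1 and are amplitude-invariant", {
  m <- evoked_metrics(make_trace(trace_spec(amplitude = 2, tau_rise = 1,
                                            tau_decay = 5))$trace)
  expect_equal(max(m$normalized$normalized), 1.0)
  n1 <- evoked_metrics(make_trace(trace_spec(amplitude = 1, tau_decay = 5))$trace)$normalized
  n3 <- evoked_metrics(make_trace(trace_spec(amplitude = 3, tau_decay = 5))$trace)$normalized
  expect_equal(n1$normalized, n3$normalized, tolerance = 1e-9)
})

test_that("metrics are polarity-symmetric", {
  m_in <- evoked_metrics(make_trace(trace_spec(polarity = "inward",
                                               tau_rise = 1, tau_decay = 5))$trace)
  m_out <- evoked_metrics(make_trace(trace_spec(polarity = "outward",
                                                tau_rise = 1, tau_decay = 5))$trace)
  expect_equal(m_in$amplitude, m_out$amplitude, tolerance = 1e-9)
  expect_equal(m_in$half_decay, m_out$half_decay, tolerance = 1e-9)
  expect_equal(m_in$charge, m_out$charge, tolerance = 1e-9)
})

test_that("metrics agree within 2% between 2.9 kHz and 29 kHz sampling", {
  for (taus in list(c(0, 3), c(0, 9.536), c(1, 5))) {
    m_lo <- evoked_metrics(make_trace(trace_spec(tau_rise = taus[1],
                                                 tau_decay = taus[2],
                                                 sampling_rate = 2.9))$trace)
    m_hi <- evoked_metrics(make_trace(trace_spec(tau_rise = taus[1],
                                                 tau_decay = taus[2],
                                                 sampling_rate = 29))$trace)
    expect_equal(m_lo$amplitude, m_hi$amplitude, tolerance = 0.02)
    expect_equal(m_lo$half_decay, m_hi$half_decay, tolerance = 0.02)
    expect_equal(m_lo$charge, m_hi$charge, tolerance = 0.02)
  }
})

test_that("noisy replicates recover half-decay with small bias and spread", {
  vals <- vapply(1:60, function(r) {
    tr <- make_trace(trace_spec(amplitude = 2, tau_rise = 0, tau_decay = 5,
                                noise_sd = 0.04, seed = r))$trace
    evoked_metrics(tr)$half_decay
  }, numeric(1))
  truth <- 5 * log(2)
  expect_lt(abs(mean(vals) - truth) / truth, 0.03)
  expect_lt(stats::sd(vals) / truth, 0.05)
})
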