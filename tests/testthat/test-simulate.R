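test_that("zero event rate gives an empty stream; impossible durations warn", {
  m <- fast_asyn(seed = 1, duration = 5, event_rate = 0)
  ev <- simulate_events(m)
  expect_equal(nrow(ev), 0L)
  m2 <- fast_asyn(seed = 1, duration = 1e-4, event_rate = 0.01)
  expect_warning(ev2 <- simulate_events(m2), "no event fits")
  expect_equal(nrow(ev2), 0L)
  expect_match(attr(ev2, "empty_reason"), "too short")
})

test_that("event arrivals follow the Poisson law with dead-time thinning", {
  m <- fast_asyn(seed = 7, duration = 100, event_rate = 10)
  ev <- simulate_events(m)
  # dead time + dwell occupancy thins ~10/s to ~9.86/s
  expect_lt(abs(nrow(ev) - 1000), 3 * sqrt(1000))
  gaps <- ev$start_s[-1] - (ev$start_s + ev$dwell_ms / 1000)[-nrow(ev)]
  expect_true(all(gaps >= m$dead_time_ms / 1000 - 1e-12))
})

test_that("dwell times are exponential with the configured scale", {
  m <- one_class_model(dwell_scale = 0.5, event_rate = 60, duration = 60,
                       seed = 5)
  ev <- simulate_events(m)
  expect_gt(nrow(ev), 2000)
  expect_lt(abs(mean(ev$dwell_ms) / 0.5 - 1), 0.05)
  # distributional shape at n >= 5000
  m2 <- one_class_model(dwell_scale = 0.5, event_rate = 80, duration = 120,
                        seed = 6)
  ev2 <- simulate_events(m2)
  expect_gt(nrow(ev2), 5000)
  ks <- stats::ks.test(ev2$dwell_ms, "pexp", rate = 1 / 0.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("class mixing fractions converge to the model weights", {
  m <- fast_asyn(seed = 9, duration = 80)
  ev <- simulate_events(m)
  w <- vapply(m$classes, `[[`, 0, "weight")
  names(w) <- vapply(m$classes, `[[`, "", "label")
  n <- nrow(ev)
  for (cl in names(w)) {
    frac <- mean(ev$class == cl)
    expect_lt(abs(frac - w[[cl]]), 3 * sqrt(w[[cl]] * (1 - w[[cl]]) / n))
  }
})

test_that("blocked-time fraction matches rate x mean dwell", {
  m <- fast_asyn(seed = 11, duration = 100)
  ev <- simulate_events(m)
  blocked <- sum(ev$dwell_ms) / 1000 / m$duration
  mean_dwell_s <- sum(vapply(m$classes, function(c) c$weight * c$dwell_scale, 0)) / 1000
  eff_rate <- nrow(ev) / m$duration
  expect_lt(abs(blocked - eff_rate * mean_dwell_s) / (eff_rate * mean_dwell_s), 0.1)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- fast_asyn(seed = 21, duration = 5)
  e1 <- simulate_events(m); e2 <- simulate_events(m)
  expect_identical(e1, e2)
  t1 <- render_trace(e1, m); t2 <- render_trace(e2, m)
  expect_identical(t1$samples, t2$samples)
  s1 <- simulate_trace(m); s2 <- simulate_trace(m)
  expect_identical(s1$trace$samples, s2$trace$samples)
  # different seed, different stream
  e3 <- simulate_events(m, seed = 99L)
  expect_false(identical(e1$start_s, e3$start_s))
})

test_that("rendering puts square blockades on the baseline", {
  m <- one_class_model(event_rate = 0, duration = 0.01, noise_sd = 0, seed = 1)
  empty <- simulate_events(m)
  tr <- render_trace(empty, m)
  expect_true(all(abs(tr$samples - m$baseline_current) < 1e-9))

  ev <- data.frame(class = "translocation", start_s = 0.004, dwell_ms = 1,
                   amplitude_pA = -85)
  tr2 <- render_trace(ev, m)
  # interior of a 1 ms event (100 samples) sits at baseline - 85
  interior <- 420:470
  expect_true(all(abs(tr2$samples[interior] - (100 - 85)) < 1e-6))
})

test_that("overlapping or out-of-range events are rejected", {
  m <- one_class_model(event_rate = 0, duration = 0.01, noise_sd = 0)
  bad <- data.frame(class = "x", start_s = c(0.001, 0.0012),
                    dwell_ms = c(0.5, 0.5), amplitude_pA = c(-85, -85))
  expect_error(render_trace(bad, m), "overlap")
  out <- data.frame(class = "x", start_s = 0.0099, dwell_ms = 1,
                    amplitude_pA = -85)
  expect_error(render_trace(out, m), "outside")
})

test_that("the recording filter attenuates events shorter than its rise time", {
  m <- one_class_model(event_rate = 0, duration = 0.01, noise_sd = 0)
  d_ms <- 0.02
  ev <- data.frame(class = "bumping", start_s = 0.005, dwell_ms = d_ms,
                   amplitude_pA = -30)
  tr <- render_trace(ev, m)
  peak <- max(100 - tr$samples)
  # analytic peak of a box through the Gaussian filter
  sigma_s <- sqrt(log(2)) / (2 * pi * m$filter_bandwidth)
  expected <- 30 * (2 * stats::pnorm((d_ms / 2000) / sigma_s) - 1)
  expect_lt(peak, 30 * 0.8)
  expect_equal(peak, expected, tolerance = 0.05)
})
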