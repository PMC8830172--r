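test_that("baseline estimation is robust to blockades", {
  expect_equal(estimate_baseline(rep(100, 1000)),
               list(level = 100, noise_sd = 0))
  expect_error(estimate_baseline(numeric(0)), "empty")

  set.seed(31)
  x <- rnorm(1e5, 100, 1.5)
  b <- estimate_baseline(x)
  expect_lt(abs(b$level - 100), 0.05)
  expect_lt(abs(b$noise_sd - 1.5), 0.05)

  # 10% of time blocked at -85 pA deflection
  x2 <- x
  x2[1:1e4] <- x2[1:1e4] - 85
  b2 <- estimate_baseline(x2)
  oracle <- estimate_baseline(x[10001:1e5])  # event-free samples
  expect_lt(abs(b2$level - oracle$level), 0.2)
  expect_lt(abs(b2$level - 100), 1)
})

test_that("detection output is invariant to a constant offset", {
  m <- fast_asyn(seed = 41, duration = 4)
  tr <- simulate_trace(m)$trace
  t1 <- detect_events(tr)
  tr2 <- tr
  tr2$samples <- tr$samples + 37.5
  t2 <- detect_events(tr2)
  expect_equal(nrow(t1), nrow(t2))
  expect_equal(t1$start_index, t2$start_index)
  expect_equal(t1$dwell_ms, t2$dwell_ms, tolerance = 1e-9)
  expect_equal(t1$blockade_pA, t2$blockade_pA, tolerance = 1e-9)
})

test_that("an event-free trace yields an empty table", {
  m <- one_class_model(event_rate = 0, duration = 0.5, seed = 8)
  tr <- render_trace(simulate_events(m), m)
  tab <- detect_events(tr)
  expect_s3_class(tab, "event_table")
  expect_equal(nrow(tab), 0L)
})

test_that("noiseless traces need an absolute threshold", {
  n <- 2000
  x <- rep(100, n)
  x[1000:1050] <- 70
  tr <- manual_trace(x, fs = 1e5)
  expect_error(detect_events(tr), "absolute_threshold")
  tab <- detect_events(tr, detection_params(absolute_threshold_pA = 15))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$blockade_pA, -30, tolerance = 1e-6)
  expect_equal(tab$dwell_ms, 51 / 1e5 * 1000, tolerance = 0.02)
})

test_that("square-pulse features are exact by construction", {
  # rendered (filtered) pulse with low noise: -30 pA for 0.5 ms at 100 kHz
  m <- one_class_model(mean_blockade = -30, sd_blockade = 3,
                       event_rate = 0, duration = 0.02, noise_sd = 0.01,
                       seed = 2)
  ev <- data.frame(class = "bumping", start_s = 0.01, dwell_ms = 0.5,
                   amplitude_pA = -30)
  tr <- render_trace(ev, m)
  tab <- detect_events(tr, baseline = list(level = 100, noise_sd = 0.01))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$blockade_pA, -30, tolerance = 0.01)
  expect_equal(tab$dwell_ms, 0.5, tolerance = 0.01)
})

test_that("amplitude estimates on noisy pulses have the expected precision", {
  m <- one_class_model(mean_blockade = -30, sd_blockade = 3,
                       event_rate = 0, duration = 0.02, noise_sd = 1.5,
                       seed = 2)
  errs <- vapply(1:50, function(s) {
    ev <- data.frame(class = "bumping", start_s = 0.01, dwell_ms = 0.5,
                     amplitude_pA = -30)
    tr <- render_trace(ev, m, seed = s)
    tab <- detect_events(tr)
    if (nrow(tab) != 1L) return(NA_real_)
    tab$blockade_pA + 30
  }, 0)
  # SE of the mean of ~50 in-event samples at 1.5 pA noise, allowing for
  # filter-induced correlation
  expect_true(mean(abs(errs) <= 3 * 1.5 / sqrt(50) * 2.2, na.rm = TRUE) >= 0.95)
  expect_lt(abs(mean(errs, na.rm = TRUE)), 0.5)
})

test_that("two pulses inside the release window merge into one event", {
  m <- one_class_model(mean_blockade = -30, sd_blockade = 3,
                       event_rate = 0, duration = 0.02, noise_sd = 0.5,
                       seed = 3)
  # 0.02 ms gap: the filtered trough stays below the release level
  ev <- data.frame(class = c("a", "b"), start_s = c(0.0100, 0.010320),
                   dwell_ms = c(0.3, 0.3), amplitude_pA = c(-30, -30))
  tr <- render_trace(ev, m)
  tab <- detect_events(tr)
  expect_equal(nrow(tab), 1L)
  # well-separated pulses stay distinct
  ev2 <- data.frame(class = c("a", "b"), start_s = c(0.0100, 0.0110),
                    dwell_ms = c(0.3, 0.3), amplitude_pA = c(-30, -30))
  tr2 <- render_trace(ev2, m)
  expect_equal(nrow(detect_events(tr2)), 2L)
})

test_that("events at the minimum duration are retained with finite features", {
  x <- rep(100, 1000)
  x[500:502] <- 60   # exactly min_duration_samples = 3
  tr <- manual_trace(x, fs = 1e5)
  tab <- detect_events(tr, detection_params(absolute_threshold_pA = 20))
  expect_equal(nrow(tab), 1L)
  expect_true(is.finite(tab$blockade_pA) && is.finite(tab$dwell_ms))
  x[500:501] <- 100; x[502] <- 60  # below minimum: dropped
  tr2 <- manual_trace(x, fs = 1e5)
  expect_equal(nrow(detect_events(tr2, detection_params(absolute_threshold_pA = 20))), 0L)
})

test_that("detected dwell is within one sample of truth at SNR >= 5", {
  m <- one_class_model(mean_blockade = -30, sd_blockade = 3,
                       event_rate = 0, duration = 0.03, noise_sd = 1.5,
                       seed = 4)
  for (d_ms in c(0.03, 0.05, 0.08, 0.2, 0.5)) {
    errs <- vapply(1:30, function(s) {
      ev <- data.frame(class = "x", start_s = 0.012, dwell_ms = d_ms,
                       amplitude_pA = -30)
      tr <- render_trace(ev, m, seed = s + 100)
      tab <- detect_events(tr)
      if (nrow(tab) != 1L) return(NA_real_)
      tab$dwell_ms - d_ms
    }, 0)
    expect_true(mean(abs(errs) <= 0.01, na.rm = TRUE) >= 0.9,
                label = sprintf("dwell accuracy at %.2f ms", d_ms))
  }
})

test_that("amplitude estimation is unbiased over many events", {
  m <- fast_asyn(seed = 51, duration = 40)
  sim <- simulate_trace(m)
  tab <- detect_events(sim$trace)
  sc <- evaluate_detection(tab, sim$truth)
  ok <- !is.na(sc$matches)
  err <- tab$blockade_pA[sc$matches[ok]] - sim$truth$amplitude_pA[ok]
  long <- sim$truth$dwell_ms[ok] > 0.15   # events much longer than the filter rise
  expect_gt(sum(long), 300)
  expect_lt(abs(mean(err[long])), 0.2)
})

test_that("detector recall and precision clear 0.95 at default SNR", {
  m <- fast_asyn(seed = 61, duration = 20)
  sim <- simulate_trace(m)
  tab <- detect_events(sim$trace)
  sc <- evaluate_detection(tab, sim$truth)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})
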