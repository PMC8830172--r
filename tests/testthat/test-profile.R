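test_that("blockade histograms conserve event counts", {
  ev <- draw_events(100, -85, 5, seed = 2)
  h <- build_blockade_histogram(ev, 2)
  expect_equal(sum(h$counts), 100)
  h2 <- build_blockade_histogram(ev, 1)
  expect_equal(sum(h2$counts), 100)
  same <- draw_events(50, -41, 0, seed = 3)
  h3 <- build_blockade_histogram(same, 2)
  expect_equal(sum(h3$counts > 0), 1L)
  expect_error(build_blockade_histogram(ev, 0), "bin_width")
  expect_error(build_blockade_histogram(ev[0, ], 2), "no events")
})

test_that("a single Gaussian population recovers its generative peak", {
  ev <- draw_events(1000, -85, 5, seed = 4)
  fit <- fit_population_model(ev, k = 1)
  expect_equal(fit$k, 1L)
  expect_lt(abs(fit$components$peak_pA + 85), 1)
  # fitted peak agrees with the sample mean (the closed-form MLE)
  expect_lt(abs(fit$components$peak_pA - mean(ev$blockade_pA)),
            2 * 5 / sqrt(1000))
  expect_error(fit_population_model(draw_events(40, -85, 5), k = 1),
               "refused")
})

test_that("two-component populations recover generative weights within 5 points", {
  w <- c(66, 24) / 90
  n <- 2000
  n1 <- round(n * w[1])
  ev <- draw_events(c(n1, n - n1), c(-85, -30), c(5, 3), seed = 5)
  fit <- fit_population_model(ev, k = 2)
  comp <- fit$components
  expect_equal(comp$class, c("translocation", "bumping"))
  expect_lt(abs(comp$population_pct[1] - 100 * w[1]), 5)
  expect_lt(abs(comp$population_pct[2] - 100 * w[2]), 5)
  expect_lt(abs(comp$peak_pA[1] + 85), 1)
  expect_lt(abs(comp$peak_pA[2] + 30), 1)
  # BIC model selection picks two components on the same sample
  auto <- fit_population_model(ev, k = "auto")
  expect_equal(auto$k, 2L)
})

test_that("histogram least-squares fitting agrees with the likelihood route", {
  ev <- draw_events(c(1400, 600), c(-85, -30), c(5, 3), seed = 6)
  f1 <- fit_population_model(ev, k = 2, method = "mle")
  f2 <- fit_population_model(ev, k = 2, method = "histogram_ls")
  expect_equal(f2$components$peak_pA, f1$components$peak_pA, tolerance = 0.02)
  expect_equal(f2$components$population_pct, f1$components$population_pct,
               tolerance = 0.1)
  expect_true(is.finite(f2$goodness$rss))
})

test_that("component labels follow peak depth, with absolute anchors for k = 1", {
  ev3 <- draw_events(c(800, 500, 700), c(-85, -50, -30), c(5, 3, 3), seed = 7)
  fit3 <- fit_population_model(ev3, k = 3)
  expect_equal(fit3$components$class,
               c("translocation", "intercalation", "bumping"))
  bump_only <- draw_events(500, -30, 3, seed = 8)
  f1 <- fit_population_model(bump_only, k = 1)
  expect_equal(f1$components$class, "bumping")
  deep_only <- draw_events(500, -85, 5, seed = 9)
  expect_equal(fit_population_model(deep_only, k = 1)$components$class,
               "translocation")
})

test_that("events join the nearest component window, ties to the deeper peak", {
  fit <- structure(list(components = data.frame(
    class = c("translocation", "bumping"), peak_pA = c(-85, -30),
    sigma_pA = c(12, 12), weight = c(0.7, 0.3),
    population_pct = NA_real_, n_events = NA_integer_,
    stringsAsFactors = FALSE)), class = "population_fit")
  ev <- poreblock:::new_event_table(data.frame(
    start_s = 1:4, dwell_ms = 1, blockade_pA = c(-85, -30, -57.5, -200),
    amp_se_pA = 0, class = "unclassified", low_confidence = FALSE,
    stringsAsFactors = FALSE))
  out <- assign_event_classes(ev, fit)
  expect_equal(out$class,
               c("translocation", "bumping", "translocation", "unclassified"))
  fit$components$peak_pA <- c(-50, -50)
  expect_error(assign_event_classes(ev, fit), "degenerate")
})

test_that("population shares plus unclassified always total 100", {
  for (seed in 1:5) {
    ev <- draw_events(c(700, 300), c(-85, -30), c(5, 3), seed = seed)
    fit <- fit_population_model(ev, k = "auto")
    expect_lt(abs(sum(fit$components$population_pct) +
                    fit$unclassified_pct - 100), 0.1)
  }
})

test_that("dwell-time MLE equals the arithmetic mean and meets 5% accuracy", {
  set.seed(10)
  d <- rexp(5000, 1 / 0.5)
  f <- fit_dwell_time(d)
  expect_equal(f$tau_ms, mean(d))
  expect_lt(abs(f$tau_ms / 0.5 - 1), 0.05)
  expect_equal(fit_dwell_time(rep(0.3, 25))$tau_ms, 0.3)
  expect_error(fit_dwell_time(rexp(10, 2)), "refused")
  # least-squares histogram route estimates the same parameter
  fh <- fit_dwell_time(d, method = "histogram_ls")
  expect_lt(abs(fh$tau_ms / f$tau_ms - 1), 0.1)
})

test_that("left-truncation correction undoes the missed-event bias", {
  set.seed(11)
  d <- rexp(20000, 1 / 0.05)
  c0 <- 0.004
  obs <- d[d >= c0]   # what a detector with this dead time sees
  naive <- fit_dwell_time(obs)
  corrected <- fit_dwell_time(obs, truncation_ms = c0)
  expect_gt(naive$tau_ms, 0.05 + 0.003)            # biased upward by ~c0
  expect_lt(abs(corrected$tau_ms / 0.05 - 1), 0.03)
})

test_that("peak accuracy improves as 1/sqrt(n)", {
  ns <- c(100, 400, 1600, 6400)
  mean_abs_err <- vapply(ns, function(n) {
    errs <- vapply(1:40, function(s) {
      ev <- draw_events(n, -85, 5, seed = n + s)
      fit_population_model(ev, k = 1)$components$peak_pA + 85
    }, 0)
    mean(abs(errs))
  }, 0)
  slope <- stats::coef(stats::lm(log(mean_abs_err) ~ log(ns)))[[2]]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("replicate pooling concatenates and summaries report SEM", {
  m <- fast_asyn(duration = 10)
  tabs <- lapply(1:3, function(r) {
    ev <- simulate_events(m, seed = derive_seed(77, r))
    as_event_table(ev, condition = "asyn", replicate = r)
  })
  pooled <- pool_replicates(tabs)
  expect_equal(nrow(pooled$pooled), sum(vapply(tabs, nrow, 0L)))
  bad <- tabs
  attr(bad[[2]], "meta")$condition <- "other"
  expect_error(pool_replicates(bad), "mismatched condition")

  profs <- lapply(tabs, condition_profile)
  smy <- summarize_condition(profs, condition = "asyn")
  expect_equal(smy$n_replicates, 3L)
  expect_true(all(is.finite(smy$classes$population_sem)))

  # single replicate: means only, no SEM
  s1 <- summarize_condition(profs[1])
  expect_true(all(is.na(s1$classes$population_sem)))
  # identical replicates: SEM exactly 0
  s0 <- summarize_condition(profs[c(1, 1, 1)])
  expect_true(all(s0$classes$population_sem == 0))
})

test_that("the SEM follows the textbook formula", {
  per <- rep_df("translocation", c(66, 64, 68))
  smy <- fake_summary("asyn", per)
  expect_equal(smy$classes$population_sem, sd(c(66, 64, 68)) / sqrt(3))
  expect_equal(smy$classes$population_sem, 1.1547005, tolerance = 1e-6)
})
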