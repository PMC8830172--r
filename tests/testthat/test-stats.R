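test_that("ANOVA F matches the closed-form sums of squares", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3.0, tolerance = 1e-9)
  expect_equal(res$df, c(2L, 6L))
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check against R's own linear-model ANOVA on random data
  set.seed(1)
  g <- list(rnorm(4), rnorm(5, 1), rnorm(6, 2))
  res2 <- one_way_anova(g)
  y <- unlist(g)
  f <- factor(rep(seq_along(g), lengths(g)))
  ref <- summary(stats::aov(y ~ f))[[1]]
  expect_equal(res2$F, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(res2$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("identical groups give F = 0 and p = 1", {
  res <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("summary-statistic mode reproduces the raw-data F exactly", {
  set.seed(2)
  g <- list(a = rnorm(3, 5), b = rnorm(3, 6), c = rnorm(4, 7))
  raw <- one_way_anova(g)
  smry <- data.frame(group = names(g),
                     mean = vapply(g, mean, 0),
                     sem = vapply(g, function(x) sd(x) / sqrt(length(x)), 0),
                     n = lengths(g))
  res <- one_way_anova(smry)
  expect_equal(res$F, raw$F, tolerance = 1e-9)
  expect_equal(res$p, raw$p, tolerance = 1e-9)
})

test_that("zero within-group variance with unequal means is flagged degenerate", {
  res <- one_way_anova(list(c(1, 1, 1), c(2, 2, 2)))
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
})

test_that("significance labels follow the strict threshold ladder", {
  expect_equal(significance_label(c(0.03, 0.0005, 0.009, 0.2)),
               c("*", "***", "**", "ns"))
  expect_equal(significance_label(0.05), "ns")    # strict inequality
  expect_equal(significance_label(0.01), "*")
  expect_equal(significance_label(0.001), "**")
  expect_error(significance_label(1.2), "\\[0, 1\\]")
  expect_error(significance_label(-0.1), "\\[0, 1\\]")
})

test_that("SNK calls obvious cases correctly", {
  res <- snk_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$pairwise$label, "ns")
  # two groups separated by 50 within-group SDs
  set.seed(3)
  a <- rnorm(3, 0, 1); b <- rnorm(3, 50, 1)
  res2 <- snk_posthoc(list(a = a, b = b))
  expect_equal(res2$pairwise$label, "***")
  expect_error(snk_posthoc(list(c(1, 2), 3)), "n >= 2")
})

test_that("SNK accept/reject pattern matches the numerical-integration oracle", {
  set.seed(4)
  n_data <- 40
  agree <- vapply(seq_len(n_data), function(i) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:5, 1),
                                                   mean = runif(1, 0, 3)))
    names(groups) <- paste0("g", seq_len(k))
    mine <- snk_posthoc(groups)
    all(snk_pattern_from_result(mine, length(groups)) ==
          snk_oracle_pattern(groups))
  }, NA)
  expect_true(all(agree))
})

test_that("SNK never flags a pair enclosed in a non-significant range", {
  set.seed(5)
  for (rep in 1:20) {
    k <- 4
    groups <- lapply(1:k, function(j) rnorm(3, mean = runif(1, 0, 2)))
    names(groups) <- paste0("g", 1:k)
    pw <- snk_posthoc(groups)$pairwise
    p <- matrix(NA_real_, k, k)
    idx <- 1L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      p[i, j] <- pw$p[idx]; idx <- idx + 1L
    }
    # every pair's p is at least that of any range directly enclosing it,
    # so an enclosed pair can never out-signify its enclosure
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (i > 1L) expect_gte(p[i, j], p[i - 1L, j] - 1e-12)
      if (j < k) expect_gte(p[i, j], p[i, j + 1L] - 1e-12)
    }
  }
})

test_that("increasing a true separation never raises the pairwise p", {
  set.seed(6)
  base <- list(a = rnorm(4, 0), b = rnorm(4, 0.5), c = rnorm(4, 2))
  stopifnot(mean(base$c) > max(mean(base$a), mean(base$b)))
  deltas <- seq(0, 4, by = 0.5)
  ps <- vapply(deltas, function(d) {
    g <- base
    g$c <- base$c + d
    pw <- snk_posthoc(g)$pairwise
    pw$p[pw$group1 %in% c("a") & pw$group2 == "c" |
           pw$group1 == "c" & pw$group2 == "a"][1]
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the ANOVA holds its nominal size under the null", {
  set.seed(7)
  n_sim <- 2000
  rej <- vapply(seq_len(n_sim), function(i) {
    one_way_anova(list(rnorm(3), rnorm(3), rnorm(3)))$p < 0.05
  }, NA)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
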