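# Replicate statistics: one-way ANOVA, Student-Newman-Keuls post-hoc,
# significance labelling.

# Canonicalize group input: either a list of raw numeric vectors, or a
# data.frame / list-of-lists of summary statistics (mean, sem or sd, n).
as_group_stats <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("mean", "n") %in% names(groups)))
    sd <- if ("sd" %in% names(groups)) groups$sd else {
      stopifnot("sem" %in% names(groups))
      groups$sem * sqrt(groups$n)
    }
    nm <- if (!is.null(groups$group)) as.character(groups$group) else
      paste0("group", seq_len(nrow(groups)))
    return(data.frame(group = nm, mean = groups$mean, sd = sd,
                      n = groups$n, stringsAsFactors = FALSE))
  }
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (all(vapply(groups, is.numeric, NA))) {
    nm <- names(groups)
    if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("group", seq_along(groups))
    return(data.frame(
      group = nm,
      mean = vapply(groups, mean, 0),
      sd = vapply(groups, stats::sd, 0),
      n = vapply(groups, length, 0L), stringsAsFactors = FALSE))
  }
  # list of lists with mean / sem or sd / n
  as_group_stats(do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$group %||% NA_character_, mean = g$mean,
               sem = g$sem %||% NA_real_, sd = g$sd %||% (g$sem * sqrt(g$n)),
               n = g$n, stringsAsFactors = FALSE)
  })))
}

#' One-way fixed-effects ANOVA
#'
#' Classical F test across k groups, computable either from raw
#' per-replicate values or from summary statistics (mean, SEM, n) as
#' published tables report them; the two modes agree to machine precision
#' because the sums of squares depend on the data only through
#' (mean, SD, n) per group.
#'
#' @param groups Either a named list of numeric vectors (raw mode) or a
#'   data.frame with columns `group`, `mean`, `sem` (or `sd`), `n`
#'   (summary mode). Every group needs `n >= 2`.
#' @return An `anova_result`: list with `F`, `df` (numerator, denominator),
#'   `p`, `ms_within`, `groups` (the canonical per-group stats) and a
#'   `degenerate` flag (zero within-group variance with unequal means gives
#'   `F = Inf`, `p = 0`).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  g <- as_group_stats(groups)
  k <- nrow(g)
  if (k < 2L) stop("one_way_anova: need at least 2 groups", call. = FALSE)
  if (any(g$n < 2L)) {
    stop("one_way_anova: every group needs n >= 2 (got n = ",
         paste(g$n, collapse = ", "), ")", call. = FALSE)
  }
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  df1 <- k - 1L
  df2 <- N - k
  degenerate <- FALSE
  if (ssw <= 0) {
    if (ssb > 0) {
      degenerate <- TRUE
      Fv <- Inf; p <- 0
    } else {
      Fv <- 0; p <- 1
    }
  } else {
    Fv <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = Fv, df = c(df1, df2), p = p,
                 ms_within = if (df2 > 0) ssw / df2 else NA_real_,
                 ss_between = ssb, ss_within = ssw,
                 groups = g, degenerate = degenerate),
            class = "anova_result")
}

#' Significance label for a p-value
#'
#' `p < 0.001` gives `***`, `p < 0.01` `**`, `p < 0.05` `*`, otherwise
#' `ns` (strict inequalities; `p = 0.05` is `ns`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("significance_label: p must be in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Student-Newman-Keuls post-hoc comparisons
#'
#' Stepwise studentized-range procedure after a one-way ANOVA: groups are
#' rank-ordered by mean; a pair of means r steps apart is tested against
#' the studentized range distribution with `nmeans = r` and the ANOVA's
#' within-group degrees of freedom, and a comparison enclosed in a
#' non-significant range is never declared significant (each pair's
#' reported p is the maximum over the raw p-values of all ranges enclosing
#' it, which encodes exactly that blocking rule). Unequal group sizes use
#' the harmonic mean n of the two groups compared.
#'
#' @param groups As in [one_way_anova()].
#' @param alpha Significance threshold for the accept/reject pattern.
#' @return A `comparison_result`: list with the ANOVA `F`, overall `p`,
#'   `df`, and `pairwise` data.frame (`group1`, `group2`, `diff`, `q`, `r`,
#'   `p`, `label`, `significant`).
#' @export
snk_posthoc <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  g <- an$groups
  k <- nrow(g)
  df2 <- an$df[2L]
  if (df2 < 1L) stop("snk_posthoc: within-group df < 1", call. = FALSE)
  o <- order(g$mean)
  m <- g$mean[o]; nm <- g$group[o]; nn <- g$n[o]
  msw <- an$ms_within
  # raw studentized-range p per ordered pair (i < j), r = j - i + 1
  p_raw <- matrix(NA_real_, k, k)
  q_stat <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      nh <- 2 / (1 / nn[i] + 1 / nn[j])
      se <- sqrt(msw / nh)
      q <- if (se > 0) (m[j] - m[i]) / se else if (m[j] > m[i]) Inf else 0
      q_stat[i, j] <- q
      p_raw[i, j] <- if (is.infinite(q)) 0 else
        stats::ptukey(q, nmeans = j - i + 1L, df = df2, lower.tail = FALSE)
    }
  }
  # blocking: p_adj(i,j) = max over enclosing ranges, filled widest-first
  p_adj <- p_raw
  if (k >= 3L) {
    for (r in seq(k - 1L, 2L)) {
      for (i in seq_len(k - r + 1L)) {
        j <- i + r - 1L
        encl <- c(if (i > 1L) p_adj[i - 1L, j], if (j < k) p_adj[i, j + 1L])
        if (length(encl)) p_adj[i, j] <- max(p_adj[i, j], encl)
      }
    }
  }
  pairs <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    do.call(rbind, lapply((i + 1L):k, function(j) {
      data.frame(group1 = nm[i], group2 = nm[j], diff = m[j] - m[i],
                 q = q_stat[i, j], r = j - i + 1L, p = p_adj[i, j],
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs$label <- significance_label(pairs$p)
  pairs$significant <- pairs$p < alpha
  structure(list(F = an$F, p = an$p, df = an$df, ms_within = msw,
                 pairwise = pairs, alpha = alpha, anova = an),
            class = "comparison_result")
}

#' Compare one profile metric across conditions
#'
#' Runs the one-way ANOVA + SNK pipeline on the per-replicate values of one
#' metric (`population`, `peak` or `tau`) for one event class, taken from
#' [summarize_condition()] outputs.
#'
#' @param summaries List of `condition_summary` objects.
#' @param metric `"population"`, `"peak"` or `"tau"`.
#' @param class_label Event class (`"translocation"`, `"intercalation"`,
#'   `"bumping"`).
#' @param alpha Significance threshold.
#' @return A `comparison_result`, or `NULL` when fewer than two conditions
#'   carry the class.
#' @export
compare_conditions <- function(summaries, metric = c("population", "peak", "tau"),
                               class_label = "translocation", alpha = 0.05) {
  metric <- match.arg(metric)
  col <- switch(metric, population = "population_pct", peak = "peak_pA",
                tau = "tau_ms")
  groups <- list()
  for (s in summaries) {
    stopifnot(inherits(s, "condition_summary"))
    v <- s$per_replicate[s$per_replicate$class == class_label, col]
    v <- v[is.finite(v)]
    if (length(v) >= 2L) groups[[s$condition]] <- v
  }
  if (length(groups) < 2L) return(NULL)
  res <- snk_posthoc(groups, alpha = alpha)
  res$metric <- metric
  res$class_label <- class_label
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df[1L], x$df[2L], x$F, x$p,
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> ANOVA F(%d, %d) = %.4g, p = %.4g; SNK at alpha = %g\n",
              x$df[1L], x$df[2L], x$F, x$p, x$alpha))
  print.data.frame(x$pairwise, digits = 4)
  invisible(x)
}
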