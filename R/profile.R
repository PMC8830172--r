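# Population profiles: blockade-current histograms, Gaussian mixture fits,
# class assignment, exponential dwell-time fits, replicate pooling.

#' Histogram of blockade amplitudes
#'
#' @param events An `event_table` (or data.frame with `blockade_pA`).
#' @param bin_width Bin width in pA (> 0), default 2.
#' @return List of class `blockade_histogram` with `breaks`, `mids`,
#'   `counts`, `bin_width`; `sum(counts)` equals the number of events.
#' @export
build_blockade_histogram <- function(events, bin_width = 2) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("build_blockade_histogram: bin_width must be > 0", call. = FALSE)
  }
  a <- events$blockade_pA
  if (!length(a)) stop("build_blockade_histogram: no events", call. = FALSE)
  lo <- floor(min(a) / bin_width) * bin_width
  hi <- ceiling(max(a) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(a, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 bin_width = bin_width),
            class = "blockade_histogram")
}

label_components <- function(peaks) {
  k <- length(peaks)
  labs <- character(k)
  o <- order(peaks)  # most negative first
  if (k == 1L) {
    # a lone peak is identified by its absolute depth: deep blockades are
    # translocations, shallow ones bumping, intermediate intercalation
    labs[1L] <- if (peaks <= -60) "translocation" else if (peaks >= -40) "bumping" else "intercalation"
  } else if (k == 2L) {
    labs[o] <- c("translocation", "bumping")
  } else {
    labs[o] <- c("translocation", "intercalation", "bumping")
  }
  labs
}

#' Fit a Gaussian population model to blockade amplitudes
#'
#' Fits 1-3 Gaussian components to the blockade-current distribution,
#' either by mixture maximum likelihood on the raw amplitudes (default;
#' `mclust` engine, unequal variances, BIC model selection for `k = "auto"`)
#' or by least squares of a sum of Gaussians to the binned histogram
#' (`method = "histogram_ls"`), mirroring how published profiles are fitted.
#' Components are labelled by peak depth (see [assign_event_classes()]) and
#' each component's population is the percentage of *all* detected events
#' falling inside its +/-2.5 sigma window, so populations need not sum
#' to 100; the remainder is `unclassified_pct`.
#'
#' Events shorter than the recording filter's rise time carry large
#' amplitude uncertainty (the filter attenuates them into the noise); when
#' the table has a per-event `amp_se_pA` column (as [detect_events()]
#' produces), the mixture is fitted on the well-measured events
#' (`amp_se_pA <= fit_se_max`) so that short-event noise cannot masquerade
#' as an extra broad component, while populations still count every event
#' through the measurement-error-aware assignment.
#'
#' @param events An `event_table`; at least 50 events are required.
#' @param k Number of components (1-3) or `"auto"` (BIC over 1:3).
#' @param method `"mle"` or `"histogram_ls"`.
#' @param bin_width Histogram bin width in pA (histogram route and output).
#' @param fit_se_max Maximum per-event amplitude SE (pA) for an event to
#'   enter the mixture fit (ignored when the column is absent or too few
#'   events qualify).
#' @return A `population_fit`: `components` data.frame (`class`, `peak_pA`,
#'   `sigma_pA`, `weight`, `population_pct`, `n_events`),
#'   `unclassified_pct`, `k`, `method`, `goodness`, `n_total`.
#' @export
fit_population_model <- function(events, k = "auto",
                                 method = c("mle", "histogram_ls"),
                                 bin_width = 2, fit_se_max = 3) {
  method <- match.arg(method)
  a <- events$blockade_pA
  n <- length(a)
  if (n < 50L) {
    stop("fit_population_model: refused: ", n, " events (< 50); collect more ",
         "events or pool replicates before fitting", call. = FALSE)
  }
  auto <- identical(k, "auto")
  if (!auto) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > 3L) {
      stop("fit_population_model: k must be 1, 2, 3 or \"auto\"", call. = FALSE)
    }
  }
  G <- if (auto) 1:3 else k

  a_fit <- a
  if (!is.null(events$amp_se_pA)) {
    se <- events$amp_se_pA
    well <- is.finite(se) & se <= fit_se_max & se <= 0.25 * abs(a)
    if (sum(well) >= 50L) a_fit <- a[well]
  }
  mc <- mclust::Mclust(a_fit, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(mc)) {
    stop("fit_population_model: mixture fit did not converge (n = ", n, ")",
         call. = FALSE)
  }
  mu <- as.numeric(mc$parameters$mean)
  sg <- sqrt(as.numeric(mc$parameters$variance$sigmasq))
  if (length(sg) == 1L) sg <- rep(sg, length(mu))
  pro <- as.numeric(mc$parameters$pro)
  goodness <- list(loglik = mc$loglik, bic = mc$bic, k_selected = mc$G,
                   n_fit = length(a_fit))

  if (method == "histogram_ls") {
    hfit <- fit_histogram_gaussians(a, length(mu), bin_width,
                                    start = list(mu = mu, sg = sg, pro = pro))
    mu <- hfit$mu; sg <- hfit$sg; pro <- hfit$pro
    goodness$rss <- hfit$rss
    goodness$converged <- hfit$converged
  }

  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; pro <- pro[o]
  if (length(mu) > 1L && any(diff(mu) < 1e-9)) {
    stop("fit_population_model: degenerate fit: two components share a peak",
         call. = FALSE)
  }
  comp <- data.frame(class = label_components(mu), peak_pA = mu,
                     sigma_pA = sg, weight = pro,
                     population_pct = NA_real_, n_events = NA_integer_,
                     stringsAsFactors = FALSE)
  fit <- structure(list(components = comp, unclassified_pct = NA_real_,
                        k = length(mu), method = method,
                        bin_width = bin_width, goodness = goodness,
                        n_total = n),
                   class = "population_fit")
  # populations from the class-window assignment
  assigned <- assign_event_classes(events, fit)
  tab <- table(factor(assigned$class,
                      levels = c(comp$class, "unclassified")))
  fit$components$n_events <- as.integer(tab[comp$class])
  fit$components$population_pct <- 100 * as.numeric(tab[comp$class]) / n
  fit$unclassified_pct <- 100 * as.numeric(tab[["unclassified"]]) / n
  fit
}

# least-squares sum-of-Gaussians fit to the binned amplitude histogram
fit_histogram_gaussians <- function(a, k, bin_width, start) {
  h <- build_blockade_histogram(data.frame(blockade_pA = a), bin_width)
  x <- h$mids; y <- h$counts
  n <- length(a)
  amp0 <- n * bin_width * start$pro / (start$sg * sqrt(2 * pi))
  par0 <- c(amp0, start$mu, log(start$sg))
  model <- function(p) {
    amp <- p[1:k]; mu <- p[(k + 1):(2 * k)]; sg <- exp(p[(2 * k + 1):(3 * k)])
    rowSums(vapply(seq_len(k), function(j) {
      amp[j] * exp(-(x - mu[j])^2 / (2 * sg[j]^2))
    }, numeric(length(x))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = function(p) y - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("fit_population_model: histogram least-squares fit failed to ",
         "converge; residual trail unavailable", call. = FALSE)
  }
  p <- fit$par
  amp <- p[1:k]; mu <- p[(k + 1):(2 * k)]; sg <- exp(p[(2 * k + 1):(3 * k)])
  area <- amp * sg * sqrt(2 * pi) / bin_width
  list(mu = mu, sg = sg, pro = area / sum(area),
       rss = sum(fit$fvec^2), converged = fit$info %in% 1:3)
}

#' Assign events to fitted populations
#'
#' Components are labelled by peak depth: the most negative peak is
#' translocation, the least negative bumping, and a middle component (three
#' peaks) intercalation. An event joins the component whose peak lies within
#' 2.5 sigmas of its amplitude; among several candidates the smallest |z|
#' wins, with exact ties going to the deeper component. Events outside
#' every window are `"unclassified"`. When the table carries per-event
#' amplitude SEs (`amp_se_pA`), the z denominator is
#' `sqrt(sigma_j^2 + amp_se^2)`, so a short, noisily measured event is
#' judged against its own measurement uncertainty rather than the
#' component width alone.
#'
#' @param events An `event_table`.
#' @param fit A `population_fit`.
#' @param z_max Class-window half-width in component sigmas (default 2.5).
#' @return The `event_table` with its `class` column filled in.
#' @export
assign_event_classes <- function(events, fit, z_max = 2.5) {
  stopifnot(inherits(fit, "population_fit"))
  comp <- fit$components
  if (nrow(comp) > 1L && any(diff(sort(comp$peak_pA)) < 1e-9)) {
    stop("assign_event_classes: degenerate fit: identical component peaks",
         call. = FALSE)
  }
  a <- events$blockade_pA
  se2 <- if (!is.null(events$amp_se_pA)) {
    ifelse(is.finite(events$amp_se_pA), events$amp_se_pA^2, 0)
  } else rep(0, length(a))
  z <- vapply(seq_len(nrow(comp)), function(j) {
    abs(a - comp$peak_pA[j]) / sqrt(comp$sigma_pA[j]^2 + se2)
  }, numeric(length(a)))
  z <- matrix(z, nrow = length(a))
  lab <- rep("unclassified", length(a))
  if (length(a)) {
    # order candidate columns by depth so that which.min's first-match
    # tie-break lands on the deeper component
    depth_order <- order(comp$peak_pA)
    zo <- z[, depth_order, drop = FALSE]
    best <- apply(zo, 1L, which.min)
    bestz <- zo[cbind(seq_along(a), best)]
    ok <- bestz <= z_max
    lab[ok] <- comp$class[depth_order][best[ok]]
  }
  events$class <- lab
  events
}

#' Fit a single-exponential dwell-time distribution
#'
#' The characteristic time of a blockade-event class. Default is maximum
#' likelihood (`tau = mean(dwell) - truncation`, exact for exponential data,
#' with an optional left-truncation correction for undetectable short
#' events); `"histogram_ls"` fits `A * exp(-t / tau)` to the binned dwell
#' histogram by least squares, mirroring published time profiles.
#'
#' @param dwells Numeric vector of dwell times (ms), or an `event_table`
#'   plus `class_label` to select one class.
#' @param method `"mle"` or `"histogram_ls"`.
#' @param truncation_ms Detection limit below which events are unobservable;
#'   dwells below it are dropped and the memoryless correction applied.
#' @param class_label Optional class to filter when `dwells` is a table.
#' @param min_events Minimum number of events (default 20).
#' @return A `dwell_fit`: list with `class`, `tau_ms`, `n_events`, `method`,
#'   `truncation_ms`, `goodness`.
#' @export
fit_dwell_time <- function(dwells, method = c("mle", "histogram_ls"),
                           truncation_ms = 0, class_label = NA_character_,
                           min_events = 20L) {
  method <- match.arg(method)
  if (is.data.frame(dwells)) {
    if (!is.na(class_label)) dwells <- dwells[dwells$class == class_label, ]
    dwells <- dwells$dwell_ms
  }
  x <- as.numeric(dwells)
  x <- x[is.finite(x) & x > 0]
  c0 <- max(0, truncation_ms)
  if (is.finite(c0) && c0 > 0) x <- x[x >= c0]
  n <- length(x)
  if (n < min_events) {
    stop("fit_dwell_time: refused: ", n, " usable events (< ", min_events,
         ")", if (!is.na(class_label)) paste0(" for class ", class_label),
         call. = FALSE)
  }
  if (method == "mle") {
    tau <- mean(x) - c0
    goodness <- list(loglik = -n * log(tau) - sum(x - c0) / tau,
                     se_tau = tau / sqrt(n))
  } else {
    nb <- max(10L, min(40L, floor(n / 15)))
    h <- graphics::hist(x, breaks = nb, plot = FALSE)
    xm <- h$mids; y <- h$counts
    keep <- y > 0 | xm < stats::quantile(x, 0.9)
    xm <- xm[keep]; y <- y[keep]
    tau0 <- mean(x) - c0
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(xm - c0) / tau),
                        start = list(A = max(y), tau = tau0),
                        lower = c(0, 1e-9),
                        control = stats::nls.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      stop("fit_dwell_time: histogram least-squares fit did not converge",
           call. = FALSE)
    }
    tau <- stats::coef(fit)[["tau"]]
    goodness <- list(rss = sum(stats::residuals(fit)^2))
  }
  structure(list(class = class_label, tau_ms = as.numeric(tau),
                 n_events = n, method = method, truncation_ms = c0,
                 goodness = goodness),
            class = "dwell_fit")
}

#' Full per-replicate profile: mixture fit, class labels, dwell fits
#'
#' @param events An `event_table` for one replicate.
#' @param k,method,bin_width Passed to [fit_population_model()].
#' @param dwell_method Passed to [fit_dwell_time()].
#' @param detection Optional list with `noise_sd`, `threshold_sigma` and
#'   `bandwidth`: when given, each class's dwell fit is left-truncated at
#'   its analytic detection limit (see [detection_limit_ms()]).
#' @param min_dwell_events Classes with fewer assigned events get no dwell
#'   fit (default 20).
#' @return A `condition_profile`: `fit` (the `population_fit`), `events`
#'   (labelled), `dwell` (named list of `dwell_fit`s), `condition`,
#'   `n_events`.
#' @export
condition_profile <- function(events, k = "auto", method = "mle",
                              bin_width = 2, dwell_method = "mle",
                              detection = NULL, min_dwell_events = 20L) {
  fit <- fit_population_model(events, k = k, method = method,
                              bin_width = bin_width)
  labelled <- assign_event_classes(events, fit)
  dwell <- list()
  for (cl in fit$components$class) {
    d <- labelled$dwell_ms[labelled$class == cl]
    if (length(d) < min_dwell_events) next
    trunc_ms <- 0
    if (!is.null(detection)) {
      pk <- fit$components$peak_pA[fit$components$class == cl]
      trunc_ms <- detection_limit_ms(pk, detection$noise_sd,
                                     detection$threshold_sigma %||% 5,
                                     detection$bandwidth %||% 1e4)
      if (!is.finite(trunc_ms)) trunc_ms <- 0
    }
    dwell[[cl]] <- tryCatch(
      fit_dwell_time(d, method = dwell_method, truncation_ms = trunc_ms,
                     class_label = cl, min_events = min_dwell_events),
      error = function(e) NULL)
  }
  md <- attr(events, "meta")
  structure(list(fit = fit, events = labelled,
                 dwell = Filter(Negate(is.null), dwell),
                 condition = md$condition %||% NA_character_,
                 replicate = md$replicate %||% 1L,
                 n_events = nrow(events)),
            class = "condition_profile")
}

#' Pool replicate event tables
#'
#' Replicate experiments of one condition are concatenated for display
#' histograms; per-replicate profiles are kept separate for SEM reporting.
#'
#' @param tables List of `event_table`s with matching condition metadata.
#' @return List with `pooled` (one `event_table`, `replicate` column added)
#'   and `tables` (the input list).
#' @export
pool_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  conds <- vapply(tables, function(t) {
    as.character(attr(t, "meta")$condition %||% NA_character_)
  }, "")
  if (length(unique(conds[!is.na(conds)])) > 1L) {
    stop("pool_replicates: mismatched condition metadata: ",
         paste(unique(conds), collapse = " vs "), call. = FALSE)
  }
  dfs <- lapply(seq_along(tables), function(i) {
    d <- as.data.frame(tables[[i]])
    d$replicate <- attr(tables[[i]], "meta")$replicate %||% i
    d
  })
  pooled <- do.call(rbind, dfs)
  pooled <- new_event_table(pooled, condition = conds[1L],
                            replicate = NA_integer_, source = "pooled")
  list(pooled = pooled, tables = tables)
}

#' Summarize a condition across replicates
#'
#' The published-table record: per event class, mean +/- SEM across
#' replicates of the population percentage, the fitted peak current and the
#' characteristic dwell time. SEM columns are `NA` with a single replicate;
#' classes absent from some replicates are summarized over the replicates
#' that have them and flagged (`n_reps` < `n_replicates`).
#'
#' @param profiles List of `condition_profile`s (one per replicate).
#' @param condition Condition name; defaults to the first profile's.
#' @param construct Optional construct identity (`full_length`, `N_term`,
#'   `C_term`, `delta_NAC`) carried into [call_binding()].
#' @return A `condition_summary`: data.frame `classes` with columns `class`,
#'   `population_mean/sem`, `peak_mean/sem`, `tau_mean/sem`, `n_reps`; plus
#'   `condition`, `n_replicates`, and the per-replicate values in
#'   `$per_replicate`.
#' @export
summarize_condition <- function(profiles, condition = NULL,
                                construct = NA_character_) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  for (p in profiles) stopifnot(inherits(p, "condition_profile"))
  if (is.null(condition)) condition <- profiles[[1L]]$condition
  n_rep <- length(profiles)
  per <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    comp <- p$fit$components
    tau <- vapply(comp$class, function(cl) {
      if (!is.null(p$dwell[[cl]])) p$dwell[[cl]]$tau_ms else NA_real_
    }, 0)
    data.frame(replicate = i, class = comp$class,
               population_pct = comp$population_pct,
               peak_pA = comp$peak_pA, tau_ms = tau,
               stringsAsFactors = FALSE)
  }))
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  mn <- function(v) { v <- v[is.finite(v)]; if (length(v)) mean(v) else NA_real_ }
  classes <- unique(per$class)
  rows <- lapply(classes, function(cl) {
    d <- per[per$class == cl, ]
    data.frame(class = cl,
               population_mean = mn(d$population_pct),
               population_sem = if (n_rep >= 2L) sem(d$population_pct) else NA_real_,
               peak_mean = mn(d$peak_pA),
               peak_sem = if (n_rep >= 2L) sem(d$peak_pA) else NA_real_,
               tau_mean = mn(d$tau_ms),
               tau_sem = if (n_rep >= 2L) sem(d$tau_ms) else NA_real_,
               n_reps = nrow(d), stringsAsFactors = FALSE)
  })
  structure(list(condition = condition, classes = do.call(rbind, rows),
                 n_replicates = n_rep, per_replicate = per,
                 construct = construct),
            class = "condition_summary")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> k = %d (%s), %d events, unclassified %.1f%%\n",
              x$k, x$method, x$n_total, x$unclassified_pct))
  print.data.frame(x$components, digits = 4)
  invisible(x)
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> %s: tau = %.4g ms (n = %d, %s%s)\n",
              x$class %||% "?", x$tau_ms, x$n_events, x$method,
              if (x$truncation_ms > 0)
                sprintf(", truncated at %.3g ms", x$truncation_ms) else ""))
  invisible(x)
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> '%s' (%d replicates)\n",
              x$condition, x$n_replicates))
  print.data.frame(x$classes, digits = 4)
  invisible(x)
}
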