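# Ground-truthed synthetic single-channel current generation.

#' Simulate a ground-truth blockade-event stream
#'
#' Draws event arrivals as a Poisson process of rate `event_rate` with an
#' enforced dead time between events (so events never overlap), assigns each
#' event a class by the model's mixture weights, an exponential dwell time
#' and a Gaussian blockade amplitude.
#'
#' @param model A [condition_model()].
#' @param seed Optional integer seed; defaults to `model$seed`.
#' @return A data.frame of class `ground_truth_events` with columns
#'   `class`, `start_s`, `dwell_ms`, `amplitude_pA`, sorted by start time.
#'   Attribute `empty_reason` is set when no event fits in the recording.
#' @examples
#' ev <- simulate_events(preset_condition("alpha_syn", duration = 2, seed = 1))
#' table(ev$class)
#' @export
simulate_events <- function(model, seed = NULL) {
  stopifnot(inherits(model, "condition_model"))
  if (is.null(seed)) seed <- model$seed
  set.seed(as.integer(seed))
  out <- data.frame(class = character(0), start_s = numeric(0),
                    dwell_ms = numeric(0), amplitude_pA = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth_events", "data.frame")
  if (model$event_rate <= 0) return(out)

  dead_s <- model$dead_time_ms / 1000
  dur <- model$duration
  # draw in blocks until the recording is filled
  starts <- numeric(0); dwells <- numeric(0); labels <- integer(0)
  t_cursor <- 0
  w <- vapply(model$classes, `[[`, 0, "weight")
  scales_ms <- vapply(model$classes, `[[`, 0, "dwell_scale")
  repeat {
    n_blk <- max(64L, ceiling(model$event_rate * (dur - t_cursor) * 1.5))
    gaps <- stats::rexp(n_blk, rate = model$event_rate)
    cls <- sample.int(length(w), n_blk, replace = TRUE, prob = w)
    dw <- stats::rexp(n_blk, rate = 1) * scales_ms[cls] / 1000  # seconds
    st <- numeric(n_blk)
    tc <- t_cursor
    for (i in seq_len(n_blk)) {
      st[i] <- tc + gaps[i]
      tc <- st[i] + dw[i] + dead_s
    }
    keep <- (st + dw) <= dur
    starts <- c(starts, st[keep]); dwells <- c(dwells, dw[keep])
    labels <- c(labels, cls[keep])
    if (!all(keep) || tc > dur) break
    t_cursor <- tc
  }
  n <- length(starts)
  if (n == 0L) {
    attr(out, "empty_reason") <- "duration too short to host any event at the requested rate"
    warning("simulate_events: no event fits in ", dur,
            " s at rate ", model$event_rate, "/s", call. = FALSE)
    return(out)
  }
  mu <- vapply(model$classes, `[[`, 0, "mean_blockade")
  sd <- vapply(model$classes, `[[`, 0, "sd_blockade")
  amp <- stats::rnorm(n, mean = mu[labels], sd = sd[labels])
  # amplitudes are negative deflections by construction; resample strays
  bad <- which(amp >= 0)
  while (length(bad)) {
    amp[bad] <- stats::rnorm(length(bad), mean = mu[labels[bad]],
                             sd = sd[labels[bad]])
    bad <- bad[amp[bad] >= 0]
  }
  out <- data.frame(
    class = vapply(model$classes, `[[`, "", "label")[labels],
    start_s = starts, dwell_ms = dwells * 1000, amplitude_pA = amp,
    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth_events", "data.frame")
  out
}

# Gaussian low-pass kernel with -3 dB point at `bandwidth` Hz:
# |H(f)|^2 = 1/2 at f = bandwidth  =>  sigma_t = sqrt(ln 2) / (2 pi bandwidth).
filter_sigma_s <- function(bandwidth) sqrt(log(2)) / (2 * pi * bandwidth)

gaussian_kernel <- function(sampling_rate, bandwidth) {
  sigma <- filter_sigma_s(bandwidth) * sampling_rate  # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

# centred moving convolution with edge replication
convolve_same <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  out <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + length(x))])
}

#' Render a simulated event stream into a sampled current trace
#'
#' Builds an open-pore baseline with white Gaussian noise, superimposes each
#' event as a rectangular deflection (with fractional-sample edge weighting),
#' then low-pass filters the whole trace with a Gaussian kernel whose -3 dB
#' point is the model's `filter_bandwidth`, emulating the recording filter.
#'
#' @param events A `ground_truth_events` data.frame (see [simulate_events()]).
#' @param model The [condition_model()] used to generate the events.
#' @param seed Optional noise seed; defaults to `model$seed + 1`.
#' @return A `current_trace` object: list with `samples` (pA),
#'   `sampling_rate`, and `metadata` (condition, voltage, baseline,
#'   filter bandwidth, seed).
#' @export
render_trace <- function(events, model, seed = NULL) {
  stopifnot(inherits(model, "condition_model"), is.data.frame(events))
  if (is.null(seed)) seed <- model$seed + 1L
  n <- floor(model$duration * model$sampling_rate)
  if (nrow(events)) {
    if (any(events$start_s < 0 | (events$start_s + events$dwell_ms / 1000) > model$duration)) {
      stop("render_trace: events outside [0, duration]", call. = FALSE)
    }
    ends <- events$start_s + events$dwell_ms / 1000
    o <- order(events$start_s)
    if (any(events$start_s[o][-1L] < ends[o][-length(o)])) {
      stop("render_trace: overlapping events -- simulator contract violated",
           call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  x <- if (model$noise_sd > 0) {
    model$baseline_current + stats::rnorm(n, sd = model$noise_sd)
  } else {
    rep(model$baseline_current, n)
  }
  fs <- model$sampling_rate
  for (i in seq_len(nrow(events))) {
    t0 <- events$start_s[i] * fs          # in samples (0-based continuous)
    t1 <- t0 + events$dwell_ms[i] * fs / 1000
    a <- events$amplitude_pA[i]
    i0 <- floor(t0); i1 <- floor(t1)
    if (i0 == i1) {                       # event within one sample interval
      j <- min(i0 + 1L, n)
      x[j] <- x[j] + a * (t1 - t0)
    } else {
      if (min(i1, n) >= i0 + 2L) {         # fully covered samples
        full <- (i0 + 2L):min(i1, n)
        x[full] <- x[full] + a
      }
      x[i0 + 1L] <- x[i0 + 1L] + a * (i0 + 1 - t0)
      if (i1 + 1L <= n) x[i1 + 1L] <- x[i1 + 1L] + a * (t1 - i1)
    }
  }
  x <- convolve_same(x, gaussian_kernel(fs, model$filter_bandwidth))
  structure(
    list(samples = x, sampling_rate = fs,
         metadata = list(condition = model$name, voltage = model$voltage,
                         baseline_current = model$baseline_current,
                         filter_bandwidth = model$filter_bandwidth,
                         duration = model$duration, seed = as.integer(seed))),
    class = "current_trace"
  )
}

#' One-call trace simulation
#'
#' Convenience wrapper: [simulate_events()] then [render_trace()], with the
#' noise stream seeded independently of the event stream via [derive_seed()].
#'
#' @inheritParams render_trace
#' @param seed Master seed for this trace; defaults to `model$seed`.
#' @return A list with `trace` (a `current_trace`) and `truth`
#'   (the `ground_truth_events`).
#' @export
simulate_trace <- function(model, seed = NULL) {
  if (is.null(seed)) seed <- model$seed
  ev <- simulate_events(model, seed = derive_seed(seed, 1L))
  tr <- render_trace(ev, model, seed = derive_seed(seed, 2L))
  list(trace = tr, truth = ev)
}

#' Convert ground-truth events to an analysis event table
#'
#' Bypasses trace rendering and detection: the generative dwell and
#' amplitude of each event become the measured `dwell_ms` / `blockade_pA`.
#' Useful for testing downstream profiling and inference in isolation.
#'
#' @param events A `ground_truth_events` data.frame.
#' @param condition,replicate Metadata attached to the table.
#' @return An `event_table` (see [detect_events()] for the schema).
#' @export
as_event_table <- function(events, condition = "simulated", replicate = 1L) {
  stopifnot(is.data.frame(events))
  out <- data.frame(
    start_s = events$start_s,
    dwell_ms = events$dwell_ms,
    blockade_pA = events$amplitude_pA,
    amp_se_pA = rep(0, nrow(events)),
    class = rep("unclassified", nrow(events)),
    low_confidence = rep(FALSE, nrow(events)),
    stringsAsFactors = FALSE)
  new_event_table(out, condition = condition, replicate = replicate,
                  source = "ground_truth")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> '%s': %d samples @ %.3g Hz (%.3g s), %+.4g mV, filter %.3g Hz\n",
              x$metadata$condition, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$metadata$voltage,
              x$metadata$filter_bandwidth))
  invisible(x)
}

#' Plot a current trace segment
#'
#' @param x A `current_trace`.
#' @param from,to Time window in seconds (defaults to the first 0.5 s).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.current_trace <- function(x, from = 0, to = min(0.5, length(x$samples) / x$sampling_rate), ...) {
  i <- seq.int(max(1L, floor(from * x$sampling_rate) + 1L),
               min(length(x$samples), ceiling(to * x$sampling_rate)))
  graphics::plot((i - 1) / x$sampling_rate, x$samples[i], type = "l",
                 xlab = "time (s)", ylab = "current (pA)", ...)
  invisible(x)
}
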