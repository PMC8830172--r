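# Shared fixtures, all generated in code.

# alpha-synuclein-alone condition at reduced duration for unit tests
fast_asyn <- function(seed = 1L, duration = 20, ...) {
  preset_condition("alpha_syn", seed = seed, duration = duration, ...)
}

# single-class model for controlled generative checks
one_class_model <- function(label = "translocation", mean_blockade = -85,
                            sd_blockade = 5, dwell_scale = 0.5, ...) {
  condition_model(list(class_model(label, 1, mean_blockade, sd_blockade,
                                   dwell_scale)), ...)
}

# event table straight from amplitude/dwell draws (no trace)
draw_events <- function(n, mean_pA, sd_pA, dwell_ms = 0.5, seed = 1L,
                        condition = "synthetic") {
  set.seed(seed)
  expand <- function(v) if (length(v) == 1L) rep(v, sum(n)) else rep(v, n)
  df <- data.frame(
    start_s = seq_len(sum(n)) * 0.01,
    dwell_ms = stats::rexp(sum(n), 1) * expand(dwell_ms),
    blockade_pA = stats::rnorm(sum(n), expand(mean_pA), expand(sd_pA)),
    amp_se_pA = 0, class = "unclassified", low_confidence = FALSE,
    stringsAsFactors = FALSE)
  poreblock:::new_event_table(df, condition = condition, replicate = 1L)
}

# hand-built current trace (bypasses the simulator; no filter metadata)
manual_trace <- function(samples, fs = 1e4, condition = "manual",
                         bandwidth = NA_real_) {
  structure(list(samples = as.numeric(samples), sampling_rate = fs,
                 metadata = list(condition = condition, voltage = 100,
                                 baseline_current = NA_real_,
                                 filter_bandwidth = bandwidth,
                                 duration = length(samples) / fs,
                                 seed = NA_integer_)),
            class = "current_trace")
}

# minimal condition_summary built from per-replicate metric values
fake_summary <- function(condition, per_replicate, construct = NA_character_) {
  classes <- do.call(rbind, lapply(split(per_replicate, per_replicate$class),
                                   function(d) {
    data.frame(class = d$class[1L],
               population_mean = mean(d$population_pct),
               population_sem = stats::sd(d$population_pct) / sqrt(nrow(d)),
               peak_mean = mean(d$peak_pA),
               peak_sem = stats::sd(d$peak_pA) / sqrt(nrow(d)),
               tau_mean = mean(d$tau_ms),
               tau_sem = stats::sd(d$tau_ms) / sqrt(nrow(d)),
               n_reps = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  structure(list(condition = condition, classes = classes,
                 n_replicates = length(unique(per_replicate$replicate)),
                 per_replicate = per_replicate, construct = construct),
            class = "condition_summary")
}

rep_df <- function(class, population, peak = -85, tau = 0.5) {
  data.frame(replicate = seq_along(population), class = class,
             population_pct = population, peak_pA = peak, tau_ms = tau,
             stringsAsFactors = FALSE)
}
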