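# Replicate-experiment conveniences: one condition in triplicate, and the
# four-construct domain panel workflow.

#' Run one condition as a replicated experiment
#'
#' Simulates `n_replicates` independent recordings of one condition (each
#' replicate seeded via [derive_seed()]), runs detection and profiling per
#' replicate, and summarizes across replicates. `mode = "events"` skips
#' trace rendering and detection, profiling the generative event stream
#' directly.
#'
#' @param model A [condition_model()].
#' @param n_replicates Number of replicates (default 3, the usual
#'   triplicate design).
#' @param master_seed Master seed; defaults to `model$seed`.
#' @param mode `"traces"` (full pipeline) or `"events"` (generative event
#'   tables).
#' @param params [detection_params()] for the trace route.
#' @param k Components passed to [condition_profile()].
#' @return List with `profiles` (per replicate), `summary` (a
#'   `condition_summary`), and `truths` (per-replicate ground truth).
#' @export
replicate_experiment <- function(model, n_replicates = 3,
                                 master_seed = model$seed,
                                 mode = c("traces", "events"),
                                 params = detection_params(), k = "auto") {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "condition_model"), n_replicates >= 1)
  profiles <- vector("list", n_replicates)
  truths <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed <- derive_seed(master_seed, r)
    if (mode == "traces") {
      sim <- simulate_trace(model, seed = seed)
      bl <- estimate_baseline(sim$trace)
      tab <- detect_events(sim$trace, params, baseline = bl)
      attr(tab, "meta")$condition <- model$name
      attr(tab, "meta")$replicate <- r
      det <- list(noise_sd = bl$noise_sd,
                  threshold_sigma = params$threshold_sigma,
                  bandwidth = model$filter_bandwidth)
      truths[[r]] <- sim$truth
    } else {
      ev <- simulate_events(model, seed = seed)
      tab <- as_event_table(ev, condition = model$name, replicate = r)
      det <- NULL
      truths[[r]] <- ev
    }
    profiles[[r]] <- condition_profile(tab, k = k, detection = det)
  }
  list(profiles = profiles,
       summary = summarize_condition(profiles, condition = model$name),
       truths = truths)
}

#' Run a control/drug domain panel and call the binding mode
#'
#' For each construct, runs the control and drug conditions as replicated
#' experiments, calls binding (the directional folding rule for the
#' full-length protein, the any-change rule for domain fragments), and
#' infers the knot/loop mode when both termini are present.
#'
#' @param pairs Named list keyed by construct (`full_length`, `N_term`,
#'   `C_term`, `delta_NAC`); each element a list with `control` and `drug`,
#'   either [condition_model()]s or [preset_condition()] names.
#' @param master_seed Integer master seed; control and drug of each
#'   construct get distinct derived streams.
#' @param n_replicates Replicates per condition (default 3).
#' @param mode `"events"` (default, generative event tables) or `"traces"`.
#' @param ... Acquisition overrides for preset lookups (e.g. `duration`).
#' @return List with `calls` (per construct `binding_call`), `mode_call`
#'   (a `binding_mode_call` or `NULL`), and `summaries`.
#' @export
run_domain_panel <- function(pairs, master_seed = 1L, n_replicates = 3,
                             mode = c("events", "traces"), ...) {
  mode <- match.arg(mode)
  stopifnot(is.list(pairs), length(pairs) >= 1L,
            !is.null(names(pairs)), all(names(pairs) %in% CONSTRUCTS))
  calls <- list()
  summaries <- list()
  for (ci in seq_along(pairs)) {
    construct <- names(pairs)[ci]
    pr <- pairs[[ci]]
    smy <- list()
    for (ri in 1:2) {
      role <- c("control", "drug")[ri]
      m <- pr[[role]]
      if (is.character(m)) m <- preset_condition(m, ...)
      ex <- replicate_experiment(m, n_replicates = n_replicates,
                                 master_seed = derive_seed(master_seed,
                                                           1000L * ci + ri),
                                 mode = mode)
      ex$summary$construct <- construct
      smy[[role]] <- ex$summary
    }
    summaries[[construct]] <- smy
    rule <- if (construct == "full_length") "folding" else "any-change"
    calls[[construct]] <- call_binding(smy$control, smy$drug, rule = rule,
                                       construct = construct)
  }
  mode_call <- if (all(c("N_term", "C_term") %in% names(calls))) {
    infer_binding_mode(calls)
  }
  list(calls = calls, mode_call = mode_call, summaries = summaries)
}

#' Preset construct pairs for the A1R-ligand panels
#'
#' Convenience lookup assembling the control/drug preset names for the
#' CPA-like panel, the DPCPX-like panel, or a null drug (drug identical to
#' control; only seeds differ).
#'
#' @param drug `"cpa"`, `"dpcpx"` or `"none"`.
#' @return A named list suitable for [run_domain_panel()].
#' @export
panel_presets <- function(drug = c("cpa", "dpcpx", "none")) {
  drug <- match.arg(drug)
  ctrl <- list(full_length = "alpha_syn", N_term = "n_term",
               C_term = "c_term", delta_NAC = "delta_nac")
  suffix <- switch(drug, cpa = "_cpa", dpcpx = "_dpcpx", none = "")
  lapply(ctrl, function(base) {
    list(control = base, drug = paste0(base, suffix))
  })
}
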