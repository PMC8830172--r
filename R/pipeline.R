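# End-to-end orchestration: config-driven runs from simulation (or supplied
# traces) through detection, profiling, statistics and binding calls, with a
# reproducibility manifest.

#' Validate a pipeline configuration
#'
#' @param config A list (parsed YAML) or path to a YAML file. Required
#'   fields: `experiment`, `master_seed`, `replicates`, and `constructs`
#'   (a list of entries with `name`, `control`, `drug`; each condition is a
#'   preset name, an inline model spec with `classes`, or a list of
#'   `trace_files`). Optional: `mode` (`"traces"`, default, or `"events"`),
#'   `acquisition` (parameter overrides applied to every simulated model).
#' @return The validated config list, invisibly on error-free input.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("validate_config: config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  req <- c("experiment", "master_seed", "replicates", "constructs")
  miss <- setdiff(req, names(config))
  if (length(miss)) {
    stop("validate_config: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(config$master_seed)) {
    stop("validate_config: master_seed: must be an integer", call. = FALSE)
  }
  if (!is.numeric(config$replicates) || config$replicates < 1) {
    stop("validate_config: replicates: must be >= 1", call. = FALSE)
  }
  config$mode <- config$mode %||% "traces"
  if (!config$mode %in% c("traces", "events")) {
    stop("validate_config: mode: must be \"traces\" or \"events\"", call. = FALSE)
  }
  if (!is.list(config$constructs) || !length(config$constructs)) {
    stop("validate_config: constructs: need at least one entry", call. = FALSE)
  }
  for (i in seq_along(config$constructs)) {
    cs <- config$constructs[[i]]
    for (f in c("name", "control", "drug")) {
      if (is.null(cs[[f]])) {
        stop("validate_config: constructs[", i, "].", f, ": missing",
             call. = FALSE)
      }
    }
    if (!cs$name %in% CONSTRUCTS) {
      stop("validate_config: constructs[", i, "].name: must be one of ",
           paste(CONSTRUCTS, collapse = ", "), call. = FALSE)
    }
    for (role in c("control", "drug")) {
      cond <- cs[[role]]
      if (is.list(cond) && !is.null(cond$trace_files)) {
        absent <- cond$trace_files[!file.exists(unlist(cond$trace_files))]
        if (length(absent)) {
          stop("validate_config: constructs[", i, "].", role,
               ".trace_files: missing file: ", absent[[1L]], call. = FALSE)
        }
      } else if (is.character(cond)) {
        if (!cond %in% names(PRESET_SPECS)) {
          stop("validate_config: constructs[", i, "].", role,
               ": unknown preset \"", cond, "\"", call. = FALSE)
        }
      } else if (is.list(cond)) {
        if (is.null(cond$classes)) {
          stop("validate_config: constructs[", i, "].", role,
               ".classes: missing", call. = FALSE)
        }
      } else {
        stop("validate_config: constructs[", i, "].", role,
             ": must be a preset name, model spec or trace_files list",
             call. = FALSE)
      }
    }
  }
  config
}

resolve_model <- function(cond, acquisition, name) {
  acq <- acquisition %||% list()
  if (is.character(cond)) {
    do.call(preset_condition, c(list(name = cond), acq))
  } else {
    specs <- lapply(cond$classes, function(s) s)
    args <- c(list(class_specs = specs, name = name), acq)
    for (f in intersect(names(cond), c("event_rate", "duration", "noise_sd",
                                       "baseline_current", "sampling_rate",
                                       "filter_bandwidth", "voltage",
                                       "dead_time_ms"))) {
      args[[f]] <- cond[[f]]
    }
    do.call(build_condition_model, args)
  }
}

condition_events <- function(cond, construct, role, cfg, out_dir, params,
                             files) {
  n_rep <- as.integer(cfg$replicates)
  cond_name <- if (is.character(cond)) cond else paste(construct, role, sep = "_")
  tables <- vector("list", n_rep)
  detection_meta <- NULL
  is_files <- is.list(cond) && !is.null(cond$trace_files)
  if (!is_files) model <- resolve_model(cond, cfg$acquisition, cond_name)
  for (r in seq_len(n_rep)) {
    seed <- derive_seed(cfg$master_seed, 1000L * match(role, c("control", "drug")) +
                          100L * match(construct, CONSTRUCTS) + r)
    if (is_files) {
      paths <- unlist(cond$trace_files)
      tr <- read_trace(paths[[min(r, length(paths))]])
      bl <- estimate_baseline(tr)
      tab <- detect_events(tr, params, baseline = bl)
      detection_meta <- list(noise_sd = bl$noise_sd,
                             threshold_sigma = params$threshold_sigma,
                             bandwidth = tr$metadata$filter_bandwidth)
    } else if (identical(cfg$mode, "events")) {
      ev <- simulate_events(model, seed = seed)
      tab <- as_event_table(ev, condition = cond_name, replicate = r)
    } else {
      sim <- simulate_trace(model, seed = seed)
      bl <- estimate_baseline(sim$trace)
      tab <- detect_events(sim$trace, params, baseline = bl)
      detection_meta <- list(noise_sd = bl$noise_sd,
                             threshold_sigma = params$threshold_sigma,
                             bandwidth = model$filter_bandwidth)
    }
    attr(tab, "meta")$condition <- cond_name
    attr(tab, "meta")$replicate <- r
    csv <- file.path(out_dir, sprintf("events_%s_%s_rep%d.csv",
                                      construct, role, r))
    write_events_csv(tab, csv)
    files$push(csv)
    tables[[r]] <- tab
  }
  list(name = cond_name, tables = tables, detection = detection_meta)
}

profile_json <- function(summary, profiles, path) {
  comp_list <- lapply(profiles, function(p) p$fit$components)
  obj <- list(
    condition = summary$condition,
    n_replicates = summary$n_replicates,
    components = lapply(seq_len(nrow(summary$classes)), function(i) {
      r <- summary$classes[i, ]
      list(class = r$class, peak_pA = r$peak_mean, peak_sem = r$peak_sem,
           population_pct = r$population_mean,
           population_sem = r$population_sem)
    }),
    dwell = lapply(seq_len(nrow(summary$classes)), function(i) {
      r <- summary$classes[i, ]
      list(class = r$class, tau_ms = r$tau_mean, tau_sem = r$tau_sem)
    }),
    unclassified_pct = mean(vapply(profiles, function(p)
      p$fit$unclassified_pct, 0)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full analysis pipeline from a configuration
#'
#' For every construct and condition: simulate traces (or load supplied
#' ones), detect blockade events, fit per-replicate population and
#' dwell-time profiles, summarize across replicates, compare drug against
#' control, call binding per construct, and -- when the panel carries both
#' termini -- infer the knot/loop binding mode. All artifacts (event CSVs,
#' profile JSONs, comparison JSON, binding-call JSON, run manifest) are
#' written under `output_dir`; partial outputs are removed when a stage
#' fails.
#'
#' @param config List or YAML path; see [validate_config()].
#' @param output_dir Run directory (created if needed). Defaults to
#'   `config$output` or a temp directory.
#' @param params [detection_params()] for the trace route.
#' @param master_seed Overrides `config$master_seed`.
#' @return A bundle: list with `summaries`, `comparisons`, `calls`, `mode`
#'   (a `binding_mode_call` or `NULL`), `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         params = detection_params(), master_seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(master_seed)) cfg$master_seed <- master_seed
  out_dir <- output_dir %||% cfg$output %||%
    file.path(tempdir(), paste0("poreblock_", cfg$experiment))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- new.env()
  created$paths <- character(0)
  files <- list(push = function(p) created$paths <- c(created$paths, p))

  run <- function() {
    summaries <- list(); comparisons <- list(); calls <- list()
    profiles_all <- list()
    for (cs in cfg$constructs) {
      construct <- cs$name
      pair <- list()
      for (role in c("control", "drug")) {
        ce <- condition_events(cs[[role]], construct, role, cfg, out_dir,
                               params, files)
        profs <- lapply(ce$tables, function(tab) {
          condition_profile(tab, detection = ce$detection)
        })
        smy <- summarize_condition(profs, condition = ce$name,
                                   construct = construct)
        key <- paste(construct, role, sep = ".")
        summaries[[key]] <- smy
        profiles_all[[key]] <- profs
        pj <- file.path(out_dir, sprintf("profile_%s_%s.json", construct, role))
        profile_json(smy, profs, pj)
        files$push(pj)
        pair[[role]] <- smy
      }
      cmp <- list()
      for (cl in EVENT_CLASSES) {
        res <- compare_conditions(list(pair$control, pair$drug),
                                  metric = "population", class_label = cl)
        if (!is.null(res)) cmp[[cl]] <- res
      }
      comparisons[[construct]] <- cmp
      rule <- if (construct == "full_length") "folding" else "any-change"
      calls[[construct]] <- call_binding(pair$control, pair$drug,
                                         rule = rule, construct = construct)
    }
    cmp_path <- file.path(out_dir, "comparisons.json")
    jsonlite::write_json(lapply(comparisons, function(cmp) {
      lapply(cmp, function(r) list(F = r$F, p = r$p, df = r$df,
                                   pairwise = r$pairwise))
    }), cmp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    files$push(cmp_path)

    mode_call <- NULL
    if (all(c("N_term", "C_term") %in% names(calls))) {
      mode_call <- infer_binding_mode(calls)
    }
    call_path <- file.path(out_dir, "binding_calls.json")
    jsonlite::write_json(list(
      calls = lapply(calls, function(b) list(
        construct = b$construct, bound = b$bound, strength = b$strength,
        rule = b$rule, evidence = b$evidence)),
      mode = if (!is.null(mode_call)) list(mode = mode_call$mode,
                                           rationale = mode_call$rationale)),
      call_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    files$push(call_path)

    manifest <- build_manifest(cfg, created$paths, out_dir)
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    bundle <- list(summaries = summaries, comparisons = comparisons,
                   calls = calls, mode = mode_call, manifest = manifest,
                   config = cfg, output_dir = out_dir)
    class(bundle) <- "pipeline_bundle"
    report <- render_report(bundle)
    writeLines(report, file.path(out_dir, "report.txt"))
    bundle
  }
  tryCatch(run(), error = function(e) {
    unlink(created$paths)
    stop("run_pipeline: ", conditionMessage(e), call. = FALSE)
  })
}

build_manifest <- function(cfg, paths, out_dir) {
  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_tmp)
  digest <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  list(experiment = cfg$experiment,
       config_digest = digest,
       master_seed = cfg$master_seed,
       package_version = as.character(utils::packageVersion("poreblock")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       artifacts = lapply(sort(paths), function(p) {
         list(file = basename(p), md5 = unname(tools::md5sum(p)))
       }))
}

#' Render a bundle as published-table-style text
#'
#' One block per construct, with per-class population, peak current and
#' characteristic time as mean +/- SEM and the drug column annotated with
#' its SNK significance label against the control. Regeneration from the
#' same bundle is byte-identical.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  miss <- setdiff(c("summaries", "calls"), names(bundle))
  if (length(miss) || !length(bundle$summaries)) {
    stop("render_report: incomplete bundle: missing ",
         paste(c(miss, if (!length(bundle$summaries)) "summaries"),
               collapse = ", "), call. = FALSE)
  }
  fmt <- function(m, s, unit) {
    if (!is.finite(m)) return("-")
    if (is.finite(s)) sprintf("%.3g +/- %.2g %s", m, s, unit)
    else sprintf("%.3g %s", m, unit)
  }
  lines <- c(sprintf("Experiment: %s", bundle$config$experiment %||% "?"), "")
  constructs <- unique(vapply(strsplit(names(bundle$summaries), ".",
                                       fixed = TRUE), `[[`, "", 1L))
  for (construct in constructs) {
    ctrl <- bundle$summaries[[paste0(construct, ".control")]]
    drug <- bundle$summaries[[paste0(construct, ".drug")]]
    lines <- c(lines, sprintf("== %s ==", construct))
    cmp <- bundle$comparisons[[construct]]
    for (cl in EVENT_CLASSES) {
      cm <- if (!is.null(ctrl)) ctrl$classes[ctrl$classes$class == cl, ] else NULL
      dm <- if (!is.null(drug)) drug$classes[drug$classes$class == cl, ] else NULL
      if ((is.null(cm) || !nrow(cm)) && (is.null(dm) || !nrow(dm))) next
      lab <- ""
      if (!is.null(cmp[[cl]])) lab <- paste0(" [", cmp[[cl]]$pairwise$label[1L], "]")
      pop_c <- if (!is.null(cm) && nrow(cm)) fmt(cm$population_mean, cm$population_sem, "%") else "-"
      pop_d <- if (!is.null(dm) && nrow(dm)) fmt(dm$population_mean, dm$population_sem, "%") else "-"
      pk_c <- if (!is.null(cm) && nrow(cm)) fmt(cm$peak_mean, cm$peak_sem, "pA") else "-"
      pk_d <- if (!is.null(dm) && nrow(dm)) fmt(dm$peak_mean, dm$peak_sem, "pA") else "-"
      tau_c <- if (!is.null(cm) && nrow(cm)) fmt(cm$tau_mean, cm$tau_sem, "ms") else "-"
      tau_d <- if (!is.null(dm) && nrow(dm)) fmt(dm$tau_mean, dm$tau_sem, "ms") else "-"
      lines <- c(lines,
                 sprintf("  Population of %-13s control: %-22s drug: %s%s",
                         cl, pop_c, pop_d, lab),
                 sprintf("  Peak I of %-17s control: %-22s drug: %s",
                         cl, pk_c, pk_d),
                 sprintf("  Time of %-19s control: %-22s drug: %s",
                         cl, tau_c, tau_d))
    }
    b <- bundle$calls[[construct]]
    if (!is.null(b)) {
      lines <- c(lines, sprintf("  Binding: %s (%s)", b$bound, b$strength))
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$mode)) {
    lines <- c(lines, sprintf("Binding mode: %s", bundle$mode$mode),
               sprintf("  %s", bundle$mode$rationale))
  }
  lines
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}
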