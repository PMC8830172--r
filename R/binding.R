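# Binding verdicts and knot/loop binding-mode inference.
#
# A drug that folds full-length alpha-synuclein shifts events from the
# translocation peak into the bumping peak; where on the protein it binds
# is read off a panel of domain constructs (N-terminus, C-terminus, NAC
# deletion). N-terminal-only binding leaves the aggregation-prone NAC
# region free ("knot"); binding that bridges both termini shields it
# ("loop").

CONSTRUCTS <- c("full_length", "N_term", "C_term", "delta_NAC")

pop_values <- function(summary, cl) {
  v <- summary$per_replicate[summary$per_replicate$class == cl, "population_pct"]
  v <- v[is.finite(v)]
  # a class with no fitted component has population 0 in every replicate
  if (!length(v)) rep(0, summary$n_replicates) else v
}

class_mean <- function(summary, cl, col) {
  r <- summary$classes[summary$classes$class == cl, ]
  if (!nrow(r)) return(NA_real_)
  r[[col]][1L]
}

metric_test <- function(control, drug, cl, comparison = NULL, alpha = 0.05) {
  if (!is.null(comparison)) {
    p <- if (inherits(comparison, "comparison_result")) comparison$pairwise$p[1L]
         else as.numeric(comparison)
  } else {
    a <- pop_values(control, cl); b <- pop_values(drug, cl)
    if (length(a) < 2L || length(b) < 2L) return(list(p = NA_real_))
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(list(p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0))
    }
    res <- snk_posthoc(list(control = a, drug = b), alpha = alpha)
    p <- res$pairwise$p[1L]
  }
  list(p = p)
}

#' Call drug binding from a control/drug condition pair
#'
#' Compares the control and drug condition summaries of one construct.
#' Under the default `rule = "folding"` (full-length protein) the drug is
#' called bound when the translocation population decreases significantly
#' or the bumping population increases significantly -- the signature of
#' drug-induced folding; strength is `"strong"` when both hold. Under
#' `rule = "any-change"` (domain constructs) any significant change of the
#' translocation or bumping population in either direction qualifies, as
#' does the appearance of an intercalation component. A change must both
#' reach significance (`p < alpha`) and exceed `min_effect_pp` percentage
#' points to qualify; peak-current shifts are reported as supporting
#' evidence only.
#'
#' @param control,drug `condition_summary` objects from the same construct.
#' @param comparison Optional named list of precomputed comparison results
#'   (elements `translocation`, `bumping`, `intercalation`: a
#'   `comparison_result` or a bare p-value); when omitted the per-replicate
#'   population values stored in the summaries are compared directly.
#' @param rule `"folding"` or `"any-change"`.
#' @param alpha Significance threshold (default 0.05).
#' @param min_effect_pp Minimum absolute population change, percentage
#'   points, for a significant change to count as binding evidence.
#' @param intercalation_min_pct Minimum intercalation population for an
#'   appearing intercalation component to count (rule `"any-change"`).
#' @param construct Construct identity check; taken from the summaries'
#'   `construct` field when present.
#' @return A `binding_call`: `bound` (`"yes"`/`"no"`), `strength`
#'   (`"strong"`/`"weak"`/`"none"`), `evidence` data.frame, `rule`,
#'   `construct`.
#' @export
call_binding <- function(control, drug, comparison = NULL,
                         rule = c("folding", "any-change"), alpha = 0.05,
                         min_effect_pp = 5, intercalation_min_pct = 10,
                         construct = NA_character_) {
  rule <- match.arg(rule)
  stopifnot(inherits(control, "condition_summary"),
            inherits(drug, "condition_summary"))
  cc <- control$construct %||% NA_character_
  dc <- drug$construct %||% NA_character_
  if (!is.na(cc) && !is.na(dc) && !identical(cc, dc)) {
    stop("call_binding: summaries come from different constructs: ",
         cc, " vs ", dc, call. = FALSE)
  }
  if (is.na(construct)) construct <- if (!is.na(cc)) cc else dc

  ev <- list()
  for (cl in c("translocation", "bumping", "intercalation")) {
    ctrl_m <- class_mean(control, cl, "population_mean")
    drug_m <- class_mean(drug, cl, "population_mean")
    ctrl_v <- if (is.na(ctrl_m)) 0 else ctrl_m
    drug_v <- if (is.na(drug_m)) 0 else drug_m
    change <- drug_v - ctrl_v
    tst <- metric_test(control, drug, cl, comparison = comparison[[cl]],
                       alpha = alpha)
    p <- tst$p
    direction <- if (change > 0) "increase" else if (change < 0) "decrease" else "none"
    sig <- is.finite(p) && p < alpha && abs(change) >= min_effect_pp
    qualifying <- FALSE
    if (cl == "translocation") {
      qualifying <- sig && (rule == "any-change" || change < 0)
    } else if (cl == "bumping") {
      qualifying <- sig && (rule == "any-change" || change > 0)
    } else if (cl == "intercalation" && rule == "any-change") {
      appeared <- (is.na(ctrl_m) || ctrl_v < intercalation_min_pct) &&
        drug_v >= intercalation_min_pct
      qualifying <- appeared && sig
    }
    ev[[cl]] <- data.frame(
      metric = "population_pct", class = cl, control = ctrl_v, drug = drug_v,
      change = change, p = p,
      label = if (is.finite(p)) significance_label(p) else NA_character_,
      direction = direction, qualifying = qualifying,
      stringsAsFactors = FALSE)
    # peak shift: supporting evidence, never gating
    pk_c <- class_mean(control, cl, "peak_mean")
    pk_d <- class_mean(drug, cl, "peak_mean")
    if (is.finite(pk_c) && is.finite(pk_d)) {
      ev[[paste0(cl, "_peak")]] <- data.frame(
        metric = "peak_pA", class = cl, control = pk_c, drug = pk_d,
        change = pk_d - pk_c, p = NA_real_, label = NA_character_,
        direction = if (pk_d < pk_c) "deepening" else "shallowing",
        qualifying = FALSE, stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, ev)
  rownames(evidence) <- NULL
  n_sig <- sum(evidence$qualifying)
  bound <- if (n_sig >= 1L) "yes" else "no"
  strength <- if (n_sig >= 2L) "strong" else if (n_sig == 1L) "weak" else "none"
  structure(list(bound = bound, strength = strength, evidence = evidence,
                 rule = rule, alpha = alpha, construct = construct,
                 control_condition = control$condition,
                 drug_condition = drug$condition),
            class = "binding_call")
}

#' Infer the knot/loop binding mode from a domain-construct panel
#'
#' N-terminus bound with the C-terminus free means the drug ties up only
#' the N-terminal arm, leaving the NAC region exposed: a "knot". Binding at
#' both termini bridges them across the NAC region: a "loop". C-terminal-only
#' or otherwise conflicting evidence is `"indeterminate"`; a panel with no
#' bound construct is `"none"`. NAC-deletion evidence is recorded in the
#' rationale but does not decide the mode -- the termini do.
#'
#' @param panel Named list of `binding_call`s keyed by construct
#'   (`full_length`, `N_term`, `C_term`, `delta_NAC`); `N_term` and
#'   `C_term` are required.
#' @return A `binding_mode_call`: `mode` (`"knot"`, `"loop"`,
#'   `"indeterminate"`, `"none"`), `rationale`, `panel` snapshot.
#' @export
infer_binding_mode <- function(panel) {
  if (!is.list(panel) || !length(panel)) {
    stop("infer_binding_mode: empty panel", call. = FALSE)
  }
  keys <- names(panel)
  if (is.null(keys) || anyDuplicated(keys)) {
    stop("infer_binding_mode: panel must be uniquely keyed by construct",
         call. = FALSE)
  }
  unknown <- setdiff(keys, CONSTRUCTS)
  if (length(unknown)) {
    stop("infer_binding_mode: unknown construct(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (b in panel) stopifnot(inherits(b, "binding_call"))
  if (!all(c("N_term", "C_term") %in% keys)) {
    stop("infer_binding_mode: panel needs at least N_term and C_term calls",
         call. = FALSE)
  }
  missing_constructs <- setdiff(CONSTRUCTS, keys)
  bound <- vapply(panel, function(b) identical(b$bound, "yes"), NA)
  n_b <- bound[["N_term"]]; c_b <- bound[["C_term"]]
  if (!any(bound)) {
    mode <- "none"
    why <- "no construct shows binding"
  } else if (n_b && !c_b) {
    mode <- "knot"
    why <- "N-terminus bound, C-terminus free: NAC region left exposed"
  } else if (n_b && c_b) {
    mode <- "loop"
    why <- "both termini bound: drug bridges N- and C-termini across the NAC region"
  } else {
    mode <- "indeterminate"
    why <- if (c_b) "C-terminus bound without the N-terminus" else
      "binding evidence outside the termini only"
  }
  extra <- character(0)
  if ("delta_NAC" %in% keys) {
    extra <- c(extra, sprintf("NAC-deletion construct: %s (supporting only)",
                              if (bound[["delta_NAC"]]) "bound" else "not bound"))
  }
  if ("full_length" %in% keys) {
    extra <- c(extra, sprintf("full-length protein: %s",
                              if (bound[["full_length"]]) "bound" else "not bound"))
  }
  if (length(missing_constructs)) {
    extra <- c(extra, paste("missing constructs:",
                            paste(missing_constructs, collapse = ", ")))
  }
  structure(list(mode = mode,
                 rationale = paste(c(why, extra), collapse = "; "),
                 panel = panel[order(match(keys, CONSTRUCTS))],
                 bound_constructs = names(bound)[bound]),
            class = "binding_mode_call")
}

#' @export
print.binding_call <- function(x, ...) {
  cat(sprintf("<binding_call> %s%s: bound = %s (%s, rule = %s)\n",
              x$drug_condition %||% "?",
              if (!is.na(x$construct)) paste0(" [", x$construct, "]") else "",
              x$bound, x$strength, x$rule))
  print.data.frame(x$evidence, digits = 3)
  invisible(x)
}

#' @export
print.binding_mode_call <- function(x, ...) {
  cat(sprintf("<binding_mode_call> mode = %s\n  %s\n", x$mode, x$rationale))
  invisible(x)
}
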