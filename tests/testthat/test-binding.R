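# Condition summaries shaped like published triplicate tables.

asyn_ctrl <- function(construct = "full_length") {
  fake_summary("asyn", rbind(
    rep_df("translocation", c(66, 65, 67), peak = -85, tau = 0.52),
    rep_df("bumping", c(24, 23, 25), peak = -30, tau = 0.05)),
    construct = construct)
}

test_that("a CPA-like translocation-to-bumping shift is strong binding", {
  drug <- fake_summary("asyn_cpa", rbind(
    rep_df("translocation", c(40, 39, 41), peak = -89, tau = 0.47),
    rep_df("bumping", c(37, 35, 39), peak = -30, tau = 0.09)),
    construct = "full_length")
  call <- call_binding(asyn_ctrl(), drug, rule = "folding")
  expect_equal(call$bound, "yes")
  expect_equal(call$strength, "strong")
  ev <- call$evidence
  expect_true(ev$qualifying[ev$class == "translocation" & ev$metric == "population_pct"])
  expect_true(ev$qualifying[ev$class == "bumping" & ev$metric == "population_pct"])
})

test_that("an adenosine-like translocation-only decrease is weak binding", {
  drug <- fake_summary("asyn_aden", rbind(
    rep_df("translocation", c(52, 49, 55), peak = -86, tau = 0.46),
    rep_df("bumping", c(25, 21, 29), peak = -30, tau = 0.12)),  # ns change
    construct = "full_length")
  call <- call_binding(asyn_ctrl(), drug, rule = "folding")
  expect_equal(call$bound, "yes")
  expect_equal(call$strength, "weak")
  ev <- call$evidence
  expect_false(ev$qualifying[ev$class == "bumping" & ev$metric == "population_pct"])
})

test_that("identical control and drug summaries are not bound", {
  call <- call_binding(asyn_ctrl(), asyn_ctrl())
  expect_equal(call$bound, "no")
  expect_equal(call$strength, "none")
})

test_that("the folding rule is directional but the panel rule is not", {
  # bumping *decrease* (N-terminal fragment behaviour under CPA)
  ctrl <- fake_summary("nterm", rep_df("bumping", c(70, 69, 71), peak = -30),
                       construct = "N_term")
  drug <- fake_summary("nterm_cpa", rep_df("bumping", c(46, 45, 47), peak = -26),
                       construct = "N_term")
  expect_equal(call_binding(ctrl, drug, rule = "folding")$bound, "no")
  expect_equal(call_binding(ctrl, drug, rule = "any-change")$bound, "yes")
})

test_that("an appearing intercalation component counts as panel evidence", {
  ctrl <- fake_summary("cterm", rbind(
    rep_df("translocation", c(77, 75, 79), peak = -69, tau = 0.4),
    rep_df("bumping", c(20, 19, 21), peak = -30, tau = 0.05)),
    construct = "C_term")
  drug <- fake_summary("cterm_dpcpx", rbind(
    rep_df("translocation", c(77, 75, 79), peak = -69, tau = 0.4),
    rep_df("bumping", c(20, 19, 21), peak = -30, tau = 0.05),
    rep_df("intercalation", c(33, 30, 36), peak = -31, tau = 0.2)),
    construct = "C_term")
  call <- call_binding(ctrl, drug, rule = "any-change")
  expect_equal(call$bound, "yes")
  ev <- call$evidence
  expect_true(ev$qualifying[ev$class == "intercalation" & ev$metric == "population_pct"])
})

test_that("summaries from different constructs are rejected", {
  expect_error(call_binding(asyn_ctrl("N_term"), asyn_ctrl("C_term")),
               "different constructs")
})

test_that("domain panels map to knot, loop, indeterminate and none", {
  bound_call <- function(construct) {
    ctrl <- fake_summary("c", rep_df("bumping", c(70, 69, 71)), construct)
    drug <- fake_summary("d", rep_df("bumping", c(40, 39, 41)), construct)
    call_binding(ctrl, drug, rule = "any-change", construct = construct)
  }
  free_call <- function(construct) {
    ctrl <- fake_summary("c", rep_df("bumping", c(70, 69, 71)), construct)
    call_binding(ctrl, ctrl, rule = "any-change", construct = construct)
  }
  knot <- list(N_term = bound_call("N_term"), C_term = free_call("C_term"),
               delta_NAC = bound_call("delta_NAC"))
  expect_equal(infer_binding_mode(knot)$mode, "knot")
  loop <- list(N_term = bound_call("N_term"), C_term = bound_call("C_term"),
               delta_NAC = bound_call("delta_NAC"))
  expect_equal(infer_binding_mode(loop)$mode, "loop")
  none <- list(N_term = free_call("N_term"), C_term = free_call("C_term"))
  expect_equal(infer_binding_mode(none)$mode, "none")
  conly <- list(N_term = free_call("N_term"), C_term = bound_call("C_term"))
  expect_equal(infer_binding_mode(conly)$mode, "indeterminate")
  naconly <- list(N_term = free_call("N_term"), C_term = free_call("C_term"),
                  delta_NAC = bound_call("delta_NAC"))
  expect_equal(infer_binding_mode(naconly)$mode, "indeterminate")
})

test_that("the mode is none exactly when no construct binds", {
  free <- function(construct) {
    ctrl <- fake_summary("c", rep_df("bumping", c(70, 69, 71)), construct)
    call_binding(ctrl, ctrl, rule = "any-change", construct = construct)
  }
  panel <- list(N_term = free("N_term"), C_term = free("C_term"),
                delta_NAC = free("delta_NAC"), full_length = free("full_length"))
  m <- infer_binding_mode(panel)
  expect_equal(m$mode, "none")
  expect_equal(length(m$bound_constructs), 0L)
})

test_that("panel order never changes the call, and bad panels error", {
  bound_call <- function(construct) {
    ctrl <- fake_summary("c", rep_df("bumping", c(70, 69, 71)), construct)
    drug <- fake_summary("d", rep_df("bumping", c(40, 39, 41)), construct)
    call_binding(ctrl, drug, rule = "any-change", construct = construct)
  }
  p1 <- list(N_term = bound_call("N_term"), C_term = bound_call("C_term"))
  p2 <- rev(p1)
  expect_equal(infer_binding_mode(p1)$mode, infer_binding_mode(p2)$mode)
  expect_error(infer_binding_mode(list()), "empty")
  expect_error(infer_binding_mode(list(N_term = p1$N_term)), "C_term")
  expect_error(infer_binding_mode(list(garbage = p1$N_term)), "unknown construct")
})
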