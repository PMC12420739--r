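#' Score one knockout scenario against its enrichment result
#'
#' The target (knocked-out) pathway is a true positive when testable with
#' `p <= alpha`, a false negative when testable with `p > alpha`; a
#' non-testable target is `not_run` under ORA (too few differential
#' metabolites to test) and counted as a false negative under GSEA (not
#' detected). Every other pathway in the universe is a false positive when
#' testable with `p <= alpha`, otherwise a true negative.
#'
#' @param scenario Pathway id of the knockout.
#' @param result An `enrichment_result` tibble for this scenario's profile.
#' @param alpha Significance threshold (default 0.05, nominal, uncorrected).
#' @param universe Pathway ids counted as FP/TN (default: every pathway in
#'   `result`); typically the functional tested pathways.
#' @return A one-row tibble: `scenario`, `method`, `target_label`
#'   (`TP`/`FN`/`not_run`), `fp_count`, `tn_count`, `tested_pathway_count`.
#' @export
classify_scenario <- function(scenario, result, alpha = 0.05, universe = NULL) {
  universe <- universe %||% result$pathway_id
  result <- filter(result, .data$pathway_id %in% universe)
  method <- result$method[[1]]
  target <- filter(result, .data$pathway_id == scenario)
  if (!nrow(target)) {
    abort(paste0("scenario pathway '", scenario, "' missing from the result universe"))
  }
  label <- if (!target$testable) {
    if (method == "ora") "not_run" else "FN"
  } else if (target$p_value <= alpha) "TP" else "FN"
  others <- filter(result, .data$pathway_id != scenario)
  fp <- sum(others$testable & others$p_value <= alpha, na.rm = TRUE)
  tibble(
    scenario = scenario, method = method, target_label = label,
    fp_count = fp, tn_count = nrow(others) - fp,
    tested_pathway_count = nrow(result)
  )
}

#' Aggregate scenario outcomes into benchmark rates
#'
#' `TPR`, `FNR` and `not_run_rate` are proportions of scenarios (they sum
#' to 1 exactly); `FPR` and `TNR` are the mean false-positive and
#' true-negative pathway counts per scenario.
#'
#' @param outcomes Tibble of [classify_scenario()] rows, one method only.
#' @param alpha The significance threshold the outcomes were scored at
#'   (recorded in the summary).
#' @return A `pa_evaluation` object; see [tidy()]/[glance()] methods.
#' @export
aggregate_outcomes <- function(outcomes, alpha = 0.05) {
  if (!nrow(outcomes)) abort("no scenario outcomes to aggregate")
  if (dplyr::n_distinct(outcomes$method) != 1) {
    abort("outcomes mix methods; aggregate one method at a time")
  }
  s <- tibble(
    method = outcomes$method[[1]],
    n_scenarios = nrow(outcomes),
    tpr = mean(outcomes$target_label == "TP"),
    fnr = mean(outcomes$target_label == "FN"),
    not_run_rate = mean(outcomes$target_label == "not_run"),
    fpr = mean(outcomes$fp_count),
    tnr = mean(outcomes$tn_count),
    conditional_tpr = conditional_tpr(outcomes),
    alpha = alpha
  )
  structure(list(outcomes = outcomes, summary = s), class = "pa_evaluation")
}

#' Conditional true-positive rate over runnable tests
#'
#' `TP / (TP + FN)`, excluding `not_run` scenarios; `NA` when no scenario
#' was runnable.
#'
#' @param outcomes Tibble of [classify_scenario()] rows, or a
#'   `pa_evaluation`.
#' @return A proportion, or `NA_real_`.
#' @export
conditional_tpr <- function(outcomes) {
  if (inherits(outcomes, "pa_evaluation")) outcomes <- outcomes$outcomes
  run <- outcomes$target_label[outcomes$target_label != "not_run"]
  if (!length(run)) return(NA_real_)
  mean(run == "TP")
}

#' @export
print.pa_evaluation <- function(x, ...) {
  s <- x$summary
  cat(
    "<pa_evaluation> ", s$method, ": ", s$n_scenarios, " scenarios | TPR ",
    round(s$tpr, 3), ", FNR ", round(s$fnr, 3), ", not-run ",
    round(s$not_run_rate, 3), " | FPR ", round(s$fpr, 2), ", TNR ",
    round(s$tnr, 2), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn aggregate_outcomes Per-scenario outcome rows.
#' @param x A `pa_evaluation`.
#' @param ... Unused.
#' @export
tidy.pa_evaluation <- function(x, ...) x$outcomes

#' @describeIn aggregate_outcomes One-row rate summary (method, TPR, FNR,
#'   not-run rate, FPR, TNR, conditional TPR).
#' @export
glance.pa_evaluation <- function(x, ...) x$summary

#' Evaluate enrichment results across all scenarios of one method
#'
#' Convenience wrapper: scores every scenario with [classify_scenario()]
#' against the shared universe and aggregates.
#'
#' @param results Named list of `enrichment_result` tibbles, one per
#'   scenario (names are the knocked-out pathway ids).
#' @param alpha Significance threshold.
#' @param universe FP/TN universe (default: the scenario names, i.e. the
#'   functional tested pathways).
#' @return A `pa_evaluation`.
#' @export
evaluate_scenarios <- function(results, alpha = 0.05, universe = NULL) {
  universe <- universe %||% names(results)
  outcomes <- purrr::imap_dfr(
    results,
    ~ classify_scenario(.y, .x, alpha = alpha, universe = universe)
  )
  aggregate_outcomes(outcomes, alpha = alpha)
}
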