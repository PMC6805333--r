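## Sensitivity analysis: full-pipeline scenario runs over analysis sets,
## scoring methods, and futility boundaries.

#' Run one analysis scenario end to end
#'
#' Filter the corpus to an analysis set, score positivity under a
#' confirmatory method, classify outcomes into evidence groups, and
#' evaluate concordance with the gold standard.
#'
#' @param ds a [case_dataset()].
#' @param set_spec an [analysis_set_spec()].
#' @param method `"strong"` or `"weak"`.
#' @param cfg a [classification_config()].
#' @param confidence confidence level for all intervals, default 0.95.
#' @return A list of class `sweep_result`: `label`, `n_cases`,
#'   `n_publications`, `evidence` (evidence table), `confusion`,
#'   `validity`, `agreement`.
#' @examples
#' run_scenario(mpsii_corpus(), analysis_set_spec("primary"), "strong")
#' @export
run_scenario <- function(ds, set_spec, method = c("strong", "weak"),
                         cfg = classification_config(), confidence = 0.95) {
  method <- match.arg(method)
  sub <- apply_analysis_set(ds, set_spec)
  counts <- count_positives(sub, method)
  ev <- classify_evidence(counts, cfg)
  ct <- confusion_from_classification(ev, sub$outcomes)
  structure(
    list(label = sprintf("set=%s method=%s p0=%g q=%g rule=%s",
                         set_spec$name, method, cfg$p0, cfg$q, cfg$rule),
         n_cases = n_cases(sub), n_publications = n_publications(sub),
         evidence = ev, confusion = ct,
         validity = validity_indices(ct, confidence),
         agreement = agreement_with_gold(counts, sub$outcomes, confidence)),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  cat(sprintf("  %d cases from %d publications\n", x$n_cases,
              x$n_publications))
  print(x$confusion)
  v <- x$validity
  cat("  ", paste(sprintf("%s=%s%%", v$index, percent(v$estimate)),
                  collapse = " "), "\n")
  print(x$agreement)
  invisible(x)
}

#' Sweep the futility boundary
#'
#' Re-runs a scenario with the null boundary `p0` set to each requested
#' value. The published sweep uses 1, 5 (primary), 10, 15 and 20%.
#'
#' @inheritParams run_scenario
#' @param boundaries numeric vector of null boundaries, all in (0, 1).
#' @param q FDR level, default 0.10.
#' @param rule classification rule, default `"per_rank"`.
#' @return A list of `sweep_result`, one per boundary, named by boundary.
#' @export
boundary_sweep <- function(ds, set_spec, method = c("strong", "weak"),
                           boundaries = c(0.01, 0.05, 0.10, 0.15, 0.20),
                           q = 0.10, rule = "per_rank", confidence = 0.95) {
  if (length(boundaries) == 0L)
    stop("domain error: empty boundary list", call. = FALSE)
  if (any(boundaries <= 0) || any(boundaries >= 1))
    stop("domain error: boundaries must lie in (0, 1)", call. = FALSE)
  method <- match.arg(method)
  res <- lapply(boundaries, function(p0)
    run_scenario(ds, set_spec, method,
                 classification_config(p0 = p0, q = q, rule = rule),
                 confidence))
  names(res) <- as.character(boundaries)
  res
}

#' Summarize sweep results as one table
#'
#' @param results a list of `sweep_result` (e.g. from [boundary_sweep()] or
#'   built by repeated [run_scenario()] calls).
#' @return A `data.frame` with one row per scenario: label, case and
#'   publication counts, confusion cells, whole-percent validity indices,
#'   and agreement rho with its interval.
#' @export
sweep_summary <- function(results) {
  if (inherits(results, "sweep_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    v <- setNames(r$validity$estimate, r$validity$index)
    data.frame(
      label = r$label, n_publications = r$n_publications,
      n_cases = r$n_cases,
      tp = r$confusion$tp, fp = r$confusion$fp,
      fn = r$confusion$fn, tn = r$confusion$tn,
      accuracy = percent(v[["accuracy"]]),
      sensitivity = percent(v[["sensitivity"]]),
      specificity = percent(v[["specificity"]]),
      ppv = percent(v[["ppv"]]), npv = percent(v[["npv"]]),
      rho = r$agreement$rho,
      rho_lower = r$agreement$ci[["lower"]],
      rho_upper = r$agreement$ci[["upper"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
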