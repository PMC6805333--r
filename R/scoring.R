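## Confirmatory scoring: derive per-case, per-outcome positivity under the
## strong (documented evaluation method or quantitative measure required)
## and weak (mere mention of improvement) rules.

#' Positivity of a single observation under a confirmatory method
#'
#' Benefit outcomes: under the strong method an outcome counts as modified
#' only when improvement is mentioned AND the evaluation method is described
#' or a quantitative measure is reported; under the weak method mention of
#' improvement suffices. Harm outcomes: an infusion-related reaction counts
#' (under both methods) only when it forced a dose change
#' (`irr_dose_change`); other harm outcomes (e.g. antibody development)
#' follow the benefit-shaped rule, so documented detection is required under
#' the strong method and mention under the weak one. Unreported outcomes are
#' negative under both methods — the conservative assumption that an outcome
#' a case report does not mention did not improve.
#'
#' @param obs one row (or several) of an observation table, with the flag
#'   columns of [case_dataset()].
#' @param outcome the matching row(s) of the outcome table.
#' @param method `"strong"` or `"weak"`.
#' @return Logical vector of positivity calls.
#' @export
is_positive <- function(obs, outcome, method = c("strong", "weak")) {
  method <- match.arg(method)
  if (!all(obs$outcome_id == outcome$outcome_id))
    stop("usage error: observation and outcome rows refer to different ",
         "outcome_id", call. = FALSE)
  documented <- obs$method_described | obs$quantitative_measure
  base <- if (method == "strong") {
    obs$improvement_mentioned & documented
  } else {
    obs$improvement_mentioned
  }
  # the IRR dose-change flag qualifies under both methods
  (base | obs$irr_dose_change) & obs$reported
}

#' Per-outcome positive counts
#'
#' Counts, for every configured outcome, the number of cases scored
#' positive under the given confirmatory method. The denominator `n` is the
#' number of cases in the dataset for every outcome — cases not reporting
#' an outcome count as negatives, not as missing.
#'
#' @param ds a [case_dataset()].
#' @param method `"strong"` or `"weak"`.
#' @param outcome optional single `outcome_id` to restrict to.
#' @return A `data.frame` with columns `outcome_id`, `k` (positives), `n`
#'   (total cases), in the order of `ds$outcomes`.
#' @examples
#' prim <- apply_analysis_set(mpsii_corpus(), analysis_set_spec("primary"))
#' count_positives(prim, "strong")
#' @export
count_positives <- function(ds, method = c("strong", "weak"),
                            outcome = NULL) {
  stopifnot(inherits(ds, "case_dataset"))
  method <- match.arg(method)
  outcomes <- ds$outcomes
  if (!is.null(outcome)) {
    if (!outcome %in% outcomes$outcome_id)
      stop("unknown outcome_id: ", outcome, call. = FALSE)
    outcomes <- outcomes[outcomes$outcome_id == outcome, , drop = FALSE]
  }
  obs <- ds$observations
  if (nrow(obs) > 0L) {
    oc <- ds$outcomes[match(obs$outcome_id, ds$outcomes$outcome_id), ,
                      drop = FALSE]
    pos <- is_positive(obs, oc, method)
    tab <- table(factor(obs$outcome_id[pos], levels = outcomes$outcome_id))
    k <- as.integer(tab)
  } else {
    k <- integer(nrow(outcomes))
  }
  data.frame(outcome_id = outcomes$outcome_id, k = k,
             n = nrow(ds$cases), stringsAsFactors = FALSE)
}
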