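## Synthetic case-report corpora: per-outcome response probabilities, a
## reporting-quality model, and an explicit publication-bias mechanism,
## plus operating-characteristic simulation of the classification pipeline.

#' Define a simulation scenario
#'
#' Each simulated case draws, independently per outcome, a true
#' modification with probability `true_modification_prob`. A modified
#' outcome is always mentioned; with probability
#' `prob_strong_documentation` the report also documents the evaluation
#' method (so the strong rule scores it positive), otherwise only the weak
#' rule does. An unmodified outcome is reported (without improvement) with
#' probability `prob_reported_given_no_improvement`. Publication bias is
#' modeled explicitly: a case whose report mentions no modification at all
#' is dropped from the corpus with probability `publication_bias` —
#' published case series over-represent positive results, which inflates
#' observed positive proportions above the true modification probability.
#'
#' Outcome modifications are drawn independently across outcomes within a
#' case; `severity_sd > 0` optionally adds a shared per-case severity
#' factor (a logit-normal random intercept) that correlates outcomes
#' within a case. It defaults to 0 (off) because the published analysis
#' assumes no dependence structure.
#'
#' @param n_cases number of cases drawn before publication-bias dropout.
#' @param outcomes outcome table (see [outcome_spec()]).
#' @param true_modification_prob per-outcome probability (recycled).
#' @param prob_strong_documentation probability a modification is
#'   documented at strong level (recycled); default 0.7.
#' @param prob_reported_given_no_improvement probability an unmodified
#'   outcome is still reported (recycled); default 0.3.
#' @param publication_bias probability a fully-negative case is dropped;
#'   default 0.
#' @param congress_fraction probability a case is a congress
#'   communication; default 0.
#' @param severity_sd standard deviation of the shared per-case severity
#'   factor on the logit scale; default 0 (independent outcomes).
#' @param seed optional integer seed frozen into the scenario; the same
#'   scenario always generates the same corpus.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_cases, outcomes,
                                true_modification_prob,
                                prob_strong_documentation = 0.7,
                                prob_reported_given_no_improvement = 0.3,
                                publication_bias = 0,
                                congress_fraction = 0,
                                severity_sd = 0,
                                seed = NULL) {
  outcomes <- validate_outcomes(outcomes)
  m <- nrow(outcomes)
  probs <- list(
    true_modification_prob = rep_len(true_modification_prob, m),
    prob_strong_documentation = rep_len(prob_strong_documentation, m),
    prob_reported_given_no_improvement =
      rep_len(prob_reported_given_no_improvement, m)
  )
  for (nm in names(probs))
    if (any(probs[[nm]] < 0 | probs[[nm]] > 1))
      stop("domain error: ", nm, " must lie in [0, 1]", call. = FALSE)
  if (publication_bias < 0 || publication_bias > 1 ||
      congress_fraction < 0 || congress_fraction > 1)
    stop("domain error: probabilities must lie in [0, 1]", call. = FALSE)
  if (n_cases < 0)
    stop("domain error: n_cases must be >= 0", call. = FALSE)
  structure(
    c(list(n_cases = as.integer(n_cases), outcomes = outcomes), probs,
      list(publication_bias = publication_bias,
           congress_fraction = congress_fraction,
           severity_sd = severity_sd, seed = seed)),
    class = "simulation_scenario"
  )
}

#' Generate a synthetic case-report corpus
#'
#' Draws a corpus under a [simulation_scenario()]. The result satisfies
#' every dataset invariant, and by construction strong positivity implies
#' weak positivity while unreported outcomes carry no flags.
#'
#' @param scenario a [simulation_scenario()].
#' @return A [case_dataset()].
#' @examples
#' sc <- simulation_scenario(20, mpsii_outcomes(), 0.05, seed = 1)
#' generate_corpus(sc)
#' @export
generate_corpus <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_cases
  out <- scenario$outcomes
  m <- nrow(out)

  if (n == 0L) {
    return(case_dataset(
      data.frame(case_id = character(), publication_id = character(),
                 publication_date = as.Date(character()),
                 publication_type = character(),
                 in_clinical_meta_analysis = logical(),
                 aggregated_form = logical(), stringsAsFactors = FALSE),
      empty_observations(), out, provenance = "synthetic corpus (empty)"))
  }

  p_mod <- matrix(rep(scenario$true_modification_prob, each = n), n, m)
  if (scenario$severity_sd > 0) {
    sev <- stats::rnorm(n, 0, scenario$severity_sd)
    p_mod <- stats::plogis(stats::qlogis(pmin(pmax(p_mod, 1e-12),
                                              1 - 1e-12)) + sev)
  }
  improved <- matrix(stats::runif(n * m) < p_mod, n, m)
  documented <- improved &
    matrix(stats::runif(n * m) <
             rep(scenario$prob_strong_documentation, each = n), n, m)
  reported_neg <- !improved &
    matrix(stats::runif(n * m) <
             rep(scenario$prob_reported_given_no_improvement, each = n),
           n, m)

  # publication bias: fully-negative reports may never be published
  all_negative <- rowSums(improved) == 0L
  dropped <- all_negative &
    (stats::runif(n) < scenario$publication_bias)
  keep <- which(!dropped)

  ids <- sprintf("sim%04d", keep)
  congress <- stats::runif(length(keep)) < scenario$congress_fraction
  cases <- data.frame(
    case_id = ids, publication_id = paste0("pub_", ids),
    publication_date = as.Date("2010-01-01") + (keep - 1L),
    publication_type = ifelse(congress, "congress_communication", "article"),
    in_clinical_meta_analysis = FALSE, aggregated_form = FALSE,
    stringsAsFactors = FALSE
  )

  idx <- which(improved[keep, , drop = FALSE] |
                 reported_neg[keep, , drop = FALSE], arr.ind = TRUE)
  obs <- if (nrow(idx) > 0L) {
    imp <- improved[keep, , drop = FALSE][idx]
    doc <- documented[keep, , drop = FALSE][idx]
    data.frame(
      case_id = ids[idx[, 1L]],
      outcome_id = out$outcome_id[idx[, 2L]],
      reported = TRUE, improvement_mentioned = imp,
      method_described = doc, quantitative_measure = FALSE,
      irr_dose_change = FALSE, stringsAsFactors = FALSE
    )
  } else {
    empty_observations()
  }
  case_dataset(cases, obs, out,
               provenance = sprintf("synthetic corpus (n=%d drawn, %d published)",
                                    n, length(keep)))
}

#' Operating characteristics of the classification procedure
#'
#' Repeatedly generates corpora under a scenario, runs the full
#' count-test-classify pipeline, and reports the per-outcome rejection
#' rate: the fraction of replicates in which the outcome lands in the
#' acceptable evidence group. Under an all-null scenario
#' (`true_modification_prob = p0` everywhere) these rates estimate the
#' per-outcome false-discovery behavior of the procedure; under an
#' alternative they estimate power.
#'
#' Each replicate uses its own seed derived from `seed` (`seed + r - 1`),
#' so replicate r is reproducible regardless of how many replicates are
#' run.
#'
#' @param scenario a [simulation_scenario()] (its own `seed` is ignored
#'   here in favor of the per-replicate seeds).
#' @param cfg a [classification_config()].
#' @param replicates number of replicates, >= 1.
#' @param seed master integer seed; default 1.
#' @param method confirmatory method to score with, default `"strong"`.
#' @return A list of class `operating_characteristics`: `rejection_rate`
#'   (named per-outcome vector), `replicates`, `method`, `config`.
#' @export
operating_characteristics <- function(scenario,
                                      cfg = classification_config(),
                                      replicates, seed = 1,
                                      method = "strong") {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (replicates < 1)
    stop("domain error: replicates must be >= 1", call. = FALSE)
  if (seed + replicates >= 2^31)
    stop("domain error: seed too large for per-replicate derivation",
         call. = FALSE)
  ids <- scenario$outcomes$outcome_id
  hits <- setNames(numeric(length(ids)), ids)
  for (r in seq_len(replicates)) {
    scenario$seed <- seed + r - 1L
    ds <- generate_corpus(scenario)
    ev <- classify_evidence(count_positives(ds, method), cfg)
    acc <- ev$outcome_id[ev$group == "acceptable"]
    hits[acc] <- hits[acc] + 1
  }
  structure(
    list(rejection_rate = hits / replicates, replicates = replicates,
         method = method, config = cfg),
    class = "operating_characteristics"
  )
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d replicates, %s method, p0=%g, q=%g):\n",
              x$replicates, x$method, x$config$p0, x$config$q))
  print(round(x$rejection_rate, 4))
  invisible(x)
}
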