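## Case-level data model: a corpus of narrative case reports, each with
## publication metadata and at most one observation per configured outcome.

.case_cols <- c("case_id", "publication_id", "publication_date",
                "publication_type", "in_clinical_meta_analysis",
                "aggregated_form")
.obs_cols <- c("case_id", "outcome_id", "reported", "improvement_mentioned",
               "method_described", "quantitative_measure", "irr_dose_change")
.obs_flags <- c("reported", "improvement_mentioned", "method_described",
                "quantitative_measure", "irr_dose_change")

#' Construct a case-report dataset
#'
#' The container for a corpus: one row per case in `cases` (publication
#' metadata), one row per case x outcome observation in `observations`
#' (reporting-quality flags), and the outcome configuration. Invariants
#' enforced: unique `case_id`; every observation's `case_id` exists; every
#' `outcome_id` is configured; at most one observation per (case, outcome);
#' an unreported observation carries no other flag; `method_described` or
#' `quantitative_measure` implies `reported`; `irr_dose_change` is only set
#' on harm outcomes.
#'
#' @param cases `data.frame` with columns `case_id`, `publication_id`,
#'   `publication_date` (`Date` or ISO-8601 string), `publication_type`
#'   (`"article"` or `"congress_communication"`),
#'   `in_clinical_meta_analysis` (logical: case analyzed in the
#'   clinical-study meta-analysis used as gold standard), `aggregated_form`
#'   (logical: results published only in aggregated, non-narrative form).
#' @param observations `data.frame` with columns `case_id`, `outcome_id`
#'   and the logical flags `reported`, `improvement_mentioned`,
#'   `method_described`, `quantitative_measure`, `irr_dose_change`.
#' @param outcomes outcome configuration, see [outcome_spec()].
#' @param provenance free-text label describing the origin of the data.
#' @return An object of class `case_dataset`.
#' @seealso [read_case_dataset()], [apply_analysis_set()], [mpsii_corpus()]
#' @export
case_dataset <- function(cases, observations, outcomes,
                         provenance = "unspecified") {
  outcomes <- validate_outcomes(outcomes)
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)

  miss <- setdiff(.case_cols, names(cases))
  if (length(miss) > 0L)
    stop("case table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(observations) == 0L)
    observations <- empty_observations()
  miss <- setdiff(.obs_cols, names(observations))
  if (length(miss) > 0L)
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  cases <- cases[.case_cols]
  observations <- observations[.obs_cols]
  cases$case_id <- as.character(cases$case_id)
  cases$publication_id <- as.character(cases$publication_id)
  cases$publication_date <- as.Date(cases$publication_date)
  cases$publication_type <- as.character(cases$publication_type)
  cases$in_clinical_meta_analysis <- as.logical(cases$in_clinical_meta_analysis)
  cases$aggregated_form <- as.logical(cases$aggregated_form)
  observations$case_id <- as.character(observations$case_id)
  observations$outcome_id <- as.character(observations$outcome_id)
  for (fl in .obs_flags) observations[[fl]] <- as.logical(observations[[fl]])

  validate_case_dataset(cases, observations, outcomes)
  structure(
    list(cases = cases, observations = observations, outcomes = outcomes,
         provenance = as.character(provenance)[1L]),
    class = "case_dataset"
  )
}

empty_observations <- function() {
  data.frame(case_id = character(), outcome_id = character(),
             reported = logical(), improvement_mentioned = logical(),
             method_described = logical(), quantitative_measure = logical(),
             irr_dose_change = logical(), stringsAsFactors = FALSE)
}

validate_case_dataset <- function(cases, observations, outcomes) {
  if (anyDuplicated(cases$case_id))
    stop("integrity error: duplicate case_id: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(cases$publication_type),
                 c("article", "congress_communication"))
  if (length(bad) > 0L)
    stop("invalid publication_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyNA(cases$publication_date))
    stop("unparseable publication_date for case(s): ",
         paste(cases$case_id[is.na(cases$publication_date)], collapse = ", "),
         call. = FALSE)
  if (nrow(observations) == 0L) return(invisible(TRUE))

  orphan <- setdiff(observations$case_id, cases$case_id)
  if (length(orphan) > 0L)
    stop("integrity error: observation for unknown case_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  unknown <- setdiff(observations$outcome_id, outcomes$outcome_id)
  if (length(unknown) > 0L)
    stop("integrity error: unknown outcome_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  key <- paste(observations$case_id, observations$outcome_id)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (case_id, outcome_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (anyNA(observations[.obs_flags]))
    stop("integrity error: missing (NA) observation flag values",
         call. = FALSE)

  any_other <- observations$improvement_mentioned |
    observations$method_described | observations$quantitative_measure |
    observations$irr_dose_change
  bad <- !observations$reported & any_other
  if (any(bad))
    stop("integrity error: unreported observation carries positive flags ",
         "for case(s): ",
         paste(observations$case_id[bad], collapse = ", "), call. = FALSE)
  harm_ids <- outcomes$outcome_id[outcomes$direction == "harm"]
  bad <- observations$irr_dose_change &
    !(observations$outcome_id %in% harm_ids)
  if (any(bad))
    stop("integrity error: irr_dose_change set on benefit outcome for ",
         "case(s): ", paste(observations$case_id[bad], collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Number of cases and publications in a dataset
#'
#' @param ds a [case_dataset()].
#' @return `n_cases()`: the number of case reports; `n_publications()`: the
#'   number of distinct publications they appeared in.
#' @export
n_cases <- function(ds) {
  stopifnot(inherits(ds, "case_dataset"))
  nrow(ds$cases)
}

#' @rdname n_cases
#' @export
n_publications <- function(ds) {
  stopifnot(inherits(ds, "case_dataset"))
  length(unique(ds$cases$publication_id))
}

#' @export
print.case_dataset <- function(x, ...) {
  cat("Case-report dataset:", n_cases(x), "cases from", n_publications(x),
      "publications;", nrow(x$outcomes), "configured outcomes\n")
  cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a case-report dataset from tabular files
#'
#' The cases file is a flat CSV with one row per case x outcome observation
#' (case metadata repeated on each row). Rows with an empty `outcome_id`
#' contribute only case metadata — they represent cases with no scored
#' observation. Rows sharing a `case_id` are merged into one case; their
#' metadata must agree.
#'
#' @param path path to the cases CSV.
#' @param outcomes_path path to the outcome configuration (JSON or CSV,
#'   see [read_outcomes()]), or an already-validated outcome `data.frame`.
#' @param provenance optional label; defaults to the file name.
#' @return A [case_dataset()].
#' @export
read_case_dataset <- function(path, outcomes_path,
                              provenance = basename(path)) {
  if (!file.exists(path))
    stop("cases file not found: ", path, call. = FALSE)
  outcomes <- if (is.data.frame(outcomes_path)) {
    validate_outcomes(outcomes_path)
  } else {
    read_outcomes(outcomes_path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  all_cols <- union(.case_cols, .obs_cols)
  miss <- setdiff(all_cols, names(raw))
  if (length(miss) > 0L)
    stop("schema error: cases file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  cases <- unique(raw[.case_cols])
  if (anyDuplicated(cases$case_id))
    stop("integrity error: conflicting metadata rows for case_id: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]),
               collapse = ", "), call. = FALSE)

  obs <- raw[!is.na(raw$outcome_id) & raw$outcome_id != "", .obs_cols]
  for (fl in .obs_flags) obs[[fl]] <- parse_bool(obs[[fl]], fl)
  cases$in_clinical_meta_analysis <-
    parse_bool(cases$in_clinical_meta_analysis, "in_clinical_meta_analysis")
  cases$aggregated_form <- parse_bool(cases$aggregated_form, "aggregated_form")

  case_dataset(cases, obs, outcomes, provenance = provenance)
}

parse_bool <- function(x, col) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  if (anyNA(out) && length(x) > 0L)
    stop("schema error: column '", col,
         "' contains non-boolean value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Write a case-report dataset to the flat CSV schema
#'
#' Inverse of [read_case_dataset()]: one row per observation, with case
#' metadata repeated; cases without observations are written as a single
#' metadata row with empty outcome fields. `write_case_dataset` followed by
#' `read_case_dataset` reproduces the dataset exactly.
#'
#' @param ds a [case_dataset()].
#' @param path output CSV path.
#' @param outcomes_path optional path; when given, the outcome
#'   configuration is also written (JSON if the extension is `.json`,
#'   else CSV).
#' @return Invisibly, `path`.
#' @export
write_case_dataset <- function(ds, path, outcomes_path = NULL) {
  stopifnot(inherits(ds, "case_dataset"))
  obs <- ds$observations
  lonely <- setdiff(ds$cases$case_id, obs$case_id)
  if (length(lonely) > 0L) {
    pad <- empty_observations()[rep(1L, 0L), ]
    pad <- data.frame(case_id = lonely, outcome_id = "",
                      reported = FALSE, improvement_mentioned = FALSE,
                      method_described = FALSE, quantitative_measure = FALSE,
                      irr_dose_change = FALSE, stringsAsFactors = FALSE)
    obs <- rbind(obs, pad)
  }
  flat <- merge(ds$cases, obs, by = "case_id", sort = FALSE)
  flat <- flat[order(flat$case_id, flat$outcome_id), union(.case_cols, .obs_cols)]
  flat$publication_date <- format(flat$publication_date, "%Y-%m-%d")
  for (col in names(flat))
    if (is.logical(flat[[col]]))
      flat[[col]] <- ifelse(flat[[col]], "true", "false")
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  if (!is.null(outcomes_path)) {
    if (grepl("\\.json$", outcomes_path, ignore.case = TRUE)) {
      jsonlite::write_json(ds$outcomes, outcomes_path, dataframe = "rows",
                           pretty = TRUE)
    } else {
      utils::write.csv(ds$outcomes, outcomes_path, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Packaged MPS-II idursulfase case-report corpus (reconstruction)
#'
#' A synthetic reconstruction of the corpus of 56 published case reports of
#' idursulfase enzyme replacement therapy in mucopolysaccharidosis type II
#' (Hunter syndrome). The individual per-case outcome flags were never
#' published; this fixture was constructed so that every published marginal
#' is reproduced exactly: 56 narrative cases in total, 44 in the primary
#' analysis set (published on or before 2015-12-31), 36 after excluding
#' congress communications, 33 after excluding cases analyzed in the
#' clinical-study meta-analysis, and the per-outcome positive counts under
#' the strong and weak confirmatory methods on the primary set. The
#' assignment of positives to specific cases within a count is arbitrary
#' and frozen; no row corresponds to an identifiable published patient.
#'
#' @return `mpsii_corpus()`: a [case_dataset()] with 56 cases;
#'   `mpsii_outcomes()`: the 11-outcome configuration with gold-standard
#'   SOE grades.
#' @examples
#' ds <- mpsii_corpus()
#' n_cases(ds)
#' @export
mpsii_corpus <- function() {
  read_case_dataset(
    system.file("extdata", "mpsii_cases.csv", package = "metacase",
                mustWork = TRUE),
    mpsii_outcomes(),
    provenance = "MPS-II idursulfase case-report corpus (synthetic reconstruction of published marginals)"
  )
}

#' @rdname mpsii_corpus
#' @export
mpsii_outcomes <- function() {
  read_outcomes(system.file("extdata", "mpsii_outcomes.json",
                            package = "metacase", mustWork = TRUE))
}
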