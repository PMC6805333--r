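#' Outcome configuration
#'
#' An outcome table declares the endpoints analyzed across the corpus: a
#' short identifier, a display label, the direction of the expected
#' treatment effect (`"benefit"` for efficacy outcomes scored on
#' improvement, `"harm"` for safety outcomes scored on impairment), and the
#' strength-of-evidence (SOE) grade assigned to the outcome by the
#' clinical-study meta-analysis used as gold standard.
#'
#' @param outcome_id character vector of unique short tokens.
#' @param label display names, same length as `outcome_id`.
#' @param direction `"benefit"` or `"harm"`, recycled if scalar.
#' @param soe_grade one of `"insufficient"`, `"low"`, `"moderate"`,
#'   `"high"` per outcome.
#' @return A `data.frame` with columns `outcome_id`, `label`, `direction`,
#'   `soe_grade`, validated.
#' @examples
#' outcome_spec("ugags", "Urinary GAGs", "benefit", "moderate")
#' @export
outcome_spec <- function(outcome_id, label = outcome_id,
                         direction = "benefit", soe_grade = "insufficient") {
  out <- data.frame(
    outcome_id = as.character(outcome_id),
    label = as.character(label),
    direction = rep_len(as.character(direction), length(outcome_id)),
    soe_grade = rep_len(as.character(soe_grade), length(outcome_id)),
    stringsAsFactors = FALSE
  )
  validate_outcomes(out)
}

#' @keywords internal
validate_outcomes <- function(outcomes) {
  req <- c("outcome_id", "label", "direction", "soe_grade")
  miss <- setdiff(req, names(outcomes))
  if (length(miss) > 0L)
    stop("outcome table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(outcomes$outcome_id))
    stop("duplicate outcome_id in outcome table: ",
         paste(unique(outcomes$outcome_id[duplicated(outcomes$outcome_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(outcomes$direction), c("benefit", "harm"))
  if (length(bad) > 0L)
    stop("invalid direction value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(outcomes$soe_grade), names(.soe_levels))
  if (length(bad) > 0L)
    stop("invalid soe_grade value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  outcomes[req]
}

.soe_levels <- c(insufficient = 1L, low = 2L, moderate = 3L, high = 4L)

#' Ordinal score of a strength-of-evidence grade
#'
#' Maps SOE grades to the ordinal scale 1 (insufficient), 2 (low),
#' 3 (moderate), 4 (high), and back. The mapping is lossless:
#' `soe_grade_from_score(soe_score(g)) == g`.
#'
#' @param grade character vector of SOE grades.
#' @return Integer scores in 1..4.
#' @examples
#' soe_score(c("insufficient", "moderate"))
#' @export
soe_score <- function(grade) {
  s <- .soe_levels[as.character(grade)]
  if (anyNA(s))
    stop("unknown SOE grade(s): ",
         paste(unique(grade[is.na(s)]), collapse = ", "), call. = FALSE)
  unname(s)
}

#' @rdname soe_score
#' @param score integer vector of ordinal scores in 1..4.
#' @export
soe_grade_from_score <- function(score) {
  if (!all(score %in% .soe_levels))
    stop("SOE scores must be integers in 1..4", call. = FALSE)
  names(.soe_levels)[match(score, .soe_levels)]
}

#' Read an outcome configuration file
#'
#' Accepts either a JSON array of objects or a CSV file with columns
#' `outcome_id`, `label`, `direction`, `soe_grade`.
#'
#' @param path path to a `.json` or `.csv` file.
#' @return A validated outcome `data.frame` (see [outcome_spec()]).
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path))
    stop("outcome configuration file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::fromJSON(path)
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_outcomes(as.data.frame(out, stringsAsFactors = FALSE))
}
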