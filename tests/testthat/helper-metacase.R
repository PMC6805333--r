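# In-code builders for tiny datasets used across the suite.

toy_outcomes <- function() {
  outcome_spec(
    outcome_id = c("biomarker", "walk", "reaction"),
    label = c("Biomarker", "Walk test", "Infusion reaction"),
    direction = c("benefit", "benefit", "harm"),
    soe_grade = c("moderate", "low", "low")
  )
}

toy_case_row <- function(case_id, pub = paste0("pub_", case_id),
                         date = "2012-01-01", type = "article",
                         overlap = FALSE, aggregated = FALSE) {
  data.frame(case_id = case_id, publication_id = pub,
             publication_date = date, publication_type = type,
             in_clinical_meta_analysis = overlap,
             aggregated_form = aggregated, stringsAsFactors = FALSE)
}

toy_obs_row <- function(case_id, outcome_id, reported = TRUE,
                        mention = FALSE, method = FALSE, quant = FALSE,
                        irr = FALSE) {
  data.frame(case_id = case_id, outcome_id = outcome_id,
             reported = reported, improvement_mentioned = mention,
             method_described = method, quantitative_measure = quant,
             irr_dose_change = irr, stringsAsFactors = FALSE)
}

toy_dataset <- function() {
  cases <- rbind(
    toy_case_row("a", date = "2011-05-01"),
    toy_case_row("b", date = "2013-08-01", type = "congress_communication"),
    toy_case_row("c", date = "2016-02-01"),
    toy_case_row("d", date = "2014-03-01", overlap = TRUE)
  )
  obs <- rbind(
    toy_obs_row("a", "biomarker", mention = TRUE, quant = TRUE),
    toy_obs_row("a", "walk", mention = TRUE),
    toy_obs_row("b", "biomarker", mention = TRUE, method = TRUE),
    toy_obs_row("c", "reaction", irr = TRUE),
    toy_obs_row("d", "walk", reported = TRUE)
  )
  case_dataset(cases, obs, toy_outcomes(), provenance = "toy")
}

# independent oracle: upper binomial tail by direct log-space summation
sum_upper_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  js <- k:n
  sum(exp(lchoose(n, js) + js * log(p0) + (n - js) * log1p(-p0)))
}

table1_counts <- function() {
  data.frame(
    outcome_id = c("ugags", "liver_vol", "antibodies", "6mwt", "jrom",
                   "growth", "irr", "pulmonary", "cardiac", "qol",
                   "sleep_apnea"),
    k = c(20L, 8L, 6L, 4L, 4L, 3L, 2L, 1L, 0L, 0L, 0L),
    n = 44L, stringsAsFactors = FALSE)
}

table2_counts <- function() {
  data.frame(
    outcome_id = c("ugags", "liver_vol", "antibodies", "6mwt", "jrom",
                   "growth", "irr", "pulmonary", "cardiac", "qol",
                   "sleep_apnea"),
    k = c(20L, 13L, 6L, 15L, 5L, 5L, 2L, 4L, 0L, 8L, 1L),
    n = 44L, stringsAsFactors = FALSE)
}
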