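#' Analysis-set specification
#'
#' An analysis set is a conjunctive filter over a case-report corpus: an
#' optional publication-date cutoff (keep cases published on or before it),
#' optional exclusion of congress communications, optional exclusion of
#' cases that were analyzed in the clinical-study meta-analysis used as
#' gold standard, and exclusion of cases published only in aggregated form
#' (on by default: aggregated data are not narrative case reports).
#'
#' Four named presets cover the published analysis sets:
#' \describe{
#'   \item{`"primary"`}{narrative cases published on or before the
#'     clinical-study search date (2015-12-31).}
#'   \item{`"all"`}{all narrative cases regardless of date.}
#'   \item{`"no_overlap"`}{primary set minus cases analyzed in the
#'     clinical-study meta-analysis.}
#'   \item{`"no_congress"`}{primary set minus congress communications.}
#' }
#'
#' @param name a preset name above, or any label for a custom spec.
#' @param date_cutoff `Date` (or ISO-8601 string) or `NULL` for no cutoff.
#' @param exclude_congress drop congress communications?
#' @param exclude_overlap drop cases analyzed in the gold-standard
#'   clinical-study meta-analysis?
#' @param exclude_aggregated drop cases published only in aggregated form?
#' @return An object of class `analysis_set_spec`.
#' @examples
#' analysis_set_spec("primary")
#' analysis_set_spec("custom", date_cutoff = "2012-12-31")
#' @export
analysis_set_spec <- function(name = "custom", date_cutoff = NULL,
                              exclude_congress = FALSE,
                              exclude_overlap = FALSE,
                              exclude_aggregated = TRUE) {
  presets <- list(
    primary     = list(date_cutoff = as.Date("2015-12-31"),
                       exclude_congress = FALSE, exclude_overlap = FALSE),
    all         = list(date_cutoff = NULL,
                       exclude_congress = FALSE, exclude_overlap = FALSE),
    no_overlap  = list(date_cutoff = as.Date("2015-12-31"),
                       exclude_congress = FALSE, exclude_overlap = TRUE),
    no_congress = list(date_cutoff = as.Date("2015-12-31"),
                       exclude_congress = TRUE, exclude_overlap = FALSE)
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    date_cutoff <- p$date_cutoff
    exclude_congress <- p$exclude_congress
    exclude_overlap <- p$exclude_overlap
    exclude_aggregated <- TRUE
  }
  if (!is.null(date_cutoff)) date_cutoff <- as.Date(date_cutoff)
  structure(
    list(name = name, date_cutoff = date_cutoff,
         exclude_congress = isTRUE(exclude_congress),
         exclude_overlap = isTRUE(exclude_overlap),
         exclude_aggregated = isTRUE(exclude_aggregated)),
    class = "analysis_set_spec"
  )
}

#' @export
print.analysis_set_spec <- function(x, ...) {
  cat("Analysis set '", x$name, "': ", sep = "")
  parts <- c(
    if (!is.null(x$date_cutoff))
      paste0("published <= ", format(x$date_cutoff)),
    if (x$exclude_congress) "no congress communications",
    if (x$exclude_overlap) "no clinical-meta-analysis overlap",
    if (x$exclude_aggregated) "narrative form only"
  )
  cat(if (length(parts)) paste(parts, collapse = "; ") else "all cases", "\n")
  invisible(x)
}

#' Filter a corpus to an analysis set
#'
#' Applies the conjunctive filters of an [analysis_set_spec()]. Filtering is
#' idempotent and never increases the case count; an empty result is legal.
#' The returned dataset's provenance records the resulting case and
#' publication counts.
#'
#' @param ds a [case_dataset()].
#' @param spec an [analysis_set_spec()].
#' @return The filtered [case_dataset()].
#' @examples
#' prim <- apply_analysis_set(mpsii_corpus(), analysis_set_spec("primary"))
#' n_cases(prim)   # 44
#' @export
apply_analysis_set <- function(ds, spec) {
  stopifnot(inherits(ds, "case_dataset"), inherits(spec, "analysis_set_spec"))
  keep <- rep(TRUE, nrow(ds$cases))
  if (!is.null(spec$date_cutoff))
    keep <- keep & ds$cases$publication_date <= spec$date_cutoff
  if (spec$exclude_congress)
    keep <- keep & ds$cases$publication_type != "congress_communication"
  if (spec$exclude_overlap)
    keep <- keep & !ds$cases$in_clinical_meta_analysis
  if (spec$exclude_aggregated)
    keep <- keep & !ds$cases$aggregated_form
  cases <- ds$cases[keep, , drop = FALSE]
  obs <- ds$observations[ds$observations$case_id %in% cases$case_id, ,
                         drop = FALSE]
  out <- case_dataset(cases, obs, ds$outcomes,
                      provenance = sprintf(
                        "%s | set '%s': %d cases from %d publications",
                        ds$provenance, spec$name, nrow(cases),
                        length(unique(cases$publication_id))))
  out
}
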