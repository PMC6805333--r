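## Evidence classification: exact binomial futility test per outcome and
## FDR-based grouping into acceptable / unacceptable evidence.

#' Exact upper-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p0): the one-sided p-value of the futility
#' test of H0 "true modification proportion <= p0" against the observed
#' count of k positive cases out of n. Computed through the exact
#' incomplete-beta form of the binomial distribution function.
#'
#' @param k observed positives, 0 <= k <= n (vectorized).
#' @param n total cases.
#' @param p0 null boundary proportion in (0, 1); default 0.05.
#' @return Probabilities in `[0, 1]`; `1` at `k = 0` and `p0^n` at `k = n`.
#' @examples
#' binomial_upper_tail_p(6, 44, 0.05)   # 0.022
#' @export
binomial_upper_tail_p <- function(k, n, p0 = 0.05) {
  if (any(n < 0) || any(k < 0) || any(k > n))
    stop("domain error: need 0 <= k <= n", call. = FALSE)
  if (any(p0 <= 0) || any(p0 >= 1))
    stop("domain error: p0 must lie in (0, 1)", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' FDR critical values
#'
#' The Benjamini-Hochberg critical value at rank r among nr outcomes for an
#' FDR level q is r / nr * q; the full ladder is strictly increasing and
#' ends at q.
#'
#' @param nr number of outcomes (>= 1).
#' @param q FDR level in (0, 1); default 0.10.
#' @return Numeric vector of length `nr`, value `r/nr * q` at rank r.
#' @examples
#' round(fdr_critical_values(11, 0.10)[1:3], 3)  # 0.009 0.018 0.027
#' @export
fdr_critical_values <- function(nr, q = 0.10) {
  if (length(nr) != 1L || is.na(nr) || nr < 1)
    stop("domain error: nr must be a single integer >= 1", call. = FALSE)
  if (q <= 0 || q >= 1)
    stop("domain error: q must lie in (0, 1)", call. = FALSE)
  seq_len(nr) / nr * q
}

#' Rank p-values with dense minimum-rank ties
#'
#' Sorting the p-values ascending defines ranks 1, 2, ...; all members of a
#' tie group share one rank and the next distinct value gets the following
#' rank ("dense" ranking). Sharing the lowest rank of a tie group is the
#' conservative choice for the FDR criterion, because the critical value
#' r/nr*q grows with the rank. Ties are detected on exact equality of the
#' full-precision p-values (ties arise from identical counts).
#'
#' @param p_values non-empty numeric vector of p-values.
#' @return Integer ranks, same order as the input.
#' @examples
#' assign_ranks(c(0.001, 0.177, 0.177, 1, 1))  # 1 2 2 3 3
#' @export
assign_ranks <- function(p_values) {
  if (length(p_values) == 0L)
    stop("domain error: empty p-value list", call. = FALSE)
  match(p_values, sort(unique(p_values)))
}

#' Classification configuration
#'
#' Bundles the null futility boundary `p0` (null hypothesis: the true
#' proportion of cases with an outcome modification is at most `p0`), the
#' FDR level `q`, and the grouping rule. `"per_rank"` marks an outcome
#' acceptable iff its own p-value is at or below its own critical value
#' (the rule as published); `"step_up"` is the orthodox Benjamini-Hochberg
#' step-up, which additionally accepts any outcome ranked below some
#' accepted one. The two coincide whenever the sub-threshold p-values form
#' a prefix of the ranking, as they do on the shipped corpus.
#'
#' @param p0 null boundary in (0, 1); default 0.05.
#' @param q FDR level in (0, 1); default 0.10.
#' @param rule `"per_rank"` (default) or `"step_up"`.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(p0 = 0.05, q = 0.10,
                                  rule = c("per_rank", "step_up")) {
  if (p0 <= 0 || p0 >= 1) stop("domain error: p0 in (0,1)", call. = FALSE)
  if (q <= 0 || q >= 1) stop("domain error: q in (0,1)", call. = FALSE)
  structure(list(p0 = p0, q = q, rule = match.arg(rule)),
            class = "classification_config")
}

#' Classify outcomes into evidence groups
#'
#' For each outcome, tests H0 "true modification proportion <= p0" with the
#' exact one-sided binomial test on its (k, n) count, ranks the p-values
#' (dense minimum-rank ties, see [assign_ranks()]), computes the FDR
#' critical value rank/nr * q, and labels the outcome `acceptable` if its
#' p-value passes the configured rule, else `unacceptable`.
#'
#' @param counts `data.frame` with columns `outcome_id`, `k`, `n` (from
#'   [count_positives()]); all rows must share the same `n`.
#' @param cfg a [classification_config()].
#' @return A `data.frame` of class `evidence_table` with columns
#'   `outcome_id`, `k`, `n`, `proportion`, `p_value`, `rank`,
#'   `critical_value`, `group`, sorted by rank then `outcome_id`.
#' @examples
#' prim <- apply_analysis_set(mpsii_corpus(), analysis_set_spec("primary"))
#' classify_evidence(count_positives(prim, "strong"))
#' @export
classify_evidence <- function(counts, cfg = classification_config()) {
  stopifnot(inherits(cfg, "classification_config"))
  req <- c("outcome_id", "k", "n")
  if (!all(req %in% names(counts)))
    stop("counts must have columns outcome_id, k, n", call. = FALSE)
  if (nrow(counts) < 1L)
    stop("domain error: at least one outcome required", call. = FALSE)
  if (length(unique(counts$n)) != 1L)
    stop("domain error: inconsistent n across outcomes", call. = FALSE)

  nr <- nrow(counts)
  p <- binomial_upper_tail_p(counts$k, counts$n, cfg$p0)
  r <- assign_ranks(p)
  crit <- r / nr * cfg$q
  acceptable <- if (cfg$rule == "per_rank") {
    p <= crit
  } else {
    # step-up: largest sorted position i with p_(i) <= i/nr * q; accept all
    # p-values at or below that one
    ord <- order(p)
    ok <- which(p[ord] <= seq_len(nr) / nr * cfg$q)
    if (length(ok) == 0L) rep(FALSE, nr) else p <= p[ord][max(ok)]
  }
  out <- data.frame(
    outcome_id = counts$outcome_id, k = counts$k, n = counts$n,
    proportion = ifelse(counts$n > 0, counts$k / counts$n, NA_real_),
    p_value = p, rank = r, critical_value = crit,
    group = ifelse(acceptable, "acceptable", "unacceptable"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank, out$outcome_id), ]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Format a p-value the way the evidence tables print it
#'
#' Three decimal places; values below 1e-4 render as `"< 0.0001"`.
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "< 0.0001", formatC(round(p, 3), format = "fg"))
}

#' Render an evidence table as aligned text
#'
#' Mirrors the published column order: rank, outcome (with SOE grade when
#' an outcome table is supplied), positives/total, p-value, FDR critical
#' value, evidence group.
#'
#' @param ev an `evidence_table` from [classify_evidence()].
#' @param outcomes optional outcome table for labels and SOE grades.
#' @return Character vector of lines, invisibly printed with `cat()` by
#'   `print.evidence_table`.
#' @export
format_evidence_table <- function(ev, outcomes = NULL) {
  lab <- ev$outcome_id
  if (!is.null(outcomes)) {
    m <- match(ev$outcome_id, outcomes$outcome_id)
    lab <- sprintf("%s (%s)", outcomes$label[m], outcomes$soe_grade[m])
  }
  header <- sprintf("%-4s %-34s %-9s %-9s %-10s %s",
                    "Rank", "Outcome (SOE)", "Nr+/N", "p-value",
                    "FDR crit.", "Evidence group")
  rows <- sprintf("%-4d %-34s %-9s %-9s %-10s %s",
                  ev$rank, lab, paste0(ev$k, "/", ev$n),
                  format_p(ev$p_value),
                  formatC(round(ev$critical_value, 3), format = "fg"),
                  ev$group)
  c(header, rows)
}

#' @export
print.evidence_table <- function(x, outcomes = NULL, ...) {
  cat(format_evidence_table(x, outcomes), sep = "\n")
  invisible(x)
}
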