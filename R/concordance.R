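## Concordance with the gold standard: 2x2 validity indices with exact
## Clopper-Pearson intervals and tie-corrected Spearman agreement with a
## Fisher-z interval.

#' Confusion table against the strength-of-evidence gold standard
#'
#' Test-positive = outcome classified in the acceptable evidence group;
#' gold-positive = outcome graded moderate or high SOE by the
#' clinical-study meta-analysis.
#'
#' @param rows an `evidence_table` from [classify_evidence()] (an empty
#'   `data.frame` yields an all-zero table).
#' @param outcomes outcome table supplying `soe_grade` for every
#'   classified outcome.
#' @return An object of class `confusion_table`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_from_classification <- function(rows, outcomes) {
  if (nrow(rows) == 0L)
    return(structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 0L),
                     class = "confusion_table"))
  m <- match(rows$outcome_id, outcomes$outcome_id)
  if (anyNA(m))
    stop("domain error: no gold-standard SOE grade for outcome(s): ",
         paste(rows$outcome_id[is.na(m)], collapse = ", "), call. = FALSE)
  gold <- outcomes$soe_grade[m] %in% c("moderate", "high")
  test <- rows$group == "acceptable"
  structure(
    list(tp = sum(test & gold), fp = sum(test & !gold),
         fn = sum(!test & gold), tn = sum(!test & !gold)),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion vs gold standard: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a proportion, through the beta-quantile
#' closed form: lower = qbeta(alpha/2; x, n-x+1), upper =
#' qbeta(1-alpha/2; x+1, n-x), with lower = 0 at x = 0 and upper = 1 at
#' x = n. With zero trials the proportion is undefined and `c(NA, NA)` is
#' returned.
#'
#' @param successes number of successes, 0 <= successes <= trials.
#' @param trials number of trials.
#' @param confidence confidence level, default 0.95.
#' @return `c(lower, upper)`, or `c(NA, NA)` when `trials == 0`.
#' @examples
#' round(clopper_pearson_interval(3, 3), 3)   # 0.292 1.000
#' @export
clopper_pearson_interval <- function(successes, trials, confidence = 0.95) {
  if (trials == 0) return(c(lower = NA_real_, upper = NA_real_))
  if (successes < 0 || successes > trials)
    stop("domain error: need 0 <= successes <= trials", call. = FALSE)
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Validity indices of a confusion table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp), negative predictive value tn/(tn+fn), and accuracy
#' (tp+tn)/total, each with an exact Clopper-Pearson interval. An index
#' with a zero denominator is undefined and reported as `NA`.
#'
#' @param ct a `confusion_table`.
#' @param confidence confidence level, default 0.95.
#' @return A `data.frame` of class `validity_result` with columns `index`,
#'   `numerator`, `denominator`, `estimate`, `lower`, `upper`.
#' @export
validity_indices <- function(ct, confidence = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- ct$tp + ct$fp + ct$fn + ct$tn
  if (total == 0)
    stop("domain error: all-zero confusion table", call. = FALSE)
  defs <- list(
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv         = c(ct$tp, ct$tp + ct$fp),
    npv         = c(ct$tn, ct$tn + ct$fn),
    accuracy    = c(ct$tp + ct$tn, total)
  )
  rows <- lapply(names(defs), function(nm) {
    num <- defs[[nm]][1]; den <- defs[[nm]][2]
    if (den == 0) {
      data.frame(index = nm, numerator = num, denominator = den,
                 estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      ci <- clopper_pearson_interval(num, den, confidence)
      data.frame(index = nm, numerator = num, denominator = den,
                 estimate = num / den, lower = ci[["lower"]],
                 upper = ci[["upper"]], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validity_result", "data.frame")
  out
}

#' Whole-percent display (round half away from zero)
#'
#' Renders a proportion as a whole percentage, rounding .5 away from zero
#' (so 10/11 -> 91, 2/3 -> 67, 8/9 -> 89), matching the published tables.
#'
#' @param x proportions in `[0, 1]`.
#' @return Integer percents (NA preserved).
#' @export
percent <- function(x) {
  ifelse(is.na(x), NA_integer_,
         as.integer(sign(x) * floor(abs(x) * 100 + 0.5)))
}

#' Midranks
#'
#' Average ranks with tied values receiving the mean of the rank positions
#' they span; ranks always sum to n(n+1)/2.
#'
#' @param values numeric (or otherwise order-comparable) vector.
#' @return Numeric midranks.
#' @examples
#' midrank(c(0, 0, 0, 1))  # 2 2 2 4
#' @export
midrank <- function(values) {
  if (length(values) == 0L)
    stop("domain error: empty input", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Tie-corrected Spearman rank correlation
#'
#' The product-moment correlation of the midranks of `x` and `y`. With
#' ties present this is the standard tie-corrected Spearman coefficient;
#' without ties it coincides with the classical 1 - 6*sum(d^2)/(n(n^2-1))
#' formula. Returns `NA` when either midrank vector has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return The correlation in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' spearman_midrank(c(20, 8, 6, 4, 4, 3, 2, 1, 0, 0, 0),
#'                  c(3, 3, 3, 2, 1, 2, 2, 2, 1, 1, 1))  # 0.817...
#' @export
spearman_midrank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("domain error: x and y must have equal length >= 2", call. = FALSE)
  mx <- midrank(x) - (length(x) + 1) / 2
  my <- midrank(y) - (length(y) + 1) / 2
  den <- sqrt(sum(mx^2) * sum(my^2))
  if (den == 0) return(NA_real_)
  sum(mx * my) / den
}

#' Fisher-z confidence interval for a correlation
#'
#' Transforms rho with atanh, takes a normal interval with standard error
#' 1/sqrt(n - 3), and back-transforms with tanh. Undefined (returns
#' `c(NA, NA)`) when |rho| = 1 or n <= 3; endpoints are always strictly
#' inside (-1, 1).
#'
#' @param rho correlation with |rho| < 1.
#' @param n number of paired observations, n > 3.
#' @param confidence confidence level, default 0.95.
#' @return `c(lower, upper)`.
#' @examples
#' round(fisher_z_interval(0.817, 11), 2)   # 0.43 0.95
#' @export
fisher_z_interval <- function(rho, n, confidence = 0.95) {
  if (is.na(rho) || abs(rho) >= 1 || n <= 3)
    return(c(lower = NA_real_, upper = NA_real_))
  z <- atanh(rho)
  half <- stats::qnorm(1 - (1 - confidence) / 2) / sqrt(n - 3)
  c(lower = tanh(z - half), upper = tanh(z + half))
}

#' Relative agreement between evidence counts and SOE scores
#'
#' Computes the tie-corrected Spearman correlation between per-outcome
#' positive counts and the ordinal SOE scores of the gold standard
#' (insufficient = 1 .. high = 4), with a Fisher-z confidence interval.
#'
#' @param counts `data.frame` with `outcome_id` and `k` (e.g. from
#'   [count_positives()] or an evidence table).
#' @param outcomes outcome table with `soe_grade`.
#' @param confidence confidence level, default 0.95.
#' @return A list of class `agreement_result`: `rho`, `ci` (`c(lower,
#'   upper)` or NAs), `n`, and the `scatter` data (`outcome_id`, `k`,
#'   `soe_score`) for plotting.
#' @export
agreement_with_gold <- function(counts, outcomes, confidence = 0.95) {
  m <- match(counts$outcome_id, outcomes$outcome_id)
  if (anyNA(m))
    stop("domain error: no gold-standard SOE grade for outcome(s): ",
         paste(counts$outcome_id[is.na(m)], collapse = ", "), call. = FALSE)
  score <- soe_score(outcomes$soe_grade[m])
  rho <- spearman_midrank(counts$k, score)
  structure(
    list(rho = rho,
         ci = fisher_z_interval(rho, length(score), confidence),
         n = length(score),
         scatter = data.frame(outcome_id = counts$outcome_id,
                              k = counts$k, soe_score = score,
                              stringsAsFactors = FALSE)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  if (is.na(x$rho)) {
    cat("Agreement: rho undefined (zero rank variance), n =", x$n, "\n")
  } else {
    cat(sprintf("Agreement: rho = %.2f (95%%CI %.2f to %.2f), n = %d\n",
                x$rho, x$ci[["lower"]], x$ci[["upper"]], x$n))
  }
  invisible(x)
}
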