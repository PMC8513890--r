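# Diagnostic-validity estimation for a 2x2 algorithm-vs-gold-standard table.
#
# All interval estimates are Clopper-Pearson exact binomial intervals: the
# boundary rows of a validation study (x = n successes, e.g. NPV with zero
# false negatives) still get honest, conservative intervals there, which
# Wald/Wilson approximations do not provide.

#' 2x2 contingency table of algorithm result vs gold standard
#'
#' @param tp,fp,tn,fn Non-negative counts: algorithm-positive cases with and
#'   without disease, algorithm-negative cases without and with disease.
#' @param weighted Whether the counts have been scaled by sampling weights.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(tp, fp, tn, fn, weighted = FALSE) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0))
    stop_domain("2x2 counts must be non-negative")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 weighted = isTRUE(weighted)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2>", if (x$weighted) "(weighted)" else "", "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("disease+", "disease-")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower=, upper=)`.
#' @examples
#' clopper_pearson(83, 100)  # c(0.742, 0.898) to 3 decimals
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n))
    stop_domain("x and n must be single non-missing numbers")
  if (n < 1 || x < 0 || x > n)
    stop_domain("need 0 <= x <= n with n >= 1 (got x=", x, ", n=", n, ")")
  if (level <= 0 || level >= 1) stop_domain("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Sensitivity, specificity, PPV and NPV with exact confidence intervals
#'
#' Each metric is a binomial proportion on its own denominator:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), with a [clopper_pearson()] interval. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0 or 1.
#'
#' @param table A [contingency_2x2()].
#' @param level Confidence level, default 0.95.
#' @return A `validity_result`: data frame with columns `metric`, `estimate`,
#'   `ci_low`, `ci_high`, `x`, `n`.
#' @export
diagnostic_metrics <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  tot <- table$tp + table$fp + table$tn + table$fn
  if (tot <= 0) stop_domain("all-zero 2x2 table: no metrics are defined")
  one <- function(metric, x, n) {
    if (n == 0) {
      data.frame(metric = metric, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, x = x, n = n)
    } else {
      ci <- clopper_pearson(x, n, level)
      data.frame(metric = metric, estimate = x / n, ci_low = ci[["lower"]],
                 ci_high = ci[["upper"]], x = x, n = n)
    }
  }
  out <- rbind(
    one("sensitivity", table$tp, table$tp + table$fn),
    one("specificity", table$tn, table$tn + table$fp),
    one("ppv",         table$tp, table$tp + table$fp),
    one("npv",         table$tn, table$tn + table$fn)
  )
  attr(out, "level") <- level
  attr(out, "weighted") <- table$weighted
  class(out) <- c("validity_result", "data.frame")
  out
}

#' @export
print.validity_result <- function(x, digits = 3, ...) {
  cat("<validity_result> level =", attr(x, "level"),
      if (isTRUE(attr(x, "weighted"))) "(weighted table)" else "", "\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extrapolate a sampled 2x2 table to the source cohort
#'
#' Scales the algorithm-positive cells by `pos_weight` and the
#' algorithm-negative cells by `neg_weight` (population count / sampled
#' count), flooring to whole patients.
#'
#' @param table A [contingency_2x2()].
#' @param pos_weight,neg_weight Non-negative scaling weights (>= 1 in the
#'   intended use).
#' @return A weighted [contingency_2x2()].
#' @examples
#' extrapolate_2x2(contingency_2x2(83, 17, 200, 0), 255 / 100, 1)
#' @export
extrapolate_2x2 <- function(table, pos_weight, neg_weight) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (is.na(pos_weight) || is.na(neg_weight) || pos_weight < 0 || neg_weight < 0)
    stop_domain("weights must be non-negative")
  contingency_2x2(
    tp = floor(table$tp * pos_weight),
    fp = floor(table$fp * pos_weight),
    tn = floor(table$tn * neg_weight),
    fn = floor(table$fn * neg_weight),
    weighted = TRUE
  )
}

#' Estimated number of true cases among those extracted
#'
#' `floor(n_extracted * ppv)`: the expected count of true cases in the full
#' criterion-positive pool given the PPV measured on the validation sample.
#'
#' @param n_extracted Number of criterion-positive patients extracted.
#' @param ppv Positive predictive value in `[0, 1]`.
#' @return Integer count.
#' @examples
#' estimate_true_count(255, 0.83)  # 211
#' estimate_true_count(197, 0.97)  # 191
#' @export
estimate_true_count <- function(n_extracted, ppv) {
  if (is.na(ppv) || ppv < 0 || ppv > 1) stop_domain("ppv must be in [0, 1]")
  if (is.na(n_extracted) || n_extracted < 0) stop_domain("n_extracted must be >= 0")
  as.integer(floor(n_extracted * ppv))
}

#' Sample size for estimating a proportion to a target CI half-width
#'
#' Smallest n with `z^2 p (1-p) / n <= halfwidth^2` under the normal
#' approximation, i.e. `ceiling(z^2 p (1-p) / halfwidth^2)`. With the default
#' worst-case planning proportion 0.5 and a +/-0.1 half-width at 95%
#' confidence this gives 97, typically rounded up to a round 100 in study
#' protocols.
#'
#' @param halfwidth Target confidence-interval half-width, in (0, 1).
#' @param level Confidence level, default 0.95.
#' @param planning_p Assumed proportion, in (0, 1); default 0.5 (worst case).
#' @return Integer sample size.
#' @examples
#' required_n_for_proportion(0.1)   # 97
#' required_n_for_proportion(0.05)  # 385
#' @export
required_n_for_proportion <- function(halfwidth, level = 0.95, planning_p = 0.5) {
  if (is.na(halfwidth) || halfwidth <= 0 || halfwidth >= 1)
    stop_domain("halfwidth must be in (0, 1)")
  if (is.na(planning_p) || planning_p <= 0 || planning_p >= 1)
    stop_domain("planning_p must be strictly inside (0, 1)")
  if (level <= 0 || level >= 1) stop_domain("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  as.integer(ceiling(z^2 * planning_p * (1 - planning_p) / halfwidth^2))
}
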