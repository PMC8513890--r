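# Chance-corrected agreement between two rating passes over the chart-review
# categories (confirmed < suspected < negative, a clinical ordering used by
# the weighting schemes).
#
# Cohen's kappa corrects observed agreement by the margin-product chance
# model; weighted kappa gives partial credit for near-miss disagreements on
# the ordered scale; Gwet's AC1 replaces the chance model with one robust to
# skewed category prevalence (the "kappa paradox": near-unanimous ratings can
# yield low kappa while raw agreement is high).
#
# Variance estimators: kappa and weighted kappa use the large-sample
# delta-method formula of Fleiss, Cohen & Everitt (1969); AC1 uses Gwet's
# linearized variance. No continuity corrections.

REVIEW_CATEGORIES <- c("confirmed", "suspected", "negative")

#' Cross-tabulation of two rating passes
#'
#' @param ratings1,ratings2 Equal-length vectors of category labels
#'   (rater 1 / pass 1 in rows, rater 2 / pass 2 in columns). Intra-rater
#'   reliability uses the same operation on the two passes of one reviewer.
#' @param categories Ordered category labels; default
#'   confirmed/suspected/negative.
#' @return An `agreement_table`: q x q integer matrix with an `n` attribute.
#' @export
cross_tabulate <- function(ratings1, ratings2, categories = REVIEW_CATEGORIES) {
  if (length(ratings1) != length(ratings2))
    stop_domain("rating vectors differ in length (", length(ratings1),
                " vs ", length(ratings2), ")")
  if (length(ratings1) == 0L) stop_domain("empty rating vectors")
  unknown <- setdiff(unique(c(ratings1, ratings2)), categories)
  if (length(unknown))
    stop_domain("unknown category label(s): ", paste(unknown, collapse = ", "))
  f1 <- factor(ratings1, levels = categories)
  f2 <- factor(ratings2, levels = categories)
  agreement_table(unclass(table(f1, f2)), categories)
}

#' Construct an agreement table from a count matrix
#'
#' @param counts Square matrix of non-negative counts, rows = rater 1.
#' @param categories Ordered category labels (defaults to dimnames or
#'   the review categories for 3x3 input).
#' @return An `agreement_table`.
#' @export
agreement_table <- function(counts, categories = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) != ncol(m) || nrow(m) < 2L)
    stop_domain("agreement table must be square with >= 2 categories")
  if (any(is.na(m)) || any(m < 0)) stop_domain("counts must be non-negative")
  n <- sum(m)
  if (n <= 0) stop_domain("agreement table has no observations")
  if (is.null(categories)) {
    categories <- if (!is.null(rownames(m))) rownames(m)
    else if (nrow(m) == 3L) REVIEW_CATEGORIES
    else paste0("cat", seq_len(nrow(m)))
  }
  dimnames(m) <- list(rater1 = categories, rater2 = categories)
  structure(m, class = c("agreement_table", "matrix"), n = n)
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("<agreement_table> n =", attr(x, "n"), "\n")
  print(matrix(x, nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

agreement_coef <- function(method, estimate, se, n, level, extra = NULL) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else estimate + c(-1, 1) * z * se
  ci <- pmin(pmax(ci, -1), 1)  # coefficients live in [-1, 1]
  structure(c(list(method = method, estimate = estimate, se = se,
                   ci_low = ci[1L], ci_high = ci[2L], n = n, level = level),
              extra),
            class = "agreement_coef")
}

#' @export
print.agreement_coef <- function(x, digits = 4, ...) {
  cat("<agreement_coef> ", x$method, ": ", round(x$estimate, digits),
      " (", 100 * x$level, "% CI ", round(x$ci_low, digits), " to ",
      round(x$ci_high, digits), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

table_probs <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  n <- attr(table, "n")
  p <- matrix(table, nrow(table), ncol(table)) / n
  list(p = p, pr = rowSums(p), pc = colSums(p), n = n, q = nrow(p))
}

#' Cohen's unweighted kappa
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (diagonal
#' mass) and expected agreement `p_e` (sum of row x column margin products).
#'
#' @param table An [agreement_table()].
#' @param level Confidence level for the asymptotic interval, default 0.95.
#' @return An `agreement_coef` object.
#' @export
cohen_kappa <- function(table, level = 0.95) {
  tp <- table_probs(table)
  p <- tp$p; pr <- tp$pr; pc <- tp$pc; n <- tp$n
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps^0.5)
    stop_domain("degenerate table: expected agreement is 1, kappa undefined")
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt (1969) large-sample variance
  a <- sum(diag(p) * ((1 - pe) - (pr + pc) * (1 - po))^2)
  m <- outer(pc, pr, `+`)^2          # (p_.i + p_j.)^2 for cell (i, j)
  b <- (1 - po)^2 * (sum(p * m) - sum(diag(p) * diag(m)))
  cc <- (po * pe - 2 * pe + po)^2
  v <- (a + b - cc) / (n * (1 - pe)^4)
  agreement_coef("kappa", k, sqrt(max(v, 0)), n, level)
}

kappa_weights <- function(q, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(q), seq_len(q), `-`))
  if (scheme == "linear") 1 - d / (q - 1) else 1 - d^2 / (q - 1)^2
}

#' Weighted kappa for ordered categories
#'
#' Agreement weights `w_ij = 1 - |i-j|/(q-1)` (linear) or
#' `1 - (i-j)^2/(q-1)^2` (quadratic) give partial credit to near misses;
#' `kappa_w = (p_o* - p_e*) / (1 - p_e*)` with weighted observed and expected
#' agreement. For two categories both schemes reduce to unweighted kappa.
#'
#' @inheritParams cohen_kappa
#' @param scheme Weighting scheme, `"linear"` (default) or `"quadratic"`.
#' @return An `agreement_coef` object (the `scheme` element records which
#'   weights were used).
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic"), level = 0.95) {
  scheme <- match.arg(scheme)
  tp <- table_probs(table)
  p <- tp$p; pr <- tp$pr; pc <- tp$pc; n <- tp$n; q <- tp$q
  w <- kappa_weights(q, scheme)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (1 - pe < .Machine$double.eps^0.5)
    stop_domain("degenerate table: weighted expected agreement is 1")
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt weighted variance
  wr <- as.vector(w %*% pc)   # row-conditional expected weight
  wc <- as.vector(pr %*% w)   # column-conditional expected weight
  wij_bar <- outer(wr, wc, `+`)
  v <- (sum(p * (w * (1 - pe) - wij_bar * (1 - po))^2) -
          (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  agreement_coef(paste0("weighted_kappa_", scheme), k, sqrt(max(v, 0)), n,
                 level, extra = list(scheme = scheme))
}

#' Gwet's AC1 agreement coefficient
#'
#' Chance agreement is `p_g = sum_k pi_k (1 - pi_k) / (q - 1)` with
#' `pi_k = (row_k + col_k) / (2n)`; `AC1 = (p_o - p_g) / (1 - p_g)`. The
#' variance is Gwet's linearized estimator over items, so the interval remains
#' informative even at near-unanimous ratings where kappa collapses.
#'
#' @inheritParams cohen_kappa
#' @return An `agreement_coef` object.
#' @export
gwet_ac1 <- function(table, level = 0.95) {
  tp <- table_probs(table)
  p <- tp$p; n <- tp$n; q <- tp$q
  pik <- (tp$pr + tp$pc) / 2
  po <- sum(diag(p))
  pe <- sum(pik * (1 - pik)) / (q - 1)
  if (1 - pe < .Machine$double.eps^0.5)
    stop_domain("degenerate table: AC1 chance agreement is 1")
  ac1 <- (po - pe) / (1 - pe)
  se <- NA_real_
  if (n >= 2) {
    # expand the table into per-item rating pairs for the linearized variance
    idx <- which(matrix(table, q, q) > 0, arr.ind = TRUE)
    cnt <- matrix(table, q, q)[idx]
    i1 <- rep(idx[, 1L], cnt)
    i2 <- rep(idx[, 2L], cnt)
    pa_i <- as.numeric(i1 == i2)
    # pe_i = sum_k (r_ik / 2) (1 - pi_k) / (q - 1), r_ik = raters putting item in k
    pe_i <- ((1 - pik[i1]) + (1 - pik[i2])) / (2 * (q - 1))
    ac1_i <- (pa_i - pe) / (1 - pe)
    ac1_star <- ac1_i - 2 * (1 - ac1) * (pe_i - pe) / (1 - pe)
    v <- sum((ac1_star - ac1)^2) / (n * (n - 1))
    se <- sqrt(max(v, 0))
  }
  agreement_coef("gwet_ac1", ac1, se, n, level)
}
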