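# Case-identification algorithms over monthly claims.
#
# IC-A: a confirmed target diagnosis code (K50 prefix) in some month, with no
#       confirmed exclusion code (K51/M35 prefix) in that same month. The
#       suspected-diagnosis flag marks rule-out codes, which never qualify —
#       and a suspected-flagged exclusion code does not veto the month either.
# IC-B: IC-A plus a disease-specific prescription code in the same month.
# IC-C: IC-A plus a prescription OR surgical code in the same month.
# Hence, month-wise and patient-wise, B implies C implies A.

#' Evaluate the inclusion criteria for one patient-month
#'
#' @param lines Data frame of claim lines sharing one patient and month
#'   (columns `code_type`, `code`, `suspected`; codes normalized; optional
#'   `patient_id`/`month` columns are checked for uniqueness).
#' @param cb A [codebook()].
#' @return Named logical vector `c(meets_a=, meets_b=, meets_c=)`.
#' @export
evaluate_month <- function(lines, cb) {
  stopifnot(inherits(cb, "codebook"))
  lines <- as.data.frame(lines)
  for (col in c("patient_id", "month")) {
    if (col %in% names(lines) && length(unique(lines[[col]])) > 1L)
      stop_domain("evaluate_month: lines span multiple values of ", col)
  }
  if (nrow(lines) == 0L)
    return(c(meets_a = FALSE, meets_b = FALSE, meets_c = FALSE))
  conf_dx <- lines$code_type == "DX" & !as.logical(lines$suspected)
  a <- any(conf_dx & code_matches(lines$code, cb$cd_dx_prefixes)) &&
    !any(conf_dx & code_matches(lines$code, cb$excl_dx_prefixes))
  rx <- any(lines$code_type == "RX" & lines$code %in% cb$cd_rx_codes)
  pr <- any(lines$code_type == "PR" & lines$code %in% cb$cd_pr_codes)
  c(meets_a = a, meets_b = a && rx, meets_c = a && (rx || pr))
}

#' Classify every patient in a claims table against IC-A/B/C
#'
#' Evaluates each patient-month, then aggregates: a patient is included under
#' a criterion when at least `min_qualifying_months` of their months qualify
#' (default 1; repeat-month protocols raise it). `first_month_x` is the month
#' in which the criterion is first satisfied (the `min_qualifying_months`-th
#' qualifying month).
#'
#' @param claims Claims table as returned by [read_claims()] or
#'   [generate_claims()].
#' @param cb A [codebook()].
#' @param window Optional [obs_window()]; lines outside it are ignored.
#' @param min_qualifying_months Minimum number of qualifying months (>= 1).
#' @return A `data.table`, one row per patient with any in-window claims:
#'   `patient_id, in_a, in_b, in_c, first_month_a, first_month_b,
#'   first_month_c` (month labels, `NA` when not included).
#' @export
classify_patients <- function(claims, cb, window = NULL, min_qualifying_months = 1L) {
  stopifnot(inherits(cb, "codebook"))
  k <- as.integer(min_qualifying_months)
  if (is.na(k) || k < 1L) stop_domain("min_qualifying_months must be >= 1")
  dt <- data.table::as.data.table(claims)
  if (!"month_id" %in% names(dt)) dt <- dt[, month_id := month_id(month)]
  if (!is.null(window)) {
    stopifnot(inherits(window, "obs_window"))
    dt <- dt[month_id >= window$start & month_id <= window$end]
  }
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      patient_id = character(), in_a = logical(), in_b = logical(), in_c = logical(),
      first_month_a = character(), first_month_b = character(), first_month_c = character()))
  }
  susp <- as.logical(dt$suspected)
  dt[, hit_cd := code_type == "DX" & !susp & code_matches(code, cb$cd_dx_prefixes)]
  dt[, hit_ex := code_type == "DX" & !susp & code_matches(code, cb$excl_dx_prefixes)]
  dt[, hit_rx := code_type == "RX" & code %in% cb$cd_rx_codes]
  dt[, hit_pr := code_type == "PR" & code %in% cb$cd_pr_codes]

  bym <- dt[, .(meets_a = any(hit_cd) && !any(hit_ex),
                rx = any(hit_rx), pr = any(hit_pr)),
            by = .(patient_id, month_id)]
  bym[, meets_b := meets_a & rx]
  bym[, meets_c := meets_a & (rx | pr)]

  kth <- function(mid, flag) {
    m <- sort(mid[flag])
    if (length(m) >= k) m[k] else NA_integer_
  }
  res <- bym[, .(
    first_a = kth(month_id, meets_a),
    first_b = kth(month_id, meets_b),
    first_c = kth(month_id, meets_c)
  ), by = patient_id]
  out <- res[, .(
    patient_id,
    in_a = !is.na(first_a), in_b = !is.na(first_b), in_c = !is.na(first_c),
    first_month_a = month_label(first_a),
    first_month_b = month_label(first_b),
    first_month_c = month_label(first_c)
  )]
  data.table::setkey(out, patient_id)
  out[]
}

#' Count patients meeting each inclusion criterion
#'
#' @param results Output of [classify_patients()].
#' @return A `cohort_counts` object: `n_total` (patients classified), `n_a`,
#'   `n_b`, `n_c`. By construction `n_b <= n_c <= n_a`.
#' @export
cohort_counts <- function(results) {
  res <- data.table::as.data.table(results)
  out <- structure(list(
    n_total = nrow(res),
    n_a = if (nrow(res)) sum(res$in_a) else 0L,
    n_b = if (nrow(res)) sum(res$in_b) else 0L,
    n_c = if (nrow(res)) sum(res$in_c) else 0L
  ), class = "cohort_counts")
  out
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat("<cohort_counts> patients:", x$n_total,
      "| IC-A:", x$n_a, "| IC-B:", x$n_b, "| IC-C:", x$n_c, "\n")
  invisible(x)
}
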