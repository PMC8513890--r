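# Study-design stages of the validation: age-stratified sampling of
# criterion-positive and criterion-negative patients with Horvitz-Thompson
# weights, consensus adjudication of duplicate reviews, breakdown reporting of
# final review categories, and assembly of the 2x2 table.

# Largest-remainder (Hamilton) apportionment of n across strata of sizes N_h.
# Ties on the fractional part are broken toward the larger stratum, then by
# stratum order, so allocation is deterministic.
allocate_proportional <- function(N_h, n) {
  stopifnot(n <= sum(N_h))
  quota <- n * N_h / sum(N_h)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, N_h, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Age-stratified random sampling of validation cases
#'
#' Draws `n_pos` patients from the criterion-positive pool and `n_neg` from
#' the criterion-negative pool (its complement among the roster), stratifying
#' both arms by age band at a reference year. Within each arm the allocation
#' is proportional to stratum size with largest-remainder rounding; sampling
#' is without replacement and each sampled case carries its Horvitz-Thompson
#' weight (stratum pool size / stratum sample size).
#'
#' Note the negative pool for criterion B or C is everyone not meeting that
#' criterion, so patients meeting A but not B fall into the negative pool;
#' this choice is reported via a message.
#'
#' @param inclusion Output of [classify_patients()].
#' @param patients Patient roster (`patient_id`, `birth_year`); roster
#'   patients absent from `inclusion` count as meeting no criterion.
#' @param criterion `"A"`, `"B"` or `"C"`.
#' @param n_pos,n_neg Sample sizes for the two arms (default 100 / 200).
#' @param band_width_years Age-band width in years, default 10.
#' @param age_ref_year Year at which age is computed (observation-window
#'   start), default 2015.
#' @param seed Integer RNG seed; draws are deterministic given the seed.
#' @return A `data.table` of sampled cases: `patient_id`, `arm`
#'   (`"criterion_positive:<X>"` or `"criterion_negative"`), `stratum`
#'   (age-band label), `weight` (>= 1).
#' @export
stratified_sample <- function(inclusion, patients, criterion = c("A", "B", "C"),
                              n_pos = 100L, n_neg = 200L,
                              band_width_years = 10L, age_ref_year = 2015L,
                              seed = NULL) {
  criterion <- match.arg(criterion)
  if (band_width_years < 1L) stop_domain("band_width_years must be >= 1")
  pts <- data.table::as.data.table(patients)[, .(patient_id = as.character(patient_id), birth_year)]
  inc <- data.table::as.data.table(inclusion)
  col <- paste0("in_", tolower(criterion))
  pos_ids <- inc$patient_id[inc[[col]]]
  pts[, in_crit := patient_id %in% pos_ids]
  age <- age_ref_year - pts$birth_year
  if (any(age < 0)) stop_domain("negative age at reference year ", age_ref_year)
  lo <- (age %/% band_width_years) * band_width_years
  pts[, stratum := sprintf("%d-%d", lo, lo + band_width_years - 1L)]

  if (criterion != "A")
    message("criterion-negative pool for IC-", criterion,
            " includes patients meeting IC-A but not IC-", criterion)

  draw_arm <- function(pool, n, arm) {
    if (nrow(pool) < n)
      stop_domain("requested ", n, " cases for arm '", arm, "' but pool has only ",
                  nrow(pool))
    sizes <- pool[, .N, by = stratum][order(stratum)]
    n_h <- allocate_proportional(sizes$N, n)
    picked <- vector("list", nrow(sizes))
    for (i in seq_len(nrow(sizes))) {
      if (n_h[i] == 0L) next
      ids <- pool[stratum == sizes$stratum[i], patient_id]
      take <- if (length(ids) == 1L) ids else sample(ids, n_h[i])
      picked[[i]] <- data.table::data.table(
        patient_id = take, arm = arm, stratum = sizes$stratum[i],
        weight = sizes$N[i] / n_h[i])
    }
    data.table::rbindlist(picked)
  }

  out <- with_seed(seed, {
    rbind(
      draw_arm(pts[in_crit == TRUE], as.integer(n_pos),
               paste0("criterion_positive:", criterion)),
      draw_arm(pts[in_crit == FALSE], as.integer(n_neg), "criterion_negative")
    )
  })
  out[]
}

#' Consensus adjudication of duplicate chart reviews
#'
#' When the two primary reviewers agree, their category stands; otherwise the
#' third reviewer's category is decisive. A disagreement with no third rating
#' available is an error naming the cases.
#'
#' @param r1,r2 Category vectors from the two primary reviewers.
#' @param r3 Optional category vector from the third reviewer (`NA` allowed
#'   where not needed).
#' @param ids Optional case identifiers used in error messages.
#' @return Character vector of final categories.
#' @export
adjudicate <- function(r1, r2, r3 = NULL, ids = NULL) {
  r1 <- as.character(r1); r2 <- as.character(r2)
  if (length(r1) != length(r2)) stop_domain("reviewer vectors differ in length")
  vals <- c(r1, r2, if (!is.null(r3)) as.character(r3)[!is.na(r3)])
  unknown <- setdiff(unique(vals), REVIEW_CATEGORIES)
  if (length(unknown))
    stop_domain("unknown category label(s): ", paste(unknown, collapse = ", "))
  final <- r1
  need3 <- r1 != r2
  if (any(need3)) {
    r3 <- if (is.null(r3)) rep(NA_character_, length(r1)) else as.character(r3)
    missing3 <- need3 & is.na(r3)
    if (any(missing3)) {
      who <- if (is.null(ids)) which(missing3) else ids[missing3]
      stop_domain("third review needed for case(s): ",
                  paste(utils::head(who, 10L), collapse = ", "))
    }
    final[need3] <- r3[need3]
  }
  final
}

#' Breakdown of final review categories and confirmed-diagnosis sources
#'
#' Summarizes adjudicated reviews into the percentage of cases confirmed by
#' each diagnosis source (a: own institution; b: IBD specialist or
#' gastroenterologist elsewhere; c: primary care, findings documented;
#' d: primary care, no findings documented), suspected, and negative.
#'
#' @param category Final categories (confirmed/suspected/negative).
#' @param source Diagnosis sources (`"a"`..`"d"`), required exactly where
#'   `category == "confirmed"`, `NA` elsewhere.
#' @return A `review_summary`: data frame with `group`, `n`, `percent`
#'   (percentages sum to 100 up to rounding of the printout).
#' @export
summarize_review <- function(category, source = NULL) {
  n <- length(category)
  if (n == 0L) stop_domain("no review results to summarize")
  unknown <- setdiff(unique(category), REVIEW_CATEGORIES)
  if (length(unknown))
    stop_domain("unknown category label(s): ", paste(unknown, collapse = ", "))
  if (is.null(source)) source <- rep(NA_character_, n)
  source <- as.character(source)
  conf <- category == "confirmed"
  if (any(conf & (is.na(source) | !source %in% c("a", "b", "c", "d"))))
    stop_domain("confirmed cases must carry a diagnosis source a-d")
  groups <- c("a", "b", "c", "d", "suspected", "negative")
  cnt <- c(vapply(c("a", "b", "c", "d"), function(s) sum(conf & source == s), 0L),
           sum(category == "suspected"),
           sum(category == "negative"))
  out <- data.frame(group = groups, n = as.integer(cnt), percent = 100 * cnt / n)
  class(out) <- c("review_summary", "data.frame")
  out
}

#' @export
print.review_summary <- function(x, ...) {
  cat("<review_summary> n =", sum(x$n), "\n")
  df <- as.data.frame(x)
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Assemble the 2x2 contingency table from a validation sample
#'
#' Test-positive is membership in the criterion-positive arm; disease-positive
#' is a final review category of `confirmed` (case definition
#' `"confirmed_only"`) or `confirmed`/`suspected`
#' (`"confirmed_or_suspected"`). Counts are unweighted; weighted extrapolation
#' is a separate step ([extrapolate_2x2()]).
#'
#' @param sample Output of [stratified_sample()].
#' @param reviews Data frame `patient_id`, `category` of final adjudicated
#'   categories covering every sampled case.
#' @param case_def `"confirmed_only"` or `"confirmed_or_suspected"`.
#' @return A [contingency_2x2()].
#' @export
build_2x2 <- function(sample, reviews,
                      case_def = c("confirmed_only", "confirmed_or_suspected")) {
  case_def <- match.arg(case_def)
  s <- data.table::as.data.table(sample)
  if (nrow(s) == 0L) stop_domain("empty validation sample")
  rv <- data.table::as.data.table(reviews)
  cat_map <- rv$category[match(s$patient_id, rv$patient_id)]
  if (anyNA(cat_map))
    stop_domain("no final category for case(s): ",
                paste(utils::head(s$patient_id[is.na(cat_map)], 10L), collapse = ", "))
  unknown <- setdiff(unique(cat_map), REVIEW_CATEGORIES)
  if (length(unknown))
    stop_domain("unknown category label(s): ", paste(unknown, collapse = ", "))
  disease_pos <- if (case_def == "confirmed_only") cat_map == "confirmed"
  else cat_map %in% c("confirmed", "suspected")
  test_pos <- startsWith(s$arm, "criterion_positive")
  contingency_2x2(
    tp = sum(test_pos & disease_pos),
    fp = sum(test_pos & !disease_pos),
    tn = sum(!test_pos & !disease_pos),
    fn = sum(!test_pos & disease_pos)
  )
}
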