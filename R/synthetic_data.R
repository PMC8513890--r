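# Seeded generator of a hospital-scale synthetic claims database with known
# ground truth, plus a simulator of the duplicate chart-review process.
#
# The generative model, per patient: a true status (Crohn's disease, one of a
# spectrum of mimic diseases that attract K50 codes, or neither), a set of
# visit months inside the observation window, and per visit month the billing
# lines a hospital would file: a background diagnosis, possibly a confirmed
# K50-prefix code (always for no-one, rarely for mimics, usually for true CD),
# same-month CD prescription codes conditional on true disease, occasional
# surgery codes in prescription-free coded months, and for intestinal-Behcet
# mimics a same-month M35 code that exercises the exclusion rule. Patients
# without disease can receive suspected-flagged (rule-out) K50 lines, which
# never qualify.

MIMIC_LABELS <- c("infectious_enterocolitis", "intestinal_behcet",
                  "drug_induced_enterocolitis", "intestinal_tuberculosis",
                  "unspecified_stenosis", "cirrhosis")

MIMIC_OWN_CODE <- c(infectious_enterocolitis = "A099",
                    intestinal_behcet = "M352",
                    drug_induced_enterocolitis = "K529",
                    intestinal_tuberculosis = "A188",
                    unspecified_stenosis = "K566",
                    cirrhosis = "K746")

K50_SUBCODES <- c("K500", "K501", "K508", "K509")
BACKGROUND_DX <- c("J069", "I109", "E119", "M545", "K219", "J459", "E785", "K590")

#' Default reviewer confusion matrix
#'
#' Row-stochastic 3x3 matrix over confirmed/suspected/negative: rows index the
#' chart truth, columns the category a reviewer records. The default diagonal
#' (0.97/0.93/0.97) reflects experienced reviewers with small, mostly
#' adjacent-category error.
#'
#' @return A 3x3 matrix with category dimnames.
#' @export
default_reviewer_confusion <- function() {
  m <- matrix(c(0.97, 0.02, 0.01,
                0.04, 0.93, 0.03,
                0.01, 0.02, 0.97),
              nrow = 3, byrow = TRUE,
              dimnames = list(truth = REVIEW_CATEGORIES,
                              rated = REVIEW_CATEGORIES))
  m
}

check_prob <- function(cfg, fields) {
  for (f in fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_domain("sim_config: ", f, " must be a single probability in [0, 1]")
  }
}

#' Configuration of the synthetic claims generator
#'
#' Defaults emulate, at desk scale, a single specialist hospital whose
#' claims feed the validation design: ~20,000 visitors over a five-year
#' window, a small population of true Crohn's disease patients who are coded
#' K50 at most visits and co-prescribed CD drugs, and a smaller population of
#' mimic diseases (spectrum in the proportions 4:2:1:1:1:1 across infectious
#' enterocolitis, intestinal Behcet's disease, drug-induced enterocolitis,
#' intestinal tuberculosis, unspecified stenosis and cirrhosis) that attract
#' K50 codes occasionally and CD prescriptions rarely. The defaults are
#' calibrated so that roughly 83% of patients meeting the diagnosis-code-only
#' criterion truly have CD, rising above 95% once same-month prescriptions
#' are required.
#'
#' @param n_patients Number of roster patients.
#' @param prevalence_cd Probability a patient truly has CD.
#' @param prevalence_mimic Probability a patient has a mimic disease.
#' @param mimic_spectrum Named probability masses over the mimic labels
#'   (must sum to 1).
#' @param p_k50_given_cd,p_k50_given_mimic Per-visit-month probability of a
#'   confirmed K50 code.
#' @param p_excl_code_given_behcet Per-month probability an intestinal-Behcet
#'   mimic also carries a confirmed M35 code.
#' @param p_rx_given_cd_coded,p_rx_given_mimic_coded Probability a K50-coded
#'   month also carries a CD prescription code.
#' @param p_pr_given_rx_absent Probability of a CD surgery code in a coded
#'   month without prescriptions.
#' @param p_k50_suspected_given_none Per-visit-month probability a disease-free
#'   patient receives a rule-out (suspected-flagged) K50 line.
#' @param p_suspected_given_mimic Probability a mimic patient's chart reads
#'   `suspected` rather than `negative` (equivocal work-up).
#' @param mean_months_cd,mean_months_other Poisson means for visit months
#'   beyond the first (true CD patients visit near-monthly; others rarely).
#' @param reviewer_confusion Row-stochastic 3x3 reviewer error matrix.
#' @param source_distribution Probabilities over confirmed-diagnosis sources
#'   a/b/c/d.
#' @param window [obs_window()] of billable months.
#' @param seed Integer seed; [generate_claims()] is deterministic given it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_patients = 20000L,
                       prevalence_cd = 0.007,
                       prevalence_mimic = 0.0022,
                       mimic_spectrum = c(infectious_enterocolitis = 0.4,
                                          intestinal_behcet = 0.2,
                                          drug_induced_enterocolitis = 0.1,
                                          intestinal_tuberculosis = 0.1,
                                          unspecified_stenosis = 0.1,
                                          cirrhosis = 0.1),
                       p_k50_given_cd = 0.9,
                       p_k50_given_mimic = 0.3,
                       p_excl_code_given_behcet = 0.5,
                       p_rx_given_cd_coded = 0.85,
                       p_rx_given_mimic_coded = 0.08,
                       p_pr_given_rx_absent = 0.05,
                       p_k50_suspected_given_none = 0.002,
                       p_suspected_given_mimic = 0.41,
                       mean_months_cd = 12,
                       mean_months_other = 3,
                       reviewer_confusion = default_reviewer_confusion(),
                       source_distribution = c(a = 0.75, b = 0.24, c = 0, d = 0.01),
                       window = obs_window("2015-01", "2019-12"),
                       seed = 20150101L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (cfg$n_patients < 1) stop_domain("sim_config: n_patients must be >= 1")
  check_prob(cfg, c("prevalence_cd", "prevalence_mimic", "p_k50_given_cd",
                    "p_k50_given_mimic", "p_excl_code_given_behcet",
                    "p_rx_given_cd_coded", "p_rx_given_mimic_coded",
                    "p_pr_given_rx_absent", "p_k50_suspected_given_none",
                    "p_suspected_given_mimic"))
  if (cfg$prevalence_cd + cfg$prevalence_mimic > 1)
    stop_domain("sim_config: prevalence_cd + prevalence_mimic must be <= 1")
  if (!setequal(names(cfg$mimic_spectrum), MIMIC_LABELS))
    stop_domain("sim_config: mimic_spectrum must be named over: ",
                paste(MIMIC_LABELS, collapse = ", "))
  if (any(cfg$mimic_spectrum < 0) || abs(sum(cfg$mimic_spectrum) - 1) > 1e-8)
    stop_domain("sim_config: mimic_spectrum masses must be non-negative and sum to 1")
  validate_confusion(cfg$reviewer_confusion)
  if (length(cfg$source_distribution) != 4L || any(cfg$source_distribution < 0) ||
      abs(sum(cfg$source_distribution) - 1) > 1e-8)
    stop_domain("sim_config: source_distribution must be 4 probabilities summing to 1")
  if (cfg$mean_months_cd < 0 || cfg$mean_months_other < 0)
    stop_domain("sim_config: mean visit months must be >= 0")
  stopifnot(inherits(cfg$window, "obs_window"))
  cfg
}

validate_confusion <- function(m) {
  if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 3L)
    stop_domain("reviewer confusion must be a 3x3 matrix over ",
                paste(REVIEW_CATEGORIES, collapse = "/"))
  if (any(is.na(m)) || any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
    stop_domain("reviewer confusion rows must be non-negative and sum to 1")
  invisible(m)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n_patients =", x$n_patients,
      "| prevalence: CD", x$prevalence_cd, ", mimic", x$prevalence_mimic, "\n")
  cat("  window ", month_label(x$window$start), "..", month_label(x$window$end),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic claims database with known ground truth
#'
#' @param config A [sim_config()].
#' @return A `cd_sim` list:
#'   * `patients` — roster (`patient_id`, `birth_year`, `sex`);
#'   * `claims` — claim lines (`patient_id`, `month`, `code_type`, `code`,
#'     `suspected`, plus `month_id`);
#'   * `gold` — one row per patient: `true_status` (`"CD"`,
#'     `"mimic:<label>"`, `"none"`), `chart_category`
#'     (confirmed/suspected/negative) and `source` (a-d, present iff
#'     confirmed);
#'   * `config` — the configuration used.
#' Deterministic given `config$seed`.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_claims_impl(config))
}

generate_claims_impl <- function(cfg) {
  n <- as.integer(cfg$n_patients)
  W <- window_length(cfg$window)
  ids <- sprintf("P%06d", seq_len(n))

  # true status
  u <- runif(n)
  status <- rep("none", n)
  status[u < cfg$prevalence_cd] <- "CD"
  is_mimic <- u >= cfg$prevalence_cd & u < cfg$prevalence_cd + cfg$prevalence_mimic
  mimic_lab <- rep(NA_character_, n)
  if (any(is_mimic)) {
    mimic_lab[is_mimic] <- sample(MIMIC_LABELS, sum(is_mimic), replace = TRUE,
                                  prob = cfg$mimic_spectrum[MIMIC_LABELS])
    status[is_mimic] <- "mimic"
  }

  # roster: age structure differs by status (IBD skews young-adult)
  ref_year <- cfg$window$start %/% 12L
  age <- ifelse(status == "none",
                round(rnorm(n, 48, 20)),
                round(rnorm(n, 44, 14)))
  age <- pmin(pmax(age, ifelse(status == "none", 0, 16)), 95)
  sex_p <- ifelse(status == "CD", 0.70, ifelse(status == "mimic", 0.55, 0.5))
  sex <- ifelse(runif(n) < sex_p, "M", "F")
  patients <- data.table::data.table(patient_id = ids,
                                     birth_year = as.integer(ref_year - age),
                                     sex = sex)

  # visit months (>= 1 per patient, without replacement inside the window)
  lambda <- ifelse(status == "CD", cfg$mean_months_cd, cfg$mean_months_other)
  n_months <- pmin(1L + rpois(n, lambda), W)
  pm <- data.table::data.table(
    patient_id = rep(ids, n_months),
    status = rep(status, n_months),
    mimic_lab = rep(mimic_lab, n_months),
    month_id = cfg$window$start +
      unlist(lapply(n_months, function(k) sample.int(W, k) - 1L), use.names = FALSE)
  )
  np <- nrow(pm)

  # per-month events
  p_k50 <- ifelse(pm$status == "CD", cfg$p_k50_given_cd,
                  ifelse(pm$status == "mimic", cfg$p_k50_given_mimic, 0))
  coded <- runif(np) < p_k50
  susp_k50 <- pm$status == "none" & runif(np) < cfg$p_k50_suspected_given_none
  p_rx <- ifelse(pm$status == "CD", cfg$p_rx_given_cd_coded, cfg$p_rx_given_mimic_coded)
  rx <- coded & runif(np) < p_rx
  pr <- coded & !rx & runif(np) < cfg$p_pr_given_rx_absent
  behcet_m35 <- pm$mimic_lab %in% "intestinal_behcet" &
    runif(np) < cfg$p_excl_code_given_behcet

  cb <- default_codebook()
  line <- function(keep, code_type, code, suspected = FALSE) {
    data.table::data.table(patient_id = pm$patient_id[keep],
                           month_id = pm$month_id[keep],
                           code_type = code_type,
                           code = code,
                           suspected = suspected)
  }
  all_rows <- rep(TRUE, np)
  # Behcet's own disease code IS the M35 exclusion code, drawn above; every
  # other mimic bills its own diagnosis each visit month.
  own <- !is.na(pm$mimic_lab) & pm$mimic_lab != "intestinal_behcet"
  claims <- data.table::rbindlist(list(
    line(all_rows, "DX", sample(BACKGROUND_DX, np, replace = TRUE)),
    line(coded, "DX", sample(K50_SUBCODES, sum(coded), replace = TRUE)),
    line(susp_k50, "DX", sample(K50_SUBCODES, sum(susp_k50), replace = TRUE),
         suspected = TRUE),
    line(behcet_m35, "DX", MIMIC_OWN_CODE[["intestinal_behcet"]]),
    line(own, "DX", MIMIC_OWN_CODE[pm$mimic_lab[own]]),
    line(rx, "RX", sample(cb$cd_rx_codes, sum(rx), replace = TRUE)),
    line(pr, "PR", sample(cb$cd_pr_codes, sum(pr), replace = TRUE))
  ))
  claims[, month := month_label(month_id)]
  data.table::setcolorder(claims, c("patient_id", "month", "code_type", "code",
                                    "suspected", "month_id"))
  data.table::setkey(claims, patient_id, month_id)

  # gold standard: chart truth and confirmed-diagnosis source
  chart <- rep("negative", n)
  chart[status == "CD"] <- "confirmed"
  chart[status == "mimic" & runif(n) < cfg$p_suspected_given_mimic] <- "suspected"
  src <- rep(NA_character_, n)
  conf <- chart == "confirmed"
  if (any(conf))
    src[conf] <- sample(c("a", "b", "c", "d"), sum(conf), replace = TRUE,
                        prob = cfg$source_distribution)
  gold <- data.table::data.table(
    patient_id = ids,
    true_status = ifelse(status == "mimic", paste0("mimic:", mimic_lab), status),
    chart_category = chart,
    source = src
  )

  structure(list(patients = patients, claims = claims, gold = gold,
                 config = cfg),
            class = "cd_sim")
}

#' @export
print.cd_sim <- function(x, ...) {
  cat("<cd_sim>", nrow(x$patients), "patients,", nrow(x$claims), "claim lines\n")
  print(table(truth = x$gold$true_status))
  invisible(x)
}

#' Simulate independent chart reviews
#'
#' Each reviewer's recorded category is drawn independently from the row of
#' the confusion matrix indexed by the patient's chart category.
#'
#' @param gold Gold table (or subset) with `patient_id` and `chart_category`.
#' @param confusion Row-stochastic 3x3 matrix, rows/columns ordered
#'   confirmed/suspected/negative; default [default_reviewer_confusion()].
#' @param seed Integer seed; draws are deterministic given it.
#' @param raters Number of independent raters to simulate (default 2; use 3
#'   to also draw the tie-breaking reviewer).
#' @return A `data.table`: `patient_id`, `rater1`, ..., `rater<raters>`.
#' @export
simulate_review <- function(gold, confusion = default_reviewer_confusion(),
                            seed = NULL, raters = 2L) {
  validate_confusion(confusion)
  g <- data.table::as.data.table(gold)
  if (nrow(g) == 0L) {
    out <- data.table::data.table(patient_id = character())
    for (r in seq_len(raters)) out[, (paste0("rater", r)) := character()]
    return(out[])
  }
  row_idx <- match(g$chart_category, REVIEW_CATEGORIES)
  if (anyNA(row_idx)) stop_domain("gold chart_category outside ",
                                  paste(REVIEW_CATEGORIES, collapse = "/"))
  with_seed(seed, {
    out <- data.table::data.table(patient_id = g$patient_id)
    cum <- t(apply(confusion, 1L, cumsum))
    for (r in seq_len(raters)) {
      u <- runif(nrow(g))
      pick <- 1L + (u > cum[row_idx, 1L]) + (u > cum[row_idx, 2L])
      out[, (paste0("rater", r)) := REVIEW_CATEGORIES[pick]]
    }
    out[]
  })
}
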