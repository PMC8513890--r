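# Independent oracles and fixture builders shared across tests. Each oracle
# re-derives its quantity from first principles (loops, pair enumeration,
# leave-one-out), never by calling the implementation it checks.

# -- month-level criteria: naive line-by-line evaluator -----------------------
brute_month_flags <- function(lines, cb) {
  has_cd <- FALSE; has_ex <- FALSE; has_rx <- FALSE; has_pr <- FALSE
  for (i in seq_len(nrow(lines))) {
    ct <- lines$code_type[i]; code <- lines$code[i]; susp <- lines$suspected[i]
    if (ct == "DX" && !susp) {
      for (p in cb$cd_dx_prefixes)
        if (substr(code, 1, nchar(p)) == p) has_cd <- TRUE
      for (p in cb$excl_dx_prefixes)
        if (substr(code, 1, nchar(p)) == p) has_ex <- TRUE
    }
    if (ct == "RX" && code %in% cb$cd_rx_codes) has_rx <- TRUE
    if (ct == "PR" && code %in% cb$cd_pr_codes) has_pr <- TRUE
  }
  a <- has_cd && !has_ex
  c(meets_a = a, meets_b = a && has_rx, meets_c = a && (has_rx || has_pr))
}

tiny_codebook <- function() {
  codebook(cd_dx_prefixes = "K50",
           excl_dx_prefixes = c("K51", "M35"),
           cd_rx_codes = c("RXCD1", "RXCD2"),
           cd_pr_codes = "PRCD1")
}

# random single-month claim-line sets exercising every rule interaction
random_month_lines <- function(n_lines) {
  dx_pool <- c("K500", "K509", "K51", "K519", "M352", "J069", "K5")
  rx_pool <- c("RXCD1", "RXCD2", "RXOTHER")
  pr_pool <- c("PRCD1", "PROTHER")
  ct <- sample(c("DX", "RX", "PR"), n_lines, replace = TRUE, prob = c(.6, .25, .15))
  code <- character(n_lines)
  code[ct == "DX"] <- sample(dx_pool, sum(ct == "DX"), replace = TRUE)
  code[ct == "RX"] <- sample(rx_pool, sum(ct == "RX"), replace = TRUE)
  code[ct == "PR"] <- sample(pr_pool, sum(ct == "PR"), replace = TRUE)
  data.frame(code_type = ct, code = code,
             suspected = ct == "DX" & runif(n_lines) < 0.3)
}

# random multi-patient claims table (one draw covers many patient-months)
random_claims_table <- function(n_patients, months_per_patient = 10L,
                                lines_per_month = 3L) {
  rows <- list()
  k <- 0L
  for (p in seq_len(n_patients)) {
    for (m in sample(0:59, months_per_patient)) {
      lines <- random_month_lines(sample.int(lines_per_month, 1L))
      lines$patient_id <- sprintf("P%04d", p)
      lines$month <- sprintf("%04d-%02d", 2015L + m %/% 12L, m %% 12L + 1L)
      k <- k + 1L
      rows[[k]] <- lines
    }
  }
  data.table::rbindlist(rows)[, .(patient_id, month, code_type, code, suspected)]
}

# -- agreement coefficients from an expanded list of rating pairs -------------
expand_pairs <- function(tab) {
  q <- nrow(tab)
  idx <- which(matrix(tab, q, q) >= 0, arr.ind = TRUE)
  r1 <- integer(0); r2 <- integer(0)
  for (k in seq_len(nrow(idx))) {
    cnt <- matrix(tab, q, q)[idx[k, 1], idx[k, 2]]
    if (cnt > 0) {
      r1 <- c(r1, rep(idx[k, 1], cnt))
      r2 <- c(r2, rep(idx[k, 2], cnt))
    }
  }
  list(r1 = unname(r1), r2 = unname(r2), q = q)
}

pairs_kappa <- function(pairs) {
  n <- length(pairs$r1)
  po <- mean(pairs$r1 == pairs$r2)
  pe <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    pe <- pe + (pairs$r1[i] == pairs$r2[j])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

pairs_weighted_kappa <- function(pairs, scheme = "linear") {
  q <- pairs$q; n <- length(pairs$r1)
  w <- function(i, j) {
    if (scheme == "linear") 1 - abs(i - j) / (q - 1) else 1 - (i - j)^2 / (q - 1)^2
  }
  po <- mean(mapply(w, pairs$r1, pairs$r2))
  pe <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) pe <- pe + w(pairs$r1[i], pairs$r2[j])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

pairs_ac1 <- function(pairs) {
  q <- pairs$q; n <- length(pairs$r1)
  po <- mean(pairs$r1 == pairs$r2)
  pik <- vapply(seq_len(q), function(k)
    (sum(pairs$r1 == k) + sum(pairs$r2 == k)) / (2 * n), 0)
  pe <- sum(pik * (1 - pik)) / (q - 1)
  (po - pe) / (1 - pe)
}

# leave-one-out jackknife standard error of AC1 computed from pairs
jackknife_ac1_se <- function(tab) {
  pairs <- expand_pairs(tab)
  n <- length(pairs$r1)
  theta <- vapply(seq_len(n), function(i) {
    sub <- list(r1 = pairs$r1[-i], r2 = pairs$r2[-i], q = pairs$q)
    pairs_ac1(sub)
  }, 0)
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

random_agreement_table <- function(n_items, q = 3L) {
  r1 <- sample.int(q, n_items, replace = TRUE)
  agree <- runif(n_items) < 0.6
  r2 <- ifelse(agree, r1, sample.int(q, n_items, replace = TRUE))
  m <- matrix(0L, q, q)
  for (i in seq_len(n_items)) m[r1[i], r2[i]] <- m[r1[i], r2[i]] + 1L
  agreement_table(m, paste0("cat", seq_len(q)))
}

run_validation_pipeline <- function(cfg, criterion, cb = default_codebook(),
                                    case_def = "confirmed_only") {
  sim <- generate_claims(cfg)
  inc <- classify_patients(sim$claims, cb, cfg$window)
  s <- suppressMessages(stratified_sample(inc, sim$patients, criterion,
                                          n_pos = 100, n_neg = 200,
                                          seed = cfg$seed + 1L))
  g <- sim$gold[match(s$patient_id, sim$gold$patient_id), ]
  rv <- simulate_review(g, cfg$reviewer_confusion, seed = cfg$seed + 2L, raters = 3L)
  fin <- adjudicate(rv$rater1, rv$rater2, rv$rater3, ids = rv$patient_id)
  tab <- build_2x2(s, data.frame(patient_id = rv$patient_id, category = fin), case_def)
  list(sim = sim, inclusion = inc, sample = s, final = fin, table = tab,
       metrics = diagnostic_metrics(tab))
}

metric_of <- function(m, which) m$estimate[m$metric == which]
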