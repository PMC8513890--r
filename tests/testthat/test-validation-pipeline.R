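# small deterministic pool builders
make_pool <- function(n, birth_years, pos_frac = 1) {
  data.frame(patient_id = sprintf("Q%04d", seq_len(n)),
             birth_year = birth_years,
             sex = "U")
}
inclusion_for <- function(patients, pos_ids) {
  data.frame(patient_id = patients$patient_id,
             in_a = patients$patient_id %in% pos_ids,
             in_b = FALSE, in_c = FALSE)
}

test_that("proportional allocation with largest-remainder rounding (150/50 -> 75/25)", {
  pts <- make_pool(400, c(rep(1975, 150), rep(1945, 50), rep(1990, 200)))
  inc <- inclusion_for(pts, pts$patient_id[1:200])
  s <- stratified_sample(inc, pts, "A", n_pos = 100, n_neg = 200, seed = 41)
  pos <- s[startsWith(s$arm, "criterion_positive"), ]
  expect_equal(nrow(pos), 100L)
  expect_equal(unname(table(pos$stratum)[c("40-49", "70-79")]), c(75L, 25L),
               ignore_attr = TRUE)
  # Horvitz-Thompson weights recover the pool size
  expect_equal(sum(pos$weight), 150 + 50)
  expect_true(all(s$weight >= 1))
})

test_that("taking the whole single-stratum pool gives unit weights", {
  pts <- make_pool(400, rep(1980, 400))
  inc <- inclusion_for(pts, pts$patient_id[1:200])
  s <- stratified_sample(inc, pts, "A", n_pos = 200, n_neg = 200, seed = 42)
  pos <- s[startsWith(s$arm, "criterion_positive"), ]
  expect_setequal(pos$patient_id, pts$patient_id[1:200])
  expect_true(all(s$weight == 1))
})

test_that("a pool smaller than the request is an explicit error, not a silent take-all", {
  pts <- make_pool(150, rep(1980, 150))
  inc <- inclusion_for(pts, pts$patient_id[1:50])
  expect_error(stratified_sample(inc, pts, "A", n_pos = 100, n_neg = 50, seed = 1),
               "pool has only 50")
})

test_that("samples are duplicate-free, seeded, and hit allocation fractions", {
  pts <- make_pool(300, c(rep(1975, 180), rep(1950, 120)))
  inc <- inclusion_for(pts, pts$patient_id)  # all positive
  one <- function(seed) stratified_sample(inc, pts, "A", n_pos = 50, n_neg = 0,
                                          seed = seed)
  s1 <- one(7); s2 <- one(7); s3 <- one(8)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
  expect_equal(anyDuplicated(s1$patient_id), 0L)

  # over 200 seeded draws, each patient's inclusion frequency matches n_h/N_h
  draws <- lapply(1:200, one)
  alloc <- c("40-49" = 30 / 180, "60-69" = 20 / 120)  # proportional: 30/20 of 50
  for (st in names(alloc)) {
    ids_in <- pts$patient_id[pts$birth_year == c("40-49" = 1975, "60-69" = 1950)[[st]]]
    freq <- mean(vapply(draws, function(d) mean(ids_in %in% d$patient_id), 0))
    se <- sqrt(alloc[[st]] * (1 - alloc[[st]]) / 200)
    expect_lt(abs(freq - alloc[[st]]), 3 * se)
  }
})

test_that("adjudication takes agreement, defers to the third reviewer, and errors otherwise", {
  expect_equal(adjudicate("confirmed", "confirmed"), "confirmed")
  expect_equal(adjudicate("confirmed", "negative", "suspected"), "suspected")
  expect_error(adjudicate("suspected", "negative"), "third review")
  expect_error(adjudicate("suspected", "negative", NA_character_, ids = "P9"), "P9")
  # vectorized mix
  fin <- adjudicate(c("confirmed", "confirmed", "negative"),
                    c("confirmed", "suspected", "negative"),
                    c(NA, "confirmed", NA))
  expect_equal(fin, c("confirmed", "confirmed", "negative"))
  expect_error(adjudicate("confirmed", "maybe", "confirmed"), "unknown category")
})

test_that("review summary reports the source/suspected/negative breakdown in percent", {
  category <- c(rep("confirmed", 83), rep("suspected", 7), rep("negative", 10))
  source <- c(rep("a", 62), rep("b", 20), rep("d", 1), rep(NA, 17))
  sm <- summarize_review(category, source)
  expect_equal(sm$percent[sm$group %in% c("a", "b", "c", "d", "suspected", "negative")],
               c(62, 20, 0, 1, 7, 10))
  expect_equal(sum(sm$percent), 100)

  all_a <- summarize_review(rep("confirmed", 5), rep("a", 5))
  expect_equal(all_a$percent[all_a$group == "a"], 100)
  half <- summarize_review(c("confirmed", "negative"), c("a", NA))
  expect_equal(half$percent[half$group %in% c("a", "negative")], c(50, 50))
  expect_error(summarize_review("confirmed", NA), "source")
})

test_that("the 2x2 table classifies arms vs case definitions as in a validation study", {
  sample <- data.frame(
    patient_id = sprintf("S%03d", 1:300),
    arm = c(rep("criterion_positive:A", 100), rep("criterion_negative", 200)),
    stratum = "all", weight = 1)
  reviews <- data.frame(
    patient_id = sample$patient_id,
    category = c(rep("confirmed", 83), rep("suspected", 7), rep("negative", 10),
                 rep("negative", 200)))
  t_conf <- build_2x2(sample, reviews, "confirmed_only")
  expect_equal(c(t_conf$tp, t_conf$fp, t_conf$tn, t_conf$fn), c(83, 17, 200, 0))
  t_cs <- build_2x2(sample, reviews, "confirmed_or_suspected")
  expect_equal(c(t_cs$tp, t_cs$fp, t_cs$tn, t_cs$fn), c(90, 10, 200, 0))
  # arm totals are preserved under every case definition, and TP only grows
  for (tab in list(t_conf, t_cs)) {
    expect_equal(tab$tp + tab$fp, 100)
    expect_equal(tab$tn + tab$fn, 200)
  }
  expect_gte(t_cs$tp, t_conf$tp)
  expect_error(build_2x2(sample[0, ], reviews), "empty")
  expect_error(build_2x2(sample, reviews[-1, ]), "S001")
})
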