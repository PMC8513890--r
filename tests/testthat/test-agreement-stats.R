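balanced2 <- agreement_table(matrix(c(45, 5, 5, 45), 2, byrow = TRUE), c("x", "y"))
skewed2 <- agreement_table(matrix(c(80, 5, 10, 5), 2, byrow = TRUE), c("x", "y"))
mixed3 <- agreement_table(matrix(c(40, 5, 0, 5, 30, 5, 0, 5, 10), 3, byrow = TRUE))

test_that("cross-tabulation counts rating pairs and validates inputs", {
  tab <- cross_tabulate(c("confirmed", "suspected"), c("confirmed", "negative"))
  expect_equal(tab["confirmed", "confirmed"], 1L, ignore_attr = TRUE)
  expect_equal(tab["suspected", "negative"], 1L, ignore_attr = TRUE)
  expect_equal(attr(tab, "n"), 2L)
  ident <- cross_tabulate(rep(c("confirmed", "suspected", "negative"), 2),
                          rep(c("confirmed", "suspected", "negative"), 2))
  expect_equal(sum(diag(ident)), attr(ident, "n"))
  expect_error(cross_tabulate(character(), character()), class = "cdclaims_domain_error")
  expect_error(cross_tabulate("confirmed", c("confirmed", "negative")),
               class = "cdclaims_domain_error")
  expect_error(cross_tabulate("confirmed", "perhaps"), "unknown category")
})

test_that("kappa matches hand evaluation, its limits, and the frozen reference values", {
  k <- cohen_kappa(balanced2)
  expect_equal(k$estimate, 0.8)          # p_o = .9, p_e = .5
  expect_equal(k$se, 0.06, tolerance = 1e-9)

  # perfect diagonal
  expect_equal(cohen_kappa(agreement_table(diag(c(7, 3, 5))))$estimate, 1)
  # independence: table equal to the outer product of its margins
  indep <- agreement_table(matrix(c(40, 10, 40, 10), 2, byrow = TRUE), c("x", "y"))
  expect_equal(cohen_kappa(indep)$estimate, 0)
  # frozen large-sample SEs (independent reference implementation)
  k3 <- cohen_kappa(mixed3)
  expect_equal(k3$estimate, 0.674796748, tolerance = 1e-8)
  expect_equal(k3$se, 0.0639240549, tolerance = 1e-8)
  ks <- cohen_kappa(skewed2)
  expect_equal(ks$estimate, 0.3181818182, tolerance = 1e-8)
  expect_equal(ks$se, 0.1334565212, tolerance = 1e-8)
  # degenerate one-category table
  degen <- agreement_table(matrix(c(9, 0, 0, 0), 2, byrow = TRUE), c("x", "y"))
  expect_error(cohen_kappa(degen), class = "cdclaims_domain_error")
})

test_that("weighted kappa reduces to kappa for q=2 and matches the references", {
  expect_equal(weighted_kappa(balanced2, "linear")$estimate,
               cohen_kappa(balanced2)$estimate)
  wl <- weighted_kappa(mixed3, "linear")
  expect_equal(wl$estimate, 0.7333333333, tolerance = 1e-8)
  expect_equal(wl$se, 0.0535934398, tolerance = 1e-8)
  wq <- weighted_kappa(mixed3, "quadratic")
  expect_equal(wq$estimate, 0.8039215686, tolerance = 1e-8)
  expect_equal(wq$se, 0.0415936281, tolerance = 1e-8)
  expect_equal(weighted_kappa(agreement_table(diag(c(4, 4, 4))), "linear")$estimate, 1)
  expect_equal(weighted_kappa(agreement_table(diag(c(4, 4, 4))), "quadratic")$estimate, 1)
})

test_that("weighted kappa matches the brute-force pair-enumeration oracle", {
  expect_equal(weighted_kappa(mixed3, "linear")$estimate,
               pairs_weighted_kappa(expand_pairs(mixed3), "linear"),
               tolerance = 1e-12)
  set.seed(61)
  for (rep in 1:5) {
    tab <- random_agreement_table(sample(10:30, 1))
    expect_equal(weighted_kappa(tab, "linear")$estimate,
                 pairs_weighted_kappa(expand_pairs(tab), "linear"),
                 tolerance = 1e-12)
    expect_equal(cohen_kappa(tab)$estimate, pairs_kappa(expand_pairs(tab)),
                 tolerance = 1e-12)
    expect_equal(gwet_ac1(tab)$estimate, pairs_ac1(expand_pairs(tab)),
                 tolerance = 1e-12)
  }
})

test_that("AC1 resists skewed margins where kappa collapses (kappa paradox)", {
  ac <- gwet_ac1(skewed2)
  k <- cohen_kappa(skewed2)
  expect_equal(ac$estimate, 0.808, tolerance = 1e-3)   # p_o=.85, pi_1=.875
  expect_equal(k$estimate, 0.318, tolerance = 1e-3)
  expect_gt(ac$estimate, k$estimate + 0.4)
  # balanced margins: AC1 equals kappa
  expect_equal(gwet_ac1(balanced2)$estimate, 0.8)
  expect_equal(gwet_ac1(agreement_table(diag(c(5, 5, 5))))$estimate, 1)
})

test_that("AC1 linearized variance is consistent with a jackknife oracle", {
  for (tab in list(skewed2, mixed3)) {
    expect_equal(gwet_ac1(tab)$se, jackknife_ac1_se(tab), tolerance = 0.05)
  }
})

test_that("perfect observed agreement forces all three coefficients to one", {
  set.seed(62)
  for (rep in 1:5) {
    tab <- agreement_table(diag(sample(1:20, 3)))
    expect_equal(cohen_kappa(tab)$estimate, 1)
    expect_equal(weighted_kappa(tab)$estimate, 1)
    expect_equal(gwet_ac1(tab)$estimate, 1)
  }
})

test_that("kappa and AC1 are invariant to consistent category relabelling", {
  set.seed(63)
  for (rep in 1:5) {
    tab <- random_agreement_table(40)
    perm <- sample(3)
    m <- matrix(tab, 3, 3)[perm, perm]
    ptab <- agreement_table(m, paste0("cat", 1:3))
    expect_equal(cohen_kappa(ptab)$estimate, cohen_kappa(tab)$estimate,
                 tolerance = 1e-12)
    expect_equal(gwet_ac1(ptab)$estimate, gwet_ac1(tab)$estimate,
                 tolerance = 1e-12)
  }
})

test_that("confidence intervals bracket the estimate and stay within [-1, 1]", {
  set.seed(64)
  for (rep in 1:10) {
    tab <- random_agreement_table(sample(15:60, 1))
    for (coef in list(cohen_kappa(tab), weighted_kappa(tab, "quadratic"), gwet_ac1(tab))) {
      expect_lte(coef$ci_low, coef$estimate)
      expect_gte(coef$ci_high, coef$estimate)
      expect_gte(coef$ci_low, -1)
      expect_lte(coef$ci_high, 1)
    }
  }
})

test_that("intra-rater reliability reuses the same operations on two passes", {
  set.seed(65)
  gold <- data.frame(patient_id = sprintf("I%03d", 1:120),
                     chart_category = sample(c("confirmed", "suspected", "negative"),
                                             120, TRUE, prob = c(.7, .15, .15)))
  passes <- simulate_review(gold, seed = 66L, raters = 2L)  # one reviewer, two passes
  tab <- cross_tabulate(passes$rater1, passes$rater2)
  res <- weighted_kappa(tab, "linear")
  expect_s3_class(res, "agreement_coef")
  expect_true(res$estimate > 0.5)
})
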