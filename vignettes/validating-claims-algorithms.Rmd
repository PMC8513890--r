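---
title: "Validating claims-based case-identification algorithms for Crohn's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-based case-identification algorithms for Crohn's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdclaims)
library(data.table)
```

## The problem

Administrative claims databases record, month by month, every diagnosis,
prescription and procedure a provider bills. They are the only practical way
to assemble large real-world cohorts for a low-prevalence disease such as
Crohn's disease (CD, prevalence on the order of 55 per 100,000 in Japan) —
but a billed ICD-10 code is not a clinical diagnosis. Rule-out ("suspected")
codes, look-alike diseases and coding habits all put K50 codes on charts of
patients who do not have CD. Before a phenotyping rule can be trusted, its
positive predictive value (PPV) must be measured against chart review.

`cdclaims` implements both halves of that task:

* the **case-identification rules** themselves, evaluated month-wise over
  claims lines, and
* the **validation machinery** around them — age-stratified sampling,
  duplicate chart review with consensus adjudication, diagnostic-validity
  statistics with exact confidence intervals, survey-weighted extrapolation,
  sample-size planning, and chance-corrected agreement coefficients —
* plus a seeded **synthetic claims generator** with known ground truth, so
  the whole design can be exercised and tested end to end without access to
  protected medical records.

## The inclusion criteria

All criteria are month-scoped; "in the same month" is the atomic time unit
and days are never parsed.

| Criterion | Rule for a qualifying month |
|---|---|
| IC-A | a confirmed (non-suspected) diagnosis code with prefix K50, and no confirmed K51 (ulcerative colitis) or M35 (Behçet's disease) code in the same month |
| IC-B | IC-A **and** a CD-specific prescription code in the same month |
| IC-C | IC-A **and** a CD-specific prescription **or** surgical code in the same month |

A patient is included under a criterion when at least one month qualifies
(`min_qualifying_months` raises this for repeated-detection protocols). By
construction IC-B ⊆ IC-C ⊆ IC-A, patient-wise and month-wise.

Two readings of the rule deserve emphasis because they are easy to get
wrong. First, the suspected-diagnosis flag (the Japanese claims convention
marking rule-out diagnoses) disqualifies a K50 line from *inclusion*, and a
suspected-flagged K51/M35 line equally does **not** veto the month: only
confirmed codes act, in either direction. Second, the exclusion is
month-scoped, not patient-scoped — a confirmed K51 in March does not veto a
clean K50 month in May. Whether the diagnosis must occupy a claim's
"main disease" field is not modelled; claims here have no such field.

ICD-10 matching is by normalized prefix (uppercase, dots stripped), so
`K50` covers `K50.0`–`K50.9`. The shipped `default_codebook()` names the CD
drug classes (mesalazine, thiopurines, elemental diet, budesonide,
infliximab and biosimilar, adalimumab, ustekinumab, vedolizumab) as
placeholder codes; real analyses must supply the fee-schedule codes in use
at their site via a YAML codebook.

## The validation design

```{r pipeline}
cfg <- sim_config()          # defaults documented below
sim <- generate_claims(cfg)
cb  <- default_codebook()
inc <- classify_patients(sim$claims, cb, cfg$window)
cohort_counts(inc)
```

From the criterion-positive pool, 100 cases are drawn by age-stratified
random sampling (10-year bands by default; the band width is a parameter
because no single width is canonical), and 200 from the criterion-negative
complement. Allocation across strata is proportional with largest-remainder
rounding; every sampled case carries its Horvitz–Thompson weight
(stratum pool size / stratum sample size), so the weights of an arm add
back up to its pool.

```{r sample}
s <- stratified_sample(inc, sim$patients, criterion = "A",
                       n_pos = 100, n_neg = 200, seed = 1)
sum(s$weight[startsWith(s$arm, "criterion_positive")])  # = IC-A pool size
```

Two reviewers independently classify each sampled chart as
confirmed / suspected / negative; disagreements go to a decisive third
reviewer (`adjudicate()`). Validity is then assessed under two case
definitions — disease-positive = confirmed only, or confirmed-or-suspected —
because a "suspected" chart is a genuinely ambiguous gold standard, not a
soft positive.

```{r review}
g  <- sim$gold[match(s$patient_id, sim$gold$patient_id)]
rv <- simulate_review(g, cfg$reviewer_confusion, seed = 2, raters = 3)
fin <- adjudicate(rv$rater1, rv$rater2, rv$rater3, ids = rv$patient_id)
tab <- build_2x2(s, data.frame(patient_id = rv$patient_id, category = fin),
                 "confirmed_only")
diagnostic_metrics(tab)
```

### Why Clopper–Pearson intervals

A validation sample of this shape routinely produces boundary proportions —
zero false negatives make sensitivity and NPV exactly 1. Wald intervals
collapse there and Wilson intervals are approximate; the Clopper–Pearson
exact interval from beta quantiles remains valid (if conservative) at x = 0
and x = n, which is why it is the only interval family offered. Metrics
whose denominator is zero are reported as `NA` — a metric with no
observations is undefined, not perfect.

Note what a hospital-based design can and cannot estimate: PPV and NPV are
estimated well from 100 + 200 charts, but with a population prevalence of
~0.06% a criterion-negative sample of 200 contains essentially no true
cases, so sensitivity ≈ 1 and NPV ≈ 1 are near-structural and their exact
estimation would need tens of thousands of negative charts.
`required_n_for_proportion()` exposes the planning rule actually used for
the positive arm: a 95% CI half-width of ±0.1 at the worst-case proportion
0.5 needs 97 charts, rounded up to 100 in protocol terms.

### Extrapolation to the source cohort

`extrapolate_2x2()` scales the sampled table by arm weights (flooring to
whole patients), and `estimate_true_count()` applies the measured PPV to the
full extraction count: with 255 patients extracted at PPV 0.83 the cohort is
estimated to contain `floor(255 × 0.83) = 211` true cases; at 197 extracted
and PPV 0.97, 191. Floor, not rounding, is deliberate: these are counts of
whole patients and the conservative direction is down.

### Agreement coefficients

Duplicate review (a 20% subsample in the emulated design) is summarized by
Cohen's κ, weighted κ, and Gwet's AC1 over the ordered categories
confirmed < suspected < negative. All three are chance-corrected ratios
`(p_o − p_chance)/(1 − p_chance)`; they differ only in the chance model.
κ uses margin products and is known to collapse when one category dominates
(the "kappa paradox" — compare the fixtures in the test suite where raw
agreement 0.85 yields κ = 0.32 but AC1 = 0.81); AC1's chance model
`Σ π_k(1−π_k)/(q−1)` is robust to that skew, which matters here because
near-unanimous "confirmed" ratings are exactly what a good chart review
produces. Weighted κ defaults to linear weights (quadratic is available and
labelled in the result); for two categories both reduce to unweighted κ.
Standard errors are the large-sample Fleiss–Cohen–Everitt estimator for both
kappas, without continuity correction, and Gwet's linearized estimator for
AC1; reported intervals are truncated to [−1, 1]. Intra-rater reliability is
the same computation applied to one reviewer's two passes — there is
deliberately no separate code path.

## The synthetic generator

`sim_config()` defines the study conditions; `generate_claims()` is
deterministic given `seed`. The model per patient: a true status (CD, one of
six mimic diseases, or none), visit months in the window (1 + Poisson; mean
12 beyond the first for CD — a chronic disease under near-monthly
management — and 3 for everyone else), and per visit month the billing lines
a hospital would file. The defaults, chosen once as a realistic emulation of
a specialist IBD centre and then left alone:

* `prevalence_cd = 0.007`, `prevalence_mimic = 0.0022`. At n = 20,000 this
  yields an IC-A pool of ~165 patients (≈0.8% of visitors), deliberately
  denser than a general hospital so that the 100/200 sampling design always
  has a pool to draw from at desk scale; the CD:mimic mix is what fixes the
  PPV structure, and it is preserved.
* `mimic_spectrum` in proportions 4:2:1:1:1:1 over infectious enterocolitis,
  intestinal Behçet's disease, drug-induced enterocolitis, intestinal
  tuberculosis, unspecified stenosis and cirrhosis — the disease mix actually
  found behind false-positive K50 codes in chart reviews.
* `p_k50_given_cd = 0.9` per visit month, versus `p_k50_given_mimic = 0.3`:
  mimics attract K50 codes transiently during work-up. With these rates a CD
  patient essentially always meets IC-A; false negatives (CD never coded) are
  possible but rare, matching a specialist-centre setting — there is no
  published false-negative structure to calibrate against, so treat
  sensitivity/NPV results as structural, not empirical.
* `p_rx_given_cd_coded = 0.85` versus `p_rx_given_mimic_coded = 0.08`: CD
  co-prescription conditional on true disease is what makes IC-B specific.
  Raising the mimic rate can only dilute IC-B's PPV (a tested monotonicity
  property).
* Intestinal-Behçet mimics carry a confirmed M35 code in half of their
  K50-coded months (`p_excl_code_given_behcet = 0.5`) — the minimal mechanism
  that makes the exclusion rule consequential. Other mimics bill their own
  diagnosis codes, which never collide with K50.
* Charts: true CD reads `confirmed` (with a source a–d drawn as 75/24/0/1 —
  own institution, outside specialist, documented and undocumented primary
  care); a mimic's chart reads `suspected` with probability 0.41, else
  `negative`; disease-free patients read `negative`. Under these defaults
  ~83% of IC-A patients truly have CD, so the confirmed-only PPV of IC-A
  sits near 0.83 and rises above 0.95 under IC-B, and the
  confirmed-or-suspected PPV of IC-A sits near 0.90 — the qualitative
  signature of a diagnosis-code-only rule versus a code-plus-prescription
  rule.
* `reviewer_confusion` is row-stochastic over chart truth with diagonals
  0.97/0.93/0.97; the third reviewer draws from the same matrix unless a
  different one is passed.

What the generator does **not** emulate: longitudinal disease progression,
costs, dosing, realistic code dictionaries, inter-month correlation of
coding, or reviewer errors correlated between reviewers. Passing end-to-end
tests therefore shows the machinery is correct and the design behaves as
published under a faithful generative model — it does not certify any PPV
for a particular real database.

## Numerical and design choices

* Proportional allocation uses largest-remainder rounding with ties broken
  toward the larger stratum, then stratum order — deterministic.
* The criterion-negative pool for IC-B/C is the complement of that
  criterion, so patients meeting IC-A but not IC-B are eligible as
  negatives; the function says so in a message because the alternative
  (complement of IC-A) is also defensible.
* A sampling request larger than its pool is an error, never a silent
  take-all.
* Degenerate agreement tables (all mass in one category) raise an
  undefined-coefficient error rather than returning 0/0.
* Observation windows are configuration, not constants; ages are computed at
  the window-start year.
* Desk-scale defaults keep every simulation in seconds: n = 20,000 patients,
  and the test suite's end-to-end checks average 20 seeded replicates. The
  full-scale cohort (~83,000 visitors) is a `sim_config(n_patients = ...)`
  away.

## Limitations

The shipped codebook is a placeholder; prefix-level ICD-10 matching is the
standard but not the only reading of a chapter code; the generator's
false-negative structure is assumed, not validated; and agreement-coefficient
confidence intervals are asymptotic, so they are unreliable below a few
dozen duplicate-reviewed charts.
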