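---
title: "Scoring awake bruxism with ABIT: methods and design notes"
author: "abit package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring awake bruxism with ABIT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abit)
```

## The instrument

The Awake Bruxism Identification Tool (ABIT) screens children aged 8–12 for
awake bruxism (AB) — masticatory muscle activity during wakefulness, i.e.
repetitive or sustained tooth contact and/or bracing or thrusting of the
mandible. Rather than a present/absent dichotomy, ABIT places a child on an
*AB Spectrum* composed from six components:

* **R1** — parents' report at the initial interview: three questions
  (teeth grinding, teeth clenching, mandible bracing/thrusting) on a
  5-point frequency Likert scale (*never* … *always*, scored 0–4) with an
  unscored *don't know* (DK) option;
* **SR** — the child's self-report, same three questions;
* **R2** — parents' report after a seven-day guided observation period,
  same questions in the past tense;
* **ICA / ECA** — intraoral and extraoral clinical assessment: one point
  per positive finding (five named intraoral mucosal markers; masseter and
  temporal hypertrophy extraorally). Per-tooth wear is recorded on a
  five-point ordinal scale as complementary data and never scores;
* **EMA** — an analog ecological momentary assessment: a paper sheet of 42
  emoji slots (6 per day × 7 days); the child colours one emoji per
  perceived AB event.

### Component scoring rules

Each report component sums its three question scores (DK answers are
excluded from the sum but counted in `dk_count`), so its range is 0–12.
Three statuses are distinguished:

* **zero** — every scored answer is 0 (an all-DK triplet is also zero, and
  is flagged by `validate_record()`);
* **null** — exactly one of the three behaviours is reported and its
  frequency is *almost never* (score 1). Such an isolated, minimal report
  is not treated as positive;
* **positive** — anything else with a nonzero sum. In particular, two
  answers at score 1 are positive: the null rule concerns a *single*
  behaviour only.

The EMA raw sum is the number of painted slots (0–42); the component is
positive when paintings appear on **four or more days**, null on 1–3 days,
zero on an empty sheet. Positivity is a function of painted *days* alone —
it is invariant to how events distribute across slots within a day.

The clinical assessment identifies AB only through the conjunction
ICA ≥ 1 **and** ECA ≥ 1; isolated markers lack predictive power. The
published item description contains one internal contradiction (a "No"
sentence vs. "1 point … for the presence"); scoring one point per *present*
finding is the only reading consistent with the rest of the instrument and
is what this package implements.

### Composition and categories

The AB Spectrum total sums the component contributions: positive components
contribute their raw sum; zero and null report/EMA components contribute
nothing (null is grouped with zero under "Not AB", so null points must not
accumulate into a nonzero spectrum). The clinical components are the one
deliberate exception: their raw sums always enter the total — the
instrument states that both assessments' scores are summed to define the
spectrum — while the conjunction governs only the *category*. An ICA or ECA
score that fails the conjunction is reported with status `null` to make
this visible.

Categories are assigned as a set: any positive report or self-report gives
*AB based on R/SR*; together with a positive EMA this becomes *AB based on
R/SR and EMA* (replacing the bare category); a positive EMA alone gives
*AB based on EMA*; the clinical conjunction adds *AB based on CA* to
whatever else holds; a child with only zero/null components is *Not AB*.
The label concatenates categories in a fixed presentational order
(R/SR+EMA, R/SR, EMA, CA). Whether a positive self-report alone (parents
reporting all *never*) qualifies as "AB based on R/SR" is not settled by
the published definitions; this package answers **yes** (any of R1/SR/R2)
and says so in its report metadata.

### The 86 vs 96 discrepancy

The published component table lists spectrum maxima of 12, 12, 12, 6, 2
and 42, and a headline AB Spectrum range of 0–96. Those maxima sum to 86,
not 96, and each maximum is forced by the item structure (3 questions × 4
points; 42 slots; 6 declared intraoral points; 2 muscles), so the headline
total is an arithmetic slip in the published table. `max_spectrum()`
therefore reports the true sum of the configured component maxima — 86 for
the default instrument — rather than echoing the printed 96. A related
wrinkle: the table declares an ICA range of 0–6 while only five intraoral
findings are named and score points. The default instrument keeps the
declared maximum of 6 (a sixth finding slot is permitted by the definition
but ships disabled), so an exam built from the five named findings can
reach at most 5.

```{r}
inst <- default_instrument()
inst
max_spectrum(inst)
```

## Reliability statistics

Temporal stability of the instrument is assessed by a test–retest design
(a 15-day interval in the original pilot). `reliability_report()` computes:

* **Cronbach's alpha** per administration over the three questions of R1
  and of R2 (items = questions, subjects = participants):
  \(\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)\) with
  sample variances. Alpha is undefined when the total-score variance is
  zero, and participants with a DK answer are dropped (with a warning)
  since the item matrix must be complete.
* **ICC**, single measures, from the two-way subjects × administrations
  ANOVA decomposition with \(k = 2\): consistency
  \((MS_R - MS_E)/(MS_R + (k-1)MS_E)\) and absolute agreement
  \((MS_R - MS_E)/(MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E))\) — the
  McGraw–Wong ICC(C,1) and ICC(A,1) forms, which match the plain
  "consistency"/"agreement" labels used in common software. The mean
  squares are extracted from `stats::aov()`; the test suite checks them
  against explicit sums-of-squares arithmetic. Note the often-quoted rule
  "agreement ≤ consistency" requires both \(MS_R > MS_E\) and
  \(MS_C \ge MS_E\); equality holds exactly when \(MS_C = MS_E\).
* **Lin's CCC** for paired totals,
  \(\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)\) with
  \(n\)-denominator moments, equal to Pearson's \(r\) times a bias
  correction \(C_b \in (0, 1]\), so \(|\rho_c| \le |r|\) always. The 95% CI
  uses Fisher's z-transform with Lin's 1989 variance estimator — a closed
  form that stays reproducible at the pilot's n = 5, where a bootstrap
  would not.

Because the published pilot does not include its participant-level data,
its coefficients (R1 alpha 0.462, R2 alpha 0.827, ICC 0.880 consistency /
0.831 agreement, CCC 0.997 with CI 0.979–0.999) serve here as
documentation examples only; nothing in the package asserts them. Which
composite the pilot's ICC/CCC were taken over is likewise unstated, so the
report computes both the AB Spectrum totals block and a summed-reports
(R1+SR+R2) block, labelled.

## The synthetic cohort generator

`simulate_cohort()` exists so scoring, classification and reliability can
be exercised end to end with known ground truth. Each child carries a
latent propensity: a group flag (active with probability `prevalence`) and
a daily AB event rate \(\theta\), lognormal around the group rate
(`theta_active` / `theta_inactive`, spread `theta_sigma`). From \(\theta\):

* daily event counts are Poisson(\(\theta\)) truncated at the six sheet
  slots (the generator can never emit more paintings than the physical
  sheet holds); each event is painted with probability `adherence`;
* each Likert answer derives from the behaviour-specific rate
  \(\theta \cdot w_b\) (weights 0.5 / 1.0 / 0.9 for grinding / clenching /
  bracing, reflecting clenching being the most-perceived behaviour)
  through fixed thresholds at 0.05, 0.35, 1.0 and 2.0 events/day, then
  slips one category with probability `report_noise`. The thresholds are
  fixed constants, not fitted — no calibration data exist;
* the seven clinical findings are independent Bernoulli draws with a
  group-specific probability; eight FDI index teeth receive wear grades
  0–2 with group-specific probabilities.

Test and retest share **all** non-latent draws (common random numbers);
only \(\theta\) moves between stages, through a Gaussian copula on the
latent normal \(z\) with correlation `retest_rho`. Consequences: with
`retest_rho = 1` and `report_noise = 0` the retest records equal the test
records exactly, and clinical findings and tooth wear are stable across
the 15-day interval — which is also the clinically realistic behaviour for
hypertrophy, hyperkeratosis and wear.

Defaults were chosen once to mirror a pilot-scale study: n = 10,
prevalence 0.4 (the pilot classified 40% of children as AB by
report/self-report), θ_active = 1.5 events/day (enough to cross the EMA
day cut-off most weeks without saturating the sheet), θ_inactive = 0.02,
noise 0.1, clinical probabilities 0.15/0.03, adherence 0.9,
retest_rho 0.9.

### What recovery means here

With equal margins across stages, the CCC of the paired latent normals
\((z_{test}, z_{retest})\) equals their Pearson correlation, i.e.
`retest_rho` in expectation — so the parameter-recovery check computes the
CCC on the truth table's latent scale, where 0.9 is the exact target. The
CCC of the *observed* spectrum totals is attenuated below `retest_rho` by
the ordinal response mapping, reporting noise and diary truncation; it is
reported, not asserted. The generator emulates the statistical structure
the instrument assumes — a single propensity driving correlated reports,
paintings and findings — and deliberately omits features of real cohorts
(reporting bias that differs between parent and child, behaviour change
induced by observation, dropout, school/home context effects), so green
tests certify the arithmetic and the pipeline, not field validity.

## Numerical and interface choices

* Scores, totals and counts are integers throughout; no floating point
  enters the scoring path, so scoring is exactly reproducible.
* Degenerate reliability inputs raise errors rather than returning NaN:
  zero total-score variance (alpha), no subject and residual variance
  (ICC), zero variance in both members of a pair (CCC). The CCC interval
  collapses to a point at \(|\rho_c| = 1\) or \(r = 0\), where Lin's
  variance formula is undefined.
* File dialects: a flat CSV (Likert labels or the `DK` literal; EMA as 42
  binary columns `d1s1…d7s6`; wear as `tooth:grade` pairs) and an
  equivalent JSON-lines form are accepted interchangeably; parse errors
  name row, column and offending token, and per-day painting counts above
  six are structurally impossible to express. Output files carry a `#`
  header with tool version, instrument hash and seed; readers skip such
  lines. Exit codes: 0 ok, 2 validation, 3 I/O.
* Event tallies (`aggregate_event_counts`) count any answer above *never*,
  including answers inside null triplets: the tally records perceived
  events while the null rule governs positivity. The choice is recorded in
  the output metadata.

## Problem sizes

The test suite enumerates all 125 triplet patterns, all 128 clinical
finding combinations and all 324 realizable component-status profiles
exactly; Monte-Carlo checks use 10^4-row matrices for the
uncorrelated-items alpha, 10^4 random diaries for the EMA cut-off
property, and 100 replicates of 200-child paired cohorts for latent-
correlation recovery. The acceptance script uses the same sizes with 5000
diaries per cut-off arm and a 1000-child cohort for the classification
rate — sizes at which every binomial standard error is well below the
asserted margins.
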