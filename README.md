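# abit — a scoring engine for the Awake Bruxism Identification Tool

Awake bruxism (AB) in children — repetitive or sustained tooth contact,
or bracing/thrusting of the mandible while awake — is hard to measure:
electromyography is costly, one-off questionnaires are unreliable, and
children aged 8–12 need guidance to recognise the behaviour at all. The
Awake Bruxism Identification Tool (ABIT) addresses this by combining four
information sources for each child into a composite *AB Spectrum* instead
of a present/absent verdict:

| Component | Source | Range | Cut-off |
|---|---|---|---|
| R1 | parents' report, 3 Likert questions | 0–12 | ≥ 1 (single "almost never" is null) |
| SR | child self-report, 3 Likert questions | 0–12 | ≥ 1 (same null rule) |
| R2 | parents' report after 7-day observation | 0–12 | ≥ 1 (same null rule) |
| ICA | intraoral clinical findings | 0–6 | ≥ 1, valid only with ECA ≥ 1 |
| ECA | extraoral clinical findings (hypertrophy) | 0–2 | ≥ 1, valid only with ICA ≥ 1 |
| EMA | analog 7-day × 6-slot emoji painting diary | 0–42 | ≥ 4 days with paintings |

Each Likert answer scores 0–4 (*never* … *always*; *don't know* carries no
score). Positive components contribute their raw sums to the spectrum
total, and the pattern of positive components assigns the identification
categories *Not AB*, *AB based on R/SR*, *AB based on R/SR and EMA*,
*AB based on EMA* and *AB based on CA* (the last requires intraoral **and**
extraoral findings together). Note that the published component maxima sum
to 86, although the instrument's headline range is printed as 0–96; see the
methods vignette (`vignettes/abit-methods.Rmd`) for this and every other
scoring subtlety.

This package is the full pipeline for ABIT studies:

* typed participant records (reports, diary, clinical exam) with
  validation, CSV and JSON-lines input/output;
* component scoring with the DK, null, EMA cut-off and clinical
  conjunction rules; spectrum composition and category assignment;
  behaviour-by-source event tallies;
* test–retest reliability: Cronbach's alpha, two-way single-measure ICC
  (consistency and agreement), and Lin's concordance correlation
  coefficient with a Fisher-z confidence interval;
* a seeded synthetic-cohort generator with known ground truth, pairing
  test and retest administrations through a Gaussian copula;
* a command-line interface (`score`, `reliability`, `simulate`, `report`).

## A worked example

```r
library(abit)

rec <- participant_record(
  participant_id = "P07", age_years = 9, stage = "test",
  r1 = behavior_triplet("R1", "never", "sometimes", "never"),
  sr = behavior_triplet("SR", "almost_never", "most_of_time", "never"),
  r2 = behavior_triplet("R2", "never", "sometimes", "almost_never"),
  ema = ema_diary(matrix(c(rep(1, 5), rep(0, 37)), nrow = 7)), # 5 painted days
  exam = clinical_exam(buccal_hyperkeratosis_linea_alba = TRUE,
                       tooth_wear = c("16" = 1, "26" = 1)),
  sb_reported = FALSE
)
classify_record(rec)
#> AB Spectrum: 15  [AB based on R/SR and EMA]
#>   contributions: R1=2, SR=4, R2=3, ICA=1, ECA=0, EMA=5
```

Reading the output: the parents and the child both report behaviours above
"never", so the reports are positive and contribute their sums (2, 4, 3);
the diary shows paintings on five days — past the four-day cut-off — so its
five events count and the child is categorised *AB based on R/SR and EMA*.
The lone intraoral finding (linea alba) adds its point to the total but
does **not** trigger *AB based on CA*, because no extraoral finding
accompanies it. Tooth wear is complementary data and never scores.

Reliability on a simulated paired cohort:

```r
sim <- simulate_cohort(simulation_params(n_participants = 30, seed = 42))
reliability_report(sim$test, sim$retest)
#> ABIT test-retest reliability (n = 30 matched pairs)
#>   Cronbach's alpha: R1 = 0.952, R2 = 0.957
#>   AB Spectrum totals: ICC consistency = 0.989, ICC agreement = 0.989,
#>     CCC = 0.989 (95% CI 0.977-0.995)
#>   Report sums (R1+SR+R2): ICC consistency = 0.988, ICC agreement = 0.989,
#>     CCC = 0.988 (95% CI 0.976-0.994)
```

From the shell, the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/abit.R", package = "abit"))')" \
  simulate --out sim --n 20 --seed 7
Rscript "$(Rscript -e 'cat(system.file("cli/abit.R", package = "abit"))')" \
  score --input sim/test.csv --out results
```

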