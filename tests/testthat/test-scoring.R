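test_that("Likert labels map to their points and DK carries no score", {
  labels <- c("never", "almost_never", "sometimes", "most_of_time", "always")
  expect_identical(vapply(labels, score_likert, integer(1), USE.NAMES = FALSE), 0:4)
  expect_identical(score_likert("dont_know"), NA_integer_)
  expect_identical(score_likert("DK"), NA_integer_)
  expect_error(score_likert("sometmes"), "sometmes")
})

test_that("triplet scoring matches the exhaustive decision-table oracle", {
  # all 5^3 non-DK answer combinations
  combos <- expand.grid(q1 = 0:4, q2 = 0:4, q3 = 0:4)
  got <- character(nrow(combos))
  want <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    s <- unlist(combos[i, ])
    cs <- score_triplet(triplet_from_scores(s[1], s[2], s[3]))
    expect_identical(cs$raw_sum, as.integer(sum(s)))
    got[i] <- cs$status
    want[i] <- oracle_triplet_status(s)
  }
  expect_identical(got, want)
  expect_identical(sum(got == "null"), 3L)
  expect_identical(sum(got == "zero"), 1L)
  expect_identical(sum(got == "positive"), 121L)
})

test_that("a lone 'almost never' is null; two score-1 answers are positive", {
  expect_identical(score_triplet(triplet_from_scores(0L, 1L, 0L))$status, "null")
  expect_identical(score_triplet(triplet_from_scores(1L, 1L, 0L))$status, "positive")
  expect_identical(score_triplet(triplet_from_scores(2L, 3L, 0L))$status, "positive")
  expect_identical(score_triplet(triplet_from_scores(0L, 0L, 0L))$status, "zero")
})

test_that("DK answers are ignored by the null rule and counted separately", {
  # one scored behaviour at 1, two DK -> null
  cs <- score_triplet(triplet_from_scores(NA, 1L, NA))
  expect_identical(cs$status, "null")
  expect_identical(cs$raw_sum, 1L)
  expect_identical(cs$dk_count, 2L)
  # DK plus a frequent behaviour -> positive, sum excludes the DK
  cs <- score_triplet(triplet_from_scores(NA, 3L, 0L))
  expect_identical(cs$raw_sum, 3L)
  expect_identical(cs$status, "positive")
})

test_that("EMA scoring applies the four-day cut-off", {
  empty <- score_ema(ema_diary(matrix(FALSE, 7, 6)))
  expect_identical(empty$raw_sum, 0L)
  expect_identical(empty$status, "zero")

  three_days <- score_ema(ema_diary(grid_with(1:3, 2L)))
  expect_identical(three_days$raw_sum, 6L)
  expect_identical(three_days$days_with_paintings, 3L)
  expect_identical(three_days$status, "null")

  four_days <- score_ema(ema_diary(grid_with(1:4, 1L)))
  expect_identical(four_days$raw_sum, 4L)
  expect_identical(four_days$status, "positive")
})

test_that("EMA scoring is slot-permutation invariant and monotone", {
  set.seed(11)
  for (rep in 1:50) {
    g <- matrix(runif(42) < 0.3, 7, 6)
    base <- score_ema(ema_diary(g))
    perm <- t(apply(g, 1L, sample)) # permute slots within each day
    s2 <- score_ema(ema_diary(perm))
    expect_identical(s2$raw_sum, base$raw_sum)
    expect_identical(s2$days_with_paintings, base$days_with_paintings)
    # add one painted slot: raw_sum +1, days never decrease
    off <- which(!g)
    if (length(off) > 0L) {
      g2 <- g
      g2[off[sample.int(length(off), 1L)]] <- TRUE
      s3 <- score_ema(ema_diary(g2))
      expect_identical(s3$raw_sum, base$raw_sum + 1L)
      expect_gte(s3$days_with_paintings, base$days_with_paintings)
    }
  }
})

test_that("upgrading a Likert answer never decreases a triplet's raw sum", {
  set.seed(12)
  for (rep in 1:50) {
    s <- sample(0:4, 3, replace = TRUE)
    q <- sample.int(3, 1)
    if (s[q] == 4L) next
    up <- s; up[q] <- up[q] + 1L
    expect_gt(score_triplet(triplet_from_scores(up[1], up[2], up[3]))$raw_sum,
              score_triplet(triplet_from_scores(s[1], s[2], s[3]))$raw_sum - 1L)
  }
})

test_that("clinical scoring enforces the intra/extraoral conjunction over all finding sets", {
  # brute force over all 2^7 finding combinations
  for (mask in 0:127) {
    flags <- as.logical(bitwAnd(mask, 2^(0:6)) > 0)
    cli <- score_clinical(exam_from_findings(flags))
    eca_true <- sum(flags[1:2]) # masseter, temporal
    ica_true <- sum(flags[3:7])
    expect_identical(cli$eca$raw_sum, as.integer(eca_true))
    expect_identical(cli$ica$raw_sum, as.integer(ica_true))
    expect_identical(cli$ca_positive, ica_true >= 1 && eca_true >= 1)
  }
})

test_that("isolated clinical markers do not qualify the clinical assessment", {
  linea_alba_only <- exam_from_findings(c(FALSE, FALSE, TRUE, rep(FALSE, 4)))
  cli <- score_clinical(linea_alba_only)
  expect_identical(cli$ica$raw_sum, 1L)
  expect_identical(cli$eca$raw_sum, 0L)
  expect_false(cli$ca_positive)

  both <- exam_from_findings(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  cli <- score_clinical(both)
  expect_identical(cli$ica$raw_sum, 2L)
  expect_identical(cli$eca$raw_sum, 1L)
  expect_true(cli$ca_positive)
})

test_that("tooth-wear histogram counts teeth per grade and conserves totals", {
  expect_identical(summarize_tooth_wear(exam_from_findings()),
                   c("0" = 0L, "1" = 0L, "2" = 0L, "3" = 0L, "4" = 0L))
  ex <- exam_from_findings(tooth_wear = c("16" = 1L, "26" = 1L, "36" = 2L))
  h <- summarize_tooth_wear(ex)
  expect_identical(h[["1"]], 2L)
  expect_identical(h[["2"]], 1L)
  expect_identical(sum(h), 3L)
  # never alters scores
  expect_identical(score_clinical(ex)$ica$raw_sum, 0L)
})

test_that("event aggregation counts any above-never answer, with conserved totals", {
  recs <- list(
    make_record("A", r1 = c(1L, 0L, 0L), sr = c(0L, 2L, 0L)), # null R1 still counts
    make_record("B", r1 = c(0L, 3L, 4L), r2 = c(0L, 0L, 2L)),
    make_record("C")
  )
  agg <- aggregate_event_counts(recs, "test")
  expect_identical(agg$Total, as.integer(rowSums(as.matrix(agg[, c("R1", "R2", "SR")]))))
  expect_identical(agg$R1[agg$behavior == "grinding"], 1L) # the null triplet's answer
  expect_identical(agg$SR[agg$behavior == "clenching"], 1L)
  expect_identical(attr(agg, "counting_rule"),
                   "any answer with score > 0 counts, including answers inside null triplets")
})

test_that("event aggregation rejects mixed stages and handles empty cohorts", {
  recs <- list(make_record("A", stage = "test"), make_record("B", stage = "retest"))
  expect_error(aggregate_event_counts(recs, "test"), "retest")
  empty <- aggregate_event_counts(list(), "retest")
  expect_identical(empty$Total, rep(0L, 3L))
})

test_that("score_cohort emits one complete row per record", {
  recs <- list(make_record("A", r1 = c(2L, 0L, 0L), ema = grid_with(1:5)),
               make_record("B", sr = c(NA, 1L, 0L)))
  df <- score_cohort(recs)
  expect_identical(nrow(df), 2L)
  expect_identical(df$r1_status, c("positive", "zero"))
  expect_identical(df$sr_dk, c(0L, 1L))
  expect_identical(df$ema_days, c(5L, 0L))
})
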