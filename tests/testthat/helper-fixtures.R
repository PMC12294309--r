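# Shared builders for ABIT test objects.

LIKERT <- c("never", "almost_never", "sometimes", "most_of_time", "always")

# triplet from integer scores 0-4 (or NA for don't-know)
triplet_from_scores <- function(s1, s2, s3, source = "R1") {
  lab <- function(s) if (is.na(s)) "dont_know" else LIKERT[s + 1L]
  behavior_triplet(source, lab(s1), lab(s2), lab(s3))
}

# 7x6 grid with `slots_per_day[d]` painted slots on each listed day
grid_with <- function(days, slots_per_day = 1L) {
  slots_per_day <- rep_len(slots_per_day, length(days))
  g <- matrix(FALSE, 7, 6)
  for (i in seq_along(days)) {
    if (slots_per_day[i] > 0L) g[days[i], seq_len(slots_per_day[i])] <- TRUE
  }
  g
}

exam_from_findings <- function(flags = logical(7), tooth_wear = integer(0)) {
  flags <- rep_len(flags, 7L)
  clinical_exam(
    masseter_hypertrophy = flags[1], temporal_hypertrophy = flags[2],
    buccal_hyperkeratosis_linea_alba = flags[3], labial_hyperkeratosis = flags[4],
    labial_indentation = flags[5], tongue_indentation = flags[6],
    buccal_indentation = flags[7], tooth_wear = tooth_wear
  )
}

make_record <- function(id = "P01", stage = "test", age = 10L,
                        r1 = c(0L, 0L, 0L), sr = c(0L, 0L, 0L),
                        r2 = c(0L, 0L, 0L),
                        ema = matrix(FALSE, 7, 6),
                        exam = exam_from_findings(),
                        sb = NA) {
  participant_record(
    participant_id = id, age_years = age, stage = stage,
    r1 = triplet_from_scores(r1[1], r1[2], r1[3], "R1"),
    sr = triplet_from_scores(sr[1], sr[2], sr[3], "SR"),
    r2 = triplet_from_scores(r2[1], r2[2], r2[3], "R2"),
    ema = ema_diary(ema), exam = exam, sb_reported = sb
  )
}

# identical-content comparison for records, ignoring the stage field
record_equal_ignoring_stage <- function(a, b) {
  a$stage <- b$stage <- "x"
  identical(a, b)
}
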