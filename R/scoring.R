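# Component scoring: Likert maps, null rules, EMA cut-off, CA conjunction.

new_component_score <- function(component, raw_sum, status,
                                dk_count = NA_integer_,
                                days_with_paintings = NA_integer_) {
  structure(list(
    component = component,
    raw_sum = as.integer(raw_sum),
    status = status,
    dk_count = as.integer(dk_count),
    days_with_paintings = as.integer(days_with_paintings)
  ), class = "abit_component_score")
}

#' @export
print.abit_component_score <- function(x, ...) {
  extra <- ""
  if (!is.na(x$dk_count) && x$dk_count > 0L) extra <- sprintf(", %d DK", x$dk_count)
  if (!is.na(x$days_with_paintings)) {
    extra <- sprintf(", %d day(s) with paintings", x$days_with_paintings)
  }
  cat(sprintf("%s: raw sum %d, status %s%s\n", x$component, x$raw_sum, x$status, extra))
  invisible(x)
}

#' Score a single Likert answer
#'
#' Maps the 5-point frequency scale to points: never = 0, almost never = 1,
#' sometimes = 2, most of the time = 3, always = 4. "Don't know" carries no
#' score and is returned as `NA` (the DK sentinel, excluded from sums).
#'
#' @param label Likert label (`"DK"` accepted as an alias for `"dont_know"`).
#' @return Integer 0-4, or `NA_integer_` for don't-know.
#' @export
score_likert <- function(label) {
  label <- canonical_likert(label)
  if (identical(label, DK_LABEL)) return(NA_integer_)
  idx <- match(label, LIKERT_LABELS)
  if (is.na(idx)) {
    stop("unknown Likert label '", label, "'", call. = FALSE)
  }
  idx - 1L
}

#' Score a behaviour-report triplet
#'
#' Sums the points of the three questions (don't-know answers are excluded).
#' Status follows the component rules: `zero` when every scored answer is 0
#' (an all-don't-know triplet is also zero), `null` when exactly one
#' behaviour is reported and its frequency is "almost never" (score 1) --
#' such a report is not classed as positive -- and `positive` otherwise.
#'
#' @param triplet A [behavior_triplet()].
#' @return An `abit_component_score` with `raw_sum` in 0-12, `status`, and
#'   `dk_count`.
#' @export
score_triplet <- function(triplet) {
  stopifnot(inherits(triplet, "abit_triplet"))
  pts <- vapply(triplet$answers, score_likert, integer(1))
  dk <- sum(is.na(pts))
  scored <- pts[!is.na(pts)]
  raw <- sum(scored)
  status <- if (length(scored) == 0L || all(scored == 0L)) {
    "zero"
  } else if (sum(scored > 0L) == 1L && max(scored) == 1L) {
    "null"
  } else {
    "positive"
  }
  new_component_score(triplet$source, raw, status, dk_count = dk)
}

#' Score an EMA painting diary
#'
#' The raw sum is the number of painted slots (0-42). The component is
#' positive when paintings are present on four or more of the seven days,
#' null when present on one to three days, and zero for an empty sheet.
#'
#' @param diary An [ema_diary()].
#' @return An `abit_component_score` with `days_with_paintings` filled in.
#' @export
score_ema <- function(diary) {
  stopifnot(inherits(diary, "abit_ema"))
  g <- diary$grid
  raw <- sum(g)
  days <- sum(rowSums(g) > 0L)
  status <- if (raw == 0L) "zero" else if (days < 4L) "null" else "positive"
  new_component_score("EMA", raw, status, days_with_paintings = days)
}

#' Score the clinical examination
#'
#' One point per positive finding: up to 2 extraoral (masseter / temporal
#' hypertrophy) and up to 5 intraoral (hyperkeratoses and indentations).
#' The clinical assessment identifies awake bruxism only when both sides
#' present at least one finding (`ca_positive`); isolated markers lack
#' predictive power. A component with findings that fails the conjunction
#' is reported with status `null` -- its points still enter the AB Spectrum,
#' since both assessments' scores are summed to define the spectrum, but it
#' does not trigger the clinical identification category. Tooth wear never
#' contributes.
#'
#' @param exam A [clinical_exam()].
#' @return A list with elements `ica` and `eca` (`abit_component_score`s)
#'   and `ca_positive` (logical).
#' @export
score_clinical <- function(exam) {
  stopifnot(inherits(exam, "abit_exam"))
  ica_raw <- sum(exam$findings[INTRAORAL_FINDINGS])
  eca_raw <- sum(exam$findings[EXTRAORAL_FINDINGS])
  ca_positive <- ica_raw >= 1L && eca_raw >= 1L
  status_of <- function(raw) {
    if (raw == 0L) "zero" else if (ca_positive) "positive" else "null"
  }
  list(
    ica = new_component_score("ICA", ica_raw, status_of(ica_raw)),
    eca = new_component_score("ECA", eca_raw, status_of(eca_raw)),
    ca_positive = ca_positive
  )
}

#' Tooth-wear histogram
#'
#' Counts recorded teeth per wear grade 0-4. Complementary data: the
#' histogram never alters a score.
#'
#' @param exam A [clinical_exam()].
#' @return Named integer vector with names `"0"` ... `"4"`.
#' @export
summarize_tooth_wear <- function(exam) {
  stopifnot(inherits(exam, "abit_exam"))
  counts <- tabulate(exam$tooth_wear + 1L, nbins = 5L)
  names(counts) <- as.character(0:4)
  counts
}

#' Score all six components of a record
#'
#' @param record An `abit_record`.
#' @return A list with one `abit_component_score` per component (named
#'   R1, SR, R2, ICA, ECA, EMA) plus `ca_positive`.
#' @export
score_record <- function(record) {
  stopifnot(inherits(record, "abit_record"))
  cli <- score_clinical(record$exam)
  list(
    R1 = score_triplet(record$r1),
    SR = score_triplet(record$sr),
    R2 = score_triplet(record$r2),
    ICA = cli$ica,
    ECA = cli$eca,
    EMA = score_ema(record$ema),
    ca_positive = cli$ca_positive
  )
}

#' Score a cohort into a table
#'
#' One row per record: raw sums and statuses for the six components, DK
#' counts for the triplets, days with paintings, and the CA conjunction.
#'
#' @param records List of `abit_record`s.
#' @return A data frame.
#' @export
score_cohort <- function(records) {
  rows <- lapply(records, function(r) {
    s <- score_record(r)
    data.frame(
      participant_id = r$participant_id,
      stage = r$stage,
      r1_sum = s$R1$raw_sum, r1_status = s$R1$status, r1_dk = s$R1$dk_count,
      sr_sum = s$SR$raw_sum, sr_status = s$SR$status, sr_dk = s$SR$dk_count,
      r2_sum = s$R2$raw_sum, r2_status = s$R2$status, r2_dk = s$R2$dk_count,
      ica_sum = s$ICA$raw_sum, ica_status = s$ICA$status,
      eca_sum = s$ECA$raw_sum, eca_status = s$ECA$status,
      ema_sum = s$EMA$raw_sum, ema_status = s$EMA$status,
      ema_days = s$EMA$days_with_paintings,
      ca_positive = s$ca_positive,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Tabulate perceived awake-bruxism events by behaviour and source
#'
#' For one stage, counts how many participants answered a given behaviour
#' question with any frequency above "never" (score > 0), per source (R1,
#' R2, SR), with a row total across sources. Answers inside null triplets
#' are counted: the tally records perceived events, while the null rule
#' only governs component positivity.
#'
#' @param records List of `abit_record`s, all at `stage`.
#' @param stage `"test"` or `"retest"`.
#' @return A data frame with columns `stage`, `behavior`, `R1`, `R2`, `SR`,
#'   `Total`, and attribute `counting_rule` documenting the interpretation.
#' @export
aggregate_event_counts <- function(records, stage) {
  stage <- match.arg(stage, STAGES)
  actual <- vapply(records, function(r) r$stage, character(1))
  if (length(records) > 0L && any(actual != stage)) {
    stop("aggregate_event_counts: records at stage(s) ",
         paste(unique(actual[actual != stage]), collapse = ", "),
         " mixed into a '", stage, "' aggregate", call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(BEHAVIORS), ncol = 3L,
                   dimnames = list(BEHAVIORS, c("R1", "R2", "SR")))
  for (r in records) {
    for (src in c(R1 = "r1", R2 = "r2", SR = "sr")) {
      tr <- r[[src]]
      pts <- vapply(tr$answers, score_likert, integer(1))
      pos <- !is.na(pts) & pts > 0L
      counts[pos, tr$source] <- counts[pos, tr$source] + 1L
    }
  }
  out <- data.frame(
    stage = stage,
    behavior = BEHAVIORS,
    R1 = counts[, "R1"], R2 = counts[, "R2"], SR = counts[, "SR"],
    Total = as.integer(rowSums(counts)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "counting_rule") <- "any answer with score > 0 counts, including answers inside null triplets"
  out
}
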