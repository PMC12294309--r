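#' Default ABIT instrument definition
#'
#' Component-level score ranges, cut-off rules and spectrum maxima of the
#' Awake Bruxism Identification Tool. Each of the three behaviour-report
#' components (parents' report R1, child self-report SR, parents' report
#' after guided observation R2) sums three 5-point Likert questions, so its
#' component-level range is 0-12. The intraoral clinical assessment (ICA)
#' carries up to 6 points, the extraoral assessment (ECA) up to 2, and the
#' 7-day x 6-slot EMA painting diary up to 42 painted slots. The published
#' instrument table states an overall AB Spectrum range of 0-96, but its
#' own per-component maxima sum to 86; this engine always reports the
#' arithmetic sum of the component maxima (see [max_spectrum()]).
#'
#' @return An object of class `abit_instrument`: a data frame with columns
#'   `component`, `score_min`, `score_max`, `cutoff_rule` and `spectrum_max`,
#'   one row per component in canonical order (R1, SR, R2, ICA, ECA, EMA).
#' @examples
#' inst <- default_instrument()
#' max_spectrum(inst) # 86
#' @seealso [max_spectrum()], [read_instrument()], [write_instrument()]
#' @export
default_instrument <- function() {
  def <- data.frame(
    component = COMPONENTS,
    score_min = 0L,
    score_max = c(12L, 12L, 12L, 6L, 2L, 42L),
    cutoff_rule = c(
      ">=1, null if a single question scores 1",
      ">=1, null if a single question scores 1",
      ">=1, null if a single question scores 1",
      ">=1, valid only with ECA >= 1",
      ">=1, valid only with ICA >= 1",
      ">=4 days with paintings"
    ),
    spectrum_max = c(12L, 12L, 12L, 6L, 2L, 42L),
    stringsAsFactors = FALSE
  )
  class(def) <- c("abit_instrument", "data.frame")
  def
}

#' @export
print.abit_instrument <- function(x, ...) {
  cat("ABIT instrument definition (", nrow(x), " components, spectrum max ",
      sum(x$spectrum_max), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Maximum attainable AB Spectrum score
#'
#' @param instrument An `abit_instrument` definition.
#' @return Integer sum of the per-component spectrum maxima (86 for the
#'   default instrument, despite the published 0-96 headline range).
#' @export
max_spectrum <- function(instrument = default_instrument()) {
  stopifnot(is.data.frame(instrument))
  if (nrow(instrument) == 0L) return(0L)
  as.integer(sum(instrument$spectrum_max))
}

#' Read / write an instrument definition as JSON
#'
#' The JSON format holds one object per component with fields `component`,
#' `score_min`, `score_max`, `cutoff_rule` and `spectrum_max`. Writing is
#' canonical (fixed field order, two-space indentation) so that a definition
#' round-trips byte-identically through `write_instrument()` /
#' `read_instrument()`.
#'
#' @param path File path.
#' @param instrument An `abit_instrument` definition.
#' @return `read_instrument()` returns an `abit_instrument`;
#'   `write_instrument()` returns `path` invisibly.
#' @export
read_instrument <- function(path) {
  df <- jsonlite::fromJSON(path)
  needed <- c("component", "score_min", "score_max", "cutoff_rule", "spectrum_max")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("instrument definition at '", path, "' lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, needed]
  df$score_min <- as.integer(df$score_min)
  df$score_max <- as.integer(df$score_max)
  df$spectrum_max <- as.integer(df$spectrum_max)
  class(df) <- c("abit_instrument", "data.frame")
  df
}

#' @rdname read_instrument
#' @export
write_instrument <- function(instrument, path) {
  json <- jsonlite::toJSON(as.data.frame(instrument), pretty = 2, auto_unbox = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# MD5 of the canonical JSON serialization; stamped into output headers.
instrument_hash <- function(instrument = default_instrument()) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_instrument(instrument, tf)
  unname(tools::md5sum(tf))
}

#' Behaviour-report triplet
#'
#' One administration of a three-question instrument (parents' report R1,
#' child self-report SR, or parents' report after guided observation R2).
#' The three questions ask, in fixed order, about awake teeth grinding,
#' teeth clenching, and mandible bracing/thrusting; answers are on a 5-point
#' frequency Likert scale with an additional "don't know" option.
#'
#' @param source One of `"R1"`, `"SR"`, `"R2"`.
#' @param grinding,clenching,bracing_thrusting Likert labels: one of
#'   `"never"`, `"almost_never"`, `"sometimes"`, `"most_of_time"`,
#'   `"always"`, `"dont_know"` (the file dialect also accepts `"DK"`).
#' @return An object of class `abit_triplet`.
#' @export
behavior_triplet <- function(source, grinding, clenching, bracing_thrusting) {
  source <- match.arg(source, TRIPLET_SOURCES)
  ans <- c(grinding = canonical_likert(grinding),
           clenching = canonical_likert(clenching),
           bracing_thrusting = canonical_likert(bracing_thrusting))
  structure(list(source = source, answers = ans), class = "abit_triplet")
}

# Normalise a Likert label; "DK" is the file alias for dont_know.
# Unknown labels pass through so validate_record() can report them.
canonical_likert <- function(label) {
  label <- as.character(label)
  if (length(label) != 1L || is.na(label)) return(NA_character_)
  if (identical(label, "DK")) return(DK_LABEL)
  label
}

#' EMA painting diary
#'
#' The analog ecological momentary assessment sheet: 42 emoji slots, six per
#' study day over the seven days following the initial interview. A painted
#' slot records one perceived awake-bruxism event.
#'
#' @param grid 7 x 6 logical (or 0/1) matrix; rows are study days 1-7,
#'   columns slots 1-6.
#' @return An object of class `abit_ema`.
#' @export
ema_diary <- function(grid = matrix(FALSE, 7, 6)) {
  grid <- matrix(as.logical(grid), nrow = nrow(as.matrix(grid)))
  dimnames(grid) <- list(paste0("d", seq_len(nrow(grid))),
                         paste0("s", seq_len(ncol(grid))))
  structure(list(grid = grid), class = "abit_ema")
}

#' Clinical examination record
#'
#' Extraoral findings (masseter and temporal muscle hypertrophy) and the
#' five point-scoring intraoral findings (buccal hyperkeratosis / linea
#' alba, labial hyperkeratosis, labial indentation, tongue indentation,
#' buccal indentation), plus per-tooth wear grades on the five-point
#' ordinal scale (0 = none ... 4 = crown height loss >= 2/3). Tooth wear is
#' complementary data and never enters any score.
#'
#' @param masseter_hypertrophy,temporal_hypertrophy Logical.
#' @param buccal_hyperkeratosis_linea_alba,labial_hyperkeratosis,labial_indentation,tongue_indentation,buccal_indentation
#'   Logical.
#' @param tooth_wear Named integer vector, names are FDI two-digit tooth
#'   identifiers, values wear grades in 0-4.
#' @return An object of class `abit_exam`.
#' @export
clinical_exam <- function(masseter_hypertrophy = FALSE,
                          temporal_hypertrophy = FALSE,
                          buccal_hyperkeratosis_linea_alba = FALSE,
                          labial_hyperkeratosis = FALSE,
                          labial_indentation = FALSE,
                          tongue_indentation = FALSE,
                          buccal_indentation = FALSE,
                          tooth_wear = integer(0)) {
  findings <- c(
    masseter_hypertrophy = as.logical(masseter_hypertrophy),
    temporal_hypertrophy = as.logical(temporal_hypertrophy),
    buccal_hyperkeratosis_linea_alba = as.logical(buccal_hyperkeratosis_linea_alba),
    labial_hyperkeratosis = as.logical(labial_hyperkeratosis),
    labial_indentation = as.logical(labial_indentation),
    tongue_indentation = as.logical(tongue_indentation),
    buccal_indentation = as.logical(buccal_indentation)
  )
  tw <- tooth_wear
  if (length(tw) > 0L) {
    storage.mode(tw) <- "integer"
    if (is.null(names(tw))) stop("tooth_wear must be a named vector (FDI tooth -> grade)", call. = FALSE)
  } else {
    tw <- structure(integer(0), names = character(0))
  }
  structure(list(findings = findings, tooth_wear = tw), class = "abit_exam")
}

#' Participant record
#'
#' One ABIT administration for one child at one stage (test or retest):
#' the three behaviour-report triplets, the EMA diary, the clinical exam,
#' and the anamnesis sleep-bruxism flag (metadata only; it never enters a
#' score).
#'
#' @param participant_id Character id.
#' @param age_years Integer, 8-12.
#' @param stage `"test"` or `"retest"`.
#' @param r1,sr,r2 [behavior_triplet()] objects with matching sources.
#' @param ema An [ema_diary()].
#' @param exam A [clinical_exam()].
#' @param sb_reported Optional logical: sleep bruxism reported at anamnesis.
#' @return An object of class `abit_record`.
#' @export
participant_record <- function(participant_id, age_years, stage,
                               r1, sr, r2, ema, exam, sb_reported = NA) {
  structure(list(
    participant_id = as.character(participant_id),
    age_years = as.integer(age_years),
    stage = as.character(stage),
    r1 = r1, sr = sr, r2 = r2,
    ema = ema, exam = exam,
    sb_reported = as.logical(sb_reported)
  ), class = "abit_record")
}

#' @export
print.abit_record <- function(x, ...) {
  cat("ABIT record ", x$participant_id, " (age ", x$age_years, ", ",
      x$stage, ")\n", sep = "")
  for (s in c("r1", "sr", "r2")) {
    cat("  ", toupper(s), ": ", paste(x[[s]]$answers, collapse = ", "), "\n", sep = "")
  }
  cat("  EMA: ", sum(x$ema$grid), " painted slot(s) on ",
      sum(rowSums(x$ema$grid) > 0), " day(s)\n", sep = "")
  cat("  Exam: ", sum(x$exam$findings), " positive finding(s), ",
      length(x$exam$tooth_wear), " teeth graded\n", sep = "")
  invisible(x)
}

finding_row <- function(field, rule, message, severity = "error") {
  data.frame(field = field, rule = rule, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

#' Validate a participant record
#'
#' Checks every structural invariant of an ABIT record and returns findings
#' rather than raising conditions: age within 8-12, recognised stage, triplet
#' sources matching their slots, legal Likert labels, a 7 x 6 EMA grid, wear
#' grades on the 0-4 ordinal scale. An all-"don't know" triplet is legal but
#' flagged with a warning-severity finding. The record is never mutated.
#'
#' @param record An `abit_record`.
#' @return A data frame with columns `field`, `rule`, `message`, `severity`;
#'   zero rows when every invariant holds. A record is valid when it has no
#'   `"error"`-severity finding.
#' @export
validate_record <- function(record) {
  f <- list()
  add <- function(x) f[[length(f) + 1L]] <<- x

  if (!inherits(record, "abit_record")) {
    return(finding_row("record", "class", "not an abit_record"))
  }
  if (is.na(record$age_years) || record$age_years < 8L || record$age_years > 12L) {
    add(finding_row("age_years", "range",
                    sprintf("age_years must be in [8, 12], got %s", record$age_years)))
  }
  if (!record$stage %in% STAGES) {
    add(finding_row("stage", "domain",
                    sprintf("stage must be 'test' or 'retest', got '%s'", record$stage)))
  }
  for (slot in c("r1", "sr", "r2")) {
    tr <- record[[slot]]
    want <- toupper(sub("^sr$", "SR", slot))
    want <- c(r1 = "R1", sr = "SR", r2 = "R2")[[slot]]
    if (!inherits(tr, "abit_triplet")) {
      add(finding_row(slot, "class", sprintf("%s is not a behavior_triplet", slot)))
      next
    }
    if (!identical(tr$source, want)) {
      add(finding_row(slot, "source",
                      sprintf("%s slot must have source %s, got %s", slot, want, tr$source)))
    }
    bad <- !(tr$answers %in% c(LIKERT_LABELS, DK_LABEL))
    for (q in names(tr$answers)[bad]) {
      add(finding_row(paste0(slot, "_", q), "likert_label",
                      sprintf("unknown Likert label '%s'", tr$answers[[q]])))
    }
    if (!any(bad) && all(tr$answers == DK_LABEL)) {
      add(finding_row(slot, "all_dk",
                      sprintf("%s triplet is all 'don't know'; scored as zero with dk_count 3", slot),
                      severity = "warning"))
    }
  }
  if (!inherits(record$ema, "abit_ema") ||
      !identical(dim(record$ema$grid), c(7L, 6L)) ||
      anyNA(record$ema$grid)) {
    add(finding_row("ema", "grid",
                    "EMA grid must be a complete 7 x 6 logical matrix"))
  }
  if (!inherits(record$exam, "abit_exam") || anyNA(record$exam$findings)) {
    add(finding_row("exam", "findings",
                    "clinical exam must record all seven findings as TRUE/FALSE"))
  } else {
    tw <- record$exam$tooth_wear
    bad <- is.na(tw) | tw < 0L | tw > 4L
    if (any(bad)) {
      add(finding_row("tooth_wear", "grade_scale",
                      sprintf("wear grade outside 0-4 for tooth/teeth %s",
                              paste(names(tw)[bad], collapse = ", "))))
    }
  }
  if (length(f) == 0L) {
    return(data.frame(field = character(0), rule = character(0),
                      message = character(0), severity = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, f)
}

# TRUE when a record carries no error-severity finding.
record_is_valid <- function(record) {
  v <- validate_record(record)
  !any(v$severity == "error")
}
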