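# Cohort file formats: flat CSV and a JSON-lines dialect with nested
# objects, interchangeable and round-trip safe. Output files carry a header
# comment with tool version, instrument hash and seed; readers skip
# '#'-prefixed lines.

EMA_COLUMNS <- as.vector(t(outer(1:7, 1:6, function(d, s) sprintf("d%ds%d", d, s))))
CLINICAL_COLUMNS <- c(EXTRAORAL_FINDINGS, INTRAORAL_FINDINGS)
TRIPLET_COLUMNS <- as.vector(t(outer(c("r1", "sr", "r2"), BEHAVIORS, paste, sep = "_")))
COHORT_COLUMNS <- c("participant_id", "age_years", "stage", TRIPLET_COLUMNS,
                    EMA_COLUMNS, CLINICAL_COLUMNS, "tooth_wear", "sb_reported")

validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("abit_validation_error", "error")))
}
io_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("abit_io_error", "error")))
}

output_header <- function(seed = NA) {
  sprintf("# abit %s instrument=%s seed=%s",
          as.character(utils::packageVersion("abit")),
          instrument_hash(), as.character(seed))
}

is_jsonl_path <- function(path) grepl("\\.(json|jsonl|ndjson)$", path, ignore.case = TRUE)

parse_likert_cell <- function(token, row, column) {
  tok <- canonical_likert(token)
  if (!tok %in% c(LIKERT_LABELS, DK_LABEL)) {
    validation_error("row ", row, ", column '", column,
                     "': unknown Likert label '", token, "'")
  }
  tok
}

parse_binary_cell <- function(token, row, column) {
  if (!token %in% c("0", "1", "TRUE", "FALSE")) {
    validation_error("row ", row, ", column '", column,
                     "': expected 0/1, got '", token, "'")
  }
  token %in% c("1", "TRUE")
}

parse_tooth_wear <- function(token, row) {
  if (is.na(token) || !nzchar(token)) {
    return(structure(integer(0), names = character(0)))
  }
  pairs <- strsplit(token, ";", fixed = TRUE)[[1L]]
  parts <- strsplit(pairs, ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L || !grepl("^[0-9]+$", p[2L]), logical(1))
  if (any(bad)) {
    validation_error("row ", row, ", column 'tooth_wear': expected ",
                     "semicolon-delimited tooth:grade pairs, got '", token, "'")
  }
  grades <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  names(grades) <- vapply(parts, `[[`, character(1), 1L)
  grades
}

check_cohort_schema <- function(cols) {
  ema_like <- grepl("^d[0-9]+s[0-9]+$", cols)
  stray <- setdiff(cols[ema_like], EMA_COLUMNS)
  if (length(stray) > 0L) {
    validation_error("schema: EMA column(s) outside the 7-day x 6-slot sheet: ",
                     paste(stray, collapse = ", "))
  }
  required <- setdiff(COHORT_COLUMNS, c("tooth_wear", "sb_reported"))
  missing <- setdiff(required, cols)
  if (length(missing) > 0L) {
    validation_error("schema: missing column(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(cols, COHORT_COLUMNS)
  if (length(unknown) > 0L) {
    validation_error("schema: unknown column(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

cohort_row_to_record <- function(row, i) {
  triplet_of <- function(slot, source) {
    labs <- vapply(BEHAVIORS, function(b) {
      col <- paste(slot, b, sep = "_")
      parse_likert_cell(row[[col]], i, col)
    }, character(1))
    behavior_triplet(source, labs[1L], labs[2L], labs[3L])
  }
  grid <- matrix(FALSE, 7L, 6L)
  for (d in 1:7) for (s in 1:6) {
    col <- sprintf("d%ds%d", d, s)
    grid[d, s] <- parse_binary_cell(row[[col]], i, col)
  }
  findings <- lapply(CLINICAL_COLUMNS, function(col) parse_binary_cell(row[[col]], i, col))
  names(findings) <- CLINICAL_COLUMNS
  age <- suppressWarnings(as.integer(row[["age_years"]]))
  if (is.na(age)) {
    validation_error("row ", i, ", column 'age_years': expected an integer, got '",
                     row[["age_years"]], "'")
  }
  sb <- row[["sb_reported"]]
  sb <- if (is.null(sb) || is.na(sb) || !nzchar(sb)) NA else parse_binary_cell(sb, i, "sb_reported")
  tw_tok <- if (is.null(row[["tooth_wear"]])) "" else row[["tooth_wear"]]
  participant_record(
    participant_id = row[["participant_id"]],
    age_years = age,
    stage = row[["stage"]],
    r1 = triplet_of("r1", "R1"),
    sr = triplet_of("sr", "SR"),
    r2 = triplet_of("r2", "R2"),
    ema = ema_diary(grid),
    exam = do.call(clinical_exam, c(findings, list(tooth_wear = parse_tooth_wear(tw_tok, i)))),
    sb_reported = sb
  )
}

#' Read a cohort of participant records
#'
#' Accepts the flat CSV dialect (one row per participant-stage; Likert
#' labels or `"DK"`; EMA as 0/1 columns `d1s1` ... `d7s6`; clinical findings
#' as 0/1; tooth wear as `"tooth:grade"` pairs joined by `";"`) or the
#' equivalent JSON-lines dialect with nested objects (extension `.json` /
#' `.jsonl`). Lines starting with `#` are skipped. Parse problems are
#' reported with the offending row, column and token; records violating a
#' structural invariant raise a validation error.
#'
#' @param path Input file.
#' @return List of `abit_record`s.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) io_error("input file not found: ", path)
  records <- if (is_jsonl_path(path)) read_cohort_jsonl(path) else read_cohort_csv(path)
  for (i in seq_along(records)) {
    v <- validate_record(records[[i]])
    errs <- v[v$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0L) {
      validation_error("record ", i, " (", records[[i]]$participant_id, "): ",
                       paste(errs$message, collapse = "; "))
    }
  }
  records
}

read_cohort_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", comment.char = "#",
                    check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) io_error("cannot parse CSV at ", path, ": ", conditionMessage(e))
  )
  check_cohort_schema(names(df))
  lapply(seq_len(nrow(df)), function(i) cohort_row_to_record(as.list(df[i, ]), i))
}

read_cohort_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) validation_error("row ", i, ": malformed JSON: ",
                                                         conditionMessage(e)))
    json_record(obj, i)
  })
}

json_record <- function(obj, i) {
  need <- c("participant_id", "age_years", "stage", "r1", "sr", "r2", "ema", "exam")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0L) {
    validation_error("row ", i, ": missing field(s): ", paste(missing, collapse = ", "))
  }
  triplet_of <- function(slot, source) {
    tr <- obj[[slot]]
    labs <- vapply(BEHAVIORS, function(b) {
      if (is.null(tr[[b]])) validation_error("row ", i, ": ", slot, " lacks '", b, "'")
      parse_likert_cell(as.character(tr[[b]]), i, paste(slot, b, sep = "_"))
    }, character(1))
    behavior_triplet(source, labs[1L], labs[2L], labs[3L])
  }
  ema <- obj$ema
  if (is.list(ema)) {
    if (length(ema) != 7L || any(lengths(ema) != 6L)) {
      validation_error("row ", i, ": EMA grid must be 7 days of 6 slots")
    }
    ema <- do.call(rbind, ema)
  }
  ema <- as.matrix(ema)
  if (!identical(dim(ema), c(7L, 6L))) {
    validation_error("row ", i, ": EMA grid must be 7 days of 6 slots")
  }
  ex <- obj$exam
  findings <- lapply(CLINICAL_COLUMNS, function(col) {
    if (is.null(ex[[col]])) validation_error("row ", i, ": exam lacks '", col, "'")
    isTRUE(ex[[col]] == 1) || isTRUE(ex[[col]])
  })
  names(findings) <- CLINICAL_COLUMNS
  tw <- ex$tooth_wear
  tw <- if (is.null(tw) || length(tw) == 0L) {
    structure(integer(0), names = character(0))
  } else {
    structure(as.integer(unlist(tw)), names = names(tw))
  }
  sb <- obj$sb_reported
  sb <- if (is.null(sb) || length(sb) == 0L || is.na(sb)) NA else isTRUE(sb == 1) || isTRUE(sb)
  participant_record(
    participant_id = as.character(obj$participant_id),
    age_years = as.integer(obj$age_years),
    stage = as.character(obj$stage),
    r1 = triplet_of("r1", "R1"), sr = triplet_of("sr", "SR"),
    r2 = triplet_of("r2", "R2"),
    ema = ema_diary(ema),
    exam = do.call(clinical_exam, c(findings, list(tooth_wear = tw))),
    sb_reported = sb
  )
}

record_to_row <- function(r) {
  row <- list(participant_id = r$participant_id,
              age_years = r$age_years,
              stage = r$stage)
  for (slot in c("r1", "sr", "r2")) {
    for (b in BEHAVIORS) {
      lab <- r[[slot]]$answers[[b]]
      row[[paste(slot, b, sep = "_")]] <- if (lab == DK_LABEL) "DK" else lab
    }
  }
  for (d in 1:7) for (s in 1:6) {
    row[[sprintf("d%ds%d", d, s)]] <- as.integer(r$ema$grid[d, s])
  }
  for (col in CLINICAL_COLUMNS) row[[col]] <- as.integer(r$exam$findings[[col]])
  tw <- r$exam$tooth_wear
  row[["tooth_wear"]] <- if (length(tw) == 0L) "" else {
    paste(sprintf("%s:%d", names(tw), tw), collapse = ";")
  }
  row[["sb_reported"]] <- if (is.na(r$sb_reported)) "" else as.integer(r$sb_reported)
  row
}

#' Write a cohort of participant records
#'
#' Writes the canonical form of the documented CSV or JSON-lines dialect,
#' preceded by a `#` header line with tool version, instrument hash and
#' seed. `write_cohort(read_cohort(f))` is byte-equivalent to the canonical
#' form of `f`.
#'
#' @param records List of `abit_record`s.
#' @param path Output file; a `.json`/`.jsonl` extension selects the
#'   JSON-lines dialect.
#' @param seed Seed stamped in the header (NA when the cohort was not
#'   simulated).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, seed = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  if (is_jsonl_path(path)) {
    for (r in records) {
      obj <- list(
        participant_id = r$participant_id, age_years = r$age_years,
        stage = r$stage,
        r1 = as.list(ifelse(r$r1$answers == DK_LABEL, "DK", r$r1$answers)),
        sr = as.list(ifelse(r$sr$answers == DK_LABEL, "DK", r$sr$answers)),
        r2 = as.list(ifelse(r$r2$answers == DK_LABEL, "DK", r$r2$answers)),
        ema = apply(unname(r$ema$grid) * 1L, 1L, identity, simplify = FALSE),
        exam = c(as.list(as.integer(r$exam$findings))[seq_along(CLINICAL_COLUMNS)],
                 list(tooth_wear = as.list(r$exam$tooth_wear))),
        sb_reported = if (is.na(r$sb_reported)) NULL else as.integer(r$sb_reported)
      )
      names(obj$exam)[seq_along(CLINICAL_COLUMNS)] <- CLINICAL_COLUMNS
      writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")), con)
    }
  } else {
    rows <- lapply(records, record_to_row)
    df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE,
                                                                check.names = FALSE)))
    if (is.null(df)) {
      df <- as.data.frame(stats::setNames(rep(list(character(0)), length(COHORT_COLUMNS)),
                                          COHORT_COLUMNS), check.names = FALSE)
    }
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Generic CSV writer with the standard header comment.
write_output_csv <- function(df, path, seed = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

reliability_as_list <- function(rep) {
  list(
    alpha_r1 = rep$alpha_r1, alpha_r2 = rep$alpha_r2,
    totals = rep$totals, report_sums = rep$report_sums,
    n = rep$n, ci_level = rep$ci_level
  )
}

write_reliability_json <- function(rep, path, seed = NA) {
  obj <- c(list(`_meta` = list(tool = "abit",
                               version = as.character(utils::packageVersion("abit")),
                               instrument = instrument_hash(),
                               seed = if (is.na(seed)) NULL else seed)),
           reliability_as_list(rep))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
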