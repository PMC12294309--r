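# AB Spectrum composition and identification categories.

CATEGORY_ORDER <- c("AB_R_SR_EMA", "AB_R_SR", "AB_EMA", "AB_CA", "NOT_AB")
CATEGORY_LABELS <- c(
  AB_R_SR_EMA = "AB based on R/SR and EMA",
  AB_R_SR = "AB based on R/SR",
  AB_EMA = "AB based on EMA",
  AB_CA = "AB based on CA",
  NOT_AB = "Not AB"
)

#' Points a component contributes to the AB Spectrum
#'
#' Positive components contribute their raw sum. Zero components contribute
#' nothing. Null report and EMA components contribute nothing -- null is
#' grouped with zero under "Not AB", and letting their points accumulate
#' would give a "Not AB" child a nonzero spectrum. The clinical components
#' (ICA, ECA) always contribute their raw sums: both assessments' scores are
#' summed to define the spectrum even when the conjunction required for the
#' clinical identification category fails.
#'
#' @param score An `abit_component_score`.
#' @param instrument An `abit_instrument`.
#' @return Integer points, never exceeding the component's spectrum maximum.
#' @export
component_contribution <- function(score, instrument = default_instrument()) {
  stopifnot(inherits(score, "abit_component_score"))
  row <- instrument[instrument$component == score$component, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("component '", score$component, "' not in instrument definition", call. = FALSE)
  }
  if (score$raw_sum > row$score_max || score$raw_sum < row$score_min) {
    stop("raw_sum ", score$raw_sum, " outside declared range [",
         row$score_min, ", ", row$score_max, "] for ", score$component,
         call. = FALSE)
  }
  if (score$component %in% c("ICA", "ECA")) return(score$raw_sum)
  switch(score$status,
         positive = score$raw_sum,
         zero = 0L,
         null = 0L,
         stop("unknown status '", score$status, "'", call. = FALSE))
}

#' Compose component scores into an AB Spectrum result
#'
#' Sums the per-component contributions into the AB Spectrum total and assigns
#' identification categories: a positive report or self-report (any of R1,
#' SR, R2) gives "AB based on R/SR"; combined with a positive EMA it becomes
#' "AB based on report, self-report and EMA" (replacing the bare category);
#' a positive EMA without any positive report gives "AB based on EMA"; a
#' positive clinical conjunction adds "AB based on CA" to whatever else
#' holds; and a child whose components are all zero or null is "Not AB".
#'
#' @param scores Named list of six `abit_component_score`s
#'   (R1, SR, R2, ICA, ECA, EMA).
#' @param ca_positive Logical: both clinical assessments present at least
#'   one finding.
#' @param instrument An `abit_instrument`.
#' @return An object of class `abit_spectrum`: list with `contributions`
#'   (named integer vector), `total`, `categories` (character subset of the
#'   category codes) and `label` (human-readable, fixed order).
#' @export
compute_spectrum <- function(scores, ca_positive,
                             instrument = default_instrument()) {
  missing <- setdiff(COMPONENTS, names(scores))
  if (length(missing) > 0L) {
    stop("compute_spectrum needs one score per component; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contributions <- vapply(
    COMPONENTS,
    function(cp) component_contribution(scores[[cp]], instrument),
    integer(1)
  )
  total <- as.integer(sum(contributions))

  report_pos <- any(vapply(c("R1", "SR", "R2"),
                           function(cp) scores[[cp]]$status == "positive",
                           logical(1)))
  ema_pos <- scores$EMA$status == "positive"

  cats <- character(0)
  if (report_pos && ema_pos) cats <- c(cats, "AB_R_SR_EMA")
  if (report_pos && !ema_pos) cats <- c(cats, "AB_R_SR")
  if (!report_pos && ema_pos) cats <- c(cats, "AB_EMA")
  if (isTRUE(ca_positive)) cats <- c(cats, "AB_CA")
  if (length(cats) == 0L) cats <- "NOT_AB"
  cats <- CATEGORY_ORDER[CATEGORY_ORDER %in% cats]

  structure(list(
    contributions = contributions,
    total = total,
    categories = cats,
    label = paste(CATEGORY_LABELS[cats], collapse = " + ")
  ), class = "abit_spectrum")
}

#' @export
print.abit_spectrum <- function(x, ...) {
  cat("AB Spectrum: ", x$total, "  [", x$label, "]\n", sep = "")
  cat("  contributions: ",
      paste(sprintf("%s=%d", names(x$contributions), x$contributions),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify a participant record
#'
#' Convenience wrapper: scores all six components of a record and composes
#' them into a spectrum result.
#'
#' @param record An `abit_record`.
#' @param instrument An `abit_instrument`.
#' @return An `abit_spectrum`.
#' @export
classify_record <- function(record, instrument = default_instrument()) {
  s <- score_record(record)
  compute_spectrum(s[COMPONENTS], s$ca_positive, instrument)
}

#' Classify a cohort into a table
#'
#' @param records List of `abit_record`s.
#' @param instrument An `abit_instrument`.
#' @return Data frame: participant, stage, six contributions, total,
#'   category codes (comma-joined) and label.
#' @export
classify_cohort <- function(records, instrument = default_instrument()) {
  rows <- lapply(records, function(r) {
    sp <- classify_record(r, instrument)
    df <- data.frame(
      participant_id = r$participant_id,
      stage = r$stage,
      stringsAsFactors = FALSE
    )
    for (cp in COMPONENTS) df[[tolower(cp)]] <- sp$contributions[[cp]]
    df$total <- sp$total
    df$categories <- paste(sp$categories, collapse = ",")
    df$label <- sp$label
    df
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
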