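# Test-retest reliability: Cronbach's alpha, two-way single-measure ICC
# (consistency and agreement forms), Lin's concordance correlation
# coefficient with a Fisher-z confidence interval.

check_ratings <- function(m, min_rows = 2L, min_cols = 2L) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("ratings matrix must be numeric", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("ratings matrix must have finite entries and no missing cells", call. = FALSE)
  }
  if (nrow(m) < min_rows) {
    stop("need at least ", min_rows, " subjects, got ", nrow(m), call. = FALSE)
  }
  if (ncol(m) < min_cols) {
    stop("need at least ", min_cols, " columns, got ", ncol(m), call. = FALSE)
  }
  m
}

#' Cronbach's alpha
#'
#' Internal consistency over the items of one administration:
#' alpha = k/(k-1) * (1 - sum(item variances) / variance of the total),
#' with sample (n-1) variances.
#'
#' @param m Numeric matrix, subjects x items (k >= 2), no missing cells.
#' @return Alpha (<= 1; can be negative for adversely correlated items).
#' @examples
#' m <- matrix(c(1, 2, 2, 3, 3, 4, 4, 5), ncol = 2, byrow = TRUE)
#' cronbach_alpha(m) # 1
#' @export
cronbach_alpha <- function(m) {
  m <- check_ratings(m)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  }
  item_var <- sum(apply(m, 2L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

# Two-way mean squares (subjects x raters/administrations), via aov.
two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1L]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  list(msr = ms[["subject"]], msc = ms[["rater"]], mse = ms[["Residuals"]],
       n = n, k = k)
}

#' Single-measure intraclass correlation, two-way model
#'
#' From the two-way ANOVA decomposition over subjects x administrations
#' with k = 2 administrations. The consistency form is
#' (MSR - MSE) / (MSR + (k-1) MSE); the absolute-agreement form adds the
#' administration (column) variance to the denominator:
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)). These are the
#' McGraw-Wong ICC(C,1) and ICC(A,1) single-measure coefficients.
#'
#' @param m Numeric matrix, subjects x administrations (n >= 3, typically
#'   2 columns).
#' @param form `"consistency"` or `"agreement"`.
#' @return The ICC (<= 1).
#' @export
icc_single <- function(m, form = c("consistency", "agreement")) {
  form <- match.arg(form)
  m <- check_ratings(m, min_rows = 3L)
  ms <- two_way_ms(m)
  if (ms$msr <= .Machine$double.eps && ms$mse <= .Machine$double.eps) {
    stop("degenerate ratings (no subject or residual variance); ICC undefined",
         call. = FALSE)
  }
  num <- ms$msr - ms$mse
  den <- ms$msr + (ms$k - 1) * ms$mse
  if (form == "agreement") den <- den + (ms$k / ms$n) * (ms$msc - ms$mse)
  num / den
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements around the identity line:
#' ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with
#' n-denominator moments. The confidence interval applies Fisher's
#' z-transform to the ccc with Lin's (1989) variance estimator and
#' back-transforms the endpoints.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param ci_level Confidence level, default 0.95.
#' @return List with `ccc`, `ci_low`, `ci_high`, `n`.
#' @export
lin_ccc <- function(x, y, ci_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs, got ", n, call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired scores", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 <= 0 && sy2 <= 0) {
    stop("zero variance in both measurements; CCC undefined", call. = FALSE)
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  # Lin 1989 variance of the z-transformed ccc; degenerates (r = 0 or
  # |ccc| = 1) yield a collapsed or unit-width interval.
  ci_low <- ci_high <- ccc
  r2 <- if (sx2 > 0 && sy2 > 0) sxy^2 / (sx2 * sy2) else 0
  if (n > 2L && r2 > 0 && abs(ccc) < 1) {
    u2 <- (mx - my)^2 / sqrt(sx2 * sy2)
    one_m <- 1 - ccc^2
    var_z <- (1 / (n - 2)) * (
      (1 - r2) * ccc^2 / (one_m * r2) +
        2 * ccc^3 * (1 - ccc) * u2 / (sqrt(r2) * one_m^2) -
        ccc^4 * u2^2 / (2 * r2 * one_m^2)
    )
    var_z <- max(var_z, 0)
    z <- atanh(ccc)
    zc <- stats::qnorm(1 - (1 - ci_level) / 2)
    ci_low <- tanh(z - zc * sqrt(var_z))
    ci_high <- tanh(z + zc * sqrt(var_z))
  }
  list(ccc = ccc, ci_low = ci_low, ci_high = ci_high, n = n)
}

# Subjects x 3 matrix of question scores for one report of one cohort.
# Participants with a DK (unscored) answer are dropped with a warning,
# since alpha requires complete cells.
triplet_item_matrix <- function(records, slot) {
  rows <- t(vapply(records, function(r) {
    vapply(r[[slot]]$answers, score_likert, integer(1))
  }, integer(3)))
  keep <- stats::complete.cases(rows)
  if (any(!keep)) {
    warning(sum(!keep), " participant(s) dropped from alpha(",
            toupper(slot), "): don't-know answers leave no score", call. = FALSE)
  }
  rows[keep, , drop = FALSE]
}

#' Test-retest reliability report
#'
#' Computes the reliability statistics of a paired test/retest design:
#' Cronbach's alpha over the three parents'-report questions (R1) and the
#' three post-observation questions (R2) of the test administration;
#' two-way single-measure ICC (consistency and agreement) and Lin's CCC
#' with confidence interval over the paired AB Spectrum totals. Because
#' the literature does not fix which composite the temporal-stability
#' coefficients are taken over, the same ICC/CCC block is also computed
#' over the summed report scores (R1 + SR + R2) and labelled as such.
#'
#' @param test_cohort,retest_cohort Lists of `abit_record`s with matching
#'   participant ids (an unmatched id on either side is an error).
#' @param instrument An `abit_instrument`.
#' @param ci_level Confidence level for the CCC interval.
#' @return An object of class `abit_reliability`: list with `alpha_r1`,
#'   `alpha_r2`, `totals` and `report_sums` blocks (each with
#'   `icc_consistency`, `icc_agreement`, `ccc`, `ccc_ci_low`,
#'   `ccc_ci_high`), and `n` matched pairs.
#' @export
reliability_report <- function(test_cohort, retest_cohort,
                               instrument = default_instrument(),
                               ci_level = 0.95) {
  ids_t <- vapply(test_cohort, function(r) r$participant_id, character(1))
  ids_r <- vapply(retest_cohort, function(r) r$participant_id, character(1))
  orphans <- c(setdiff(ids_t, ids_r), setdiff(ids_r, ids_t))
  if (length(orphans) > 0L) {
    stop("unmatched participant id(s) across stages: ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  }
  n <- length(ids_t)
  if (n < 3L) {
    stop("need at least 3 matched participants for ICC/CCC, got ", n, call. = FALSE)
  }
  retest_cohort <- retest_cohort[match(ids_t, ids_r)]

  totals <- function(cohort) {
    vapply(cohort, function(r) classify_record(r, instrument)$total, integer(1))
  }
  report_sum <- function(cohort) {
    vapply(cohort, function(r) {
      s <- score_record(r)
      s$R1$raw_sum + s$SR$raw_sum + s$R2$raw_sum
    }, integer(1))
  }

  pair_block <- function(x, y) {
    m <- cbind(x, y)
    ccc <- lin_ccc(x, y, ci_level)
    list(icc_consistency = icc_single(m, "consistency"),
         icc_agreement = icc_single(m, "agreement"),
         ccc = ccc$ccc, ccc_ci_low = ccc$ci_low, ccc_ci_high = ccc$ci_high)
  }

  structure(list(
    alpha_r1 = cronbach_alpha(triplet_item_matrix(test_cohort, "r1")),
    alpha_r2 = cronbach_alpha(triplet_item_matrix(test_cohort, "r2")),
    totals = pair_block(totals(test_cohort), totals(retest_cohort)),
    report_sums = pair_block(report_sum(test_cohort), report_sum(retest_cohort)),
    n = n,
    ci_level = ci_level
  ), class = "abit_reliability")
}

#' @export
print.abit_reliability <- function(x, ...) {
  cat("ABIT test-retest reliability (n =", x$n, "matched pairs)\n")
  cat(sprintf("  Cronbach's alpha: R1 = %.3f, R2 = %.3f\n", x$alpha_r1, x$alpha_r2))
  blk <- function(name, b) {
    cat(sprintf("  %s: ICC consistency = %.3f, ICC agreement = %.3f,\n",
                name, b$icc_consistency, b$icc_agreement))
    cat(sprintf("    CCC = %.3f (%.0f%% CI %.3f-%.3f)\n",
                b$ccc, 100 * x$ci_level, b$ccc_ci_low, b$ccc_ci_high))
  }
  blk("AB Spectrum totals", x$totals)
  blk("Report sums (R1+SR+R2)", x$report_sums)
  invisible(x)
}
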