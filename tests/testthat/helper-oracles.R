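# Independent oracles, coded from definitions along different routes than
# the implementation.

# --- triplet status: explicit pattern sets, not the implementation's rule
oracle_triplet_status <- function(scores) {
  s <- scores[!is.na(scores)]
  key <- paste(sort(s, decreasing = TRUE), collapse = ",")
  null_patterns <- c("1,0,0", "1,0", "1") # one answer at 1, rest (if any) at 0
  zero_patterns <- c("0,0,0", "0,0", "0", "")
  if (key %in% zero_patterns) "zero" else if (key %in% null_patterns) "null" else "positive"
}

# --- category decision table from the published definitions
oracle_categories <- function(st_r1, st_sr, st_r2, st_ema, ca_positive) {
  rep_pos <- "positive" %in% c(st_r1, st_sr, st_r2)
  ema_pos <- st_ema == "positive"
  cats <- character(0)
  if (rep_pos && ema_pos) cats <- "AB_R_SR_EMA"
  if (rep_pos && !ema_pos) cats <- "AB_R_SR"
  if (!rep_pos && ema_pos) cats <- "AB_EMA"
  if (ca_positive) cats <- c(cats, "AB_CA")
  if (length(cats) == 0L) cats <- "NOT_AB"
  sort(cats)
}

# --- Cronbach's alpha via the item covariance matrix
oracle_alpha_cov <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
}

# --- two-way mean squares by explicit sums of squares (no aov)
oracle_two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)))
}

oracle_icc <- function(m, form) {
  ms <- oracle_two_way_ms(m)
  n <- nrow(m); k <- ncol(m)
  den <- ms$msr + (k - 1) * ms$mse
  if (form == "agreement") den <- den + (k / n) * (ms$msc - ms$mse)
  (ms$msr - ms$mse) / den
}

# --- CCC as pearson r times the bias-correction factor C_b
oracle_ccc_rcb <- function(x, y) {
  n <- length(x)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  v <- sx / sy
  cb <- 2 / (v + 1 / v + u^2)
  stats::cor(x, y) * cb
}
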