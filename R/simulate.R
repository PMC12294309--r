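# Seeded synthetic ABIT cohorts with known ground truth.
#
# Each child carries a latent awake-bruxism propensity theta (mean daily
# event rate). Daily event counts are Poisson(theta) truncated at the six
# sheet slots; a slot is painted when the child records the event
# (Bernoulli(adherence)). Likert answers derive from the behaviour-specific
# rate through fixed ordinal thresholds, then may slip one category with
# probability report_noise. Clinical findings are Bernoulli with
# group-specific probabilities. Test and retest share all non-latent random
# draws (common random numbers); only theta moves between stages, through a
# Gaussian copula with correlation retest_rho, so retest_rho = 1 with zero
# noise reproduces the test records exactly.

LIKERT_THRESHOLDS <- c(0.05, 0.35, 1.0, 2.0) # events/day -> category 0..4
SIM_TEETH <- c("16", "26", "36", "46", "11", "21", "31", "41") # index teeth, FDI

#' Simulation parameters for synthetic ABIT cohorts
#'
#' Defaults describe a pilot-scale cohort: 10 children aged 8-12, 40%
#' carrying the behaviour, actives averaging 1.5 awake-bruxism events per
#' day against a 0.02/day background, 10% chance that any Likert answer
#' slips one category, stable clinical markers (per-finding probabilities
#' 0.15 active / 0.03 inactive), retest propensity correlation 0.9 and 90%
#' diary adherence.
#'
#' @param n_participants Cohort size.
#' @param prevalence Fraction of children with the latent behaviour.
#' @param theta_active,theta_inactive Mean daily event rates by group.
#' @param report_noise Probability a Likert answer deviates one category.
#' @param clinical_prob_active,clinical_prob_inactive Per-finding Bernoulli
#'   probabilities.
#' @param retest_rho Latent-propensity correlation across stages, in 0-1.
#' @param adherence Probability an occurring event is painted.
#' @param seed Integer RNG seed.
#' @param behavior_weights Multipliers applied to theta per behaviour
#'   (grinding, clenching, bracing/thrusting); clenching is the most
#'   perceived behaviour, grinding the least.
#' @param theta_sigma Lognormal spread of theta around the group rate.
#' @return An object of class `abit_sim_params`.
#' @export
simulation_params <- function(n_participants = 10L,
                              prevalence = 0.4,
                              theta_active = 1.5,
                              theta_inactive = 0.02,
                              report_noise = 0.1,
                              clinical_prob_active = 0.15,
                              clinical_prob_inactive = 0.03,
                              retest_rho = 0.9,
                              adherence = 0.9,
                              seed = 1L,
                              behavior_weights = c(grinding = 0.5,
                                                   clenching = 1.0,
                                                   bracing_thrusting = 0.9),
                              theta_sigma = 0.5) {
  probs <- c(prevalence = prevalence, report_noise = report_noise,
             clinical_prob_active = clinical_prob_active,
             clinical_prob_inactive = clinical_prob_inactive,
             retest_rho = retest_rho, adherence = adherence)
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  rates <- c(theta_active = theta_active, theta_inactive = theta_inactive,
             theta_sigma = theta_sigma)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and non-negative", call. = FALSE)
  }
  if (n_participants < 0L) stop("n_participants must be >= 0", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    prevalence = prevalence,
    theta_active = theta_active, theta_inactive = theta_inactive,
    report_noise = report_noise,
    clinical_prob_active = clinical_prob_active,
    clinical_prob_inactive = clinical_prob_inactive,
    retest_rho = retest_rho, adherence = adherence,
    seed = as.integer(seed),
    behavior_weights = behavior_weights,
    theta_sigma = theta_sigma
  ), class = "abit_sim_params")
}

# The non-latent random draws of one cohort, shared across stages.
draw_cohort_uniforms <- function(n) {
  list(
    age = sample(8:12, n, replace = TRUE),
    sb = stats::runif(n) < 0.3,
    u_events = matrix(stats::runif(n * 7L), nrow = n),
    u_paint = array(stats::runif(n * 7L * 6L), dim = c(n, 7L, 6L)),
    u_likert = array(stats::runif(n * 3L * 3L), dim = c(n, 3L, 3L)), # source x behaviour
    u_clinical = matrix(stats::runif(n * 7L), nrow = n),
    u_wear = matrix(stats::runif(n * length(SIM_TEETH)), nrow = n)
  )
}

likert_from_rate <- function(rate, u_noise, noise) {
  cat <- findInterval(rate, LIKERT_THRESHOLDS)
  shift <- ifelse(u_noise < noise / 2, -1L, ifelse(u_noise < noise, 1L, 0L))
  cat <- pmin(pmax(cat + shift, 0L), 4L)
  LIKERT_LABELS[cat + 1L]
}

# Build one stage's record for participant i from shared uniforms + theta.
build_sim_record <- function(params, i, stage, theta, active, unifs, id) {
  events <- pmin(stats::qpois(unifs$u_events[i, ], theta), 6L)
  grid <- matrix(FALSE, 7L, 6L)
  for (d in 1:7) {
    if (events[d] > 0L) {
      grid[d, seq_len(events[d])] <- unifs$u_paint[i, d, seq_len(events[d])] < params$adherence
    }
  }
  triplets <- lapply(1:3, function(src) {
    labels <- vapply(1:3, function(b) {
      likert_from_rate(theta * params$behavior_weights[[b]],
                       unifs$u_likert[i, src, b], params$report_noise)
    }, character(1))
    behavior_triplet(TRIPLET_SOURCES[src], labels[1], labels[2], labels[3])
  })
  p_find <- if (active) params$clinical_prob_active else params$clinical_prob_inactive
  findings <- unifs$u_clinical[i, ] < p_find
  wear_thr <- if (active) c(g2 = 0.10, g12 = 0.30) else c(g2 = 0.02, g12 = 0.10)
  uw <- unifs$u_wear[i, ]
  wear <- ifelse(uw < wear_thr[["g2"]], 2L, ifelse(uw < wear_thr[["g12"]], 1L, 0L))
  names(wear) <- SIM_TEETH
  participant_record(
    participant_id = id,
    age_years = unifs$age[i],
    stage = stage,
    r1 = triplets[[1L]], sr = triplets[[2L]], r2 = triplets[[3L]],
    ema = ema_diary(grid),
    exam = clinical_exam(
      masseter_hypertrophy = findings[1L],
      temporal_hypertrophy = findings[2L],
      buccal_hyperkeratosis_linea_alba = findings[3L],
      labial_hyperkeratosis = findings[4L],
      labial_indentation = findings[5L],
      tongue_indentation = findings[6L],
      buccal_indentation = findings[7L],
      tooth_wear = wear
    ),
    sb_reported = unifs$sb[i]
  )
}

#' Simulate one participant record from a known latent propensity
#'
#' @param params An [simulation_params()] object.
#' @param latent_theta Mean daily event rate for this child.
#' @param stage `"test"` or `"retest"`.
#' @param participant_id Id string.
#' @param active Ground-truth group label; defaults to comparing
#'   `latent_theta` against the midpoint of the two group rates.
#' @param seed Optional seed; when given, the draw is reproducible on its
#'   own, otherwise the current RNG stream is used.
#' @return List with `record` (an `abit_record`) and `truth`
#'   (`latent_theta`, `true_label`).
#' @export
simulate_participant <- function(params, latent_theta, stage = "test",
                                 participant_id = "P001", active = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(active)) {
    active <- latent_theta >= (params$theta_active + params$theta_inactive) / 2
  }
  unifs <- draw_cohort_uniforms(1L)
  rec <- build_sim_record(params, 1L, stage, latent_theta, active, unifs,
                          participant_id)
  list(record = rec,
       truth = list(latent_theta = latent_theta,
                    true_label = if (active) "active" else "inactive"))
}

#' Simulate a paired test/retest cohort
#'
#' Draws a latent standard-normal propensity per child and stage through a
#' Gaussian copula with correlation `retest_rho`, maps it to a lognormal
#' daily event rate around the child's group rate, and generates full ABIT
#' records for both stages from shared non-latent draws. Output is fully
#' determined by `params` (including its seed).
#'
#' @param params An [simulation_params()] object.
#' @return List with `test` and `retest` (lists of `abit_record`s) and
#'   `truth`: a data frame with `participant_id`, `true_label`, the latent
#'   normals `z_test`/`z_retest` and event rates `theta_test`/`theta_retest`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "abit_sim_params"))
  n <- params$n_participants
  empty_truth <- data.frame(
    participant_id = character(0), true_label = character(0),
    z_test = numeric(0), z_retest = numeric(0),
    theta_test = numeric(0), theta_retest = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(list(test = list(), retest = list(), truth = empty_truth))
  set.seed(params$seed)
  active <- stats::runif(n) < params$prevalence
  z1 <- stats::rnorm(n)
  z2 <- params$retest_rho * z1 +
    sqrt(1 - params$retest_rho^2) * stats::rnorm(n)
  base <- ifelse(active, params$theta_active, params$theta_inactive)
  sg <- params$theta_sigma
  theta1 <- base * exp(sg * z1 - sg^2 / 2)
  theta2 <- base * exp(sg * z2 - sg^2 / 2)
  unifs <- draw_cohort_uniforms(n)
  ids <- sprintf("P%04d", seq_len(n))
  test <- lapply(seq_len(n), function(i) {
    build_sim_record(params, i, "test", theta1[i], active[i], unifs, ids[i])
  })
  retest <- lapply(seq_len(n), function(i) {
    build_sim_record(params, i, "retest", theta2[i], active[i], unifs, ids[i])
  })
  truth <- data.frame(
    participant_id = ids,
    true_label = ifelse(active, "active", "inactive"),
    z_test = z1, z_retest = z2,
    theta_test = theta1, theta_retest = theta2,
    stringsAsFactors = FALSE
  )
  list(test = test, retest = retest, truth = truth)
}
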