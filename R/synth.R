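# Synthetic claims generator with planted propensity and remission
# structure.  The generator writes the same three tables a claims extract
# would provide (members, medical claims, pharmacy fills) plus a ground
# truth object, so parameter-recovery and deconfounding tests can run
# without any proprietary data.

#' Configuration for the synthetic claims generator
#'
#' Defines a cohort of patients with independent binary medical-history
#' features, a feature-dependent multinomial-logit drug assignment
#' (planting confounding by indication), and fill sequences whose
#' duration/dose/switch/augmentation patterns encode a known remission
#' outcome drawn from a per-drug logistic model.
#'
#' Default intercepts reproduce a realistic prescribing mix (prevalences
#' from under 1% to 24% across the 16 labels) and per-drug remission
#' prevalences between 3% and 49%; each drug's propensity and remission
#' models share one active feature, so confounding by indication is
#' present by default.
#'
#' @param n_patients number of patients.
#' @param n_features number of binary history features.
#' @param feature_prevalence scalar or length-`n_features` vector of
#'   Bernoulli prevalences.
#' @param feature_cor optional exchangeable within-block latent
#'   correlation (0 disables; blocks of `block_size` features).
#' @param block_size block width used when `feature_cor > 0`.
#' @param drugs character vector of treatment labels; the last label may
#'   be `"Other"`, which is generated directly as monotherapy with an
#'   unlisted antidepressant.
#' @param propensity_coefs `(n_features + 1) x length(drugs)` matrix of
#'   multinomial-logit coefficients (first row intercept, log-odds scale).
#' @param remission_coefs same shape, per-drug logistic remission model.
#' @param clinician_code_rate probability that a true remission also
#'   receives a clinician remission diagnosis code.
#' @param episodes_per_patient probability vector over 1, 2, ... episodes.
#' @param coverage_span days of continuous eligibility per patient.
#' @param dose_thresholds named vector of minimum therapeutic daily doses.
#' @param p_female probability a patient is female.
#' @param age_group_probs probabilities over the five age groups
#'   13-19, 20-40, 41-64, 65-79, 80+.
#' @param ineligible_rate fraction of patients generated with too little
#'   coverage history before their first episode (to exercise the
#'   eligibility filter; default 0 so every episode is eligible).
#' @param origin first possible coverage start date.
#' @param seed integer seed; identical config implies byte-identical
#'   output tables.
#' @return A validated `synth_config` object (list).
#' @export
synth_config <- function(n_patients = 2000L,
                         n_features = 20L,
                         feature_prevalence = 0.3,
                         feature_cor = 0,
                         block_size = 5L,
                         drugs = ad_drug_names(include_other = TRUE),
                         propensity_coefs = NULL,
                         remission_coefs = NULL,
                         clinician_code_rate = 0.1,
                         episodes_per_patient = c(0.45, 0.30, 0.15, 0.10),
                         coverage_span = 2200L,
                         dose_thresholds = default_dose_thresholds(),
                         p_female = 0.6936,
                         age_group_probs = c(0.0685, 0.3147, 0.4475, 0.1357, 0.0335),
                         ineligible_rate = 0,
                         origin = as.Date("2001-01-01"),
                         seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  n_features <- check_count(n_features, "n_features")
  if (length(feature_prevalence) == 1L)
    feature_prevalence <- rep(feature_prevalence, n_features)
  if (length(feature_prevalence) != n_features)
    stopf("configuration error: 'feature_prevalence' must have length 1 or n_features")
  check_prob(feature_prevalence, "feature_prevalence")
  check_prob(clinician_code_rate, "clinician_code_rate")
  check_prob(p_female, "p_female")
  check_prob(ineligible_rate, "ineligible_rate")
  check_prob(feature_cor, "feature_cor")
  if (!is.character(drugs) || length(drugs) < 2L || anyDuplicated(drugs))
    stopf("configuration error: 'drugs' must be >= 2 distinct labels")
  if (is.null(propensity_coefs))
    propensity_coefs <- default_planted_coefs(n_features, drugs, target = "propensity")
  if (is.null(remission_coefs))
    remission_coefs <- default_planted_coefs(n_features, drugs, target = "remission")
  for (nm in c("propensity_coefs", "remission_coefs")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != n_features + 1L || ncol(m) != length(drugs))
      stopf("configuration error: '%s' must be a (n_features + 1) x n_drugs matrix", nm)
  }
  colnames(propensity_coefs) <- colnames(remission_coefs) <- drugs
  missing_thr <- setdiff(drugs, names(dose_thresholds))
  if (length(missing_thr))
    stopf("configuration error: 'dose_thresholds' missing entries for: %s",
          paste(missing_thr, collapse = ", "))
  if (abs(sum(episodes_per_patient) - 1) > 1e-3 || any(episodes_per_patient < 0))
    stopf("configuration error: 'episodes_per_patient' must be a probability vector")
  if (abs(sum(age_group_probs) - 1) > 1e-3 || length(age_group_probs) != 5L)
    stopf("configuration error: 'age_group_probs' must be 5 probabilities summing to 1")
  episodes_per_patient <- episodes_per_patient / sum(episodes_per_patient)
  age_group_probs <- age_group_probs / sum(age_group_probs)
  cfg <- list(
    n_patients = n_patients, n_features = n_features,
    feature_prevalence = feature_prevalence, feature_cor = feature_cor,
    block_size = as.integer(block_size), drugs = drugs,
    propensity_coefs = propensity_coefs, remission_coefs = remission_coefs,
    clinician_code_rate = clinician_code_rate,
    episodes_per_patient = episodes_per_patient,
    coverage_span = check_count(coverage_span, "coverage_span"),
    dose_thresholds = dose_thresholds, p_female = p_female,
    age_group_probs = age_group_probs, ineligible_rate = ineligible_rate,
    origin = as.Date(origin), seed = check_count(seed, "seed", min = 0L)
  )
  class(cfg) <- "synth_config"
  cfg
}

# Published-scale prescribing / remission prevalences used as default
# intercepts, in ad_drug_names() order plus "Other".
.default_prescribe_prev <- c(
  Amitriptyline = 0.028, Bupropion = 0.089, Citalopram = 0.091,
  Desvenlafaxine = 0.008, Doxepin = 0.005, Duloxetine = 0.044,
  Escitalopram = 0.106, Fluoxetine = 0.087, Mirtazapine = 0.018,
  Nortriptyline = 0.009, Paroxetine = 0.047, Ropinirole = 0.006,
  Sertraline = 0.123, Trazodone = 0.046, Venlafaxine = 0.053,
  Other = 0.240
)
.default_remit_prev <- c(
  Amitriptyline = 0.031, Bupropion = 0.061, Citalopram = 0.487,
  Desvenlafaxine = 0.478, Doxepin = 0.222, Duloxetine = 0.391,
  Escitalopram = 0.205, Fluoxetine = 0.455, Mirtazapine = 0.168,
  Nortriptyline = 0.097, Paroxetine = 0.437, Ropinirole = 0.339,
  Sertraline = 0.493, Trazodone = 0.030, Venlafaxine = 0.489,
  Other = 0.351
)

# Deterministic sparse default coefficients.  Drug k gets a +0.8 push on
# feature f1(k) in the propensity model and the SAME feature gets +0.7 in
# its remission model, so indication bias is planted by construction; a
# second feature per model keeps supports of size two.
default_planted_coefs <- function(n_features, drugs, target = c("propensity", "remission")) {
  target <- match.arg(target)
  K <- length(drugs)
  m <- matrix(0, nrow = n_features + 1L, ncol = K,
              dimnames = list(c("(Intercept)", sprintf("F%03d", seq_len(n_features))), drugs))
  prev <- if (target == "propensity") .default_prescribe_prev else .default_remit_prev
  p <- prev[drugs]
  p[is.na(p)] <- if (target == "propensity") 0.02 else 0.30
  m[1L, ] <- if (target == "propensity") log(p) else qlogis(p)
  for (k in seq_len(K)) {
    f1 <- ((k - 1L) %% n_features) + 1L
    f2 <- (k %% n_features) + 1L
    f3 <- ((k + 1L) %% n_features) + 1L
    if (target == "propensity") {
      m[f1 + 1L, k] <- 0.8
      m[f2 + 1L, k] <- -0.5
    } else {
      m[f1 + 1L, k] <- 0.7
      m[f3 + 1L, k] <- 0.4
    }
  }
  m
}

#' Generate patient histories and the member table
#'
#' Draws the binary feature matrix (feature j is Bernoulli with its
#' configured prevalence, independently unless `feature_cor > 0`) and the
#' member/eligibility table with demographics and coverage spans of at
#' least `coverage_span` days.
#'
#' @param cfg a [synth_config()].
#' @return list with `features` (n_patients x n_features 0/1 matrix,
#'   columns `F001`, ...) and `members` (data.table: patient_id, gender,
#'   age, birth-cohort age group, cov_start, cov_end, eligible_by_design).
#' @export
generate_histories <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg$seed, 1L))
  n <- cfg$n_patients
  p <- cfg$n_features
  if (cfg$feature_cor > 0) {
    blocks <- split(seq_len(p), ceiling(seq_len(p) / cfg$block_size))
    X <- matrix(0L, n, p)
    for (b in blocks) {
      z0 <- rnorm(n)
      for (j in b) {
        z <- sqrt(cfg$feature_cor) * z0 + sqrt(1 - cfg$feature_cor) * rnorm(n)
        X[, j] <- as.integer(z < qnorm(cfg$feature_prevalence[j]))
      }
    }
  } else {
    X <- vapply(seq_len(p),
                function(j) rbinom(n, 1L, cfg$feature_prevalence[j]),
                integer(n))
    if (n == 1L) X <- matrix(X, nrow = 1L)
  }
  colnames(X) <- sprintf("F%03d", seq_len(p))
  grp <- sample.int(5L, n, replace = TRUE, prob = cfg$age_group_probs)
  lo <- c(13L, 20L, 41L, 65L, 80L)[grp]
  hi <- c(19L, 40L, 64L, 79L, 90L)[grp]
  age <- lo + floor(runif(n) * (hi - lo + 1L))
  members <- data.table(
    patient_id = sprintf("P%06d", seq_len(n)),
    gender = ifelse(runif(n) < cfg$p_female, "F", "M"),
    age = as.numeric(age),
    cov_start = cfg$origin + sample.int(365L, n, replace = TRUE) - 1L,
    eligible_by_design = runif(n) >= cfg$ineligible_rate
  )
  members[, cov_end := cov_start + cfg$coverage_span]
  list(features = X, members = members[])
}

#' Assign an antidepressant to each episode by multinomial logit
#'
#' Each patient contributes a configured number of episodes; the drug for
#' each episode is drawn from a multinomial logit over the configured
#' per-drug propensity coefficients evaluated on the patient's features —
#' this is where confounding by indication is planted.
#'
#' @param histories output of [generate_histories()].
#' @param cfg the same [synth_config()].
#' @return list with `episodes` (data.table: patient_id, episode_seq,
#'   start_date, drug) and `truth` (a `synth_truth` object carrying the
#'   planted supports and coefficient matrices).
#' @export
assign_drugs <- function(histories, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg$seed, 2L))
  members <- histories$members
  X <- histories$features
  n <- nrow(members)
  n_epi <- sample.int(length(cfg$episodes_per_patient), n, replace = TRUE,
                      prob = cfg$episodes_per_patient)
  pat <- rep(seq_len(n), n_epi)
  seqi <- sequence(n_epi)
  m <- length(pat)
  # episode start dates: first start >= 465 days into coverage for
  # eligible-by-design patients, < 465 for planted-ineligible ones;
  # subsequent episodes 200-320 days apart so supply gaps force splits.
  first_off <- ifelse(members$eligible_by_design[pat], 465L, 100L) +
    sample.int(91L, m, replace = TRUE) - 1L
  # cumulative gaps: each later episode starts 200-320 days after the
  # previous one, comfortably beyond any fill template's supply end
  delta <- ifelse(seqi == 1L, first_off,
                  200L + sample.int(121L, m, replace = TRUE) - 1L)
  off <- unlist(lapply(split(delta, pat), cumsum), use.names = FALSE)
  start <- members$cov_start[pat] + off
  eta <- cbind(1, X[pat, , drop = FALSE]) %*% cfg$propensity_coefs
  gumbel <- -log(-log(matrix(runif(m * ncol(eta)), m)))
  drug_idx <- max.col(eta + gumbel, ties.method = "first")
  episodes <- data.table(
    patient_id = members$patient_id[pat],
    episode_seq = seqi,
    start_date = start,
    drug = cfg$drugs[drug_idx]
  )
  truth <- structure(list(
    propensity_coefs = cfg$propensity_coefs,
    remission_coefs = cfg$remission_coefs,
    true_propensity_support = apply(cfg$propensity_coefs[-1L, , drop = FALSE], 2L,
                                    function(b) which(b != 0), simplify = FALSE),
    true_remission_support = apply(cfg$remission_coefs[-1L, , drop = FALSE], 2L,
                                   function(b) which(b != 0), simplify = FALSE),
    episodes = NULL
  ), class = "synth_truth")
  list(episodes = episodes, truth = truth)
}

# Per-mode fill templates.  Offsets are days from episode start; the
# remission index downstream must reproduce the planted label, so the
# templates are designed around its four conditions (70-day duration
# window, therapeutic dose, switch, augmentation).
.fill_templates <- list(
  remit    = list(index_off = c(0L, 30L, 60L, 90L), index_supply = 30L, dose_mult = 1.25,
                  other_off = integer(0)),
  short    = list(index_off = c(0L, 28L), index_supply = 28L, dose_mult = 1.25,
                  other_off = integer(0)),
  subdose  = list(index_off = c(0L, 30L, 60L, 90L), index_supply = 30L, dose_mult = 0.5,
                  other_off = integer(0)),
  switch   = list(index_off = c(0L, 30L), index_supply = 30L, dose_mult = 1.25,
                  other_off = c(45L, 75L, 105L)),
  augment  = list(index_off = c(0L, 30L, 60L, 90L), index_supply = 30L, dose_mult = 1.25,
                  other_off = c(45L, 75L))
)

#' Simulate pharmacy fills and medical claims encoding the remission label
#'
#' Remission is drawn per episode from the configured logistic model.  A
#' remitter's fill sequence satisfies all four index conditions (duration
#' over 10 weeks at a therapeutic dose with no switch or augmentation); a
#' non-remitter violates exactly one condition, chosen uniformly among
#' short duration, sub-therapeutic dose, switch, and augmentation.  A
#' configured fraction of remitters additionally receives a clinician
#' remission diagnosis (code `296.25`).  Patient history features are
#' materialized as dated diagnosis claims inside each episode's one-year
#' lookback so the downstream feature builder can reconstruct them.
#'
#' @param assigned output of [assign_drugs()].
#' @param histories output of [generate_histories()].
#' @param cfg the same [synth_config()].
#' @return list with `pharmacy` (FillRecord table), `medical` (claims
#'   table: patient_id, service_date, code, setting) and `truth` (the
#'   `synth_truth` completed with per-episode labels and probabilities).
#' @export
simulate_fills <- function(assigned, histories, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg$seed, 3L))
  episodes <- copy(assigned$episodes)
  X <- histories$features
  pat_idx <- match(episodes$patient_id, histories$members$patient_id)
  m <- nrow(episodes)
  eta_all <- cbind(1, X[pat_idx, , drop = FALSE]) %*% cfg$remission_coefs
  di <- match(episodes$drug, cfg$drugs)
  p_remit <- plogis(eta_all[cbind(seq_len(m), di)])
  remit <- rbinom(m, 1L, p_remit) == 1L
  mode <- ifelse(remit, "remit",
                 c("short", "subdose", "switch", "augment")[
                   sample.int(4L, m, replace = TRUE)])
  # remitters get 3 or 4 index fills (both exceed the 70-day window)
  n_index <- ifelse(mode == "remit", sample(3:4, m, replace = TRUE), NA_integer_)
  thr <- cfg$dose_thresholds
  # generic name actually dispensed: "Other" episodes are monotherapy with
  # an unlisted antidepressant
  fill_name <- ifelse(episodes$drug == "Other", "Vilazodone", episodes$drug)
  studied <- setdiff(cfg$drugs, "Other")
  other_drug <- vapply(seq_len(m), function(i) {
    if (mode[i] %in% c("switch", "augment")) {
      pool <- setdiff(studied, fill_name[i])
      pool[sample.int(length(pool), 1L)]
    } else NA_character_
  }, character(1L))

  fill_list <- vector("list", length(.fill_templates))
  names(fill_list) <- names(.fill_templates)
  for (md in names(.fill_templates)) {
    tpl <- .fill_templates[[md]]
    rows <- which(mode == md)
    if (!length(rows)) next
    offs <- tpl$index_off
    if (md == "remit") {
      # variable fill count: expand per-episode
      reps <- n_index[rows]
      idx <- rep(rows, reps)
      off <- unlist(lapply(reps, function(k) offs[seq_len(k)]))
    } else {
      idx <- rep(rows, each = length(offs))
      off <- rep(offs, times = length(rows))
    }
    part <- data.table(
      patient_id = episodes$patient_id[idx],
      drug = fill_name[idx],
      fill_date = episodes$start_date[idx] + off,
      days_supply = tpl$index_supply,
      daily_dose = tpl$dose_mult * unname(thr[episodes$drug[idx]])
    )
    if (length(tpl$other_off)) {
      idx2 <- rep(rows, each = length(tpl$other_off))
      off2 <- rep(tpl$other_off, times = length(rows))
      part2 <- data.table(
        patient_id = episodes$patient_id[idx2],
        drug = other_drug[idx2],
        fill_date = episodes$start_date[idx2] + off2,
        days_supply = 30L,
        daily_dose = 1.25 * unname(thr[other_drug[idx2]])
      )
      part <- rbind(part, part2)
    }
    fill_list[[md]] <- part
  }
  pharmacy <- rbindlist(fill_list)
  setorder(pharmacy, patient_id, fill_date, drug)

  clin <- remit & (runif(m) < cfg$clinician_code_rate)
  med_remit <- data.table(
    patient_id = episodes$patient_id[clin],
    service_date = episodes$start_date[clin] + 84L,
    code = "296.25", setting = "outpatient"
  )
  # history features as dated diagnosis claims in [start - 365, start)
  hits <- which(X[pat_idx, , drop = FALSE] == 1L, arr.ind = TRUE)
  med_hist <- data.table(
    patient_id = episodes$patient_id[hits[, 1L]],
    service_date = episodes$start_date[hits[, 1L]] -
      sample.int(365L, nrow(hits), replace = TRUE),
    code = sprintf("DX%03d", hits[, 2L]),
    setting = ifelse(hits[, 2L] %% 5L == 0L, "inpatient", "outpatient")
  )
  medical <- rbind(med_remit, med_hist)
  setorder(medical, patient_id, service_date, code)

  truth <- assigned$truth
  truth$episodes <- data.table(
    patient_id = episodes$patient_id,
    episode_seq = episodes$episode_seq,
    start_date = episodes$start_date,
    drug = episodes$drug,
    p_remit = p_remit,
    remit = remit,
    violation_mode = mode,
    clinician_coded = clin
  )
  truth$feature_codes <- sprintf("DX%03d", seq_len(cfg$n_features))
  list(pharmacy = pharmacy[], medical = medical[], truth = truth)
}

#' Generate a complete synthetic claims bundle
#'
#' Convenience wrapper running [generate_histories()], [assign_drugs()]
#' and [simulate_fills()] with one seed, returning the three claims
#' tables plus ground truth.
#'
#' @param cfg a [synth_config()].
#' @return list: `members`, `medical`, `pharmacy` (data.tables),
#'   `features` (patient feature matrix), `truth` (`synth_truth`),
#'   `config`.
#' @export
generate_claims <- function(cfg) {
  h <- generate_histories(cfg)
  a <- assign_drugs(h, cfg)
  s <- simulate_fills(a, h, cfg)
  list(members = h$members, medical = s$medical, pharmacy = s$pharmacy,
       features = h$features, truth = s$truth, config = cfg)
}

#' Write a synthetic claims bundle to CSV + JSON
#'
#' Writes `members.csv`, `medical.csv`, `pharmacy.csv` (ISO-8601 dates,
#' one row per fill/claim) and `truth.json` (planted supports,
#' coefficients, and per-episode true labels) into `dir`.
#'
#' @param bundle output of [generate_claims()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_claims <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("members.csv", "medical.csv", "pharmacy.csv", "truth.json"))
  fwrite(bundle$members, paths[1L])
  fwrite(bundle$medical, paths[2L])
  fwrite(bundle$pharmacy, paths[3L])
  tr <- bundle$truth
  jsonlite::write_json(list(
    propensity_coefs = tr$propensity_coefs,
    remission_coefs = tr$remission_coefs,
    true_propensity_support = tr$true_propensity_support,
    true_remission_support = tr$true_remission_support,
    episodes = tr$episodes
  ), paths[4L], dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Planted conditional odds ratio for a feature combination
#'
#' Computes, from the ground truth, the odds ratio of remission for one
#' drug versus the propensity-weighted mixture of the remaining drugs,
#' conditional on a fixed feature vector.  This is the estimand a
#' correctly deconfounded stratified analysis targets within a stratum.
#'
#' @param truth a `synth_truth` object.
#' @param x binary feature vector (length n_features).
#' @param drug drug label.
#' @return odds ratio (numeric scalar).
#' @export
true_stratum_or <- function(truth, x, drug) {
  stopifnot(inherits(truth, "synth_truth"))
  drugs <- colnames(truth$propensity_coefs)
  k <- match(drug, drugs)
  if (is.na(k)) stopf("unknown drug '%s'", drug)
  xx <- c(1, x)
  p_all <- plogis(drop(xx %*% truth$remission_coefs))
  w <- exp(drop(xx %*% truth$propensity_coefs))
  w <- w / sum(w)
  p1 <- p_all[k]
  p0 <- sum(w[-k] * p_all[-k]) / sum(w[-k])
  unname((p1 / (1 - p1)) / (p0 / (1 - p0)))
}
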