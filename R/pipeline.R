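# End-to-end orchestration: synthetic (or user-supplied) claims ->
# labeled episodes -> screened features -> robust propensity/remission
# models -> per-drug strata -> stratified effects, with a reproducible
# run manifest.

#' Pipeline configuration
#'
#' Bundles every stage's parameters.  Defaults follow the published
#' settings wherever one exists: 5 CV folds, 40 bootstrap resamples at
#' 95% sign agreement, screening to 1,000 predictors, a 365-day lookback,
#' a 70-day (10-week) outcome window, eligibility of 1 year and 100 days,
#' and a minimum stratum size of 100.
#'
#' @param synth a [synth_config()] to generate inputs, or `NULL` when
#'   `input_dir` points at existing `members.csv` / `medical.csv` /
#'   `pharmacy.csv`.
#' @param input_dir directory with the three claims CSVs (ignored when
#'   `synth` is given).
#' @param drugs treatment labels to analyze (`NULL` = all observed with
#'   enough data).
#' @param gap_days,window,min_history episode construction parameters.
#' @param thresholds dose-threshold table.
#' @param remission_codes clinician remission diagnosis codes.
#' @param K,folds,B,stability model-selection parameters.
#' @param min_size,report_min,alpha,conf_level stratification/effect
#'   parameters.
#' @param min_drug_n minimum episodes of a drug for it to be modeled.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = NULL, input_dir = NULL, drugs = NULL,
                            gap_days = 30, window = 70, min_history = 465,
                            thresholds = default_dose_thresholds(),
                            remission_codes = "296.25",
                            K = 1000L, folds = 5L, B = 40L, stability = 0.95,
                            min_size = 100L, report_min = 25L,
                            alpha = 1e-4, conf_level = 0.99,
                            min_drug_n = 200L, seed = 1L) {
  if (is.null(synth) && is.null(input_dir))
    stopf("configuration error: provide 'synth' or 'input_dir'")
  structure(as.list(environment()), class = "pipeline_config")
}

read_claims_dir <- function(dir) {
  paths <- file.path(dir, c("members.csv", "medical.csv", "pharmacy.csv"))
  for (p in paths) if (!file.exists(p)) stopf("input file missing: %s", p)
  members <- fread(paths[1L])
  medical <- fread(paths[2L])
  pharmacy <- fread(paths[3L])
  for (cc in c("cov_start", "cov_end"))
    members[, (cc) := as.Date(get(cc))]
  medical[, service_date := as.Date(service_date)]
  pharmacy[, fill_date := as.Date(fill_date)]
  list(members = members, medical = medical, pharmacy = pharmacy)
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes the stage outputs to
#' `out_dir`: `episodes.csv`, `features_triplets.csv` +
#' `features_columns.csv`, per-drug `model_<drug>.json`, a Table-2-style
#' `models_summary.csv` (prevalence, holdout AROC, number of robust
#' predictors for both model families), `strata.csv`, `effects.csv`
#' (per-drug stratum counts, Breslow-Day statistic and p, common OR and
#' CI), `rates.csv`, `gain.json`, `cohort_summary.csv`, and
#' `manifest.json` with parameters and MD5 hashes of every output.
#' Rerunning with the same configuration reproduces identical hashes.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param progress print stage-level progress with record counts.
#' @return invisibly, a list with all in-memory stage results (`bundle`,
#'   `episodes`, `features`, `models`, `partitions`, `effects`, `rates`,
#'   `gain`, `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir, progress = interactive()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (progress) message(sprintf(fmt, ...))

  if (!is.null(cfg$synth)) {
    say("stage synth: generating claims (n_patients=%d)", cfg$synth$n_patients)
    bundle <- generate_claims(cfg$synth)
  } else {
    say("stage input: reading %s", cfg$input_dir)
    bundle <- read_claims_dir(cfg$input_dir)
  }

  say("stage episodes: building and labeling")
  episodes <- label_episodes(
    bundle$pharmacy, bundle$medical, bundle$members,
    gap_days = cfg$gap_days, window = cfg$window,
    thresholds = cfg$thresholds, codes = cfg$remission_codes,
    min_history = cfg$min_history
  )
  say("  %d eligible episodes (%s dropped)", nrow(episodes),
      paste(attr(episodes, "dropped"), collapse = "+"))

  say("stage features: 1-year lookback predictors")
  features <- build_features(episodes, bundle$medical, bundle$pharmacy,
                             window = 365)

  drugs <- cfg$drugs
  if (is.null(drugs)) {
    tab <- table(episodes$drug_label)
    drugs <- names(tab)[tab >= cfg$min_drug_n]
  }
  say("stage models: %d drugs (B=%d, K=%d)", length(drugs), cfg$B, cfg$K)
  models <- list()
  summary_rows <- list()
  for (dg in drugs) {
    y_prop <- as.integer(episodes$drug_label == dg)
    prop <- fit_propensity(features, episodes, bundle$members, dg,
                           K = cfg$K, B = cfg$B, stability = cfg$stability,
                           folds = cfg$folds, seed = child_seed(cfg$seed, match(dg, drugs)))
    remn <- tryCatch(
      fit_remission(features, episodes, bundle$members, dg,
                    K = cfg$K, B = cfg$B, stability = cfg$stability,
                    folds = cfg$folds,
                    seed = child_seed(cfg$seed, 1000L + match(dg, drugs))),
      error = function(e) NULL)
    dprop <- model_design(features, episodes, bundle$members, cfg$K, y_prop)
    aroc_prop <- evaluate_aroc(prop, dprop$X, y_prop, scheme = "holdout",
                               seed = cfg$seed)
    aroc_rem <- NA_real_
    prev_rem <- NA_real_
    if (!is.null(remn)) {
      sel <- remn$rows
      y_rem <- as.integer(episodes$remission[sel])
      sub <- structure(list(X = features$X[sel, , drop = FALSE],
                            meta = features$meta, window = features$window),
                       class = "feature_matrix")
      drem <- model_design(sub, episodes[sel], bundle$members, cfg$K, y_rem)
      aroc_rem <- tryCatch(
        evaluate_aroc(remn, drem$X, y_rem, scheme = "holdout", seed = cfg$seed),
        error = function(e) NA_real_)
      prev_rem <- mean(y_rem)
    }
    models[[dg]] <- list(propensity = prop, remission = remn)
    summary_rows[[dg]] <- data.table(
      drug = dg,
      prescribe_prevalence = mean(y_prop),
      propensity_aroc = aroc_prop,
      propensity_n_predictors = length(prop$features) + length(prop$forced),
      remission_prevalence = prev_rem,
      remission_aroc = aroc_rem,
      remission_n_predictors = if (is.null(remn)) NA_integer_
        else length(remn$features) + length(remn$forced)
    )
  }
  models_summary <- rbindlist(summary_rows)

  say("stage strata: per-drug trimmed partitions (min_size=%d)", cfg$min_size)
  partitions <- list()
  effects_rows <- list()
  strata_rows <- list()
  for (dg in drugs) {
    ord <- rank_variables(models[[dg]]$propensity, models[[dg]]$remission)
    part <- build_strata(episodes, features, bundle$members, ord,
                         min_size = cfg$min_size)
    partitions[[dg]] <- part
    eff <- tryCatch(stratified_effect(part, episodes, dg,
                                      conf_level = cfg$conf_level),
                    error = function(e) NULL)
    strata_rows[[dg]] <- cbind(drug = dg, part$strata)
    if (!is.null(eff)) {
      effects_rows[[dg]] <- data.table(
        drug = dg,
        n_strata = nrow(part$strata),
        n_degenerate = eff$k_degenerate,
        bd_stat = eff$bd$bd_stat, bd_df = eff$bd$df, bd_p = eff$bd$p_value,
        tarone_stat = eff$bd$tarone_stat,
        or_mh = eff$mh$or_mh,
        ci_low = eff$mh$ci[1], ci_high = eff$mh$ci[2]
      )
    }
  }
  effects_tbl <- rbindlist(effects_rows)
  strata_tbl <- rbindlist(strata_rows)

  say("stage effects: rate tables and counterfactual gain")
  # pooled decision table on the first drug's partition (every drug's
  # remission rate within one partition), used for the gain report
  pooled_part <- partitions[[1L]]
  rates <- rate_table(pooled_part, episodes, report_min = cfg$report_min)
  gain <- counterfactual_gain(rates, pooled_part, episodes)
  summary_tbl <- cohort_summary(bundle$members, episodes)

  say("stage report: writing %s", out_dir)
  out <- list()
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    fwrite(x, p)
    out[[name]] <<- p
  }
  wcsv(episodes, "episodes.csv")
  ft <- Matrix::summary(features$X)
  wcsv(data.table(row = ft$i, column = features$meta$column[ft$j], value = ft$x),
       "features_triplets.csv")
  wcsv(features$meta, "features_columns.csv")
  wcsv(models_summary, "models_summary.csv")
  wcsv(strata_tbl, "strata.csv")
  if (nrow(effects_tbl)) wcsv(effects_tbl, "effects.csv")
  wcsv(rates, "rates.csv")
  wcsv(summary_tbl, "cohort_summary.csv")
  for (dg in drugs) {
    mj <- file.path(out_dir, sprintf("model_%s.json", dg))
    rfs <- models[[dg]]$propensity
    jsonlite::write_json(list(
      drug = dg,
      propensity = robust_set_json(models[[dg]]$propensity),
      remission = if (!is.null(models[[dg]]$remission))
        robust_set_json(models[[dg]]$remission)
    ), mj, auto_unbox = TRUE, digits = NA, null = "null")
    out[[basename(mj)]] <- mj
  }
  gj <- file.path(out_dir, "gain.json")
  jsonlite::write_json(unclass(gain), gj, auto_unbox = TRUE, digits = NA)
  out[["gain.json"]] <- gj

  manifest <- list(
    package = "stratarx",
    parameters = pipeline_params(cfg),
    n_episodes = nrow(episodes),
    drugs = drugs,
    files = lapply(out, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(bundle = bundle, episodes = episodes, features = features,
                 models = models, models_summary = models_summary,
                 partitions = partitions, effects = effects_tbl,
                 rates = rates, gain = gain, cohort = summary_tbl,
                 manifest = manifest))
}

robust_set_json <- function(rfs) {
  list(target = rfs$target,
       features = as.list(stats::setNames(rfs$signs, rfs$features)),
       stability = as.list(rfs$stability),
       forced = rfs$forced,
       final_coefs = as.list(rfs$final_coefs),
       importance = as.list(rfs$importance),
       B = rfs$B, need = rfs$need)
}

pipeline_params <- function(cfg) {
  keep <- c("gap_days", "window", "min_history", "K", "folds", "B",
            "stability", "min_size", "report_min", "alpha", "conf_level",
            "min_drug_n", "seed")
  pars <- cfg[keep]
  if (!is.null(cfg$synth))
    pars$synth <- cfg$synth[c("n_patients", "n_features", "seed",
                              "clinician_code_rate", "coverage_span")]
  pars
}

#' Cohort summary by age group and gender
#'
#' Counts and percentages of patients by age group and gender, plus
#' follow-up years (coverage after first episode) mean and median —
#' the demographic table of a claims cohort.
#'
#' @param members member table.
#' @param episodes episode table (defines the analyzed cohort).
#' @return data.table with `section`, `level`, `n`, `pct`, `value`.
#' @export
cohort_summary <- function(members, episodes) {
  members <- as.data.table(members)
  episodes <- as.data.table(episodes)
  if (!nrow(episodes)) {
    warning("empty cohort", call. = FALSE)
    return(data.table(section = character(), level = character(),
                      n = integer(), pct = numeric(), value = numeric()))
  }
  pats <- unique(episodes$patient_id)
  mem <- members[patient_id %in% pats]
  n <- nrow(mem)
  ag <- mem[, .N, keyby = .(level = as.character(age_group(age)))]
  gg <- mem[, .N, keyby = .(level = gender)]
  first_ep <- episodes[, .(first_start = min(start_date)), by = patient_id]
  fu <- mem[first_ep, on = "patient_id",
            .(years = pmax(as.numeric(cov_end - i.first_start), 0) / 365.25)]
  rbind(
    data.table(section = "age_group", ag[, .(level, n = N, pct = 100 * N / n)],
               value = NA_real_),
    data.table(section = "gender", gg[, .(level, n = N, pct = 100 * N / n)],
               value = NA_real_),
    data.table(section = "follow_up_years",
               level = c("mean", "median"), n = n, pct = NA_real_,
               value = c(mean(fu$years), median(fu$years)))
  )
}
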