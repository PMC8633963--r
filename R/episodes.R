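# Treatment-episode construction and the surrogate remission outcome.
#
# A treatment episode is a contiguous run of antidepressant fills for one
# patient: consecutive fills with supply gaps of at most `gap_days` belong
# to one episode, and a larger gap starts a new one.  The analysis is done
# per episode, not per patient.

#' Build treatment episodes from pharmacy fills
#'
#' Groups each patient's fills (any antidepressant) into episodes by the
#' supply-gap rule and derives, per episode: the treatment label (via
#' [classify_treatment()]), start and end-of-supply dates, covered
#' duration, the maximum daily dose of the index drug, and switch /
#' augmentation flags within the first `window` days.
#'
#' A *switch* is a fill of a different antidepressant within `window` days
#' of the episode start with no further index-drug fills afterwards; an
#' *augmentation* is such a fill while index-drug fills continue.
#'
#' @param fills data.frame/data.table with columns `patient_id`, `drug`,
#'   `fill_date` (Date or ISO-8601 string), `days_supply`, `daily_dose`.
#' @param gap_days maximum supply gap (days) bridged within one episode.
#' @param window days from episode start in which switch/augmentation are
#'   assessed (10 weeks).
#' @param studied drug names analyzed as monotherapies; all other
#'   antidepressants map to `"Other"`.
#' @return data.table with one row per episode: `patient_id`,
#'   `episode_index`, `drug_label`, `start_date`, `end_of_supply`,
#'   `duration`, `n_fills`, `max_index_dose`, `switched_within_window`,
#'   `augmented_within_window`, and `episode_id` (row key).
#' @export
build_episodes <- function(fills, gap_days = 30, window = 70,
                           studied = ad_drug_names()) {
  fills <- as.data.table(fills)
  req <- c("patient_id", "drug", "fill_date", "days_supply", "daily_dose")
  miss <- setdiff(req, names(fills))
  if (length(miss)) stopf("fills table lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(fills) == 0L) {
    return(data.table(patient_id = character(), episode_index = integer(),
                      drug_label = character(), start_date = as.Date(character()),
                      end_of_supply = as.Date(character()), duration = numeric(),
                      n_fills = integer(), max_index_dose = numeric(),
                      switched_within_window = logical(),
                      augmented_within_window = logical(),
                      episode_id = integer()))
  }
  if (!inherits(fills$fill_date, "Date")) fills[, fill_date := as.Date(fill_date)]
  if (any(is.na(fills$days_supply)) || any(fills$days_supply <= 0))
    stopf("validation error: 'days_supply' must be positive")
  if (any(fills$daily_dose < 0))
    stopf("validation error: 'daily_dose' must be non-negative")
  fills <- copy(fills)
  setorder(fills, patient_id, fill_date, drug)
  # running end of continuous supply; a fill starting more than gap_days
  # after it opens a new episode
  fills[, `:=`(supply_end = fill_date + days_supply)]
  fills[, run_end := as.Date(cummax(as.integer(supply_end))), by = patient_id]
  fills[, new_epi := {
    prev_end <- shift(run_end)
    is.na(prev_end) | (as.integer(fill_date) - as.integer(prev_end)) > gap_days
  }, by = patient_id]
  fills[, episode_index := cumsum(new_epi), by = patient_id]
  fills[, episode_id := .GRP, by = .(patient_id, episode_index)]

  # vectorized per-episode derivation (episode counts run to millions in
  # claims data, so no per-group R closures)
  fills[, start_date := min(fill_date), by = episode_id]
  first_day <- unique(fills[fill_date == start_date, .(episode_id, drug)])
  labels <- first_day[, .(n_index = .N, index_drug = drug[1L]), by = episode_id]
  labels[, drug_label := fifelse(n_index > 1L | !index_drug %chin% studied,
                                 "Other", index_drug)]
  fills[, is_index := FALSE]
  fills[first_day, on = .(episode_id, drug), is_index := TRUE]
  fills[, idx_date := fifelse(is_index, as.integer(fill_date), NA_integer_)]
  fills[, last_index := max(idx_date, na.rm = TRUE), by = episode_id]
  fills[, other_in_win := !is_index &
          as.integer(fill_date - start_date) <= window]
  fills[, sw_flag := other_in_win & last_index <= as.integer(fill_date)]
  fills[, au_flag := other_in_win & last_index > as.integer(fill_date)]
  fills[, idx_dose := fifelse(is_index, daily_dose, -Inf)]
  episodes <- fills[, .(
    start_date = min(fill_date),
    end_of_supply = max(supply_end),
    n_fills = .N,
    max_index_dose = max(idx_dose),
    n_switch = sum(sw_flag),
    n_augment = sum(au_flag)
  ), by = .(patient_id, episode_index, episode_id)]
  episodes[, duration := as.numeric(end_of_supply - start_date)]
  episodes[, switched_within_window := n_switch > 0L]
  episodes[, augmented_within_window := n_augment > 0L]
  episodes[, c("n_switch", "n_augment") := NULL]
  episodes[labels, on = "episode_id", drug_label := i.drug_label]
  setorder(episodes, patient_id, episode_index)
  setcolorder(episodes, c("patient_id", "episode_index", "drug_label",
                          "start_date", "end_of_supply", "duration",
                          "n_fills", "max_index_dose",
                          "switched_within_window",
                          "augmented_within_window", "episode_id"))
  episodes[]
}

#' Classify an episode's treatment
#'
#' Monotherapy with one of the studied antidepressants keeps that name.
#' Two studied drugs filled on the same first day, or monotherapy with an
#' antidepressant outside the studied list, are pooled as `"Other"`.
#' Episodes whose later fills add a second drug (switch or augmentation)
#' keep the index drug's label; those patterns are captured by the
#' episode's switch/augmentation flags instead.
#'
#' @param episode_fills fills of a single episode (columns `drug`,
#'   `fill_date`).
#' @param studied studied drug names.
#' @return a single treatment label.
#' @export
classify_treatment <- function(episode_fills, studied = ad_drug_names()) {
  ef <- as.data.table(episode_fills)
  first_day <- ef$fill_date == min(ef$fill_date)
  index_drugs <- unique(ef$drug[first_day])
  if (length(index_drugs) > 1L) return("Other")
  if (!index_drugs %in% studied) return("Other")
  index_drugs
}

#' Surrogate remission index
#'
#' An episode is labeled a remission when all four conditions hold:
#' duration exceeded 10 weeks (`duration > duration_days`), the index
#' drug's dose reached the therapeutic level, and there was neither a
#' switch nor an augmentation within the first 10 weeks.  The dose
#' comparator defaults to `>=` at the configured therapeutic threshold;
#' both comparators are available.
#'
#' @param episodes episode table from [build_episodes()] (or any table
#'   with `drug_label`, `duration`, `max_index_dose`,
#'   `switched_within_window`, `augmented_within_window`).
#' @param thresholds named vector of minimum therapeutic daily doses; an
#'   entry is required for every `drug_label` present.
#' @param duration_days duration threshold in days (10 weeks).
#' @param duration_strict if `TRUE` (default) duration must strictly
#'   exceed `duration_days`.
#' @param dose_strict if `TRUE` the dose must strictly exceed the
#'   threshold; default is `>=` at the published therapeutic dose.
#' @return the episode table with columns `remission` (logical) and
#'   `remission_source` (`"index"`) appended.
#' @export
remission_index <- function(episodes, thresholds = default_dose_thresholds(),
                            duration_days = 70, duration_strict = TRUE,
                            dose_strict = FALSE) {
  episodes <- as.data.table(copy(episodes))
  missing_thr <- setdiff(unique(episodes$drug_label), names(thresholds))
  if (length(missing_thr))
    stopf("configuration error: no dose threshold for: %s",
          paste(missing_thr, collapse = ", "))
  thr <- unname(thresholds[episodes$drug_label])
  dur_ok <- if (duration_strict) episodes$duration > duration_days
            else episodes$duration >= duration_days
  dose_ok <- if (dose_strict) episodes$max_index_dose > thr
             else episodes$max_index_dose >= thr
  episodes[, remission := dur_ok & dose_ok &
             !switched_within_window & !augmented_within_window]
  episodes[, remission_source := "index"]
  episodes[]
}

#' Clinician remission-code override
#'
#' When a clinician has coded remission within an episode's observation
#' window, the episode is labeled a remission regardless of the pattern
#' of medication use.  The override can only turn a label from `FALSE` to
#' `TRUE`, never the reverse.
#'
#' @param episodes labeled episode table (output of [remission_index()]).
#' @param medical medical claims with `patient_id`, `service_date`, `code`.
#' @param codes character vector of remission diagnosis codes, matched as
#'   exact strings (default includes ICD-9 `296.25`, "partial or
#'   unspecified remission").
#' @param window_extra days after end of supply still counted as the
#'   episode's observation window.
#' @return the episode table with `remission` / `remission_source`
#'   updated (`remission_source == "clinician_code"` where overridden).
#' @export
apply_clinician_override <- function(episodes, medical,
                                     codes = "296.25", window_extra = 70) {
  episodes <- as.data.table(copy(episodes))
  if (!nrow(episodes)) return(episodes)
  med <- as.data.table(medical)
  med <- med[code %in% codes]
  if (!inherits(med$service_date, "Date") && nrow(med))
    med[, service_date := as.Date(service_date)]
  if (nrow(med)) {
    episodes[, win_end := end_of_supply + window_extra]
    hit <- med[episodes,
               on = .(patient_id, service_date >= start_date,
                      service_date <= win_end),
               nomatch = NULL, .(episode_id = i.episode_id)]
    over <- unique(hit$episode_id)
    episodes[episode_id %in% over,
             `:=`(remission = TRUE, remission_source = "clinician_code")]
    episodes[, win_end := NULL]
  }
  episodes[]
}

#' Eligibility filter: minimum coverage history before the episode
#'
#' Keeps episodes whose patient had continuous coverage for at least
#' `min_history` days (1 year and 100 days by default) before the episode
#' start, with the start itself inside a coverage span.  Removal counts
#' are attached as the `"dropped"` attribute.
#'
#' @param episodes episode table.
#' @param members member table with `patient_id`, `cov_start`, `cov_end`
#'   (one row per coverage span).
#' @param min_history required days of coverage before episode start.
#' @return filtered episode table; `attr(, "dropped")` holds counts by
#'   reason (`short_history`, `outside_coverage`).
#' @export
filter_eligibility <- function(episodes, members, min_history = 465) {
  episodes <- as.data.table(copy(episodes))
  members <- as.data.table(members)
  for (cc in c("cov_start", "cov_end"))
    if (!inherits(members[[cc]], "Date")) members[, (cc) := as.Date(get(cc))]
  if (!nrow(episodes)) {
    attr(episodes, "dropped") <- c(short_history = 0L, outside_coverage = 0L)
    return(episodes)
  }
  # an episode qualifies if some span covers [start - min_history, start]
  j <- members[episodes, on = .(patient_id, cov_start <= start_date,
                                cov_end >= start_date),
               nomatch = NA,
               .(episode_id = i.episode_id, span_start = x.cov_start,
                 start_date = i.start_date)]
  j[, ok := !is.na(span_start) &
        as.integer(start_date - span_start) >= min_history]
  in_span <- j[, .(any_span = any(!is.na(span_start)), keep = any(ok)),
               by = episode_id]
  keep_ids <- in_span[keep == TRUE, episode_id]
  dropped <- c(
    short_history = in_span[any_span == TRUE & keep == FALSE, .N],
    outside_coverage = in_span[any_span == FALSE, .N]
  )
  out <- episodes[episode_id %in% keep_ids]
  attr(out, "dropped") <- dropped
  out
}

#' Label episodes end to end
#'
#' Convenience wrapper: [build_episodes()] on the pharmacy fills, the
#' surrogate [remission_index()], the [apply_clinician_override()], and
#' the [filter_eligibility()] screen, in that order.
#'
#' @inheritParams build_episodes
#' @inheritParams remission_index
#' @inheritParams apply_clinician_override
#' @inheritParams filter_eligibility
#' @param medical medical claims table.
#' @param members member table.
#' @return labeled, eligibility-filtered episode table.
#' @export
label_episodes <- function(fills, medical, members,
                           gap_days = 30, window = 70,
                           thresholds = default_dose_thresholds(),
                           codes = "296.25", window_extra = 70,
                           min_history = 465,
                           studied = ad_drug_names()) {
  ep <- build_episodes(fills, gap_days = gap_days, window = window,
                       studied = studied)
  ep <- remission_index(ep, thresholds = thresholds)
  ep <- apply_clinician_override(ep, medical, codes = codes,
                                 window_extra = window_extra)
  filter_eligibility(ep, members, min_history = min_history)
}
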