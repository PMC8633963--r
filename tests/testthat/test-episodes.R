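# Episode construction, treatment classification, the four-condition
# remission index, the clinician override, and the eligibility filter.

mk_fills <- function(...) {
  f <- data.table::rbindlist(list(...))
  f[, fill_date := as.Date("2005-01-01") + fill_date]
  f
}
fill_row <- function(pid = "P1", drug = "Sertraline", day = 0, supply = 30,
                     dose = 60) {
  data.table::data.table(patient_id = pid, drug = drug, fill_date = day,
                         days_supply = supply, daily_dose = dose)
}

test_that("single fills and clear gaps produce the expected episodes", {
  ep <- build_episodes(mk_fills(fill_row(day = 0, supply = 30)))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration, 30)
  expect_equal(ep$drug_label, "Sertraline")

  ep2 <- build_episodes(mk_fills(fill_row(day = 0), fill_row(day = 100)),
                        gap_days = 30)
  expect_equal(nrow(ep2), 2L)  # 70-day gap between supply end and refill
  expect_equal(ep2$episode_index, 1:2)

  expect_equal(nrow(build_episodes(fill_row()[0])), 0L)
  expect_error(build_episodes(mk_fills(fill_row(supply = -5))), "days_supply")
})

test_that("episode boundaries match a brute-force scan on random fill sequences", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    fills <- data.table::data.table(
      patient_id = sample(sprintf("P%d", 1:4), n, replace = TRUE),
      drug = sample(ad_drug_names()[1:4], n, replace = TRUE),
      fill_date = as.Date("2004-06-01") + sample(0:600, n, replace = TRUE),
      days_supply = sample(c(7, 14, 30, 90), n, replace = TRUE),
      daily_dose = 50
    )
    gap <- sample(c(15, 30, 60), 1)
    got <- build_episodes(fills, gap_days = gap)
    want <- oracle_episode_bounds(fills, gap_days = gap)
    setkey(want, patient_id, episode_index)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_date, want$start)
    expect_equal(got$end_of_supply, want$end)
    expect_equal(got$n_fills, want$n_fills)
    # partition: every fill accounted for exactly once
    expect_equal(sum(got$n_fills), nrow(fills))
  }
})

test_that("treatment classification follows the monotherapy/Other rules", {
  ep <- build_episodes(mk_fills(fill_row(day = 0), fill_row(day = 30)))
  expect_equal(ep$drug_label, "Sertraline")

  combo <- build_episodes(mk_fills(fill_row(drug = "Sertraline", day = 0),
                                   fill_row(drug = "Bupropion", day = 0)))
  expect_equal(combo$drug_label, "Other")

  unlisted <- build_episodes(mk_fills(fill_row(drug = "Vilazodone", day = 0)))
  expect_equal(unlisted$drug_label, "Other")

  # later switch keeps the index drug's label
  sw <- build_episodes(mk_fills(fill_row(drug = "Sertraline", day = 0),
                                fill_row(drug = "Bupropion", day = 20)))
  expect_equal(sw$drug_label, "Sertraline")
})

test_that("the remission index is true only when all four conditions hold", {
  thr <- c(Sertraline = 50)
  grid <- data.table::CJ(dur_ok = c(TRUE, FALSE), dose_ok = c(TRUE, FALSE),
                         no_switch = c(TRUE, FALSE), no_augment = c(TRUE, FALSE))
  ep <- data.table::data.table(
    drug_label = "Sertraline",
    duration = ifelse(grid$dur_ok, 84, 56),
    max_index_dose = ifelse(grid$dose_ok, 50, 25),
    switched_within_window = !grid$no_switch,
    augmented_within_window = !grid$no_augment
  )
  lab <- remission_index(ep, thresholds = thr)
  expect_equal(lab$remission,
               grid$dur_ok & grid$dose_ok & grid$no_switch & grid$no_augment)
  expect_equal(sum(lab$remission), 1L)
  expect_true(all(lab$remission_source == "index"))

  # boundary semantics: duration strictly exceeds 70; dose >= threshold
  edge <- data.table::data.table(drug_label = "Sertraline", duration = 70,
                                 max_index_dose = 50,
                                 switched_within_window = FALSE,
                                 augmented_within_window = FALSE)
  expect_false(remission_index(edge, thr)$remission)
  expect_true(remission_index(edge, thr, duration_strict = FALSE)$remission)
  expect_false(remission_index(edge, thr, duration_strict = FALSE,
                               dose_strict = TRUE)$remission)

  expect_error(remission_index(edge, thresholds = c(Bupropion = 150)),
               "threshold")
})

test_that("switch and augmentation flags implement their definitions", {
  # switch: other drug inside window, index drug never refilled after
  sw <- build_episodes(mk_fills(fill_row(day = 0), fill_row(day = 30),
                                fill_row(drug = "Bupropion", day = 45),
                                fill_row(drug = "Bupropion", day = 75)))
  expect_true(sw$switched_within_window)
  expect_false(sw$augmented_within_window)

  # augmentation: other drug inside window while index fills continue
  au <- build_episodes(mk_fills(fill_row(day = 0), fill_row(day = 30),
                                fill_row(drug = "Bupropion", day = 45),
                                fill_row(day = 60), fill_row(day = 90)))
  expect_true(au$augmented_within_window)
  expect_false(au$switched_within_window)

  # other drug outside the 70-day window: neither flag
  late <- build_episodes(mk_fills(fill_row(day = 0), fill_row(day = 30),
                                  fill_row(day = 60),
                                  fill_row(drug = "Bupropion", day = 85)))
  expect_false(late$switched_within_window)
  expect_false(late$augmented_within_window)

  # monotonicity: adding an in-window switch can never create a remission
  base <- mk_fills(fill_row(day = 0), fill_row(day = 30), fill_row(day = 60))
  lab0 <- remission_index(build_episodes(base), c(Sertraline = 50, Other = 20))
  withsw <- mk_fills(fill_row(day = 0), fill_row(day = 30), fill_row(day = 60),
                     fill_row(drug = "Bupropion", day = 40),
                     fill_row(drug = "Bupropion", day = 95))
  lab1 <- remission_index(build_episodes(withsw),
                          c(Sertraline = 50, Other = 20, Bupropion = 150))
  expect_true(lab0$remission)
  expect_false(lab1$remission)
})

test_that("clinician override flips false to true and never the reverse", {
  ep <- build_episodes(mk_fills(fill_row(day = 0, supply = 28),
                                fill_row(pid = "P2", day = 0),
                                fill_row(pid = "P2", day = 30),
                                fill_row(pid = "P2", day = 60)))
  lab <- remission_index(ep, c(Sertraline = 50))
  expect_equal(lab[order(patient_id)]$remission, c(FALSE, TRUE))
  med <- data.table::data.table(
    patient_id = c("P1", "P2"),
    service_date = as.Date("2005-01-01") + 40,
    code = "296.25"
  )
  over <- apply_clinician_override(lab, med)
  expect_true(all(over$remission))
  expect_equal(over[order(patient_id)]$remission_source,
               c("clinician_code", "clinician_code"))

  # a non-remission code changes nothing; index=true stays true
  med2 <- data.table::data.table(patient_id = "P1",
                                 service_date = as.Date("2005-01-01") + 40,
                                 code = "311")
  same <- apply_clinician_override(lab, med2)
  expect_equal(same$remission, lab$remission)
  expect_equal(same$remission_source, lab$remission_source)

  # code outside the observation window is ignored
  med3 <- data.table::data.table(patient_id = "P1",
                                 service_date = as.Date("2005-01-01") + 400,
                                 code = "296.25")
  out <- apply_clinician_override(lab, med3)
  expect_equal(out$remission, lab$remission)
})

test_that("eligibility filter matches brute-force span arithmetic", {
  set.seed(13)
  members <- data.table::data.table(
    patient_id = sprintf("P%d", 1:60),
    cov_start = as.Date("2002-01-01") + sample(0:800, 60, replace = TRUE)
  )
  members[, cov_end := cov_start + sample(300:2000, 60, replace = TRUE)]
  episodes <- data.table::data.table(
    patient_id = sample(members$patient_id, 150, replace = TRUE),
    episode_id = 1:150,
    start_date = as.Date("2003-01-01") + sample(0:1200, 150, replace = TRUE)
  )
  kept <- filter_eligibility(episodes, members, min_history = 465)
  want <- oracle_eligible(episodes, members, min_history = 465)
  expect_setequal(kept$episode_id, episodes$episode_id[want])
  drop <- attr(kept, "dropped")
  expect_equal(sum(drop), nrow(episodes) - nrow(kept))

  # the two boundary cases: exactly 465 days kept, 100 days removed
  mem <- data.table::data.table(patient_id = c("A", "B"),
                                cov_start = as.Date("2004-01-01"),
                                cov_end = as.Date("2009-01-01"))
  eps <- data.table::data.table(
    patient_id = c("A", "B"), episode_id = 1:2,
    start_date = as.Date("2004-01-01") + c(465, 100))
  kept2 <- filter_eligibility(eps, mem)
  expect_equal(kept2$episode_id, 1L)
})
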