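# Importance ordering, the trie partition with minimum-size trimming,
# and history matching.

fake_rfs <- function(target, feats, imp, signs = NULL) {
  structure(list(target = target, features = feats,
                 signs = signs %||% rep(1L, length(feats)),
                 stability = rep(1, length(feats)),
                 forced = c("age", "gender"),
                 final_coefs = c("(Intercept)" = 0),
                 importance = imp,
                 B = 1L, stability_threshold = 1, need = 1L),
            class = "robust_feature_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_cohort <- function(n, p, seed) {
  set.seed(seed)
  feats <- matrix(rbinom(n * p, 1, runif(p, 0.2, 0.7)), n, p,
                  dimnames = list(NULL, sprintf("F%02d", 1:p)))
  members <- data.table::data.table(
    patient_id = sprintf("P%05d", 1:n),
    age = sample(13:90, n, replace = TRUE),
    gender = sample(c("F", "M"), n, replace = TRUE)
  )
  episodes <- data.table::data.table(
    patient_id = members$patient_id, episode_id = 1:n,
    drug_label = sample(c("Sertraline", "Citalopram", "Other"), n,
                        replace = TRUE),
    remission = rbinom(n, 1, 0.4) == 1
  )
  fm <- structure(list(X = Matrix::Matrix(feats, sparse = TRUE),
                       meta = NULL, window = 365),
                  class = "feature_matrix")
  list(members = members, episodes = episodes, features = fm, raw = feats)
}

test_that("variable ranking forces demographics first and takes the max importance", {
  p <- fake_rfs("propensity(X)", c("f1", "f2"),
                c(age = 2, gender = 1, f1 = 0.3, f2 = 0.8))
  r <- fake_rfs("remission(X)", c("f1", "f3"),
                c(age = 2, gender = 1, f1 = 0.9, f3 = 0.5))
  ord <- rank_variables(p, r)
  expect_equal(ord$variable, c("age_group", "gender", "f1", "f2", "f3"))
  expect_equal(ord$importance[3], 0.9)  # max(|0.3|, |0.9|)

  empty <- rank_variables(fake_rfs("p", character(0), numeric(0)),
                          fake_rfs("r", character(0), numeric(0)))
  expect_equal(empty$variable, c("age_group", "gender"))

  # random coefficient draws: order equals a brute-force sort
  set.seed(61)
  for (rep in 1:10) {
    f <- sprintf("g%02d", 1:12)
    i1 <- stats::setNames(runif(12), f); i2 <- stats::setNames(runif(12), f)
    s1 <- sample(f, 7); s2 <- sample(f, 7)
    ord <- rank_variables(fake_rfs("p", s1, i1[s1]), fake_rfs("r", s2, i2[s2]))
    pooled <- sapply(union(s1, s2), function(v)
      max(c(if (v %in% s1) i1[[v]], if (v %in% s2) i2[[v]])))
    want <- names(sort(pooled, decreasing = TRUE))
    expect_equal(ord$variable[-(1:2)], want)
  }
})

test_that("degenerate minimum sizes give the expected partitions", {
  co <- random_cohort(400, 3, seed = 3)
  ord <- c("age_group", "gender", "F01")
  # min_size > n: single root stratum with empty key
  expect_warning(
    part <- build_strata(co$episodes, co$features, co$members, ord,
                         min_size = 1000),
    "single root")
  expect_equal(nrow(part$strata), 1L)
  expect_equal(part$strata$key, "(root)")
  expect_true(all(part$assignment == 1L))

  # min_size = 1: leaves are the full observed combinations
  part1 <- build_strata(co$episodes, co$features, co$members, ord,
                        min_size = 1)
  combos <- unique(data.table::data.table(
    a = as.character(age_group(co$members$age)),
    g = co$members$gender, f = co$raw[, "F01"]))
  expect_equal(nrow(part1$strata), nrow(combos))
  expect_true(all(part1$strata$depth == 3L))
})

test_that("the trie partition equals brute-force recursion on random cohorts", {
  for (s in 1:25) {
    n <- sample(200:800, 1)
    p <- sample(3:6, 1)
    co <- random_cohort(n, p, seed = 1000 + s)
    ordv <- c("age_group", "gender", sprintf("F%02d", 1:p))
    ms <- sample(c(10, 25, 60), 1)
    part <- build_strata(co$episodes, co$features, co$members, ordv,
                         min_size = ms)
    # invariants: exact partition, minimum size respected
    expect_equal(sum(part$strata$size), n)
    expect_true(all(part$strata$size >= min(ms, n)))
    expect_equal(length(unique(part$assignment)), nrow(part$strata))
    expect_equal(as.vector(table(part$assignment)[as.character(part$strata$stratum_id)]),
                 part$strata$size)

    vals <- data.frame(
      age_group = as.character(age_group(co$members$age)),
      gender = co$members$gender,
      as.data.frame(co$raw), check.names = FALSE)
    names(vals) <- ordv
    want <- oracle_strata(vals, ms)
    expect_equal(nrow(part$strata), length(want))
    got_sets <- lapply(part$strata$stratum_id,
                       function(id) sort(which(part$assignment == id)))
    want_sets <- lapply(want, function(l) sort(l$rows))
    key_of <- function(rows) paste(rows, collapse = ",")
    expect_setequal(vapply(got_sets, key_of, ""), vapply(want_sets, key_of, ""))
  }
})

test_that("increasing min_size coarsens and refines consistently", {
  co <- random_cohort(1500, 5, seed = 77)
  ordv <- c("age_group", "gender", sprintf("F%02d", 1:5))
  p100 <- build_strata(co$episodes, co$features, co$members, ordv, min_size = 100)
  p200 <- build_strata(co$episodes, co$features, co$members, ordv, min_size = 200)
  expect_lte(nrow(p200$strata), nrow(p100$strata))
  # refinement: every coarse stratum is a union of fine strata
  for (id in p200$strata$stratum_id) {
    rows <- which(p200$assignment == id)
    fine_ids <- unique(p100$assignment[rows])
    expect_true(all(!p100$assignment[-rows] %in% fine_ids))
  }
  # determinism
  p100b <- build_strata(co$episodes, co$features, co$members, ordv, min_size = 100)
  expect_identical(p100$assignment, p100b$assignment)
  expect_equal(p100$strata, p100b$strata)
})

test_that("history matching descends to the training episode's stratum", {
  co <- random_cohort(900, 4, seed = 91)
  ordv <- c("age_group", "gender", sprintf("F%02d", 1:4))
  part <- build_strata(co$episodes, co$features, co$members, ordv, min_size = 40)

  # brute-force longest-matching-prefix over the leaf keys
  vals <- data.frame(age_group = as.character(age_group(co$members$age)),
                     gender = co$members$gender,
                     as.data.frame(co$raw), check.names = FALSE)
  names(vals) <- ordv
  oracle_match <- function(h) {
    for (id in part$strata$stratum_id) {
      pre <- part$prefixes[[id]]
      if (all(vapply(seq_along(pre),
                     function(j) h[[names(pre)[j]]] == pre[[j]], logical(1))))
        return(id)
    }
    NA_integer_
  }
  set.seed(92)
  idx <- sample(nrow(vals), 200)
  for (i in idx) {
    h <- as.list(vals[i, , drop = FALSE])
    got <- match_history(h, part)
    expect_equal(as.integer(got), part$assignment[i])
    expect_equal(as.integer(got), oracle_match(h))
  }

  # random unseen histories still land in exactly one leaf
  for (r in 1:50) {
    h <- list(age_group = sample(c("13-19", "20-40", "41-64", "65-79", "80+"), 1),
              gender = sample(c("F", "M"), 1))
    for (v in sprintf("F%02d", 1:4)) h[[v]] <- sample(0:1, 1)
    got <- match_history(h, part)
    expect_true(as.integer(got) %in% part$strata$stratum_id)
  }

  # missing feature value treated as absence
  h0 <- list(age = 30, gender = "F")
  expect_true(as.integer(match_history(h0, part)) %in% part$strata$stratum_id)
})
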