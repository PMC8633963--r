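# Stratified 2x2 tables, Mantel-Haenszel common OR + RBG interval,
# Breslow-Day homogeneity, rate tables, and the gain arithmetic.

part_of <- function(assignment, sizes = NULL) {
  ids <- sort(unique(assignment))
  st <- data.table::data.table(
    stratum_id = ids,
    key_label = as.character(ids),
    depth = 1L,
    size = as.vector(table(assignment)[as.character(ids)]))
  data.table::setnames(st, "key_label", "key")
  structure(list(
    assignment = assignment,
    strata = st,
    prefixes = as.list(as.character(ids)),
    order_vars = "g", min_size = 1L
  ), class = "strata_partition")
}

test_that("per-stratum 2x2 tables equal brute-force group-by counts", {
  set.seed(3)
  n <- 1000
  ep <- data.table::data.table(
    drug_label = sample(c("Sertraline", "Citalopram", "Other"), n, TRUE),
    remission = sample(c(TRUE, FALSE), n, TRUE))
  g <- sample(1:6, n, TRUE)
  tab <- tabulate_strata(part_of(g), ep, "Sertraline")
  for (s in 1:6) {
    sel <- g == s
    expect_equal(tab[stratum_id == s, a],
                 sum(ep$drug_label[sel] == "Sertraline" & ep$remission[sel]))
    expect_equal(tab[stratum_id == s, d],
                 sum(ep$drug_label[sel] != "Sertraline" & !ep$remission[sel]))
    expect_equal(tab[stratum_id == s, n], sum(sel))
  }
  # worked single stratum: 40 drug (24 remit), 60 other (18 remit)
  ep2 <- data.table::data.table(
    drug_label = rep(c("Sertraline", "Other"), c(40, 60)),
    remission = c(rep(c(TRUE, FALSE), c(24, 16)), rep(c(TRUE, FALSE), c(18, 42))))
  t2 <- tabulate_strata(part_of(rep(1L, 100)), ep2, "Sertraline")
  expect_equal(unlist(t2[, .(a, b, c, d)]), c(a = 24, b = 16, c = 18, d = 42))
  expect_false(t2$degenerate)
  # a stratum without the drug is degenerate
  t3 <- tabulate_strata(part_of(rep(1:2, c(50, 50))),
                        data.table::data.table(
                          drug_label = rep(c("Sertraline", "Other"), c(50, 50)),
                          remission = rep(c(TRUE, FALSE), 50)),
                        "Sertraline")
  expect_true(all(t3$degenerate))
})

test_that("MH common OR reduces to the single-table OR and is order-invariant", {
  single <- data.table::data.table(a = 24, b = 16, c = 18, d = 42)
  m1 <- mh_common_or(single)
  expect_equal(m1$or_mh, (24 * 42) / (16 * 18))  # 3.5
  # two identical tables: same point estimate
  m2 <- mh_common_or(rbind(single, single))
  expect_equal(m2$or_mh, 3.5)
  # stratum order never matters
  tbs <- random_tables(8, seed = 5)
  expect_equal(mh_common_or(tbs)$or_mh,
               mh_common_or(tbs[sample(8)])$or_mh, tolerance = 1e-14)
  expect_error(mh_common_or(single[0]), "no non-degenerate")
})

test_that("MH estimate and RBG interval match independent implementations", {
  for (s in 1:30) {
    k <- sample(2:12, 1)
    tb <- random_tables(k, n_per = sample(c(60, 200, 500), 1), seed = 200 + s)
    got <- mh_common_or(tb, conf_level = 0.99)
    want <- oracle_mh_rbg(tb$a, tb$b, tb$c, tb$d, conf = 0.99)
    expect_equal(got$or_mh, want$or, tolerance = 1e-10)
    expect_equal(got$ci, want$ci, tolerance = 1e-10)
    # stats::mantelhaen.test as a second, fully external check
    arr <- array(rbind(tb$a, tb$c, tb$b, tb$d), dim = c(2, 2, k))
    mh <- mantelhaen.test(arr, conf.level = 0.99, correct = FALSE)
    expect_equal(got$or_mh, unname(mh$estimate), tolerance = 1e-10)
  }
})

test_that("Breslow-Day matches the root-finding oracle and behaves at the poles", {
  for (s in 1:30) {
    k <- sample(2:10, 1)
    tb <- random_tables(k, n_per = sample(c(80, 300), 1), seed = 400 + s)
    psi <- mh_common_or(tb)$or_mh
    got <- breslow_day(tb, or_mh = psi)
    want <- oracle_breslow_day(tb$a, tb$b, tb$c, tb$d, psi)
    expect_equal(got$bd_stat, want$stat, tolerance = 1e-8)
    expect_equal(got$tarone_stat, want$tarone, tolerance = 1e-8)
    expect_equal(got$p_value, want$p, tolerance = 1e-8)
    expect_equal(got$df, k - 1L)
    expect_gte(got$bd_stat, 0)
  }
  # identical tables are perfectly homogeneous
  same <- data.table::data.table(a = rep(30, 5), b = rep(20, 5),
                                 c = rep(25, 5), d = rep(25, 5))
  bd <- breslow_day(same)
  expect_equal(bd$bd_stat, 0, tolerance = 1e-10)
  expect_equal(bd$p_value, 1)
  expect_error(breslow_day(same, or_mh = -1), "or_mh")
})

test_that("rate tables report, blank, and flag best drugs deterministically", {
  set.seed(9)
  g <- rep(1:2, c(300, 300))
  ep <- data.table::data.table(
    drug_label = c(rep(c("A", "B", "C"), c(160, 120, 20)),
                   rep(c("A", "B", "C"), each = 100)),
    remission = FALSE)
  # stratum 1: A 50%, B 60%, C (20 eps, below report_min) 100%
  ep$remission[1:80] <- TRUE                 # A in stratum 1
  ep$remission[161:232] <- TRUE              # B in stratum 1
  ep$remission[281:300] <- TRUE              # C in stratum 1
  # stratum 2: A and B tie at 40%, C 10%; tie broken by name (A first)
  ep$remission[301:340] <- TRUE
  ep$remission[401:440] <- TRUE
  ep$remission[501:510] <- TRUE
  rt <- rate_table(part_of(g), ep, report_min = 25)
  s1 <- rt[stratum_id == 1]
  expect_false(s1[drug == "C", reported])    # blank cell
  expect_true(s1[drug == "B", best])         # 0.6 beats 0.5; C not reported
  s2 <- rt[stratum_id == 2]
  expect_equal(s2[best == TRUE, drug], "A")  # equal rate+count: name order
  expect_true(all(rt$rate >= 0 & rt$rate <= 1))
  expect_equal(rt[, sum(best), by = stratum_id]$V1, c(1, 1))
  # brute-force tally agreement
  for (s in 1:2) for (dg in c("A", "B", "C")) {
    sel <- g == s & ep$drug_label == dg
    expect_equal(rt[stratum_id == s & drug == dg, rate], mean(ep$remission[sel]))
  }
})

test_that("counterfactual gain arithmetic matches its definition", {
  # two-stratum toy: sizes 100/200, best rates 0.5/0.4 -> counterfactual 130
  g <- rep(1:2, c(100, 200))
  ep <- data.table::data.table(
    drug_label = c(rep(c("A", "B"), c(50, 50)), rep(c("A", "B"), c(100, 100))),
    remission = c(rep(c(TRUE, FALSE), c(25, 25)),   # A s1: 0.5
                  rep(c(TRUE, FALSE), c(15, 35)),   # B s1: 0.3
                  rep(c(TRUE, FALSE), c(40, 60)),   # A s2: 0.4
                  rep(c(TRUE, FALSE), c(20, 80))))  # B s2: 0.2
  part <- part_of(g)
  rt <- rate_table(part, ep, report_min = 10)
  gr <- counterfactual_gain(rt, part, ep)
  expect_equal(gr$counterfactual_remissions, 0.5 * 100 + 0.4 * 200)  # 130
  expect_equal(gr$observed_remissions, 100)
  expect_equal(gr$additional, 30)
  expect_equal(gr$ratio, 1.3)

  # best == observed everywhere -> zero gain
  ep1 <- data.table::data.table(drug_label = "A",
                                remission = rep(c(TRUE, FALSE), 50))
  p1 <- part_of(rep(1L, 100))
  g1 <- counterfactual_gain(rate_table(p1, ep1, report_min = 10), p1, ep1)
  expect_equal(g1$additional, 0)

  # no reportable drug: stratum falls back to its overall rate
  epf <- data.table::data.table(drug_label = rep(c("A", "B"), 5),
                                remission = rep(c(TRUE, FALSE), 5))
  pf <- part_of(rep(1L, 10))
  gf <- counterfactual_gain(rate_table(pf, epf, report_min = 25), pf, epf)
  expect_equal(gf$n_fallback_strata, 1L)
  expect_equal(gf$additional, 0)
})

test_that("expected false positives is alpha times m with nearest rounding", {
  e <- expected_false_positives(0.05, 100)
  expect_equal(e$expected, 5)
  expect_equal(expected_false_positives(0.3, 0)$expected, 0)
  expect_error(expected_false_positives(1.2, 10), "alpha")
  expect_error(expected_false_positives(0.05, -1), "m")
})
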