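# Stratified effect estimation: per-stratum 2x2 tables, the
# Mantel-Haenszel common odds ratio with the Robins-Breslow-Greenland
# variance, the Breslow-Day homogeneity test (with Tarone's correction),
# remission-rate tables, and the counterfactual best-drug gain.

#' Per-stratum 2x2 tables for one drug versus the rest
#'
#' For every stratum of the partition: `a` = drug & remission, `b` = drug
#' & no remission, `c` = other & remission, `d` = other & no remission.
#' Strata with a zero margin (no exposed, no unexposed, or no outcome
#' variation) are flagged degenerate; they are excluded from the
#' Breslow-Day degrees of freedom.
#'
#' @param partition a `strata_partition` over the episode rows.
#' @param episodes labeled episode table (same row order used to build
#'   the partition).
#' @param drug treatment label contrasted against all others.
#' @return data.table (class `stratified_tables`): stratum_id, a, b, c,
#'   d, n, degenerate.
#' @export
tabulate_strata <- function(partition, episodes, drug) {
  episodes <- as.data.table(episodes)
  stopifnot(length(partition$assignment) == nrow(episodes))
  dt <- data.table(
    stratum_id = partition$assignment,
    exposed = episodes$drug_label == drug,
    remit = as.logical(episodes$remission)
  )
  tab <- dt[, .(
    a = sum(exposed & remit), b = sum(exposed & !remit),
    c = sum(!exposed & remit), d = sum(!exposed & !remit)
  ), keyby = stratum_id]
  tab[, n := a + b + c + d]
  tab[, degenerate := (a + b) == 0L | (c + d) == 0L |
        (a + c) == 0L | (b + d) == 0L]
  setattr(tab, "class", c("stratified_tables", class(tab)))
  tab[]
}

#' Mantel-Haenszel common odds ratio with RBG confidence interval
#'
#' Point estimate `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; the
#' confidence interval uses the Robins-Breslow-Greenland variance of the
#' log common odds ratio with the normal quantile (2.576 at 99%).
#' Degenerate tables contribute nothing to either sum and are dropped.
#'
#' @param tables a `stratified_tables` table, or any data.frame with
#'   columns a, b, c, d (counts).
#' @param conf_level confidence level (the stratified analysis reports
#'   99% intervals).
#' @return list (class `mh_or`): `or_mh`, `ci` (low, high), `log_or`,
#'   `se_log_or`, `conf_level`, `k` (tables used).
#' @export
mh_common_or <- function(tables, conf_level = 0.99) {
  tb <- as.data.table(tables)
  if ("degenerate" %in% names(tb)) tb <- tb[degenerate == FALSE]
  if (!nrow(tb)) stopf("estimation error: no non-degenerate strata")
  a <- as.numeric(tb$a); b <- as.numeric(tb$b)
  c <- as.numeric(tb$c); d <- as.numeric(tb$d)
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  sR <- sum(R); sS <- sum(S)
  if (sR == 0 || sS == 0)
    stopf("estimation error: Mantel-Haenszel sums are zero; OR undefined")
  or_mh <- sR / sS
  P <- (a + d) / n
  Q <- (b + c) / n
  var_log <- sum(P * R) / (2 * sR^2) +
    sum(P * S + Q * R) / (2 * sR * sS) +
    sum(Q * S) / (2 * sS^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(var_log)
  ci <- exp(log(or_mh) + c(-1, 1) * z * se)
  structure(list(or_mh = or_mh, ci = ci, log_or = log(or_mh),
                 se_log_or = se, conf_level = conf_level, k = nrow(tb)),
            class = "mh_or")
}

#' @export
print.mh_or <- function(x, ...) {
  cat(sprintf("MH common OR = %.4f (%d%% CI %.4f to %.4f; k = %d strata)\n",
              x$or_mh, round(100 * x$conf_level), x$ci[1], x$ci[2], x$k))
  invisible(x)
}

# Fitted count a_e under a common odds ratio psi with the table's fixed
# margins: the admissible root of
#   a^2 (1 - psi) + a [(n2 - t) + psi (m1 + t)] - psi m1 t = 0
# where m1 = a+b (exposed), n2 = c+d (unexposed), t = a+c (responders).
bd_expected_a <- function(a, b, c, d, psi) {
  m1 <- a + b; n2 <- c + d; t <- a + c
  if (abs(psi - 1) < 1e-12) return(m1 * t / (m1 + n2))
  A <- 1 - psi
  B <- (n2 - t) + psi * (m1 + t)
  C <- -psi * m1 * t
  disc <- sqrt(max(B^2 - 4 * A * C, 0))
  roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
  lo <- max(0, t - n2); hi <- min(m1, t)
  ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
  if (!any(ok)) stopf("Breslow-Day: no admissible fitted count")
  roots[ok][1L]
}

#' Breslow-Day test of odds-ratio homogeneity
#'
#' Tests whether the stratum-specific odds ratios share the common value
#' by comparing each table's `a` cell with its fitted value under the
#' Mantel-Haenszel common odds ratio; Tarone's bias-corrected statistic
#' is reported alongside.  Degenerate strata are excluded from the
#' degrees of freedom.
#'
#' @inheritParams mh_common_or
#' @param or_mh common odds ratio to test against (computed from the
#'   tables if `NULL`).
#' @return list (class `breslow_day`): `bd_stat`, `df`, `p_value`,
#'   `tarone_stat`, `tarone_p`, `or_mh`, `k_dropped` (degenerate strata).
#' @export
breslow_day <- function(tables, or_mh = NULL) {
  tb <- as.data.table(tables)
  k_dropped <- 0L
  if ("degenerate" %in% names(tb)) {
    k_dropped <- sum(tb$degenerate)
    tb <- tb[degenerate == FALSE]
  }
  if (is.null(or_mh)) or_mh <- mh_common_or(tb)$or_mh
  if (!is.finite(or_mh) || or_mh <= 0)
    stopf("validation error: 'or_mh' must be finite and > 0")
  k <- nrow(tb)
  ea <- va <- dev <- numeric(k)
  for (i in seq_len(k)) {
    a <- as.numeric(tb$a[i]); b <- as.numeric(tb$b[i])
    c <- as.numeric(tb$c[i]); d <- as.numeric(tb$d[i])
    ae <- bd_expected_a(a, b, c, d, or_mh)
    be <- (a + b) - ae
    ce <- (a + c) - ae
    de <- (c + d) - ce
    va[i] <- 1 / (1 / ae + 1 / be + 1 / ce + 1 / de)
    ea[i] <- ae
    dev[i] <- a - ae
  }
  bd_stat <- sum(dev^2 / va)
  tarone <- bd_stat - sum(dev)^2 / sum(va)
  df <- k - 1L
  structure(list(
    bd_stat = bd_stat, df = df,
    p_value = pchisq(bd_stat, df, lower.tail = FALSE),
    tarone_stat = tarone,
    tarone_p = pchisq(tarone, df, lower.tail = FALSE),
    or_mh = or_mh, k = k, k_dropped = k_dropped
  ), class = "breslow_day")
}

#' @export
print.breslow_day <- function(x, ...) {
  cat(sprintf("Breslow-Day X^2 = %.3f on %d df (p %s; Tarone %.3f); common OR %.4f\n",
              x$bd_stat, x$df,
              format.pval(x$p_value, digits = 3), x$tarone_stat, x$or_mh))
  invisible(x)
}

#' Stratified effect summary for one drug
#'
#' Bundles [tabulate_strata()], [mh_common_or()] and [breslow_day()] into
#' the per-drug row of the effects report.
#'
#' @inheritParams tabulate_strata
#' @param conf_level CI level for the common odds ratio.
#' @return list (class `stratified_effect`): `drug`, `tables`, `mh`,
#'   `bd`, `k`, `k_degenerate`.
#' @export
stratified_effect <- function(partition, episodes, drug, conf_level = 0.99) {
  tab <- tabulate_strata(partition, episodes, drug)
  mh <- mh_common_or(tab, conf_level = conf_level)
  bd <- breslow_day(tab, or_mh = mh$or_mh)
  structure(list(drug = drug, tables = tab, mh = mh, bd = bd,
                 k = nrow(tab), k_degenerate = sum(tab$degenerate)),
            class = "stratified_effect")
}

#' Per-stratum remission-rate table with best-drug flags
#'
#' Remission rate and episode count per (stratum, drug).  Cells with
#' fewer than `report_min` episodes are not reported (blank in the
#' printed table); the best drug per stratum is the reported drug with
#' the highest rate, ties broken by larger count then drug name.
#'
#' @inheritParams tabulate_strata
#' @param report_min minimum episodes for a (stratum, drug) cell to be
#'   reported.
#' @param drugs drugs to tally (default: all labels present).
#' @return data.table (class `stratum_rate_table`): stratum_id, drug,
#'   n, rate, reported, best.
#' @export
rate_table <- function(partition, episodes, report_min = 25L, drugs = NULL) {
  episodes <- as.data.table(episodes)
  stopifnot(length(partition$assignment) == nrow(episodes))
  dt <- data.table(
    stratum_id = partition$assignment,
    drug = episodes$drug_label,
    remit = as.numeric(episodes$remission)
  )
  if (!is.null(drugs)) dt <- dt[drug %in% drugs]
  rt <- dt[, .(n = .N, rate = mean(remit)), keyby = .(stratum_id, drug)]
  rt[, reported := n >= report_min]
  rt[, best := FALSE]
  rt[reported == TRUE,
     best := seq_len(.N) == order(-rate, -n, drug)[1L],
     by = stratum_id]
  setattr(rt, "class", c("stratum_rate_table", class(rt)))
  rt[]
}

#' Counterfactual gain from always prescribing the stratum-best drug
#'
#' Compares observed remissions with the counterfactual count obtained if
#' every episode in a stratum had experienced that stratum's best
#' reported remission rate.  Strata with no reportable drug fall back to
#' their overall remission rate (so they contribute no gain).
#'
#' @param rates a [rate_table()] result.
#' @param partition the `strata_partition` the rates were computed on.
#' @param episodes the labeled episode table.
#' @return a `gain_report` (see [gain_report()]).
#' @export
counterfactual_gain <- function(rates, partition, episodes) {
  episodes <- as.data.table(episodes)
  sizes <- partition$strata[, .(stratum_id, size)]
  obs <- data.table(stratum_id = partition$assignment,
                    remit = as.numeric(episodes$remission))[
    , .(observed = sum(remit)), keyby = stratum_id]
  best <- as.data.table(rates)[best == TRUE, .(stratum_id, best_rate = rate)]
  overall <- data.table(stratum_id = partition$assignment,
                        remit = as.numeric(episodes$remission))[
    , .(fallback = mean(remit)), keyby = stratum_id]
  m <- Reduce(function(x, y) merge(x, y, by = "stratum_id", all.x = TRUE),
              list(sizes, obs, best, overall))
  n_fallback <- sum(is.na(m$best_rate))
  m[is.na(best_rate), best_rate := fallback]
  total <- sum(m$size)
  observed <- sum(m$observed)
  counterfactual <- sum(m$best_rate * m$size)
  gain_report(total_episodes = total, observed_remissions = observed,
              counterfactual_remissions = counterfactual,
              n_fallback_strata = n_fallback)
}

#' Construct a counterfactual gain report from totals
#'
#' The arithmetic layer shared by [counterfactual_gain()] and by
#' published-totals checks: given the episode total, the observed
#' remissions, and either the counterfactual remissions or the
#' additional remissions, computes the remaining quantities and the
#' counterfactual/observed ratio.
#'
#' @param total_episodes number of episodes.
#' @param observed_remissions observed remission count.
#' @param counterfactual_remissions remissions if every episode had the
#'   stratum-best rate (optional if `additional` given).
#' @param additional counterfactual minus observed (optional).
#' @param n_fallback_strata strata that used their overall rate.
#' @return list (class `gain_report`): `total_episodes`,
#'   `observed_remissions`, `counterfactual_remissions`, `additional`,
#'   `ratio`.
#' @export
gain_report <- function(total_episodes, observed_remissions,
                        counterfactual_remissions = NULL, additional = NULL,
                        n_fallback_strata = 0L) {
  if (is.null(counterfactual_remissions)) {
    if (is.null(additional)) stopf("need counterfactual or additional remissions")
    counterfactual_remissions <- observed_remissions + additional
  }
  if (is.null(additional))
    additional <- counterfactual_remissions - observed_remissions
  structure(list(
    total_episodes = total_episodes,
    observed_remissions = observed_remissions,
    counterfactual_remissions = counterfactual_remissions,
    additional = additional,
    ratio = counterfactual_remissions / observed_remissions,
    n_fallback_strata = n_fallback_strata
  ), class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf(
    "gain_report: %.0f episodes; %.0f observed vs %.0f counterfactual remissions (+%.0f; ratio %.2f)\n",
    x$total_episodes, x$observed_remissions, x$counterfactual_remissions,
    x$additional, x$ratio))
  invisible(x)
}

#' Expected false positives under multiple comparisons
#'
#' At significance level `alpha` over `m` independent comparisons, the
#' expected number of false-positive findings is `alpha * m`; the
#' nearest-integer rounding is reported alongside (e.g. 1e-4 over 16,770
#' comparisons gives 1.677, i.e. about 2 expected errors).
#'
#' @param alpha significance level in (0, 1).
#' @param m number of comparisons (>= 0).
#' @return list: `expected` (`alpha * m`) and `rounded`.
#' @export
expected_false_positives <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("'alpha' must be in (0, 1)")
  if (!is.numeric(m) || m < 0) stopf("'m' must be >= 0")
  e <- alpha * m
  list(expected = e, rounded = round(e))
}

#' Crude (unstratified) odds ratio of remission for one drug
#'
#' The single-table drug-versus-rest odds ratio with a Wald CI; the
#' comparison point for the deconfounding property of the stratified
#' analysis.
#'
#' @param episodes labeled episode table.
#' @param drug treatment label.
#' @param conf_level confidence level.
#' @return list: `or`, `ci`.
#' @export
crude_or <- function(episodes, drug, conf_level = 0.99) {
  episodes <- as.data.table(episodes)
  a <- episodes[drug_label == drug & remission == TRUE, .N]
  b <- episodes[drug_label == drug & remission == FALSE, .N]
  c <- episodes[drug_label != drug & remission == TRUE, .N]
  d <- episodes[drug_label != drug & remission == FALSE, .N]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se),
       table = c(a = a, b = b, c = c, d = d))
}
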