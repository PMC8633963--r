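# Independent reference implementations used as oracles.  These are
# written from the definitions (brute-force scans, closed forms,
# root-finding) and deliberately share no code with the package paths
# they check.

library(data.table)

tiny_config <- function(n_patients = 300L, seed = 1L, ...) {
  synth_config(n_patients = n_patients, seed = seed, ...)
}

# --- episode construction: brute-force scan over the sorted fill timeline
oracle_episode_bounds <- function(fills, gap_days = 30) {
  fills <- as.data.table(fills)
  fills[, fill_date := as.Date(fill_date)]
  setorder(fills, patient_id, fill_date, drug)
  out <- list()
  for (pid in unique(fills$patient_id)) {
    f <- fills[patient_id == pid]
    epi <- 1L
    ids <- integer(nrow(f))
    end <- -Inf
    for (i in seq_len(nrow(f))) {
      d <- as.integer(f$fill_date[i])
      if (is.finite(end) && d - end > gap_days) epi <- epi + 1L
      end <- max(end, d + f$days_supply[i])
      ids[i] <- epi
    }
    f[, episode_index := ids]
    out[[pid]] <- f[, .(start = min(fill_date), end = max(fill_date + days_supply),
                        n_fills = .N),
                    by = .(patient_id, episode_index)]
  }
  rbindlist(out)
}

# --- eligibility: direct span arithmetic per episode
oracle_eligible <- function(episodes, members, min_history = 465) {
  members <- as.data.table(members)
  vapply(seq_len(nrow(episodes)), function(i) {
    sp <- members[patient_id == episodes$patient_id[i]]
    any(sp$cov_start <= episodes$start_date[i] - min_history &
          sp$cov_end >= episodes$start_date[i])
  }, logical(1))
}

# --- SAFE screen: per-column statistic from the definition
oracle_safe_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  apply(X, 2L, function(x) {
    if (sd(x) == 0) return(NA_real_)
    abs(sum(((x - mean(x)) / sd(x)) * (y - mean(y))))
  })
}

# --- strata: plain recursive reference implementation
oracle_strata <- function(values, min_size) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  leaves <- list()
  recurse <- function(rows, depth, prefix) {
    if (depth < ncol(values) && length(rows) >= min_size) {
      v <- values[rows, depth + 1L]
      tab <- table(v)
      if (all(tab >= min_size)) {
        for (val in sort(names(tab))) {
          recurse(rows[v == val], depth + 1L,
                  c(prefix, setNames(val, names(values)[depth + 1L])))
        }
        return(invisible())
      }
    }
    leaves[[length(leaves) + 1L]] <<- list(rows = rows, prefix = prefix)
  }
  recurse(seq_len(nrow(values)), 0L, character(0))
  leaves
}

# --- Mantel-Haenszel + RBG from the textbook formulas, written directly
oracle_mh_rbg <- function(a, b, c, d, conf = 0.99) {
  n <- a + b + c + d
  psi <- sum(a * d / n) / sum(b * c / n)
  P <- (a + d) / n; Q <- (b + c) / n
  R <- a * d / n; S <- b * c / n
  V <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = psi, ci = exp(log(psi) + c(-1, 1) * z * sqrt(V)))
}

# --- Breslow-Day with fitted counts obtained by root-finding instead of
#     the closed-form quadratic
oracle_breslow_day <- function(a, b, c, d, psi) {
  k <- length(a)
  stat <- 0
  devs <- vars <- numeric(k)
  for (i in seq_len(k)) {
    m1 <- a[i] + b[i]; n2 <- c[i] + d[i]; t <- a[i] + c[i]
    lo <- max(0, t - n2); hi <- min(m1, t)
    f <- function(x) (x * (n2 - t + x)) - psi * (m1 - x) * (t - x)
    ae <- uniroot(f, lower = lo + 1e-9, upper = hi - 1e-9, tol = 1e-12)$root
    va <- 1 / (1 / ae + 1 / (m1 - ae) + 1 / (t - ae) + 1 / (n2 - t + ae))
    devs[i] <- a[i] - ae
    vars[i] <- va
    stat <- stat + (a[i] - ae)^2 / va
  }
  list(stat = stat, tarone = stat - sum(devs)^2 / sum(vars),
       p = pchisq(stat, k - 1, lower.tail = FALSE))
}

# random non-degenerate 2x2xK table sets
random_tables <- function(k, n_per = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    n1 <- pmax(2L, rbinom(k, n_per, 0.4))
    n0 <- pmax(2L, n_per - n1)
    p1 <- runif(k, 0.15, 0.85)
    p0 <- runif(k, 0.15, 0.85)
    a <- rbinom(k, n1, p1); b <- n1 - a
    c <- rbinom(k, n0, p0); d <- n0 - c
    ok <- a > 0 & b > 0 & c > 0 & d > 0
    if (all(ok)) return(data.table(a = a, b = b, c = c, d = d))
  }
}

# simulate k strata with a common odds ratio psi (or per-stratum psi)
simulate_common_or_tables <- function(k, n_per, psi, p0_range = c(0.2, 0.6)) {
  psi <- rep_len(psi, k)
  p0 <- runif(k, p0_range[1], p0_range[2])
  odds1 <- psi * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  n1 <- n_per %/% 2L
  n0 <- n_per - n1
  a <- rbinom(k, n1, p1); b <- n1 - a
  c <- rbinom(k, n0, p0); d <- n0 - c
  data.table(a = a, b = b, c = c, d = d,
             degenerate = a + b == 0 | c + d == 0 | a + c == 0 | b + d == 0)
}
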