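# Episode-level binary predictor construction over the 1-year lookback,
# and SAFE-style screening to a fixed number of columns.

#' Build the episode-by-predictor binary matrix
#'
#' Column `j` of row `i` is 1 iff the code (or drug) occurred for that
#' patient within the year before the episode start, `[start - window,
#' start)`.  Diagnoses contribute columns prefixed `dxi:` (inpatient) or
#' `dxo:` (outpatient); prior medications contribute `rx:` columns (fills
#' of the index episode itself fall on/after the start date and are
#' therefore excluded automatically).  History columns append the number
#' of previous treatment episodes, bucketed to binary indicators
#' (`hist:prior_ge1/2/3`), and the last episode's remission status
#' (`hist:last_remission`).  A missing covariate means the patient did
#' not have the diagnosis, i.e. 0.
#'
#' @param episodes labeled episode table ([label_episodes()] output or
#'   compatible; needs `episode_id`, `patient_id`, `episode_index`,
#'   `start_date`, and `remission` for the history columns).
#' @param medical medical claims (`patient_id`, `service_date`, `code`,
#'   optional `setting` in `{"inpatient","outpatient"}`).
#' @param pharmacy pharmacy fills (`patient_id`, `drug`, `fill_date`).
#' @param window lookback length in days.
#' @return a `feature_matrix`: list with `X` (sparse 0/1 dgCMatrix, rows
#'   keyed by `episode_id`) and `meta` (data.table: column, kind).
#' @export
build_features <- function(episodes, medical, pharmacy, window = 365) {
  episodes <- as.data.table(episodes)
  stopifnot(nrow(episodes) > 0L)
  ep <- episodes[, .(episode_id, patient_id, episode_index, start_date)]
  ep[, row := .I]
  ep[, win_lo := start_date - window]

  triplet <- function(claims, datecol, codecol, prefix) {
    cl <- copy(as.data.table(claims))
    if (!nrow(cl)) return(NULL)
    if (!inherits(cl[[datecol]], "Date")) cl[, (datecol) := as.Date(get(datecol))]
    setnames(cl, c(datecol, codecol), c(".date", ".code"))
    hits <- cl[ep, on = .(patient_id, .date >= win_lo, .date < start_date),
               nomatch = NULL, .(row = i.row, code = x..code,
                                 prefix_val = prefix)]
    if (!nrow(hits)) return(NULL)
    unique(hits[, .(row, column = paste0(prefix_val, code))])
  }

  med <- as.data.table(medical)
  parts <- list()
  if (nrow(med)) {
    if (!"setting" %in% names(med)) med[, setting := "outpatient"]
    parts$dxi <- triplet(med[setting == "inpatient"], "service_date", "code", "dxi:")
    parts$dxo <- triplet(med[setting != "inpatient"], "service_date", "code", "dxo:")
  }
  parts$rx <- triplet(pharmacy, "fill_date", "drug", "rx:")

  # history columns from the episode sequence itself
  prior <- ep[, .(row, n_prior = episode_index - 1L)]
  hist_parts <- list(
    data.table(row = prior[n_prior >= 1L, row], column = "hist:prior_ge1"),
    data.table(row = prior[n_prior >= 2L, row], column = "hist:prior_ge2"),
    data.table(row = prior[n_prior >= 3L, row], column = "hist:prior_ge3")
  )
  if ("remission" %in% names(episodes)) {
    prev <- episodes[, .(patient_id, episode_index, remission)]
    prev[, episode_index := episode_index + 1L]
    last_rem <- prev[ep, on = .(patient_id, episode_index), nomatch = NULL,
                     .(row = i.row, rem = x.remission)]
    hist_parts$last <- data.table(row = last_rem[rem == TRUE, row],
                                  column = "hist:last_remission")
  }
  trip <- rbindlist(c(parts, hist_parts), use.names = TRUE)
  trip <- trip[!is.na(column)]
  cols <- sort(unique(trip$column))
  X <- Matrix::sparseMatrix(
    i = trip$row, j = match(trip$column, cols), x = 1,
    dims = c(nrow(ep), length(cols)),
    dimnames = list(as.character(ep$episode_id), cols)
  )
  X@x[] <- 1  # duplicate triplets collapse to 1, not counts
  kind <- fifelse(startsWith(cols, "dxi:"), "inpatient_dx",
          fifelse(startsWith(cols, "dxo:"), "outpatient_dx",
          fifelse(startsWith(cols, "rx:"), "medication", "history")))
  structure(list(X = X, meta = data.table(column = cols, kind = kind),
                 window = window),
            class = "feature_matrix")
}

#' SAFE-style screening to the top-K predictors
#'
#' Ranks columns by the screening statistic `|x_j' (y - mean(y))|`
#' computed on standardized columns (the quantity the SAFE rule bounds)
#' and keeps the `K` best; constant columns are dropped, and ties are
#' broken by column name so the result is deterministic.
#'
#' @param X binary predictor matrix (a `feature_matrix` or any matrix
#'   with column names).
#' @param y binary outcome vector, one entry per row of `X`.
#' @param K number of columns to keep.
#' @return a `screen_result`: list with `kept_columns` (ordered by
#'   decreasing score), `score` (named, same order) and `K`.
#' @export
safe_screen <- function(X, y, K = 1000L) {
  if (inherits(X, "feature_matrix")) X <- X$X
  K <- check_count(K, "K")
  if (nrow(X) != length(y)) stopf("'y' must have one entry per row of X")
  y <- as.numeric(y)
  n <- nrow(X)
  yc <- y - mean(y)
  raw <- abs(as.numeric(Matrix::crossprod(X, yc)))
  mu <- Matrix::colMeans(X)
  ex2 <- Matrix::colMeans(X^2)
  sdv <- sqrt(pmax(ex2 - mu^2, 0) * n / (n - 1))
  nonconst <- sdv > 0
  score <- raw / sdv
  score[!nonconst] <- NA_real_
  # rank on 10 significant digits so exact ties (common with binary
  # columns) resolve by name rather than by floating-point noise
  ord <- order(-signif(score, 10), colnames(X), na.last = TRUE)
  ord <- ord[nonconst[ord]]
  kept <- head(ord, K)
  structure(list(kept_columns = colnames(X)[kept],
                 score = stats::setNames(score[kept], colnames(X)[kept]),
                 K = K),
            class = "screen_result")
}
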