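# Importance-ordered stratification.
#
# Strata are the leaves of a trie: episodes are recursively split by the
# robust predictors in decreasing importance (age group first, then
# gender), and a split is accepted only when every resulting child holds
# at least `min_size` episodes — otherwise the node becomes a leaf.  The
# leaves partition the episodes, every episode falls into exactly one
# stratum, and the less important variables are effectively dropped
# wherever the data run thin.

#' Rank robust variables by importance
#'
#' Combines a drug's propensity and remission robust sets into a single
#' stratification order: age group first, gender second, then the union
#' of the two sets' features by decreasing importance (the absolute value
#' of the final LASSO coefficient; for a feature present in both models,
#' the larger of the two).
#'
#' @param propensity_set,remission_set `robust_feature_set`s for the same
#'   drug (either may be `NULL`).
#' @return an `importance_order`: data.table with `variable` and
#'   `importance`, forced demographics first.
#' @export
rank_variables <- function(propensity_set, remission_set) {
  imp <- list()
  for (s in list(propensity_set, remission_set)) {
    if (is.null(s)) next
    stopifnot(inherits(s, "robust_feature_set"))
    v <- s$importance[s$features]
    v <- v[!is.na(v)]
    imp[[length(imp) + 1L]] <- v
  }
  pooled <- numeric(0)
  for (v in imp) {
    for (nm in names(v)) pooled[nm] <- max(pooled[nm], v[[nm]], na.rm = TRUE)
  }
  pooled <- pooled[setdiff(names(pooled), c("age", "gender", "age_group"))]
  ord <- if (length(pooled)) order(-pooled, names(pooled)) else integer(0)
  out <- data.table(
    variable = c("age_group", "gender", names(pooled)[ord]),
    importance = c(Inf, Inf, unname(pooled)[ord])
  )
  setattr(out, "class", c("importance_order", class(out)))
  out[]
}

# Value table for the ordered variables: age_group / gender from the
# member table, everything else a 0/1 feature column.
strata_values <- function(episodes, features, members, order_vars) {
  episodes <- as.data.table(episodes)
  mem <- as.data.table(members)
  idx <- match(episodes$patient_id, mem$patient_id)
  V <- vector("list", length(order_vars))
  names(V) <- order_vars
  for (v in order_vars) {
    V[[v]] <- if (v == "age_group") as.character(age_group(mem$age[idx]))
      else if (v == "gender") mem$gender[idx]
      else if (!is.null(features) && v %in% colnames(features$X))
        as.character(as.integer(features$X[, v]))
      else stopf("stratification variable '%s' not found in the feature matrix", v)
  }
  setDT(V)
  V
}

#' Build the trimmed strata partition
#'
#' Recursive trie construction over the ordered variables: a node splits
#' by the next variable only if every child would hold at least
#' `min_size` episodes; otherwise it becomes a leaf stratum whose key is
#' its root-to-leaf prefix of variable values.  Depth may differ across
#' leaves — that is the trimming: less important variables are dropped
#' exactly where cells would get too small.
#'
#' @param episodes labeled episode table.
#' @param features `feature_matrix` aligned with `episodes` rows (may be
#'   `NULL` if the order uses only demographics).
#' @param members member table (for age and gender).
#' @param order an [rank_variables()] result, or a character vector of
#'   variable names in stratification order.
#' @param min_size minimum episodes per stratum (the trimming threshold;
#'   99 is also a supported reading).
#' @return a `strata_partition`: list with `assignment` (stratum id per
#'   episode row), `strata` (data.table: stratum_id, key, depth, size),
#'   `prefixes` (list of named value vectors), `order_vars`, `min_size`.
#' @export
build_strata <- function(episodes, features, members, order, min_size = 100L) {
  order_vars <- if (inherits(order, "importance_order")) order$variable
                else as.character(order)
  min_size <- check_count(min_size, "min_size")
  V <- strata_values(episodes, features, members, order_vars)
  n <- nrow(V)
  assignment <- integer(n)
  prefixes <- list()
  sizes <- integer(0)
  depths <- integer(0)
  if (n < min_size)
    warning(sprintf("only %d episodes (< min_size=%d): single root stratum",
                    n, min_size), call. = FALSE)
  # iterative DFS; each stack entry: row indices + prefix (named chr)
  stack <- list(list(rows = seq_len(n), depth = 0L,
                     prefix = character(0)))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    d <- node$depth
    split_ok <- FALSE
    if (d < length(order_vars) && length(node$rows) >= min_size) {
      vals <- V[[order_vars[d + 1L]]][node$rows]
      tab <- table(vals)
      split_ok <- all(tab >= min_size)
    }
    if (split_ok) {
      groups <- split(node$rows, vals)
      for (g in rev(names(groups))) {
        pre <- c(node$prefix, stats::setNames(g, order_vars[d + 1L]))
        stack[[length(stack) + 1L]] <-
          list(rows = groups[[g]], depth = d + 1L, prefix = pre)
      }
    } else {
      sid <- length(prefixes) + 1L
      prefixes[[sid]] <- node$prefix
      assignment[node$rows] <- sid
      sizes[sid] <- length(node$rows)
      depths[sid] <- d
    }
  }
  key_str <- vapply(prefixes, function(p) {
    if (!length(p)) "(root)"
    else paste(sprintf("%s=%s", names(p), unname(p)), collapse = " | ")
  }, character(1))
  strata_tbl <- data.table(stratum_id = seq_along(prefixes),
                           key_label = key_str, depth = depths, size = sizes)
  setnames(strata_tbl, "key_label", "key")
  structure(list(
    assignment = assignment,
    strata = strata_tbl,
    prefixes = prefixes,
    order_vars = order_vars,
    min_size = min_size
  ), class = "strata_partition")
}

#' @export
print.strata_partition <- function(x, ...) {
  cat(sprintf("strata_partition: %d strata over %d episodes (min_size=%d, %d variables)\n",
              nrow(x$strata), length(x$assignment), x$min_size,
              length(x$order_vars)))
  invisible(x)
}

#' Match a patient history to its stratum
#'
#' Descends the partition trie using the history's values and returns the
#' unique leaf reached — the most specific stratum that shares the
#' history's features.  A missing binary variable is treated as 0
#' (absence).  If a split's branch value was never observed in training,
#' the largest sibling stratum under that node is used.
#'
#' @param history named vector/list of variable values (`age_group`,
#'   `gender`, and 0/1 feature values, or a numeric `age`).
#' @param partition a `strata_partition`.
#' @return the matched `stratum_id` (with the key string as the
#'   `"key"` attribute).
#' @export
match_history <- function(history, partition) {
  stopifnot(inherits(partition, "strata_partition"))
  h <- as.list(history)
  if (is.null(h$age_group) && !is.null(h$age))
    h$age_group <- as.character(age_group(as.numeric(h$age)))
  value_of <- function(v) {
    val <- h[[v]]
    if (is.null(val)) "0" else as.character(val)
  }
  strata <- partition$strata
  prefixes <- partition$prefixes
  cand <- seq_len(nrow(strata))
  d <- 0L
  repeat {
    leaf <- cand[strata$depth[cand] == d]
    if (length(leaf)) return(structure(leaf[1L], key = strata$key[leaf[1L]]))
    v <- partition$order_vars[d + 1L]
    val <- value_of(v)
    nxt <- cand[vapply(prefixes[cand],
                       function(p) unname(p[[d + 1L]]) == val, logical(1))]
    if (!length(nxt)) {
      # unseen branch value: take the largest sibling subtree
      sib_vals <- vapply(prefixes[cand], function(p) unname(p[[d + 1L]]),
                         character(1))
      best <- names(sort(tapply(strata$size[cand], sib_vals, sum),
                         decreasing = TRUE))[1L]
      nxt <- cand[sib_vals == best]
    }
    cand <- nxt
    d <- d + 1L
  }
}
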