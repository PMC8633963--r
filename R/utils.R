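# Internal validation helpers and small shared utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stopf("configuration error: '%s' must be a probability in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("configuration error: '%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Names of the fifteen studied antidepressants
#'
#' The monotherapies analyzed individually; everything else (unlisted
#' antidepressants, or two studied drugs filled on the same day) is pooled
#' into an `"Other"` category.
#'
#' @param include_other append the pooled `"Other"` label.
#' @return Character vector of generic drug names.
#' @export
ad_drug_names <- function(include_other = FALSE) {
  drugs <- c(
    "Amitriptyline", "Bupropion", "Citalopram", "Desvenlafaxine",
    "Doxepin", "Duloxetine", "Escitalopram", "Fluoxetine", "Mirtazapine",
    "Nortriptyline", "Paroxetine", "Ropinirole", "Sertraline",
    "Trazodone", "Venlafaxine"
  )
  if (include_other) c(drugs, "Other") else drugs
}

#' Minimum therapeutic daily doses
#'
#' Default per-drug minimum therapeutic daily dose (mg/day), the threshold
#' used by the surrogate remission index.  Values are standard adult
#' minimum effective doses; they are configuration, not estimates, and can
#' be replaced wholesale.
#'
#' @return Named numeric vector (mg/day), one entry per analyzed label
#'   including `"Other"`.
#' @export
default_dose_thresholds <- function() {
  c(
    Amitriptyline = 75, Bupropion = 150, Citalopram = 20,
    Desvenlafaxine = 50, Doxepin = 75, Duloxetine = 60,
    Escitalopram = 10, Fluoxetine = 20, Mirtazapine = 15,
    Nortriptyline = 50, Paroxetine = 20, Ropinirole = 2,
    Sertraline = 50, Trazodone = 150, Venlafaxine = 75,
    Other = 20
  )
}

#' Age groups used for stratification and cohort summaries
#'
#' Ages are discretized to the groups 13-19, 20-40, 41-64, 65-79 and 80+
#' before entering any stratification order.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `13-19`, `20-40`, `41-64`, `65-79`, `80+`.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 19, 40, 64, 79, Inf),
      labels = c("13-19", "20-40", "41-64", "65-79", "80+"))
}

# Deterministic child seed: keeps derived seeds inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}
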