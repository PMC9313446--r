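# Lane-keeping error metric and age-stratified boxplot statistics.
#
# The error at each instant is the distance of the car from the road
# centerline, i.e. the absolute lateral position. Descriptives are standard
# Tukey boxplot quantities: quartiles by linear interpolation of the order
# statistics (quantile type 7 — the convention is recorded in the output
# because the outlier fences, and hence the attention calls, depend on it),
# IQR, and fences at Q1 - 1.5*IQR and Q3 + 1.5*IQR.

#' Per-sample absolute error of a session
#'
#' @param session A `session_record`.
#' @return An object of class `error_series`: `participant_id`, `values`
#'   (absolute lateral position per sample, m) and `sample_rate`.
#' @export
error_series <- function(session) {
  stopifnot(inherits(session, "session_record"))
  structure(list(participant_id = session$participant_id,
                 values = abs(session$samples$position),
                 sample_rate = session$sample_rate),
            class = "error_series")
}

#' Boxplot statistics with Tukey fences
#'
#' @param values Numeric vector (non-empty, no NAs).
#' @return An object of class `boxplot_stats`: `q1`, `median`, `q3`, `iqr`,
#'   `lower_fence` (`q1 - 1.5*iqr`), `upper_fence` (`q3 + 1.5*iqr`),
#'   `outlier_count` (strictly outside the fences) and `n`. The quantile
#'   convention is echoed in `quantile_type`.
#' @export
#' @examples
#' boxplot_stats(c(1:9, 100))
boxplot_stats <- function(values) {
  if (length(values) == 0) stop_param("boxplot_stats needs at least one value")
  if (anyNA(values)) stop_param("values must not contain NA")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr
  uf <- q[3] + 1.5 * iqr
  structure(list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
                 lower_fence = lf, upper_fence = uf,
                 outlier_count = sum(values < lf | values > uf),
                 n = length(values), quantile_type = 7L),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("<boxplot_stats> n=%d  Q1=%.3f  med=%.3f  Q3=%.3f  IQR=%.3f  fences=[%.3f, %.3f]  outliers=%d\n",
              x$n, x$q1, x$median, x$q3, x$iqr, x$lower_fence, x$upper_fence,
              x$outlier_count))
  invisible(x)
}

#' Pooled positions of all participants of one age
#'
#' Concatenates every sample of every participant of exactly `age` years —
#' the pooling behind the per-age boxplots and the age-referenced outlier
#' fences.
#'
#' @param cohort A `cohort`.
#' @param age Age in years.
#' @param signed If `TRUE`, return signed lateral positions (used for the
#'   attention fences, which are asymmetric around 0); if `FALSE` (default)
#'   absolute error.
#' @param exclude Optional participant ids to leave out of the pool
#'   (leave-one-out sensitivity analysis).
#' @return Numeric vector of pooled values.
#' @export
age_grouped_positions <- function(cohort, age, signed = FALSE, exclude = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- cohort$manifest$participant_id[cohort$manifest$age == age]
  ids <- setdiff(ids, exclude)
  if (!length(ids))
    stop_empty_group("no participants of age %s in cohort%s", age,
                     if (length(exclude)) " (after exclusions)" else "")
  pooled <- unlist(lapply(ids, function(id) cohort$sessions[[id]]$samples$position),
                   use.names = FALSE)
  if (signed) pooled else abs(pooled)
}

#' Boxplot table of absolute error by age
#'
#' One [boxplot_stats()] row per age present in the cohort, computed on the
#' pooled absolute errors of all participants of that age.
#'
#' @param cohort A non-empty `cohort`.
#' @return A data frame with columns `age`, `n`, `q1`, `median`, `q3`,
#'   `iqr`, `lower_fence`, `upper_fence`, `outlier_count`, plus a
#'   `quantile_type` attribute recording the convention.
#' @export
age_boxplot_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (!nrow(cohort$manifest)) stop_empty_group("cohort is empty")
  ages <- sort(unique(cohort$manifest$age))
  rows <- lapply(ages, function(a) {
    st <- boxplot_stats(age_grouped_positions(cohort, a, signed = FALSE))
    data.frame(age = a, n = st$n, q1 = st$q1, median = st$median, q3 = st$q3,
               iqr = st$iqr, lower_fence = st$lower_fence,
               upper_fence = st$upper_fence, outlier_count = st$outlier_count)
  })
  out <- do.call(rbind, rows)
  attr(out, "quantile_type") <- 7L
  out
}
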