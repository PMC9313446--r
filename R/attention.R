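# Attention loss/recovery localisation: age-referenced outlier fences on
# signed positions, outlier masking, sustained-run detection and the
# per-participant attention profile.
#
# The operational definition: a participant starts to lose attention when
# out-of-fence positions persist for at least `min_duration` seconds
# (default 1 s, i.e. 50 consecutive samples at 50 Hz); shorter excursions
# are instantaneous slips and are discarded. Fences are the Tukey fences of
# the pooled *signed* positions of the participant's age group — signed,
# because a group's non-outlier interval need not be symmetric around the
# centerline (e.g. [-2.4, 2.6]).

#' Age-group outlier fences on signed positions
#'
#' @param cohort A `cohort`.
#' @param age Age in years.
#' @param exclude Participant ids excluded from the pool (leave-one-out).
#' @return `c(lower, upper)` fence positions in meters, with the underlying
#'   [boxplot_stats()] attached as attribute `"stats"`. If the pooled IQR is
#'   zero the fences collapse to a point and every nonzero deviation is
#'   outlying; this is flagged with a warning.
#' @export
age_group_fences <- function(cohort, age, exclude = NULL) {
  pooled <- age_grouped_positions(cohort, age, signed = TRUE, exclude = exclude)
  st <- boxplot_stats(pooled)
  if (st$iqr == 0)
    warning(sprintf("age %s group has zero IQR: fences collapse to [%g, %g] and every deviation beyond is an outlier",
                    age, st$lower_fence, st$upper_fence))
  structure(c(lower = st$lower_fence, upper = st$upper_fence), stats = st)
}

#' Outlier mask of a session against fences
#'
#' A sample is outlying when its signed position is strictly below the lower
#' fence or strictly above the upper fence; positions exactly on a fence are
#' non-outlying.
#'
#' @param session A `session_record`.
#' @param fences `c(lower, upper)` with `lower < upper`, e.g. from
#'   [age_group_fences()].
#' @return An object of class `outlier_mask`: `participant_id`, logical
#'   `mask` (one entry per sample) and `fences_used`.
#' @export
outlier_mask <- function(session, fences) {
  stopifnot(inherits(session, "session_record"))
  fences <- unname(as.numeric(fences))
  if (length(fences) != 2 || !all(is.finite(fences)) || fences[1] >= fences[2])
    stop_param("fences must be c(lower, upper) with lower < upper")
  p <- session$samples$position
  structure(list(participant_id = session$participant_id,
                 mask = p < fences[1] | p > fences[2],
                 fences_used = fences),
            class = "outlier_mask")
}

#' Sustained out-of-fence runs
#'
#' Maximal stretches of consecutive outlying samples lasting at least
#' `min_duration` seconds (at least `ceiling(min_duration * sample_rate)`
#' samples, inclusive — "a second or more" at the defaults). Shorter runs
#' are discarded as instantaneous slips.
#'
#' @param mask An `outlier_mask` or a logical vector.
#' @param min_duration Minimum run duration, seconds (> 0).
#' @param sample_rate Samples per second.
#' @return A data frame of runs: half-open 0-based sample indices
#'   `start_index`, `end_index`, plus derived `start_minutes` and
#'   `duration_seconds`.
#' @export
#' @examples
#' m <- rep(FALSE, 200); m[51:150] <- TRUE
#' sustained_runs(m, min_duration = 1, sample_rate = 50)
sustained_runs <- function(mask, min_duration = 1, sample_rate = 50) {
  if (inherits(mask, "outlier_mask")) mask <- mask$mask
  if (!is.logical(mask)) stop_param("mask must be logical")
  if (!is_scalar_number(min_duration) || min_duration <= 0)
    stop_param("min_duration must be > 0")
  min_samples <- as.integer(ceiling(min_duration * sample_rate))
  if (!length(mask) || !any(mask))
    return(empty_runs())
  r <- rle(mask)
  ends <- cumsum(r$lengths)              # 1-based inclusive
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  runs <- data.frame(start_index = starts[keep] - 1L,   # 0-based
                     end_index = ends[keep])            # half-open
  runs$start_minutes = runs$start_index / sample_rate / 60
  runs$duration_seconds = (runs$end_index - runs$start_index) / sample_rate
  runs
}

empty_runs <- function() {
  data.frame(start_index = integer(0), end_index = integer(0),
             start_minutes = numeric(0), duration_seconds = numeric(0))
}

#' Convert a sample index to minutes
#'
#' @param index 0-based sample index (observation number).
#' @param sample_rate Samples per second.
#' @return Minutes since task start; display at two decimals (observation
#'   20,617 at 50 Hz is 6.87 min).
#' @export
index_to_minutes <- function(index, sample_rate = 50) {
  if (any(index < 0)) stop_param("index must be >= 0")
  if (!is_scalar_number(sample_rate) || sample_rate <= 0)
    stop_param("sample_rate must be > 0")
  index / sample_rate / 60
}

#' Attention profile from sustained runs
#'
#' @param runs A [sustained_runs()] data frame.
#' @param session_length Session length in samples.
#' @param sample_rate Samples per second.
#' @param participant_id Participant label carried into the profile.
#' @return An object of class `attention_profile`: the `runs`,
#'   `first_loss_minutes` (`NA` when attention was never lost),
#'   `total_inattentive_seconds`, and `attentive_to_end` (`TRUE` iff no run
#'   touches the final sample).
#' @export
attention_profile <- function(runs, session_length, sample_rate = 50,
                              participant_id = NA_character_) {
  stopifnot(is.data.frame(runs))
  if (nrow(runs)) {
    runs <- runs[order(runs$start_index), , drop = FALSE]
    if (any(runs$start_index[-1] < runs$end_index[-nrow(runs)]))
      stop_param("runs must be disjoint")
  }
  structure(list(
    participant_id = participant_id,
    runs = runs,
    first_loss_minutes = if (nrow(runs))
      index_to_minutes(runs$start_index[1], sample_rate) else NA_real_,
    total_inattentive_seconds = sum(runs$duration_seconds),
    attentive_to_end = !nrow(runs) || max(runs$end_index) < session_length,
    session_length = session_length,
    sample_rate = sample_rate),
    class = "attention_profile")
}

#' @export
print.attention_profile <- function(x, ...) {
  cat(sprintf("<attention_profile> %s: %d sustained run(s)\n",
              x$participant_id, nrow(x$runs)))
  if (nrow(x$runs)) {
    cat(sprintf("  first loss at %.2f min (observation %d)\n",
                x$first_loss_minutes, x$runs$start_index[1]))
    cat(sprintf("  total inattentive time %.2f s (%.2f min)\n",
                x$total_inattentive_seconds, x$total_inattentive_seconds / 60))
    cat(sprintf("  attentive to end of task: %s\n", x$attentive_to_end))
  } else {
    cat("  attention maintained throughout the task\n")
  }
  invisible(x)
}

#' Full attention analysis of one participant
#'
#' The pipeline composition: Tukey fences from the pooled signed positions
#' of the participant's age group (the participant included, unless
#' `leave_one_out`), then [outlier_mask()], [sustained_runs()] and
#' [attention_profile()].
#'
#' @param cohort A `cohort`.
#' @param participant_id The participant to analyze.
#' @param min_duration_s Minimum sustained-error duration, seconds.
#' @param leave_one_out Exclude the analyzed participant from the fence
#'   pool (sensitivity analysis; the default keeps them in, matching a
#'   reference interval computed from "all children of that age").
#' @return An `attention_profile` with the fences used attached as
#'   attribute `"fences"`.
#' @export
compute_attention <- function(cohort, participant_id, min_duration_s = 1,
                              leave_one_out = FALSE) {
  session <- cohort_session(cohort, participant_id)
  fences <- age_group_fences(cohort, session$age,
                             exclude = if (leave_one_out) participant_id)
  m <- outlier_mask(session, fences)
  runs <- sustained_runs(m, min_duration = min_duration_s,
                         sample_rate = session$sample_rate)
  out <- attention_profile(runs, nrow(session$samples), session$sample_rate,
                           participant_id = participant_id)
  attr(out, "fences") <- fences
  out
}

#' Export an attention profile as JSON
#'
#' @param profile An `attention_profile` (typically from
#'   [compute_attention()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attention_json <- function(profile, path) {
  stopifnot(inherits(profile, "attention_profile"))
  fences <- attr(profile, "fences")
  obj <- list(participant_id = profile$participant_id,
              fences = if (!is.null(fences)) as.list(fences),
              runs = profile$runs,
              first_loss_minutes = if (is.na(profile$first_loss_minutes)) NULL
                                   else profile$first_loss_minutes,
              total_inattentive_seconds = profile$total_inattentive_seconds,
              attentive_to_end = profile$attentive_to_end,
              session_length = profile$session_length,
              sample_rate = profile$sample_rate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
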