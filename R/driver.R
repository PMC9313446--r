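# Closed-loop driver models with attention-lapse schedules.
#
# Real sessions come from children steering the car; here a small feedback
# controller stands in for them. An attentive driver observes the lateral
# position with a reaction delay, presses the key toward the centerline
# whenever the delayed observation is outside a deadband, and occasionally
# mispresses (motor noise). During a scheduled lapse the driver presses
# nothing, so on curves the car drifts to the road edge — reproducing the
# large sustained deviations that the attention analysis detects.

ARCHETYPES <- c("uniform_good", "uniform_poor", "onset_loss", "alternating")

#' Driver profile
#'
#' Parameters of the stand-in driver: a delayed deadband controller with
#' motor noise and a schedule of attention lapses.
#'
#' @param reaction_delay Lag, in seconds, between the car position and the
#'   observation the driver reacts to.
#' @param deadband No correction is made while the (delayed) absolute
#'   position is at or below this many meters.
#' @param miskey_prob Per-tick probability, while attentive, that the chosen
#'   key is replaced by a uniformly random element of
#'   \{left, right, none\} (motor noise).
#' @param lapse_schedule A [lapse_schedule()] of inattentive intervals.
#' @return An object of class `driver_profile`.
#' @export
driver_profile <- function(reaction_delay = 0.1, deadband = 0.3,
                           miskey_prob = 0.01,
                           lapse_schedule = NULL) {
  if (is.null(lapse_schedule)) lapse_schedule <- drivelapse::lapse_schedule()
  if (!is_scalar_number(reaction_delay) || reaction_delay < 0)
    stop_param("reaction_delay must be >= 0")
  if (!is_scalar_number(deadband) || deadband < 0)
    stop_param("deadband must be >= 0")
  if (!is_scalar_number(miskey_prob) || miskey_prob < 0 || miskey_prob > 1)
    stop_param("miskey_prob must be in [0, 1]")
  stopifnot(inherits(lapse_schedule, "lapse_schedule"))
  structure(list(reaction_delay = reaction_delay, deadband = deadband,
                 miskey_prob = miskey_prob, lapse_schedule = lapse_schedule),
            class = "driver_profile")
}

#' Lapse schedule
#'
#' A set of disjoint, sorted half-open intervals `[start, end)` in seconds
#' during which the driver is inattentive.
#'
#' @param intervals A list of length-2 numeric vectors `c(start, end)`, or a
#'   two-column matrix. Empty means always attentive.
#' @return An object of class `lapse_schedule` (a two-column matrix with
#'   columns `start`, `end`).
#' @export
lapse_schedule <- function(intervals = list()) {
  if (is.matrix(intervals)) {
    m <- intervals
  } else if (length(intervals) == 0) {
    m <- matrix(numeric(0), ncol = 2)
  } else {
    bad <- !vapply(intervals, function(x) is.numeric(x) && length(x) == 2, TRUE)
    if (any(bad)) stop_param("each lapse interval must be c(start, end)")
    m <- do.call(rbind, intervals)
  }
  colnames(m) <- c("start", "end")
  if (nrow(m)) {
    if (any(m[, 1] < 0) || any(m[, 2] <= m[, 1]))
      stop_param("lapse intervals need 0 <= start < end")
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2]))
      stop_param("lapse intervals must be pairwise disjoint")
  }
  structure(m, class = c("lapse_schedule", class(m)))
}

#' Build a lapse schedule for a behavioral archetype
#'
#' Four qualitative performance patterns parameterise the synthetic cohort:
#' \describe{
#'   \item{`uniform_good`}{no lapses — steady low error.}
#'   \item{`uniform_poor`}{one lapse covering the whole session — high error
#'     throughout.}
#'   \item{`onset_loss`}{attentive up to an onset time, inattentive to the
#'     end (the "starts well, then persistently bad" pattern).}
#'   \item{`alternating`}{alternating attentive / inattentive stretches with
#'     exponentially distributed durations.}
#' }
#'
#' @param archetype One of `"uniform_good"`, `"uniform_poor"`,
#'   `"onset_loss"`, `"alternating"`.
#' @param session_duration Session length, seconds.
#' @param params A list of archetype parameters. `onset_loss`: `t_onset`
#'   (fixed onset, seconds) or `onset_range = c(min, max)` to draw it
#'   uniformly (default: 17\% to 70\% of the session); `alternating`:
#'   `mean_attentive` and `mean_inattentive` (exponential means, seconds).
#' @param seed Integer seed for any random draws.
#' @return A [lapse_schedule()].
#' @export
#' @examples
#' make_lapse_schedule("onset_loss", 690, list(t_onset = 210), seed = 1)
make_lapse_schedule <- function(archetype, session_duration,
                                params = list(), seed = 0L) {
  if (!is_scalar_number(session_duration) || session_duration <= 0)
    stop_param("session_duration must be > 0")
  if (!archetype %in% ARCHETYPES)
    stop_param("unknown archetype '%s' (expected one of %s)",
               archetype, paste(ARCHETYPES, collapse = ", "))
  switch(archetype,
    uniform_good = lapse_schedule(),
    uniform_poor = lapse_schedule(list(c(0, session_duration))),
    onset_loss = {
      t_onset <- if (!is.null(params$t_onset)) params$t_onset else {
        rng <- params$onset_range %||% (session_duration * c(0.17, 0.70))
        with_seed(seed, stats::runif(1, rng[1], rng[2]))
      }
      if (t_onset >= session_duration)
        stop_param("onset time %g is past the session end %g",
                   t_onset, session_duration)
      lapse_schedule(list(c(t_onset, session_duration)))
    },
    alternating = {
      mean_on <- params$mean_attentive %||% 120
      mean_off <- params$mean_inattentive %||% 60
      with_seed(seed, {
        iv <- list(); t <- 0
        while (t < session_duration) {
          t <- t + stats::rexp(1, 1 / mean_on)
          e <- min(t + stats::rexp(1, 1 / mean_off), session_duration)
          if (t < session_duration) iv <- c(iv, list(c(t, e)))
          t <- e
        }
        lapse_schedule(iv)
      })
    })
}

# Logical vector: is the driver lapsed at each time in `t`?
lapse_mask_at <- function(schedule, t) {
  out <- rep(FALSE, length(t))
  if (nrow(schedule))
    for (i in seq_len(nrow(schedule)))
      out[t >= schedule[i, 1] & t < schedule[i, 2]] <- TRUE
  out
}

#' Attentive driver policy for one tick
#'
#' The deterministic part: if the absolute delayed position is at or below
#' the deadband, press nothing; otherwise press the key toward the
#' centerline. The stochastic part: with probability `miskey_prob` the
#' output is replaced by a uniformly random key.
#'
#' `u` and `replacement` expose the tick's random draws so the policy can be
#' replayed against a pre-drawn randomness stream (as [simulate_session()]
#' does); when `NULL`, they are drawn from the current RNG in the order
#' `runif(1)` then `sample(c("left","none","right"), 1)`.
#'
#' @param position_delayed The lateral position observed `reaction_delay`
#'   seconds ago, meters.
#' @param profile A [driver_profile()].
#' @param u Uniform variate deciding whether a miskey occurs.
#' @param replacement The key used when it does.
#' @return `"left"`, `"right"` or `"none"`.
#' @export
attentive_policy <- function(position_delayed, profile, u = NULL,
                             replacement = NULL) {
  if (is.null(u)) u <- stats::runif(1)
  if (is.null(replacement)) replacement <- sample(KEYS, 1)
  key <- if (abs(position_delayed) <= profile$deadband) "none"
         else if (position_delayed > 0) "left" else "right"
  if (u < profile$miskey_prob) key <- replacement
  key
}

#' Lapsed driver policy
#'
#' While inattentive the driver presses nothing, so the car is carried by
#' the curve drift alone.
#'
#' @return `"none"`.
#' @export
lapsed_policy <- function() "none"
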