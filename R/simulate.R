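# Closed-loop session simulation and synthetic cohort generation.

#' Simulate one driving session
#'
#' Runs the closed loop policy -> key -> dynamics -> record for exactly
#' `cfg$samples_per_session` ticks at `dt = 1 / sample_rate`. Sample 0 is the
#' initial state (centerline, no key); sample `i` records the state after
#' the i-th step together with the key that produced it and the road
#' direction at the sample's time. The result is a pure function of
#' `(track, profile, cfg, seed)`.
#'
#' Randomness is pre-drawn in a documented order so seeded replays are
#' portable: under `set.seed(seed)`, first `runif(n)` miskey variates, then
#' `sample(c("left","none","right"), n, replace = TRUE)` replacement keys,
#' one pair per tick (consumed for lapsed ticks too). Tick `i` then applies
#' [attentive_policy()] (or none while lapsed) to the position observed
#' `reaction_delay` seconds earlier.
#'
#' @param track A [build_track()] circuit at least as long as the session.
#' @param profile A [driver_profile()].
#' @param cfg A [dynamics_config()].
#' @param seed Integer seed of the session's randomness stream.
#' @param participant_id,age Metadata carried into the record.
#' @return An object of class `session_record`: `participant_id`, `age`,
#'   `sample_rate`, a `samples` data frame (`index`, `t`, `position`,
#'   `road_direction` in \{S, L, R\}, `key`, `collision`) and a
#'   `config_echo` provenance list.
#' @export
#' @examples
#' trk <- build_track(4, 4, 5)
#' cfg <- dynamics_config(samples_per_session = 2000)
#' s <- simulate_session(trk, driver_profile(), cfg, seed = 1)
#' nrow(s$samples)
simulate_session <- function(track, profile, cfg = dynamics_config(),
                             seed = 0L, participant_id = "sim",
                             age = NA_integer_) {
  stopifnot(inherits(track, "track"), inherits(profile, "driver_profile"),
            inherits(cfg, "dynamics_config"))
  n <- cfg$samples_per_session
  dt <- 1 / cfg$sample_rate
  if (track$total_duration * cfg$sample_rate < n - 1e-6)
    stop_param("track (%.2f s) is shorter than the session (%d samples at %g Hz)",
               track$total_duration, n, cfg$sample_rate)
  t <- (seq_len(n) - 1) * dt
  kinds <- segment_kinds_at(track, t)
  drift <- drift_velocity(kinds, cfg)
  lapsed <- lapse_mask_at(profile$lapse_schedule, t)
  draws <- with_seed(seed, list(u = stats::runif(n),
                                repl = sample(KEYS, n, replace = TRUE)))
  repl_code <- c(left = -1L, none = 0L, right = 1L)[draws$repl]
  lag <- as.integer(round(profile$reaction_delay * cfg$sample_rate))
  dband <- profile$deadband
  mkp <- profile$miskey_prob
  vk <- cfg$lateral_speed
  hw <- cfg$half_width
  u <- draws$u

  pos <- numeric(n)
  key <- integer(n)
  coll <- logical(n)
  for (i in seq_len(n)[-1]) {
    k <- 0L
    if (!lapsed[i]) {
      pd <- pos[max(1L, i - 1L - lag)]
      if (abs(pd) > dband) k <- if (pd > 0) -1L else 1L
      if (u[i] < mkp) k <- repl_code[i]
    }
    raw <- pos[i - 1L] + dt * (vk * k + drift[i - 1L])
    p <- if (raw > hw) hw else if (raw < -hw) -hw else raw
    pos[i] <- p
    key[i] <- k
    coll[i] <- p != raw
  }

  samples <- data.frame(
    index = 0:(n - 1L),
    t = t,
    position = pos,
    road_direction = c(straight = "S", left_curve = "L", right_curve = "R")[kinds],
    key = c("left", "none", "right")[key + 2L],
    collision = coll,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(participant_id = participant_id,
                 age = as.integer(age),
                 sample_rate = cfg$sample_rate,
                 samples = samples,
                 config_echo = list(
                   config = unclass(cfg),
                   seed = as.integer(seed),
                   reaction_delay = profile$reaction_delay,
                   deadband = profile$deadband,
                   miskey_prob = profile$miskey_prob)),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s (age %s): %d samples at %g Hz, mean |error| %.3f m\n",
              x$participant_id, x$age, nrow(x$samples), x$sample_rate,
              mean(abs(x$samples$position))))
  invisible(x)
}

#' Default driver skill by age
#'
#' The synthetic cohort emulates an age gradient in lane-keeping skill:
#' older children react faster, tolerate a smaller deviation before
#' correcting, and mispress less. All three parameters shrink linearly with
#' age from their value at the reference age of 7:
#' reaction delay `0.22 - slope$delay * (age - 7)` s (default slope 0.02),
#' deadband `0.35 - slope$deadband * (age - 7)` m (default 0.015),
#' miskey probability `0.02 - slope$miskey * (age - 7)` (default 0.0015),
#' each clamped below at a small positive floor.
#'
#' @param age Age in years.
#' @param slope Named list of the three per-year decrements.
#' @param lapse_schedule Optional [lapse_schedule()] attached to the profile.
#' @return A [driver_profile()].
#' @export
default_profile_for_age <- function(age,
                                    slope = list(delay = 0.02,
                                                 deadband = 0.015,
                                                 miskey = 0.0015),
                                    lapse_schedule = drivelapse::lapse_schedule()) {
  driver_profile(
    reaction_delay = max(0.22 - slope$delay * (age - 7), 0.02),
    deadband = max(0.35 - slope$deadband * (age - 7), 0.05),
    miskey_prob = max(0.02 - slope$miskey * (age - 7), 0.001),
    lapse_schedule = lapse_schedule)
}

#' Cohort specification
#'
#' Describes a synthetic cohort: its size, age range, the mix of behavioral
#' archetypes, the age-skill slope and a master seed. Defaults mirror the
#' shape of the study cohort (63 children aged 7-17) with most participants
#' performing uniformly well and a minority showing uniformly poor,
#' onset-loss or alternating attention patterns.
#'
#' @param n_participants Cohort size.
#' @param age_range Integer `c(min, max)` years; ages are drawn uniformly
#'   over the integers in this range.
#' @param archetype_mix Named proportions over
#'   `uniform_good`, `uniform_poor`, `onset_loss`, `alternating`; must sum
#'   to 1.
#' @param skill_age_slope Passed to [default_profile_for_age()].
#' @param archetype_params Per-archetype parameter lists passed to
#'   [make_lapse_schedule()].
#' @param seed Master seed; everything downstream derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 63L,
                        age_range = c(7L, 17L),
                        archetype_mix = c(uniform_good = 0.75,
                                          uniform_poor = 0.08,
                                          onset_loss = 0.09,
                                          alternating = 0.08),
                        skill_age_slope = list(delay = 0.02,
                                               deadband = 0.015,
                                               miskey = 0.0015),
                        archetype_params = list(),
                        seed = 0L) {
  if (!is_scalar_count(n_participants))
    stop_param("n_participants must be a non-negative count")
  if (length(age_range) != 2 || age_range[2] < age_range[1])
    stop_param("age_range must be c(min, max) with min <= max")
  if (is.null(names(archetype_mix)) || !setequal(names(archetype_mix), ARCHETYPES))
    stop_param("archetype_mix must be named over: %s",
               paste(ARCHETYPES, collapse = ", "))
  archetype_mix <- archetype_mix[ARCHETYPES]
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9)
    stop_param("archetype_mix proportions must be non-negative and sum to 1")
  structure(list(n_participants = as.integer(n_participants),
                 age_range = as.integer(age_range),
                 archetype_mix = archetype_mix,
                 skill_age_slope = skill_age_slope,
                 archetype_params = archetype_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws, under `spec$seed`, an age, an archetype and a session seed for
#' each participant; builds the age-matched [default_profile_for_age()]
#' with the archetype's lapse schedule; and simulates every session on the
#' shared `track`. Participants are labeled `"<age>-<k>"` with `k` a
#' per-age counter.
#'
#' @param spec A [cohort_spec()].
#' @param track Circuit shared by all sessions (defaults to the 58+58 test
#'   circuit built from `spec$seed`).
#' @param cfg A [dynamics_config()].
#' @return An object of class `cohort`: a named list of sessions plus a
#'   `manifest` data frame (`participant_id`, `age`, `archetype`, `seed`).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_participants = 2, seed = 1))
#' co$manifest
generate_cohort <- function(spec, track = NULL, cfg = dynamics_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(track)) track <- build_track(curve_direction_seed = spec$seed)
  n <- spec$n_participants
  age_levels <- seq(spec$age_range[1], spec$age_range[2])
  draw <- with_seed(spec$seed, list(
    # index-based draw: safe when the age range is a single year
    ages = age_levels[sample.int(length(age_levels), n, replace = TRUE)],
    archetypes = if (n) sample(ARCHETYPES, n, replace = TRUE,
                               prob = spec$archetype_mix) else character(0),
    seeds = vapply(seq_len(n), function(i) child_seed(spec$seed, i), 1L)))
  session_duration <- cfg$samples_per_session / cfg$sample_rate
  counters <- new.env(parent = emptyenv())
  sessions <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    age <- draw$ages[i]
    k <- (get0(as.character(age), envir = counters) %||% 0L) + 1L
    assign(as.character(age), k, envir = counters)
    ids[i] <- sprintf("%d-%d", age, k)
    sched <- make_lapse_schedule(draw$archetypes[i], session_duration,
                                 params = spec$archetype_params[[draw$archetypes[i]]] %||% list(),
                                 seed = draw$seeds[i])
    prof <- default_profile_for_age(age, spec$skill_age_slope, sched)
    sessions[[i]] <- simulate_session(track, prof, cfg, seed = draw$seeds[i],
                                      participant_id = ids[i], age = age)
  }
  names(sessions) <- ids
  manifest <- data.frame(participant_id = ids,
                         age = as.integer(draw$ages),
                         archetype = draw$archetypes,
                         seed = as.integer(draw$seeds),
                         stringsAsFactors = FALSE)
  new_cohort(sessions, manifest)
}

#' Assemble a cohort from session records
#'
#' @param sessions A list of `session_record`s with unique participant ids.
#' @param archetype Optional archetype labels (recycled into the manifest).
#' @param seed Optional per-session seeds for the manifest.
#' @return A `cohort`.
#' @export
cohort <- function(sessions, archetype = NA_character_, seed = NA_integer_) {
  stopifnot(all(vapply(sessions, inherits, TRUE, "session_record")))
  ids <- vapply(sessions, `[[`, "", "participant_id")
  manifest <- data.frame(
    participant_id = ids,
    age = vapply(sessions, function(s) as.integer(s$age), 1L),
    archetype = rep_len(archetype, length(sessions)),
    seed = rep_len(as.integer(seed), length(sessions)),
    stringsAsFactors = FALSE)
  names(sessions) <- ids
  new_cohort(sessions, manifest)
}

new_cohort <- function(sessions, manifest) {
  if (anyDuplicated(manifest$participant_id))
    stop_format("duplicate participant_id: %s",
                manifest$participant_id[duplicated(manifest$participant_id)][1])
  structure(list(sessions = sessions, manifest = manifest), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants", nrow(x$manifest)))
  if (nrow(x$manifest))
    cat(sprintf(", ages %d-%d", min(x$manifest$age), max(x$manifest$age)))
  cat("\n")
  invisible(x)
}

#' Look up one session in a cohort
#'
#' @param cohort A `cohort`.
#' @param participant_id Participant label, e.g. `"11-6"`.
#' @return The `session_record`.
#' @export
cohort_session <- function(cohort, participant_id) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$sessions[[participant_id]]
  if (is.null(s)) stop_lookup("no participant '%s' in cohort", participant_id)
  s
}
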