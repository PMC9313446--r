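# Track construction and 1-D lateral car dynamics.
#
# The analysis only ever needs the signed lateral offset of the car from the
# road centerline, so the "world" is one dimensional: segments of road
# (straight / left curve / right curve) laid out in time, and a lateral
# position driven by key presses and, on curves, an outward drift.

SEGMENT_KINDS <- c("straight", "left_curve", "right_curve")
KEYS <- c("left", "none", "right")

#' Dynamics configuration for the driving task
#'
#' Bundles the kinematic and sampling constants of the simulated lane-keeping
#' task. Defaults reproduce the task as administered: lateral key speed of
#' 10 m/s, an outward drift on curves equal to 0.45 of the key speed,
#' recording at 50 samples per second for exactly 34,496 samples
#' (about 11.5 min).
#'
#' @param lateral_speed Lateral speed imparted by a held arrow key, m/s.
#' @param curve_drift_ratio Outward drift speed on curves, as a fraction of
#'   `lateral_speed` (dimensionless, in `[0, 1)`).
#' @param half_width Half the road width, m. The car is clamped to
#'   `[-half_width, half_width]`; touching the clamp is recorded as a
#'   collision with the road edge.
#' @param sample_rate Sampling (and integration) frequency, Hz.
#' @param samples_per_session Number of samples recorded per session.
#' @return An object of class `dynamics_config`.
#' @export
#' @examples
#' cfg <- dynamics_config()
#' cfg$samples_per_session / cfg$sample_rate / 60  # session length, minutes
dynamics_config <- function(lateral_speed = 10,
                            curve_drift_ratio = 0.45,
                            half_width = 3.0,
                            sample_rate = 50,
                            samples_per_session = 34496L) {
  if (!is_scalar_number(lateral_speed) || lateral_speed <= 0)
    stop_param("lateral_speed must be a positive number")
  if (!is_scalar_number(curve_drift_ratio) ||
      curve_drift_ratio < 0 || curve_drift_ratio >= 1)
    stop_param("curve_drift_ratio must be in [0, 1)")
  if (!is_scalar_number(half_width) || half_width <= 0)
    stop_param("half_width must be a positive number")
  if (!is_scalar_number(sample_rate) || sample_rate <= 0)
    stop_param("sample_rate must be a positive number")
  if (!is_scalar_count(samples_per_session) || samples_per_session < 1)
    stop_param("samples_per_session must be a positive count")
  structure(list(lateral_speed = lateral_speed,
                 curve_drift_ratio = curve_drift_ratio,
                 half_width = half_width,
                 sample_rate = sample_rate,
                 samples_per_session = as.integer(samples_per_session)),
            class = "dynamics_config")
}

#' @export
print.dynamics_config <- function(x, ...) {
  cat("<dynamics_config>\n")
  cat(sprintf("  lateral_speed:       %g m/s\n", x$lateral_speed))
  cat(sprintf("  curve_drift_ratio:   %g\n", x$curve_drift_ratio))
  cat(sprintf("  half_width:          %g m\n", x$half_width))
  cat(sprintf("  sample_rate:         %g Hz\n", x$sample_rate))
  cat(sprintf("  samples_per_session: %d (%.2f min)\n", x$samples_per_session,
              x$samples_per_session / x$sample_rate / 60))
  invisible(x)
}

#' Default duration of one road segment on the test circuit
#'
#' The test circuit has 116 equal segments (58 curves and 58 straights) and
#' the session records exactly `samples_per_session` samples at
#' `sample_rate` Hz, so each segment lasts
#' `samples_per_session / sample_rate / 116` seconds (about 5.948 s at the
#' defaults). Defining the segment length this way makes the sample count,
#' which the analysis depends on, tile the circuit exactly.
#'
#' @param cfg A [dynamics_config()].
#' @param n_segments Number of segments on the circuit.
#' @return Segment duration in seconds.
#' @export
default_segment_duration <- function(cfg = dynamics_config(), n_segments = 116L) {
  cfg$samples_per_session / cfg$sample_rate / n_segments
}

#' Build a virtual circuit
#'
#' Lays out a circuit of equal-duration straight and curve segments,
#' alternating straight/curve (starting with a straight) until one kind runs
#' out, then appending the remainder. Curve handedness (left vs right) is
#' drawn 50/50 from `curve_direction_seed`, so the same seed always yields
#' the same circuit. The default arguments build the test circuit of 58
#' curves and 58 straights.
#'
#' @param n_curves,n_straights Segment counts.
#' @param segment_duration Duration of every segment, seconds.
#' @param curve_direction_seed Integer seed for the handedness draw.
#' @return An object of class `track`: a list with `segments` (data frame of
#'   `kind`, `duration`), `total_duration` and the seed used.
#' @export
#' @examples
#' trk <- build_track()
#' table(trk$segments$kind)
build_track <- function(n_curves = 58L, n_straights = 58L,
                        segment_duration = default_segment_duration(),
                        curve_direction_seed = 1L) {
  if (!is_scalar_count(n_curves) || !is_scalar_count(n_straights))
    stop_param("n_curves and n_straights must be non-negative counts")
  if (!is_scalar_number(segment_duration) || segment_duration <= 0)
    stop_param("segment_duration must be a positive number of seconds")
  n_curves <- as.integer(n_curves); n_straights <- as.integer(n_straights)
  hands <- if (n_curves > 0)
    with_seed(curve_direction_seed,
              sample(c("left_curve", "right_curve"), n_curves, replace = TRUE))
  else character(0)
  kinds <- character(0)
  i_s <- 0L; i_c <- 0L
  while (i_s < n_straights || i_c < n_curves) {
    if (i_s < n_straights) { kinds <- c(kinds, "straight"); i_s <- i_s + 1L }
    if (i_c < n_curves)    { kinds <- c(kinds, hands[i_c + 1L]); i_c <- i_c + 1L }
  }
  segments <- data.frame(kind = kinds,
                         duration = rep(segment_duration, length(kinds)),
                         stringsAsFactors = FALSE)
  structure(list(segments = segments,
                 total_duration = segment_duration * length(kinds),
                 curve_direction_seed = as.integer(curve_direction_seed)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  tab <- table(factor(x$segments$kind, levels = SEGMENT_KINDS))
  cat(sprintf("<track> %d segments (%d straight, %d left, %d right), %.2f s total\n",
              nrow(x$segments), tab[["straight"]], tab[["left_curve"]],
              tab[["right_curve"]], x$total_duration))
  invisible(x)
}

#' Segment under the car at a given time
#'
#' Segments occupy half-open time intervals `[start, start + duration)`.
#'
#' @param track A [build_track()] result.
#' @param t Time in seconds, `0 <= t < track$total_duration`.
#' @return A one-row data frame with `kind`, `duration`, `start`.
#' @export
segment_at <- function(track, t) {
  stopifnot(inherits(track, "track"))
  if (!is_scalar_number(t) || t < 0 || t >= track$total_duration)
    stop_param("t = %g outside the track interval [0, %g)", t, track$total_duration)
  starts <- cumsum(c(0, track$segments$duration))
  i <- findInterval(t, starts, rightmost.closed = FALSE)
  out <- track$segments[i, , drop = FALSE]
  out$start <- starts[i]
  out
}

# Segment kind code ("straight"/"left_curve"/"right_curve") for each time in
# `t`, vectorised; times at or beyond the end of the track keep the final
# segment (used for the last recorded sample, which falls inside the track
# at the default configuration anyway).
segment_kinds_at <- function(track, t) {
  starts <- cumsum(c(0, track$segments$duration))
  i <- pmin(pmax(findInterval(t, starts), 1L), nrow(track$segments))
  track$segments$kind[i]
}

# Signed drift velocity (m/s) by segment kind: a left curve pushes the car
# toward the outside of the curve, i.e. to the right (positive), and vice
# versa; straights have no drift.
drift_velocity <- function(kind, cfg) {
  v <- cfg$curve_drift_ratio * cfg$lateral_speed
  unname(c(straight = 0, left_curve = v, right_curve = -v)[kind])
}

key_velocity <- function(key, cfg) {
  unname(c(left = -cfg$lateral_speed, none = 0, right = cfg$lateral_speed)[key])
}

#' Initial car state
#'
#' @param cfg A [dynamics_config()].
#' @return A `car_state` list: time `t`, signed `lateral_position` (m,
#'   0 = centerline, positive = right) and `collided` flag.
#' @export
car_state <- function(cfg = dynamics_config()) {
  structure(list(t = 0, lateral_position = 0, collided = FALSE),
            class = "car_state")
}

#' Advance the car by one time step
#'
#' Explicit Euler update of the lateral position:
#' `new = old + dt * (key_velocity + drift_velocity)`, where a held key moves
#' the car at `lateral_speed` (left negative, right positive) and curves add
#' an outward drift of `curve_drift_ratio * lateral_speed`. The position is
#' clamped to `[-half_width, half_width]`; the `collided` flag of the
#' returned state is `TRUE` exactly when the clamp changed the value (the car
#' touched the road edge during this step).
#'
#' @param state A `car_state`.
#' @param segment_kind `"straight"`, `"left_curve"` or `"right_curve"` (a
#'   `segment_at()` row is also accepted).
#' @param key `"left"`, `"right"` or `"none"`.
#' @param dt Time step, seconds (> 0).
#' @param cfg A [dynamics_config()].
#' @return The new `car_state`.
#' @export
#' @examples
#' s <- step_dynamics(car_state(), "straight", "right", 0.02)
#' s$lateral_position  # 0.20 m: 10 m/s for 0.02 s
step_dynamics <- function(state, segment_kind, key, dt, cfg = dynamics_config()) {
  if (is.data.frame(segment_kind)) segment_kind <- segment_kind$kind[1]
  if (!segment_kind %in% SEGMENT_KINDS)
    stop_param("unknown segment kind '%s'", segment_kind)
  if (!key %in% KEYS) stop_param("unknown key '%s'", key)
  if (!is_scalar_number(dt) || dt <= 0) stop_param("dt must be > 0")
  raw <- state$lateral_position +
    dt * (key_velocity(key, cfg) + drift_velocity(segment_kind, cfg))
  clamped <- min(max(raw, -cfg$half_width), cfg$half_width)
  structure(list(t = state$t + dt,
                 lateral_position = clamped,
                 collided = clamped != raw),
            class = "car_state")
}

#' Serialize / read a track as JSON
#'
#' @param track A `track`.
#' @param path File path.
#' @return `read_track()` returns the `track`; `write_track()` its path,
#'   invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "track"))
  obj <- list(segments = track$segments,
              total_duration = track$total_duration,
              curve_direction_seed = track$curve_direction_seed)
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write track to '%s'", path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop_io("no such file: '%s'", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$segments) || !all(c("kind", "duration") %in% names(obj$segments)))
    stop_format("'%s' is not a track file (missing segments)", path)
  structure(list(segments = as.data.frame(obj$segments),
                 total_duration = obj$total_duration,
                 curve_direction_seed = obj$curve_direction_seed %||% NA_integer_),
            class = "track")
}
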