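# Independent brute-force oracles and small fixture builders shared by the
# suite. Oracles deliberately avoid the code paths they check.

# Quantile by explicit sort + linear interpolation of order statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    lo_v <- x[lo + 1]
    hi_v <- x[min(lo + 2, n)]
    lo_v + (h - lo) * (hi_v - lo_v)
  }, 0)
}

oracle_boxplot <- function(x) {
  q <- oracle_quantile(x, c(0.25, 0.5, 0.75))
  iqr <- q[3] - q[1]
  list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       lower_fence = q[1] - 1.5 * iqr, upper_fence = q[3] + 1.5 * iqr,
       outlier_count = sum(x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr))
}

# Sustained runs by an explicit O(n) scan; returns 0-based half-open runs.
oracle_runs <- function(mask, min_samples) {
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE; start <- 0L
  for (i in seq_along(mask)) {
    if (mask[i] && !in_run) { in_run <- TRUE; start <- i }
    if (in_run && (!mask[i] || i == length(mask))) {
      end <- if (mask[i]) i else i - 1L
      if (end - start + 1L >= min_samples) {
        starts <- c(starts, start - 1L); ends <- c(ends, end)
      }
      in_run <- FALSE
    }
  }
  cbind(start = starts, end = ends)
}

# Segment lookup by linear scan over cumulative durations.
oracle_segment_index <- function(durations, t) {
  acc <- 0
  for (i in seq_along(durations)) {
    if (t >= acc && t < acc + durations[i]) return(i)
    acc <- acc + durations[i]
  }
  NA_integer_
}

# Exhaustive k-means optimum: enumerate all assignments of n points into k
# labeled groups, keep surjective ones, minimize total within-cluster SS.
oracle_kmeans_inertia <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  idx <- rep(1L, n)
  repeat {
    if (length(unique(idx)) == k) {
      ss <- sum(vapply(seq_len(k), function(cl) {
        Y <- X[idx == cl, , drop = FALSE]
        if (!nrow(Y)) return(0)
        sum(sweep(Y, 2, colMeans(Y))^2)
      }, 0))
      if (ss < best) best <- ss
    }
    j <- n
    while (j >= 1 && idx[j] == k) { idx[j] <- 1L; j <- j - 1L }
    if (j < 1) break
    idx[j] <- idx[j] + 1L
  }
  best
}

# A short test configuration: same kinematics, 2,000-sample sessions on a
# small circuit, for tests that do not need the full-scale session.
short_cfg <- function(n = 2000L) dynamics_config(samples_per_session = n)

short_track <- function(n = 2000L, seed = 1L) {
  segs <- ceiling(n / 50 / 5) + 1
  build_track(n_curves = segs, n_straights = segs, segment_duration = 5,
              curve_direction_seed = seed)
}

# Simulated age-homogeneous group with planted archetypes; returns a cohort.
archetype_group <- function(age, archetypes, seed, t_onset = NULL,
                            cfg = dynamics_config(), track = NULL) {
  if (is.null(track)) track <- build_track(curve_direction_seed = seed)
  dur <- cfg$samples_per_session / cfg$sample_rate
  sessions <- lapply(seq_along(archetypes), function(i) {
    params <- if (archetypes[i] == "onset_loss" && !is.null(t_onset))
      list(t_onset = t_onset) else list()
    sched <- make_lapse_schedule(archetypes[i], dur, params,
                                 seed = seed * 1000L + i)
    simulate_session(track, default_profile_for_age(age, lapse_schedule = sched),
                     cfg, seed = seed * 1000L + i,
                     participant_id = sprintf("%d-%d", age, i), age = age)
  })
  cohort(sessions, archetype = archetypes)
}
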