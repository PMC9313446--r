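test_that("attentive policy corrects toward the centerline outside the deadband", {
  p <- driver_profile(reaction_delay = 0, deadband = 0.1, miskey_prob = 0)
  expect_equal(attentive_policy(0, p), "none")
  expect_equal(attentive_policy(0.1, p), "none")     # boundary: inside
  expect_equal(attentive_policy(1.0, p), "left")
  expect_equal(attentive_policy(-1.0, p), "right")
  # miskey = 1 always takes the replacement draw
  p2 <- driver_profile(deadband = 0.1, miskey_prob = 1)
  expect_equal(attentive_policy(1.0, p2, u = 0.5, replacement = "right"), "right")
  # seeded replay: the draw order is runif then sample
  set.seed(99)
  u <- runif(1); repl <- sample(c("left", "none", "right"), 1)
  set.seed(99)
  expect_equal(attentive_policy(1.0, p2),
               if (u < 1) repl else "left")
  expect_equal(lapsed_policy(), "none")
})

test_that("lapse schedules validate and archetypes produce the right shapes", {
  expect_equal(nrow(make_lapse_schedule("uniform_good", 690)), 0)
  poor <- make_lapse_schedule("uniform_poor", 690)
  expect_equal(unname(poor[1, ]), c(0, 690))
  onset <- make_lapse_schedule("onset_loss", 690, list(t_onset = 210))
  expect_equal(unname(onset[1, ]), c(210, 690))
  expect_error(make_lapse_schedule("daydream", 690),
               class = "drivelapse_param_error")
  expect_error(make_lapse_schedule("uniform_good", -1),
               class = "drivelapse_param_error")
  expect_error(lapse_schedule(list(c(5, 4))), class = "drivelapse_param_error")
  expect_error(lapse_schedule(list(c(0, 10), c(5, 15))),
               class = "drivelapse_param_error")

  # alternating schedules are structurally valid across seeds
  for (s in 1:100) {
    sch <- make_lapse_schedule("alternating", 690,
                               list(mean_attentive = 120, mean_inattentive = 90),
                               seed = s)
    if (nrow(sch)) {
      expect_true(all(sch[, "start"] >= 0 & sch[, "end"] <= 690))
      expect_true(all(sch[, "end"] > sch[, "start"]))
      if (nrow(sch) > 1) {
        expect_true(all(diff(sch[, "start"]) > 0))
        expect_true(all(sch[-1, "start"] >= sch[-nrow(sch), "end"]))
      }
    }
  }
})

test_that("simulate_session honors the recording contract and is deterministic", {
  trk <- short_track()
  cfg <- short_cfg()
  prof <- default_profile_for_age(11)
  s1 <- simulate_session(trk, prof, cfg, seed = 5, participant_id = "11-1", age = 11)
  s2 <- simulate_session(trk, prof, cfg, seed = 5, participant_id = "11-1", age = 11)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$samples), cfg$samples_per_session)
  expect_equal(s1$samples$index, 0:(cfg$samples_per_session - 1))
  expect_equal(s1$samples$t, s1$samples$index / cfg$sample_rate)
  expect_true(all(abs(s1$samples$position) <= cfg$half_width))
  expect_true(all(s1$samples$road_direction %in% c("S", "L", "R")))
  expect_true(all(s1$samples$key %in% c("left", "right", "none")))
  # a track shorter than the session is rejected
  expect_error(simulate_session(build_track(1, 1, 5), prof, cfg, 1),
               class = "drivelapse_param_error")
})

test_that("the session loop replays attentive_policy plus step_dynamics exactly", {
  # independent reimplementation of the closed loop from the exported
  # single-tick primitives, consuming the documented pre-drawn RNG stream
  trk <- short_track()
  n <- 600L
  cfg <- dynamics_config(samples_per_session = n)
  prof <- driver_profile(reaction_delay = 0.1, deadband = 0.2,
                         miskey_prob = 0.3)
  ses <- simulate_session(trk, prof, cfg, seed = 17)

  set.seed(17)
  u <- runif(n)
  repl <- sample(c("left", "none", "right"), n, replace = TRUE)
  lag <- round(prof$reaction_delay * cfg$sample_rate)
  pos <- numeric(n)
  state <- car_state(cfg)
  for (i in 2:n) {
    pd <- pos[max(1, i - 1 - lag)]
    key <- attentive_policy(pd, prof, u = u[i], replacement = repl[i])
    seg <- segment_at(trk, (i - 2) / cfg$sample_rate)
    state <- structure(list(t = (i - 2) / cfg$sample_rate,
                            lateral_position = pos[i - 1], collided = FALSE),
                       class = "car_state")
    state <- step_dynamics(state, seg$kind, key, 1 / cfg$sample_rate, cfg)
    pos[i] <- state$lateral_position
  }
  expect_equal(ses$samples$position, pos)
})

test_that("a fully lapsed driver drifts to the edge and errs more than an attentive one", {
  trk <- build_track(6, 6, 5, curve_direction_seed = 2)
  cfg <- dynamics_config(samples_per_session = 3000)  # 60 s
  dur <- cfg$samples_per_session / cfg$sample_rate
  lapse_all <- lapse_schedule(list(c(0, dur)))
  lapsed <- simulate_session(trk, driver_profile(lapse_schedule = lapse_all),
                             cfg, seed = 1)
  # within each curve the clamp engages after at most half_width / 4.5 s
  segs <- cumsum(c(0, trk$segments$duration))
  for (i in which(trk$segments$kind != "straight")) {
    lo <- segs[i]; hi <- min(segs[i + 1], dur - 1 / cfg$sample_rate)
    if (hi - lo < cfg$half_width / 4.5 + 0.1) next
    idx <- which(lapsed$samples$t >= lo & lapsed$samples$t < hi)
    expect_true(any(abs(lapsed$samples$position[idx]) == cfg$half_width))
  }
  for (s in 1:5) {
    att <- simulate_session(trk, driver_profile(0.2, 0.1, 0.01), cfg, seed = s)
    lap <- simulate_session(trk, driver_profile(lapse_schedule = lapse_all),
                            cfg, seed = s)
    expect_gt(mean(abs(lap$samples$position)), mean(abs(att$samples$position)))
  }
})

test_that("a tight attentive driver stays within the one-tick overshoot bound", {
  trk <- short_track()
  cfg <- short_cfg()
  prof <- driver_profile(reaction_delay = 0, deadband = 0.05, miskey_prob = 0)
  ses <- simulate_session(trk, prof, cfg, seed = 3)
  bound <- 0.05 + (0.45 * 10 + 10) / cfg$sample_rate
  expect_true(all(abs(ses$samples$position) <= bound + 1e-12))
})

test_that("enlarging a lapse interval never decreases mean error", {
  trk <- short_track()
  cfg <- short_cfg()
  dur <- cfg$samples_per_session / cfg$sample_rate
  for (s in 1:20) {
    base_iv <- c(10, 20)
    wide_iv <- c(10, 30)
    m <- vapply(list(base_iv, wide_iv), function(iv) {
      prof <- driver_profile(0.1, 0.3, 0.01,
                             lapse_schedule(list(iv)))
      mean(abs(simulate_session(trk, prof, cfg, seed = s)$samples$position))
    }, 0)
    expect_gte(m[2], m[1])
  }
})

test_that("generate_cohort is reproducible and encodes the age-skill gradient", {
  spec <- cohort_spec(n_participants = 8, seed = 21)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$sessions[[1]]$samples, co2$sessions[[1]]$samples)
  expect_equal(nrow(co1$manifest), 8)
  expect_false(anyDuplicated(co1$manifest$participant_id) > 0)
  # ids follow the <age>-<counter> scheme
  expect_true(all(grepl("^\\d+-\\d+$", co1$manifest$participant_id)))

  expect_equal(nrow(generate_cohort(cohort_spec(n_participants = 0))$manifest), 0)
  expect_error(cohort_spec(archetype_mix = c(uniform_good = 0.5,
                                             uniform_poor = 0.4,
                                             onset_loss = 0.2,
                                             alternating = -0.1)),
               class = "drivelapse_param_error")

  # profiles shrink with age
  p7 <- default_profile_for_age(7); p17 <- default_profile_for_age(17)
  expect_gt(p7$reaction_delay, p17$reaction_delay)
  expect_gt(p7$deadband, p17$deadband)
  expect_gt(p7$miskey_prob, p17$miskey_prob)
})

test_that("an all-poor cohort errs more than an all-good cohort, participant-wise", {
  cfg <- short_cfg()
  trk <- short_track()
  mix_of <- function(a) {
    m <- c(uniform_good = 0, uniform_poor = 0, onset_loss = 0, alternating = 0)
    m[a] <- 1
    m
  }
  for (arch in list(c("uniform_good", "uniform_poor"))) {
    good <- generate_cohort(cohort_spec(5, archetype_mix = mix_of(arch[1]), seed = 4),
                            track = trk, cfg = cfg)
    poor <- generate_cohort(cohort_spec(5, archetype_mix = mix_of(arch[2]), seed = 4),
                            track = trk, cfg = cfg)
    mg <- vapply(good$sessions, function(s) mean(abs(s$samples$position)), 0)
    mp <- vapply(poor$sessions, function(s) mean(abs(s$samples$position)), 0)
    expect_true(all(mp > mg))
  }
})
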