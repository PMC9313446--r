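session_from_positions <- function(pos, id = "11-6", age = 11L, rate = 50) {
  n <- length(pos)
  structure(list(participant_id = id, age = age, sample_rate = rate,
                 samples = data.frame(index = 0:(n - 1L), t = (0:(n - 1L)) / rate,
                                      position = pos, road_direction = "S",
                                      key = "none", collision = FALSE),
                 config_echo = list()), class = "session_record")
}

test_that("outlier classification is strict at the fence boundary", {
  s <- session_from_positions(c(-2.5, 0, 2.6))
  m <- outlier_mask(s, c(-2.4, 2.6))
  expect_equal(m$mask, c(TRUE, FALSE, FALSE))  # the fence itself is not outlying
  s2 <- session_from_positions(c(0, 1, -1))
  expect_equal(outlier_mask(s2, c(-2.4, 2.6))$mask, rep(FALSE, 3))
  expect_error(outlier_mask(s, c(2.6, -2.4)), class = "drivelapse_param_error")

  # random sessions against a brute-force per-element comparison
  set.seed(3)
  for (r in 1:20) {
    pos <- runif(300, -4, 4)
    f <- sort(runif(2, -3, 3))
    got <- outlier_mask(session_from_positions(pos), f)$mask
    want <- vapply(pos, function(p) p < f[1] || p > f[2], TRUE)
    expect_identical(got, want)
  }
})

test_that("sustained_runs keeps only runs of a second or more", {
  m49 <- rep(FALSE, 200); m49[10:58] <- TRUE          # 49 samples
  expect_equal(nrow(sustained_runs(m49, 1, 50)), 0)
  m50 <- rep(FALSE, 200); m50[10:59] <- TRUE          # exactly 50 = 1.0 s
  r <- sustained_runs(m50, 1, 50)
  expect_equal(nrow(r), 1)
  expect_equal(r$duration_seconds, 1.0)
  expect_equal(r$start_index, 9)                      # 0-based
  expect_equal(r$end_index, 59)                       # half-open

  # the documented worked-example window plus isolated single-sample noise
  mask <- rep(FALSE, 34496)
  mask[(20617 + 1):31008] <- TRUE                     # 0-based [20617, 31008)
  set.seed(4)
  noise <- sample(setdiff(1:34496, 20000:31500), 30)
  mask[noise] <- TRUE
  rr <- sustained_runs(mask, 1, 50)
  expect_equal(nrow(rr), 1)
  expect_equal(rr$start_index, 20617)
  expect_equal(rr$end_index, 31008)
})

test_that("sustained_runs agrees exactly with the brute-force scan", {
  set.seed(5)
  for (r in 1:100) {
    n <- sample(2:3000, 1)
    p_true <- runif(1, 0.2, 0.95)
    mask <- runif(n) < p_true
    min_s <- sample(c(1, 5, 25, 50), 1)
    got <- sustained_runs(mask, min_s / 50, 50)
    want <- oracle_runs(mask, min_s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_index, unname(want[, "start"]))
      expect_equal(got$end_index, unname(want[, "end"]))
    }
  }
})

test_that("index_to_minutes reproduces the observation arithmetic", {
  expect_equal(round(index_to_minutes(20617, 50), 2), 6.87)
  expect_equal(index_to_minutes(0, 50), 0)
  expect_equal(round(index_to_minutes(31008, 50), 2), 10.34)
  expect_equal(index_to_minutes(31008, 50), 31008 / 3000)
  expect_error(index_to_minutes(-1), class = "drivelapse_param_error")
})

test_that("attention_profile summarises runs correctly", {
  none <- attention_profile(sustained_runs(rep(FALSE, 100), 1, 50), 100, 50)
  expect_true(is.na(none$first_loss_minutes))
  expect_true(none$attentive_to_end)
  expect_equal(none$total_inattentive_seconds, 0)

  mask <- rep(FALSE, 34496); mask[(20617 + 1):31008] <- TRUE
  prof <- attention_profile(sustained_runs(mask, 1, 50), 34496, 50)
  expect_equal(round(prof$first_loss_minutes, 2), 6.87)
  expect_true(prof$attentive_to_end)
  expect_equal(prof$total_inattentive_seconds, (31008 - 20617) / 50)

  # totals equal oracle sums over random run sets
  set.seed(6)
  for (r in 1:20) {
    mask <- runif(2000) < 0.7
    runs <- sustained_runs(mask, 0.2, 50)
    prof <- attention_profile(runs, 2000, 50)
    expect_equal(prof$total_inattentive_seconds,
                 sum((runs$end_index - runs$start_index)) / 50)
    expect_equal(prof$attentive_to_end,
                 nrow(runs) == 0 || max(runs$end_index) < 2000)
  }
})

test_that("raising the duration threshold or widening fences is monotone", {
  set.seed(7)
  mask <- runif(5000) < 0.8
  thresholds <- c(0.2, 0.5, 1, 2)
  res <- lapply(thresholds, function(th) sustained_runs(mask, th, 50))
  nruns <- vapply(res, nrow, 1L)
  totals <- vapply(res, function(r) sum(r$duration_seconds), 0)
  expect_true(all(diff(nruns) <= 0))
  expect_true(all(diff(totals) <= 0))

  pos <- runif(5000, -4, 4)
  s <- session_from_positions(pos)
  fence_sets <- list(c(-1, 1), c(-2, 2), c(-3, 3.5))
  masks <- lapply(fence_sets, function(f) outlier_mask(s, f)$mask)
  trues <- vapply(masks, sum, 1L)
  expect_true(all(diff(trues) <= 0))
  tot <- vapply(masks, function(m) sum(sustained_runs(m, 0.2, 50)$duration_seconds), 0)
  expect_true(all(diff(tot) <= 0))
})

test_that("compute_attention runs the full age-referenced pipeline", {
  # one deviant against their age group, as the procedure is meant to be used
  arch <- c(rep("uniform_good", 6), "onset_loss")
  co <- archetype_group(11, arch, seed = 31, t_onset = 412.34)
  ids <- co$manifest$participant_id

  onset_prof <- compute_attention(co, ids[7])
  expect_gt(nrow(onset_prof$runs), 0)
  expect_lt(abs(onset_prof$first_loss_minutes * 60 - 412.34), 2)

  good_prof <- compute_attention(co, ids[1])
  expect_equal(nrow(good_prof$runs), 0)
  expect_true(good_prof$attentive_to_end)

  co_alt <- archetype_group(11, c(rep("uniform_good", 6), "alternating"),
                            seed = 31)
  alt_prof <- compute_attention(co_alt, co_alt$manifest$participant_id[7])
  expect_gte(nrow(alt_prof$runs), 2)
  # attentive gaps separate consecutive sustained runs
  expect_true(all(alt_prof$runs$start_index[-1] >
                    alt_prof$runs$end_index[-nrow(alt_prof$runs)]))

  expect_error(compute_attention(co, "99-1"), class = "drivelapse_lookup_error")

  # leave-one-out fences exclude the analyzed participant
  f_in <- attr(compute_attention(co, ids[7]), "fences")
  f_out <- attr(compute_attention(co, ids[7], leave_one_out = TRUE), "fences")
  expect_false(identical(unname(f_in), unname(f_out)))
})

test_that("a zero-IQR age group triggers the degenerate-fences warning", {
  pos <- rep(0, 200)
  s1 <- session_from_positions(pos, id = "8-1", age = 8L)
  s2 <- session_from_positions(pos, id = "8-2", age = 8L)
  co <- cohort(list(s1, s2))
  expect_warning(age_group_fences(co, 8), "zero IQR")
})

test_that("attention profiles serialize to JSON", {
  mask <- rep(FALSE, 34496); mask[(20617 + 1):31008] <- TRUE
  prof <- attention_profile(sustained_runs(mask, 1, 50), 34496, 50,
                            participant_id = "11-6")
  path <- withr::local_tempfile(fileext = ".json")
  write_attention_json(prof, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$participant_id, "11-6")
  expect_equal(back$runs$start_index, 20617)
  expect_equal(back$first_loss_minutes, 20617 / 3000)
})
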