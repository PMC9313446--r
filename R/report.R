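# Report generation: the figures a study write-up needs (age boxplots,
# error-over-time, scree, per-participant attention triptych) and a
# directory-level analysis runner. Figures are artifacts; every number a
# figure shows is also written to a CSV/JSON sidecar, which is what tests
# assert on.

#' Boxplot figure of absolute error by age
#'
#' Built from the precomputed [age_boxplot_table()] statistics (whiskers at
#' the Tukey fences), not by replotting millions of raw samples.
#'
#' @param table An [age_boxplot_table()] data frame.
#' @return A ggplot object.
#' @export
plot_age_boxplots <- function(table) {
  stopifnot(is.data.frame(table))
  ggplot2::ggplot(table, ggplot2::aes(x = factor(.data$age))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = pmax(.data$lower_fence, 0), lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$upper_fence),
      stat = "identity", fill = "grey85") +
    ggplot2::labs(x = "age (years)", y = "absolute error (m)",
                  title = "Lane-keeping error by age") +
    ggplot2::theme_minimal()
}

#' Error-over-time figure for an age group
#'
#' One line per participant: binned mean absolute error against time.
#'
#' @param cohort A `cohort`.
#' @param age Age in years.
#' @param bin_width Bin width, seconds.
#' @return A ggplot object.
#' @export
plot_error_over_time <- function(cohort, age, bin_width = 10) {
  fm <- feature_matrix(cohort, age, bin_width = bin_width)
  df <- data.frame(
    participant_id = rep(fm$participant_ids, each = ncol(fm$X)),
    minutes = rep((seq_len(ncol(fm$X)) - 0.5) * bin_width / 60,
                  times = nrow(fm$X)),
    error = as.vector(t(fm$X)))
  ggplot2::ggplot(df, ggplot2::aes(.data$minutes, .data$error,
                                   colour = .data$participant_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = sprintf("mean |error| per %gs bin (m)", bin_width),
                  title = sprintf("Error over time, age %s", age),
                  colour = "participant") +
    ggplot2::theme_minimal()
}

#' Scree plot of a cluster result
#'
#' @param result A `cluster_result` (or a `(k, inertia)` data frame).
#' @return A ggplot object.
#' @export
plot_scree <- function(result) {
  df <- if (inherits(result, "cluster_result"))
    data.frame(k = result$k_values, inertia = result$inertias)
  else as.data.frame(result)
  sel <- if (inherits(result, "cluster_result")) result$selected_k
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares",
                  title = "Scree plot") +
    ggplot2::theme_minimal()
  if (!is.null(sel))
    p <- p + ggplot2::geom_vline(xintercept = sel, linetype = "dashed")
  p
}

#' Attention triptych for one participant
#'
#' Three stacked panels: the age group's pooled signed-position boxplot
#' (the source of the fences), the participant's trajectory with outlying
#' samples marked, and the trajectory with only sustained (>= 1 s) errors
#' marked.
#'
#' @param cohort A `cohort`.
#' @param participant_id Participant to display.
#' @param min_duration_s Sustained-run threshold, seconds.
#' @return A patchwork of three ggplots, with the underlying
#'   `attention_profile` attached as attribute `"profile"`.
#' @export
plot_attention_triptych <- function(cohort, participant_id, min_duration_s = 1) {
  session <- cohort_session(cohort, participant_id)
  prof <- compute_attention(cohort, participant_id, min_duration_s)
  fences <- attr(prof, "fences")
  pooled <- age_grouped_positions(cohort, session$age, signed = TRUE)
  st <- boxplot_stats(pooled)

  box_df <- data.frame(q1 = st$q1, med = st$median, q3 = st$q3,
                       lf = st$lower_fence, uf = st$upper_fence)
  p1 <- ggplot2::ggplot(box_df) +
    ggplot2::geom_boxplot(ggplot2::aes(x = "", ymin = .data$lf, lower = .data$q1,
                                       middle = .data$med, upper = .data$q3,
                                       ymax = .data$uf),
                          stat = "identity", fill = "grey85") +
    ggplot2::labs(x = sprintf("age %s pooled positions", session$age),
                  y = "position (m)",
                  title = sprintf("Non-outlier interval [%.1f, %.1f]",
                                  fences[1], fences[2])) +
    ggplot2::theme_minimal()

  df <- session$samples
  df$minutes <- df$index / session$sample_rate / 60
  m <- outlier_mask(session, fences)
  df$outlying <- m$mask
  df$sustained <- FALSE
  if (nrow(prof$runs))
    for (i in seq_len(nrow(prof$runs)))
      df$sustained[(prof$runs$start_index[i] + 1):prof$runs$end_index[i]] <- TRUE

  traj <- function(flag, lab) {
    ggplot2::ggplot(df, ggplot2::aes(.data$minutes, .data$position)) +
      ggplot2::geom_line(colour = "grey40", linewidth = 0.2) +
      ggplot2::geom_point(data = df[df[[flag]], , drop = FALSE],
                          colour = "red", size = 0.3) +
      ggplot2::geom_hline(yintercept = fences, linetype = "dotted") +
      ggplot2::labs(x = "time (min)", y = "position (m)", title = lab) +
      ggplot2::theme_minimal()
  }
  p2 <- traj("outlying", sprintf("%s: outlying positions", participant_id))
  p3 <- traj("sustained",
             sprintf("%s: sustained (>= %g s) errors", participant_id,
                     min_duration_s))
  out <- patchwork::wrap_plots(list(p1, p2, p3), ncol = 1)
  attr(out, "profile") <- prof
  out
}

#' Run the full analysis chain over a cohort
#'
#' Writes, under `out_dir`: the age boxplot table (`age_boxplot_table.csv`)
#' and figure; per-age error-over-time figures; per-age scree tables,
#' cluster assignments and scree plots (ages with at least two
#' participants); one attention JSON per participant under `attention/`;
#' optional triptych figures; and a cohort-level `summary.json` with a
#' provenance block (seed, parameters, package version).
#'
#' @param cohort A `cohort`.
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed for the clustering restarts.
#' @param bin_width Feature bin width, seconds.
#' @param k_max Largest k scanned per age group.
#' @param min_lapse_seconds Sustained-run threshold, seconds.
#' @param figures Write PNG figures as well as the numeric sidecars.
#' @param triptych_ids Participants to render as triptychs (default: those
#'   with at least one sustained run, capped at 8).
#' @return The path of `summary.json`, invisibly.
#' @export
analyze_cohort <- function(cohort, out_dir, seed = 0L, bin_width = 10,
                           k_max = 6L, min_lapse_seconds = 1,
                           figures = TRUE, triptych_ids = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(out_dir, "attention"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io("cannot create '%s'", out_dir)
  fig_dir <- file.path(out_dir, "figures")
  if (figures) dir.create(fig_dir, showWarnings = FALSE)
  save_fig <- function(p, name, width = 7, height = 5) {
    if (!figures) return(invisible())
    grDevices::png(file.path(fig_dir, name), width = width * 100,
                   height = height * 100, res = 100)
    print(p)
    grDevices::dev.off()
  }

  tab <- age_boxplot_table(cohort)
  utils::write.csv(tab, file.path(out_dir, "age_boxplot_table.csv"),
                   row.names = FALSE)
  save_fig(plot_age_boxplots(tab), "age_boxplots.png")

  ages <- sort(unique(cohort$manifest$age))
  cluster_summary <- list()
  for (a in ages) {
    n_a <- sum(cohort$manifest$age == a)
    if (n_a < 2) next
    res <- cluster_age_group(cohort, a, k_max = k_max, seed = child_seed(seed, a),
                             bin_width = bin_width)
    utils::write.csv(data.frame(k = res$k_values, inertia = res$inertias),
                     file.path(out_dir, sprintf("scree_age%d.csv", a)),
                     row.names = FALSE)
    utils::write.csv(data.frame(participant_id = names(res$assignments),
                                cluster = unname(res$assignments)),
                     file.path(out_dir, sprintf("assignments_age%d.csv", a)),
                     row.names = FALSE)
    save_fig(plot_scree(res), sprintf("scree_age%d.png", a))
    save_fig(plot_error_over_time(cohort, a, bin_width),
             sprintf("error_over_time_age%d.png", a))
    cluster_summary[[as.character(a)]] <-
      list(selected_k = res$selected_k, singletons = res$singletons,
           no_structure = res$no_structure)
  }

  profiles <- list()
  for (id in cohort$manifest$participant_id) {
    prof <- compute_attention(cohort, id, min_duration_s = min_lapse_seconds)
    write_attention_json(prof, file.path(out_dir, "attention",
                                         paste0(id, ".json")))
    profiles[[id]] <- prof
  }
  if (is.null(triptych_ids)) {
    with_runs <- names(profiles)[vapply(profiles, function(p) nrow(p$runs) > 0, TRUE)]
    triptych_ids <- utils::head(with_runs, 8)
  }
  for (id in triptych_ids)
    save_fig(plot_attention_triptych(cohort, id, min_lapse_seconds),
             sprintf("triptych_%s.png", id), width = 7, height = 9)

  summary <- list(
    provenance = list(
      package = "drivelapse",
      version = as.character(utils::packageVersion("drivelapse")),
      seed = as.integer(seed),
      bin_width = bin_width, k_max = k_max,
      min_lapse_seconds = min_lapse_seconds),
    n_participants = nrow(cohort$manifest),
    ages = as.integer(ages),
    clusters = cluster_summary,
    attention = lapply(profiles, function(p) list(
      first_loss_minutes = if (is.na(p$first_loss_minutes)) NULL
                           else p$first_loss_minutes,
      n_runs = nrow(p$runs),
      total_inattentive_seconds = p$total_inattentive_seconds,
      attentive_to_end = p$attentive_to_end)))
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(summary_path)
}

#' Worked demonstration of the attention procedure
#'
#' Constructs a session for an 11-year-old-style participant whose outlier
#' mask, against the reference non-outlier interval `[-2.4, 2.6]`, is true
#' exactly on the half-open observation window `[20617, 31008)`; runs
#' the sustained-run pipeline; and prints when attention was lost and
#' recovered. At 50 Hz, observation 20,617 is 6.87 min into the task, and
#' the inattentive stretch lasts (31008 - 20617) / 3000 minutes.
#'
#' @param fences Reference non-outlier interval, meters.
#' @param run `c(start, end)` half-open 0-based observation window of the
#'   planted sustained error.
#' @param n_samples Session length in samples.
#' @param sample_rate Samples per second.
#' @param quiet Suppress the printed narrative.
#' @return The `attention_profile`, invisibly.
#' @export
#' @examples
#' worked_example(quiet = TRUE)$first_loss_minutes * 60  # seconds
worked_example <- function(fences = c(-2.4, 2.6), run = c(20617L, 31008L),
                           n_samples = 34496L, sample_rate = 50,
                           quiet = FALSE) {
  pos <- rep(0, n_samples)
  pos[(run[1] + 1):run[2]] <- fences[2] + 0.2  # beyond the upper fence
  session <- structure(list(
    participant_id = "11-6", age = 11L, sample_rate = sample_rate,
    samples = data.frame(index = 0:(n_samples - 1L),
                         t = (0:(n_samples - 1L)) / sample_rate,
                         position = pos,
                         road_direction = "S", key = "none",
                         collision = FALSE),
    config_echo = list()), class = "session_record")
  m <- outlier_mask(session, fences)
  runs <- sustained_runs(m, min_duration = 1, sample_rate = sample_rate)
  prof <- attention_profile(runs, n_samples, sample_rate,
                            participant_id = session$participant_id)
  if (!quiet) {
    cat(sprintf("Non-outlier position interval: [%.1f, %.1f]\n",
                fences[1], fences[2]))
    cat(sprintf("Sustained errors start from observation %d, i.e., after %.2f min.\n",
                prof$runs$start_index[1], prof$first_loss_minutes))
    cat(sprintf("Attention recovered from observation %d, i.e., after %.2f min of inattention,\n",
                prof$runs$end_index[1], prof$runs$duration_seconds[1] / 60))
    cat(sprintf("and was %smaintained until the end of the task.\n",
                if (prof$attentive_to_end) "" else "not "))
  }
  invisible(prof)
}
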