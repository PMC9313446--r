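# On-disk contract between simulation and analysis: session CSVs and a
# cohort manifest CSV. Sessions are plain CSV with `#`-prefixed metadata
# comment lines so generic tools can still read them; positions are printed
# with a fixed 6-decimal format, which round-trips exactly and keeps a full
# session around 1.5 MB.

SESSION_COLUMNS <- c("index", "t", "position", "road_direction", "key", "collision")

#' Write a session recording to CSV
#'
#' Layout: `#`-prefixed metadata lines (`participant_id`, `age`,
#' `sample_rate`, compact JSON `config`), then a header
#' `index,t,position,road_direction,key,collision` and one row per sample.
#' `t` and `position` use fixed 6-decimal formatting; `road_direction` is
#' `S`/`L`/`R`; `key` is `left`/`right`/`none`; `collision` is `0`/`1`.
#' Writing a file read back with [read_session()] reproduces it
#' byte-for-byte.
#'
#' @param record A `session_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  s <- record$samples
  header <- c(
    "# drivelapse session v1",
    sprintf("# participant_id: %s", record$participant_id),
    sprintf("# age: %s", record$age),
    sprintf("# sample_rate: %s", format(record$sample_rate, digits = 15)),
    sprintf("# config: %s",
            as.character(jsonlite::toJSON(record$config_echo, auto_unbox = TRUE,
                                          digits = NA))),
    paste(SESSION_COLUMNS, collapse = ","))
  rows <- sprintf("%d,%.6f,%.6f,%s,%s,%d",
                  s$index, s$t, s$position, s$road_direction, s$key,
                  as.integer(s$collision))
  ok <- tryCatch({
    con <- file(path, open = "wb")  # binary keeps \n endings platform-stable
    on.exit(close(con))
    writeLines(c(header, rows), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write session to '%s'", path)
  invisible(path)
}

parse_meta <- function(comments) {
  out <- list()
  for (ln in comments) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Read a session recording from CSV
#'
#' Parses the dialect written by [write_session()] and validates the
#' contract: all required columns present (a missing one is a format error
#' naming it), indices contiguous from 0 (a gap is a format error reporting
#' where), direction/key codes from their legal sets. Unknown extra columns
#' are ignored with a warning.
#'
#' @param path File path.
#' @return A `session_record`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop_io("no such file: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta(lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop_format("'%s' has no CSV body", path)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing_cols))
    stop_format("'%s' is missing required column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), SESSION_COLUMNS)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s) in '%s': %s", path,
                    paste(extra, collapse = ", ")))
    df <- df[SESSION_COLUMNS]
  }
  gap <- which(df$index != seq_len(nrow(df)) - 1L)
  if (length(gap))
    stop_format("non-contiguous sample indices in '%s': first gap after index %d",
                path, if (gap[1] > 1) df$index[gap[1] - 1] else -1L)
  if (!all(df$road_direction %in% c("S", "L", "R")))
    stop_format("invalid road_direction codes in '%s'", path)
  if (!all(df$key %in% KEYS))
    stop_format("invalid key codes in '%s'", path)
  sample_rate <- as.numeric(meta$sample_rate %||% NA)
  if (is.na(sample_rate)) {
    # fall back on the recorded time base
    sample_rate <- if (nrow(df) > 1) 1 / (df$t[2] - df$t[1]) else 50
  }
  cfg_echo <- if (!is.null(meta$config))
    tryCatch(jsonlite::fromJSON(meta$config), error = function(e) NULL)
  else NULL
  df$collision <- as.logical(df$collision)
  structure(list(participant_id = meta$participant_id %||% basename(path),
                 age = suppressWarnings(as.integer(meta$age %||% NA)),
                 sample_rate = sample_rate,
                 samples = df,
                 config_echo = cfg_echo),
            class = "session_record")
}

#' Write a cohort to a directory
#'
#' Writes one session CSV per participant (`<participant_id>.csv`) and a
#' manifest CSV (`participant_id`, `age`, `archetype`, `seed`,
#' `session_file`) with session paths relative to the manifest.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @param manifest_name File name of the manifest inside `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest_name = "manifest.csv") {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_io("cannot create directory '%s'", dir)
  man <- cohort$manifest
  man$session_file <- paste0(man$participant_id, ".csv")
  for (i in seq_len(nrow(man)))
    write_session(cohort$sessions[[man$participant_id[i]]],
                  file.path(dir, man$session_file[i]))
  manifest_path <- file.path(dir, manifest_name)
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a manifest CSV with at least
#'   `participant_id`, `age`, `session_file`; session files are resolved
#'   relative to the manifest. Duplicate ids and dangling session files are
#'   errors.
#' @return A `cohort`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_io("no such file: '%s'", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if ("participant_id" %in% names(man))
    man$participant_id <- as.character(man$participant_id)
  need <- c("participant_id", "age", "session_file")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop_format("manifest '%s' is missing column(s): %s", manifest_path,
                paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$participant_id))
    stop_format("duplicate participant_id in manifest: %s",
                man$participant_id[duplicated(man$participant_id)][1])
  base <- dirname(manifest_path)
  sessions <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- file.path(base, man$session_file[i])
    if (!file.exists(p))
      stop_io("session file '%s' listed in manifest does not exist", p)
    s <- read_session(p)
    s$participant_id <- man$participant_id[i]
    s$age <- as.integer(man$age[i])
    sessions[[i]] <- s
  }
  names(sessions) <- man$participant_id
  keep <- intersect(c("participant_id", "age", "archetype", "seed"), names(man))
  new_cohort(sessions, man[keep])
}
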