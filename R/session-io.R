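# Delimited session storage: tab-separated text tables with deterministic
# column order and fixed 6-decimal (microsecond) time formatting, so a
# write -> read -> write cycle is byte-identical.

fmt_s <- function(x) sprintf("%.6f", x)

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = FALSE)
}

read_tsv_raw <- function(path, cols) {
  if (!file.exists(path)) stop("missing session file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", colClasses = NA,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Validate a session's invariants
#'
#' Checks that all spike and event times lie in `[0, session_length]`, spike
#' times are ascending within unit, unit ids are unique, each event stream is
#' ascending, and port entries/exits strictly alternate starting with an
#' entry. Errors name the offending row.
#'
#' @param session A `lick_session`.
#' @return The session, invisibly, if valid; otherwise an error.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "lick_session"))
  T <- session$session_length
  sp <- session$spikes
  ev <- session$events
  bad <- which(sp$time_s < 0 | sp$time_s > T)
  if (length(bad)) {
    stop("spike time out of [0, session_length] at spikes row ", bad[1],
         call. = FALSE)
  }
  ns <- split(seq_len(nrow(sp)), sp$unit_id)
  for (rows in ns) {
    if (is.unsorted(sp$time_s[rows])) {
      stop("non-ascending spike times for unit ", sp$unit_id[rows[1]],
           " at spikes row ", rows[which(diff(sp$time_s[rows]) < 0)[1] + 1],
           call. = FALSE)
    }
  }
  bad <- which(ev$time_s < 0 | ev$time_s > T)
  if (length(bad)) {
    stop("event time out of [0, session_length] at events row ", bad[1],
         call. = FALSE)
  }
  for (et in unique(ev$event_type)) {
    rows <- which(ev$event_type == et)
    if (is.unsorted(ev$time_s[rows])) {
      stop("non-ascending times for event type '", et, "' at events row ",
           rows[which(diff(ev$time_s[rows]) < 0)[1] + 1], call. = FALSE)
    }
  }
  pe <- ev[ev$event_type %in% c("port_entry", "port_exit"), ]
  if (nrow(pe) > 0) {
    pe <- pe[order(pe$time_s), ]
    expected <- rep(c("port_entry", "port_exit"), length.out = nrow(pe))
    mism <- which(pe$event_type != expected)
    if (length(mism)) {
      stop("port entries/exits must strictly alternate starting with an ",
           "entry (violation at port event ", mism[1], ")", call. = FALSE)
    }
  }
  invisible(session)
}

#' Write a session to delimited text files
#'
#' Emits `units.tsv` (unit_id, n_spikes), `spikes.tsv` (unit_id, time_s),
#' `events.tsv` (event_type, time_s, spout) and `metadata.tsv` (key, value)
#' into `out_dir`; when ground truth is attached, `truth_units.tsv` and
#' `truth_bouts.tsv` as well. Times are seconds from session start formatted
#' to 6 decimal places; column order and row order are deterministic, so
#' repeated writes of the same session are byte-identical.
#'
#' @param session A valid `lick_session`.
#' @param out_dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_session <- function(session, out_dir) {
  validate_session(session)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- dplyr::arrange(session$spikes, .data$unit_id, .data$time_s)
  units <- sp |>
    dplyr::count(.data$unit_id, name = "n_spikes") |>
    dplyr::arrange(.data$unit_id)
  ev <- dplyr::arrange(session$events, .data$time_s, .data$event_type,
                       .data$spout)
  paths <- c(units = file.path(out_dir, "units.tsv"),
             spikes = file.path(out_dir, "spikes.tsv"),
             events = file.path(out_dir, "events.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"))
  write_tsv_raw(units, paths["units"])
  write_tsv_raw(dplyr::mutate(sp, time_s = fmt_s(.data$time_s)),
                paths["spikes"])
  write_tsv_raw(dplyr::mutate(ev, time_s = fmt_s(.data$time_s)),
                paths["events"])
  md <- session$metadata
  sol <- md$solutions
  bw <- md$bottle_weights
  kv <- tibble::tibble(
    key = c("session_id", "session_length", "body_weight_kg", "task",
            "laser_mode", "laser_spout",
            paste0("solution.", sol$spout),
            paste0("concentration.", sol$spout),
            paste0("basis.", sol$spout),
            paste0("bottle_pre_g.", bw$spout),
            paste0("bottle_post_g.", bw$spout)),
    value = c(session$session_id, fmt_s(session$session_length),
              fmt_s(md$body_weight_kg), md$task, md$laser_mode,
              md$laser_spout, sol$solution, fmt_s(sol$concentration),
              sol$basis, fmt_s(bw$pre_g), fmt_s(bw$post_g)))
  write_tsv_raw(kv, paths["metadata"])
  if (!is.null(session$ground_truth)) {
    tu <- session$ground_truth$units |>
      dplyr::mutate(dplyr::across(dplyr::where(is.double), fmt_s))
    tb <- session$ground_truth$bouts |>
      dplyr::mutate(dplyr::across(dplyr::where(is.double), fmt_s))
    paths <- c(paths, truth_units = file.path(out_dir, "truth_units.tsv"),
               truth_bouts = file.path(out_dir, "truth_bouts.tsv"))
    write_tsv_raw(tu, paths["truth_units"])
    write_tsv_raw(tb, paths["truth_bouts"])
  }
  invisible(paths)
}

#' Read a session from delimited text files
#'
#' Reads the tables written by [write_session()], rebuilds the
#' `lick_session`, and checks every invariant ([validate_session()]); any
#' schema violation is an error naming the offending file, column or row.
#'
#' @param dir Directory containing `units.tsv`, `spikes.tsv`, `events.tsv`,
#'   `metadata.tsv` (and optionally the truth tables).
#' @return A validated `lick_session`.
#' @export
read_session <- function(dir) {
  units <- read_tsv_raw(file.path(dir, "units.tsv"), c("unit_id", "n_spikes"))
  if (anyDuplicated(units$unit_id)) {
    stop("schema error in units.tsv: duplicated unit_id at row ",
         anyDuplicated(units$unit_id), call. = FALSE)
  }
  spikes <- read_tsv_raw(file.path(dir, "spikes.tsv"), c("unit_id", "time_s"))
  spikes$unit_id <- as.character(spikes$unit_id)
  units$unit_id <- as.character(units$unit_id)
  events <- read_tsv_raw(file.path(dir, "events.tsv"),
                         c("event_type", "time_s", "spout"))
  events$spout <- as.character(events$spout)
  md <- read_tsv_raw(file.path(dir, "metadata.tsv"), c("key", "value"))
  get_md <- function(k, required = TRUE) {
    v <- md$value[md$key == k]
    if (!length(v)) {
      if (required) stop("metadata.tsv missing key '", k, "'", call. = FALSE)
      return(NULL)
    }
    v
  }
  counts <- table(spikes$unit_id)
  declared <- stats::setNames(units$n_spikes, units$unit_id)
  for (u in names(counts)) {
    if (!u %in% names(declared)) {
      stop("schema error: unit '", u, "' in spikes.tsv absent from units.tsv",
           call. = FALSE)
    }
    if (declared[[u]] != counts[[u]]) {
      stop("schema error: unit '", u, "' declares ", declared[[u]],
           " spikes but spikes.tsv has ", counts[[u]], call. = FALSE)
    }
  }
  spouts <- sub("^solution\\.", "", grep("^solution\\.", md$key, value = TRUE))
  metadata <- list(
    session_length = as.numeric(get_md("session_length")),
    body_weight_kg = as.numeric(get_md("body_weight_kg")),
    task = get_md("task"),
    laser_mode = get_md("laser_mode"),
    laser_spout = get_md("laser_spout"),
    solutions = tibble::tibble(
      spout = spouts,
      solution = vapply(spouts, function(s) get_md(paste0("solution.", s)), ""),
      concentration = vapply(spouts, function(s)
        as.numeric(get_md(paste0("concentration.", s))), numeric(1)),
      basis = vapply(spouts, function(s) get_md(paste0("basis.", s)), "")),
    bottle_weights = tibble::tibble(
      spout = spouts,
      pre_g = vapply(spouts, function(s)
        as.numeric(get_md(paste0("bottle_pre_g.", s))), numeric(1)),
      post_g = vapply(spouts, function(s)
        as.numeric(get_md(paste0("bottle_post_g.", s))), numeric(1))))
  truth <- NULL
  if (file.exists(file.path(dir, "truth_units.tsv"))) {
    tu <- read_tsv_raw(file.path(dir, "truth_units.tsv"),
                       c("unit_id", "baseline_rate", "kappa", "mu",
                         "entry_gain"))
    tu$unit_id <- as.character(tu$unit_id)
    tb <- read_tsv_raw(file.path(dir, "truth_bouts.tsv"),
                       c("spout", "bout", "start_s", "end_s", "n_licks"))
    tb$spout <- as.character(tb$spout)
    truth <- list(units = tu, bouts = tb)
  }
  session <- new_session(
    session_id = get_md("session_id"),
    session_length = as.numeric(get_md("session_length")),
    spikes = spikes,
    events = events,
    metadata = metadata,
    ground_truth = truth)
  validate_session(session)
}
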