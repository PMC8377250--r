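# File formats: event-log record CSV with schema validation, raw-sample
# CSV, summary/matrix TSV export and YAML configuration round-trips.

LOG_ACTORS <- c("agent", "human")
LOG_KINDS <- c("gaze_shift", "dwell_onset", "dwell_offset", "blink_on",
               "blink_off", "state_change")
LOG_COLUMNS <- c("t", "actor", "kind", "target", "macro_state", "block",
                 "participant")

#' Convert interval event logs to the record stream schema
#'
#' Flattens an agent and/or human interval log into the serializable record
#' schema: one `gaze_shift` record per agent state onset (`blink_on` /
#' `blink_off` for closed-eye segments) and `dwell_onset` / `dwell_offset`
#' pairs for human dwells, time-sorted within the block.
#'
#' @param agent,human Interval logs from [simulate_block()] (either may be
#'   `NULL`).
#' @param participant,block Identifiers stamped on every record.
#' @return `data.frame` with columns `t`, `actor`, `kind`, `target`,
#'   `macro_state`, `block`, `participant`.
#' @export
as_log_records <- function(agent = NULL, human = NULL, participant = "p01",
                           block = 1L) {
  recs <- list()
  if (!is.null(agent) && nrow(agent)) {
    closed <- agent$gaze_target == "CLOSED"
    recs[[1]] <- data.frame(
      t = agent$onset,
      actor = "agent",
      kind = ifelse(closed, "blink_on",
                    ifelse(c(FALSE, closed[-length(closed)]),
                           "blink_off", "gaze_shift")),
      target = agent$gaze_target, macro_state = agent$macro_state)
  }
  if (!is.null(human) && nrow(human)) {
    recs[[2]] <- data.frame(
      t = c(human$onset, human$offset),
      actor = "human",
      kind = rep(c("dwell_onset", "dwell_offset"), each = nrow(human)),
      target = rep(human$target, 2),
      macro_state = rep(human$macro_state, 2))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(t = numeric(0), actor = character(0),
                      kind = character(0), target = character(0),
                      macro_state = character(0))
  }
  out$block <- block
  out$participant <- participant
  out <- out[order(out$t, out$actor, out$kind), LOG_COLUMNS]
  rownames(out) <- NULL
  out
}

validate_log_records <- function(records, where = "records") {
  missing_cols <- setdiff(LOG_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop_input("%s: missing column(s) %s", where,
               paste(missing_cols, collapse = ", "))
  }
  check_col <- function(col, allowed) {
    bad <- which(!records[[col]] %in% allowed)
    if (length(bad)) {
      stop_input("%s: invalid %s '%s' at line %d", where, col,
                 records[[col]][bad[1]], bad[1] + 1L) # +1 for header line
    }
  }
  check_col("actor", LOG_ACTORS)
  check_col("kind", LOG_KINDS)
  bad_t <- which(!is.finite(records$t))
  if (length(bad_t)) {
    stop_input("%s: non-numeric t at line %d", where, bad_t[1] + 1L)
  }
  key <- paste(records$participant, records$block)
  for (k in unique(key)) {
    if (is.unsorted(records$t[key == k])) {
      stop_input("%s: records not time-sorted within participant/block %s",
                 where, k)
    }
  }
  invisible(TRUE)
}

#' Write / read event-log records as CSV
#'
#' `write_gaze_log()` validates against the record schema and writes CSV;
#' `read_gaze_log()` reads and re-validates, rejecting malformed rows with
#' their line number. Unknown extra columns are preserved in both
#' directions. An optional provenance string is embedded as a leading
#' comment line.
#'
#' @param records Record `data.frame` (see [as_log_records()]).
#' @param path File path.
#' @param provenance Optional single comment line (e.g. config digest and
#'   seed) written before the header.
#' @return `read_gaze_log()` returns the validated record `data.frame`;
#'   `write_gaze_log()` returns `path` invisibly.
#' @export
write_gaze_log <- function(records, path, provenance = NULL) {
  validate_log_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_log
#' @export
read_gaze_log <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             comment.char = "#")
  validate_log_records(records, where = basename(path))
  records
}

#' Write / read raw gaze samples as CSV
#'
#' Serializes the tracker-style sample stream (`t`, `x`, `y`, `valid`).
#'
#' @param samples Sample `data.frame` from [render_samples()].
#' @param path File path.
#' @param provenance Optional comment line.
#' @return `read_samples()` returns the sample `data.frame`.
#' @export
write_samples <- function(samples, path, provenance = NULL) {
  stopifnot(all(c("t", "x", "y", "valid") %in% names(samples)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.csv(samples, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("t", "x", "y", "valid")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols)) {
    stop_input("%s: missing column(s) %s", basename(path),
               paste(missing_cols, collapse = ", "))
  }
  s$valid <- as.logical(s$valid)
  s
}

#' Export a timing summary table as TSV
#'
#' Writes the columns of the standard timing-parameter table (parameter,
#' raw moments, selected family, averaged parameters, estimated moments).
#'
#' @param summary A `timing_summary` from [fit_summary_table()].
#' @param path File path.
#' @param provenance Optional comment line.
#' @param digits Rounding applied to numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path, provenance = NULL, digits = 3) {
  out <- as.data.frame(summary)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a transition matrix as TSV
#'
#' @param tm A `transition_matrix` from [estimate_transition_matrix()] or a
#'   plain labelled matrix.
#' @param path File path.
#' @param provenance Optional comment line.
#' @param digits Rounding (default 3).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(tm, path, provenance = NULL, digits = 3) {
  P <- if (inherits(tm, "transition_matrix")) tm$P else tm
  out <- data.frame(aoi = rownames(P), round(P, digits),
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

dist_to_list <- function(d) {
  out <- list(family = d$family, mu = d$mu, rho = d$rho)
  if (!is.null(d$eta)) out$eta <- d$eta
  out
}

dist_from_list <- function(x) {
  duration_dist(x$family, x$mu, x$rho, x$eta)
}

#' Write / read an experiment configuration as YAML
#'
#' Serializes an [experiment_config()] — schedule settings, agent
#' parameters, participant profile (timing laws as
#' `{family, mu, rho, eta}`, transition matrices row-wise), AOI layout and
#' parsing thresholds — to a YAML file, and reconstructs it.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `read_config()` returns an [experiment_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  pr <- config$profile
  lst <- list(
    n_blocks = config$n_blocks,
    block_duration = config$block_duration,
    pfRJA_high = config$pfRJA_high,
    pfRJA_low = config$pfRJA_low,
    rate = config$rate, noise_sd = config$noise_sd,
    dropout = config$dropout,
    parsing = config$parsing,
    blinks = config$blinks,
    seed = config$seed,
    agent = list(
      d_straight = dist_to_list(config$agent_params$d_straight),
      d_follow = dist_to_list(config$agent_params$d_follow),
      d_object = dist_to_list(config$agent_params$d_object),
      pfRJA = config$agent_params$pfRJA,
      response_window = config$agent_params$response_window,
      object_weights = as.list(config$agent_params$object_weights),
      blink = dist_to_list(config$agent_params$blink)),
    profile = list(
      timing = lapply(pr$timing, dist_to_list),
      response_probability = pr$response_probability,
      direct_next_object_probability = pr$direct_next_object_probability,
      saccade_transit = pr$saccade_transit,
      down_dwell = dist_to_list(pr$down_dwell),
      transitions = lapply(pr$transitions, function(m) {
        list(labels = rownames(m), rows = apply(m, 1, as.list,
                                                simplify = FALSE))
      })),
    layout = list(canvas = config$layout$canvas,
                  regions = as.list(config$layout$regions),
                  anchors = config$layout$anchors))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  transitions <- lapply(lst$profile$transitions, function(tr) {
    labs <- unlist(tr$labels)
    m <- do.call(rbind, lapply(tr$rows, function(r) unlist(r)[labs]))
    dimnames(m) <- list(labs, labs)
    m / rowSums(m) # absorb serialization rounding
  })
  profile <- participant_profile(
    timing = lapply(lst$profile$timing, dist_from_list),
    transitions = transitions,
    response_probability = lst$profile$response_probability,
    direct_next_object_probability = lst$profile$direct_next_object_probability,
    saccade_transit = lst$profile$saccade_transit,
    down_dwell = dist_from_list(lst$profile$down_dwell))
  agent_params <- list(
    d_straight = dist_from_list(lst$agent$d_straight),
    d_follow = dist_from_list(lst$agent$d_follow),
    d_object = dist_from_list(lst$agent$d_object),
    pfRJA = lst$agent$pfRJA,
    response_window = lst$agent$response_window,
    object_weights = unlist(lst$agent$object_weights),
    blink = dist_from_list(lst$agent$blink))
  layout <- aoi_layout(as.data.frame(lapply(lst$layout$regions, unlist)),
                       canvas = unlist(lst$layout$canvas),
                       anchors = lapply(lst$layout$anchors, unlist))
  experiment_config(
    n_blocks = lst$n_blocks, block_duration = lst$block_duration,
    pfRJA_high = lst$pfRJA_high, pfRJA_low = lst$pfRJA_low,
    profile = profile, agent_params = agent_params, layout = layout,
    rate = lst$rate, noise_sd = lst$noise_sd, dropout = lst$dropout,
    parsing = lst$parsing, blinks = lst$blinks, seed = lst$seed)
}
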