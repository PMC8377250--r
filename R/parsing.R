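# Gaze parsing: dispersion-based fixation detection on raw sample streams,
# AOI dwell merging, and the block-level data-quality exclusion rules.

#' Detect fixations with a dispersion-based (I-DT) algorithm
#'
#' Scans maximal runs of valid samples whose spatial dispersion
#' (`max(range(x), range(y))`) stays within `dispersion` px and whose
#' duration reaches `min_duration` ms. Invalid samples break a run unless
#' the time gap they leave between valid samples is at most `gap_bridge`
#' ms.
#'
#' Fixation onsets and offsets are extended by half a sampling interval
#' beyond the first/last contributing sample (`edge_correction`): a sample
#' at time `t` indicates gaze arrived somewhere in the preceding interval,
#' so the half-interval extension is the unbiased estimate of the true
#' span and removes the systematic half-period onset lag that would
#' otherwise propagate into every latency measured downstream.
#'
#' @param samples `data.frame(t, x, y, valid)` (from [render_samples()] or
#'   [read_samples()]), time-ordered.
#' @param dispersion Maximum dispersion in px (default 40).
#' @param min_duration Minimum fixation duration in ms (default 60).
#' @param gap_bridge Maximum bridgeable invalid gap in ms (default 75).
#' @param edge_correction Extend spans by half a sampling interval
#'   (default `TRUE`).
#' @return `data.frame(onset, offset, x, y, n_samples, duration)`; empty
#'   for an empty or all-invalid stream.
#' @export
detect_fixations <- function(samples, dispersion = 40, min_duration = 60,
                             gap_bridge = 75, edge_correction = TRUE) {
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "valid") %in% names(samples)))
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      x = numeric(0), y = numeric(0),
                      n_samples = integer(0), duration = numeric(0))
  v <- which(samples$valid & !is.na(samples$x) & !is.na(samples$y))
  if (!length(v)) return(empty)
  t <- samples$t[v]
  if (is.unsorted(t)) stop_input("samples must be time-ordered")
  x <- samples$x[v]
  y <- samples$y[v]
  half <- if (edge_correction) {
    stats::median(diff(samples$t)) / 2
  } else {
    0
  }
  n <- length(t)
  # runs of valid samples separated by more than gap_bridge
  run_id <- cumsum(c(1, as.integer(diff(t) > gap_bridge)))
  out <- vector("list", 16L)
  n_out <- 0L
  for (run in split(seq_len(n), run_id)) {
    i <- 1L
    m <- length(run)
    while (i <= m) {
      j <- i
      xmin <- xmax <- x[run[i]]
      ymin <- ymax <- y[run[i]]
      while (j < m) {
        nx <- x[run[j + 1L]]
        ny <- y[run[j + 1L]]
        if (max(max(xmax, nx) - min(xmin, nx),
                max(ymax, ny) - min(ymin, ny)) > dispersion) break
        j <- j + 1L
        xmin <- min(xmin, nx); xmax <- max(xmax, nx)
        ymin <- min(ymin, ny); ymax <- max(ymax, ny)
      }
      span <- t[run[j]] - t[run[i]] + 2 * half
      if (span >= min_duration) {
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        idx <- run[i:j]
        out[[n_out]] <- data.frame(
          onset = max(t[run[i]] - half, 0), offset = t[run[j]] + half,
          x = mean(x[idx]), y = mean(y[idx]),
          n_samples = length(idx), duration = span)
        i <- j + 1L
      } else {
        # window too short: slide the start by one sample so a stray
        # (e.g. in-flight) sample cannot swallow the next fixation's head
        i <- i + 1L
      }
    }
  }
  if (!n_out) return(empty)
  res <- do.call(rbind, out[seq_len(n_out)])
  rownames(res) <- NULL
  res
}

#' Merge fixations into AOI dwell events
#'
#' Assigns each fixation to the AOI containing its centroid and merges runs
#' of consecutive same-AOI fixations into one dwell event spanning from the
#' first onset to the last offset (micro-saccades within an AOI are thereby
#' ignored). A fixation outside every AOI produces no dwell and breaks the
#' run, as does a fixation in a different AOI. Runs on the same AOI
#' separated by more than `merge_gap` ms are kept as separate dwells.
#'
#' @param fixations Output of [detect_fixations()].
#' @param layout An [aoi_layout()].
#' @param merge_gap Maximum time between consecutive same-AOI fixations that
#'   still merges them (default `Inf`).
#' @return `data.frame(aoi, onset, offset, duration, n_fixations)`; the
#'   dwell duration is `offset - onset`.
#' @export
merge_to_dwells <- function(fixations, layout, merge_gap = Inf) {
  stopifnot(inherits(layout, "aoi_layout"))
  empty <- data.frame(aoi = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      n_fixations = integer(0))
  if (!nrow(fixations)) return(empty)
  aoi <- aoi_hit(layout, fixations$x, fixations$y)
  keyed <- ifelse(is.na(aoi), "<none>", aoi)
  new_run <- c(TRUE, keyed[-1] != keyed[-length(keyed)] |
                 fixations$onset[-1] - fixations$offset[-length(keyed)] >
                   merge_gap)
  grp <- cumsum(new_run)
  keep <- !is.na(aoi)
  if (!any(keep)) return(empty)
  res <- do.call(rbind, lapply(split(which(keep), grp[keep]), function(idx) {
    data.frame(aoi = aoi[idx[1]],
               onset = fixations$onset[idx[1]],
               offset = fixations$offset[idx[length(idx)]],
               n_fixations = length(idx))
  }))
  res$duration <- res$offset - res$onset
  res <- res[order(res$onset), c("aoi", "onset", "offset", "duration",
                                 "n_fixations")]
  rownames(res) <- NULL
  res
}

#' Block data-quality check
#'
#' Computes the fraction of valid samples in a block and flags the block
#' for inclusion when at least `threshold` (default two thirds) of the
#' samples are valid; the boundary value itself is included.
#'
#' @param samples `data.frame` with a logical `valid` column.
#' @param threshold Minimum valid fraction (default `2/3`).
#' @return List with `valid_fraction` and logical `include`.
#' @export
block_quality <- function(samples, threshold = 2 / 3) {
  stopifnot(is.data.frame(samples), "valid" %in% names(samples))
  vf <- if (nrow(samples)) mean(samples$valid) else 0
  list(valid_fraction = vf, include = vf >= threshold)
}

#' Tabulate block exclusions
#'
#' Applies the exclusion flags in priority order (instruction bug, then
#' blink bug, then data quality) so each block counts under exactly one
#' reason, and reports survivors with their percentage of the total
#' (rounded to integer percent).
#'
#' @param blocks `data.frame` with logical columns `instruction_bug`,
#'   `blink_bug`, `low_quality` (one row per block).
#' @return Object of class `exclusion_ledger`: list with `total`,
#'   `excluded` (named counts), `survivors`, `survivor_percent`.
#' @export
exclusion_ledger <- function(blocks) {
  need <- c("instruction_bug", "blink_bug", "low_quality")
  stopifnot(is.data.frame(blocks), all(need %in% names(blocks)))
  instr <- blocks$instruction_bug
  blink <- !instr & blocks$blink_bug
  qual <- !instr & !blink & blocks$low_quality
  total <- nrow(blocks)
  excluded <- c(instruction_bug = sum(instr), blink_bug = sum(blink),
                low_quality = sum(qual))
  survivors <- total - sum(excluded)
  structure(list(total = total, excluded = excluded, survivors = survivors,
                 survivor_percent = round(100 * survivors / max(total, 1))),
            class = "exclusion_ledger")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("<exclusion_ledger> %d blocks: %s excluded; %d survive (%d%%)\n",
              x$total,
              paste(sprintf("%d %s", x$excluded, names(x$excluded)),
                    collapse = ", "),
              x$survivors, x$survivor_percent))
  invisible(x)
}
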