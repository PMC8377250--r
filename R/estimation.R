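# Estimation pipeline: timing-observation extraction from paired
# agent/human logs, rate estimates, cross-participant summary tables,
# empirical AOI transition matrices, attention ratios and fixation
# heatmaps.

timing_obs <- function(parameter, value) {
  data.frame(parameter = parameter, value = as.numeric(value))
}

#' Extract timing observations from one block
#'
#' Applies the event grammar of the instructed state to a paired agent
#' event log and human dwell list sharing one clock, and emits one row per
#' measured reaction time or dwell time, labelled with its timing
#' parameter:
#'
#' * instructed `RJA` (agent initiating): for each agent bid, the first
#'   human dwell onset on the cued object within `response_window` ms gives
#'   `t_follow_RJA` (onset minus bid onset) and that dwell's duration gives
#'   `t_object_RJA`; later responses count as non-responses.
#' * instructed `IJA` (agent responding): every human object dwell is a
#'   bid; the duration of an agent-AOI dwell immediately preceding it gives
#'   `t_straight_IJA`. If the agent's gaze arrives on the object within the
#'   window, the time from that arrival to the human's departure gives
#'   `t_object_IJA`; otherwise the dwell's full duration gives
#'   `t_back_IJA`.
#' * non-interactive instructions: every human dwell duration on an object
#'   or on the agent AOI gives `t_object_*` / `t_agent_*` of that state.
#'
#' @param agent_log Agent event log ([run_block()] / [simulate_block()]).
#' @param dwells Human dwell events ([merge_to_dwells()]), same clock.
#' @param instructed Instructed state of the human.
#' @param response_window Classification window in ms (default 2000).
#' @return `data.frame(parameter, value)` (ms), possibly empty.
#' @export
extract_timing <- function(agent_log, dwells, instructed,
                           response_window = 2000) {
  instructed <- match.arg(instructed, MACRO_STATES)
  stopifnot(is.data.frame(dwells))
  if (is.data.frame(agent_log) && nrow(agent_log)) {
    agent_log <- collapse_blinks(agent_log)
  }
  w <- response_window
  out <- list()
  if (instructed %in% c("PO", "OO", "INT")) {
    obj <- dwells$aoi %in% OBJECT_AOIS
    agn <- dwells$aoi == "A"
    if (any(obj)) {
      out[[1]] <- timing_obs(paste0("t_object_", instructed),
                             dwells$duration[obj])
    }
    if (any(agn)) {
      out[[2]] <- timing_obs(paste0("t_agent_", instructed),
                             dwells$duration[agn])
    }
    return(bind_obs(out))
  }
  if (instructed == "RJA") {
    bids <- agent_log[agent_log$gaze_target %in% OBJECT_AOIS, , drop = FALSE]
    for (i in seq_len(nrow(bids))) {
      tb <- bids$onset[i]
      hit <- which(dwells$aoi == bids$gaze_target[i] &
                     dwells$onset > tb & dwells$onset <= tb + w)
      if (!length(hit)) next
      first <- hit[which.min(dwells$onset[hit])]
      out[[length(out) + 1L]] <- rbind(
        timing_obs("t_follow_RJA", dwells$onset[first] - tb),
        timing_obs("t_object_RJA", dwells$duration[first]))
    }
    return(bind_obs(out))
  }
  # instructed IJA: human leads, agent follows with probability pfRJA
  follows <- agent_log[agent_log$gaze_target %in% OBJECT_AOIS, , drop = FALSE]
  for (i in seq_len(nrow(dwells))) {
    if (!dwells$aoi[i] %in% OBJECT_AOIS) next
    tb <- dwells$onset[i]
    if (i > 1L && dwells$aoi[i - 1L] == "A") {
      out[[length(out) + 1L]] <-
        timing_obs("t_straight_IJA", dwells$duration[i - 1L])
    }
    hit <- which(follows$gaze_target == dwells$aoi[i] &
                   follows$onset > tb & follows$onset <= tb + w)
    if (length(hit)) {
      ta <- min(follows$onset[hit])
      if (dwells$offset[i] > ta) {
        out[[length(out) + 1L]] <-
          timing_obs("t_object_IJA", dwells$offset[i] - ta)
      }
    } else {
      out[[length(out) + 1L]] <- timing_obs("t_back_IJA", dwells$duration[i])
    }
  }
  bind_obs(out)
}

bind_obs <- function(out) {
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(parameter = character(0), value = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interaction rates of a block (or concatenated blocks)
#'
#' Computes the agent's joint-attention bid rate, the human's initiation
#' rate and the human's response fraction from an agent event log and the
#' human dwell events sharing its clock.
#'
#' @param agent_log Agent event log; bid events are object-target spans of
#'   the initiating (`IJA`) agent, follow events those of the responding
#'   (`RJA`) agent.
#' @param dwells Optional human dwell events used for the response fraction
#'   and the initiation rate.
#' @param response_window Classification window in ms.
#' @return List with `bids_per_min`, `initiations_per_min`,
#'   `response_fraction` (`NA` where the corresponding events are absent).
#' @export
estimate_rates <- function(agent_log, dwells = NULL, response_window = 2000) {
  validate_event_log(agent_log)
  agent_log <- collapse_blinks(agent_log)
  minutes <- (max(agent_log$offset) - min(agent_log$onset)) / 60000
  if (minutes <= 0) stop_input("zero exposure time")
  is_ija <- agent_log$macro_state == "IJA"
  bids <- agent_log[is_ija & agent_log$gaze_target %in% OBJECT_AOIS, ,
                    drop = FALSE]
  bids_per_min <- if (any(is_ija)) nrow(bids) / minutes else NA_real_
  response_fraction <- NA_real_
  if (nrow(bids) && !is.null(dwells)) {
    resp <- vapply(seq_len(nrow(bids)), function(i) {
      any(dwells$aoi == bids$gaze_target[i] &
            dwells$onset > bids$onset[i] &
            dwells$onset <= bids$onset[i] + response_window)
    }, logical(1))
    response_fraction <- mean(resp)
  } else if (nrow(bids)) {
    response_fraction <- NA_real_
  } else if (any(is_ija)) {
    response_fraction <- NA_real_
  }
  initiations_per_min <- if (!is.null(dwells) &&
                               any(agent_log$macro_state == "RJA")) {
    sum(dwells$aoi %in% OBJECT_AOIS) / minutes
  } else {
    NA_real_
  }
  list(bids_per_min = bids_per_min,
       initiations_per_min = initiations_per_min,
       response_fraction = response_fraction)
}

#' Fit and summarize all timing parameters
#'
#' For each timing parameter present in `observations`, fits the candidate
#' families separately per participant, selects one family by total BIC
#' ([select_family()]) and averages the fitted parameters and closed-form
#' moments across participants ([summarize_parameter()]). Raw mean/SD are
#' pooled sample moments. Parameters where no participant reaches the
#' minimum sample size are reported with `NA` estimates and a note.
#'
#' @param observations `data.frame(parameter, participant, value)`.
#' @param candidates Families to compare (default all three).
#' @param min_n Minimum per-participant sample size (default 10).
#' @return `data.frame` of class `timing_summary` with one row per
#'   parameter: `parameter`, `n_obs`, `n_participants`, `raw_mean`,
#'   `raw_sd`, `family`, `mu`, `rho`, `eta`, `est_mean`, `est_sd`, `note`.
#' @export
fit_summary_table <- function(observations, candidates = DIST_FAMILIES,
                              min_n = 10) {
  stopifnot(is.data.frame(observations),
            all(c("parameter", "participant", "value") %in%
                  names(observations)))
  params <- intersect(TIMING_PARAMETERS, unique(observations$parameter))
  rows <- lapply(params, function(p) {
    obs <- observations[observations$parameter == p, , drop = FALSE]
    samples <- split(obs$value, obs$participant)
    base <- data.frame(parameter = p, n_obs = nrow(obs),
                       n_participants = NA_integer_,
                       raw_mean = mean(obs$value), raw_sd = stats::sd(obs$value),
                       family = NA_character_, mu = NA_real_, rho = NA_real_,
                       eta = NA_real_, est_mean = NA_real_, est_sd = NA_real_,
                       note = "")
    sel <- tryCatch(select_family(samples, candidates, min_n = min_n),
                    error = function(e) conditionMessage(e))
    if (is.character(sel)) {
      base$note <- sel
      return(base)
    }
    sm <- summarize_parameter(p, sel$fits, observations = obs$value)
    base$n_participants <- sm$n_participants
    base$family <- sm$family
    base$mu <- sm$mean_params[["mu"]]
    base$rho <- sm$mean_params[["rho"]]
    base$eta <- if (sm$family == "exgauss") sm$mean_params[["eta"]] else NA_real_
    base$est_mean <- sm$est_mean
    base$est_sd <- sm$est_sd
    if (sm$degenerate) base$note <- "degenerate fit(s)"
    base
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("timing_summary", class(res))
  res
}

#' Estimate an AOI transition matrix from dwell sequences
#'
#' For each participant, transition probabilities are the observed
#' frequencies of gaze shifts between AOIs over consecutive dwell pairs
#' within a block (`p(a -> b) = n(a -> b) / n(a -> .)`, `a != b`;
#' self-pairs are excluded since a merged dwell cannot follow itself).
#' Participant matrices are then averaged entry-wise; rows with no
#' outgoing shifts for a participant are excluded from the average, and
#' averaged rows are renormalized to sum to 1.
#'
#' @param dwells `data.frame` with columns `aoi`, `onset` and `participant`
#'   (and optionally `block`; transitions never span block boundaries).
#' @param labels AOI labels defining the matrix (default `O1..O4`, `A`);
#'   dwells on other targets are dropped.
#' @return Object of class `transition_matrix`: list with `P` (averaged
#'   row-stochastic matrix, `NA` rows where no participant contributed),
#'   `counts` (pooled shift counts) and `n_participants`.
#' @export
estimate_transition_matrix <- function(dwells,
                                       labels = c(OBJECT_AOIS, "A")) {
  stopifnot(is.data.frame(dwells), all(c("aoi", "onset") %in% names(dwells)))
  if (!"participant" %in% names(dwells)) dwells$participant <- "p1"
  if (!"block" %in% names(dwells)) dwells$block <- 1L
  dwells <- dwells[dwells$aoi %in% labels, , drop = FALSE]
  k <- length(labels)
  counts_total <- matrix(0, k, k, dimnames = list(labels, labels))
  mats <- list()
  for (pid in unique(dwells$participant)) {
    dp <- dwells[dwells$participant == pid, , drop = FALSE]
    cnt <- matrix(0, k, k, dimnames = list(labels, labels))
    for (b in unique(dp$block)) {
      db <- dp[dp$block == b, , drop = FALSE]
      db <- db[order(db$onset), , drop = FALSE]
      if (nrow(db) < 2L) next
      from <- db$aoi[-nrow(db)]
      to <- db$aoi[-1]
      ok <- from != to
      if (any(ok)) {
        tab <- table(factor(from[ok], labels), factor(to[ok], labels))
        cnt <- cnt + unclass(tab)
      }
    }
    counts_total <- counts_total + cnt
    rs <- rowSums(cnt)
    P <- cnt / ifelse(rs > 0, rs, NA_real_)
    P[rs == 0, ] <- NA_real_
    mats[[pid]] <- P
  }
  if (!length(mats) || sum(counts_total) == 0) {
    stop_input("no dwell transitions to estimate from")
  }
  arr <- simplify2array(mats)
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  rs <- rowSums(avg, na.rm = TRUE)
  ok_rows <- !apply(avg, 1, function(r) all(is.na(r)))
  avg[ok_rows, ] <- avg[ok_rows, , drop = FALSE] / rs[ok_rows]
  structure(list(P = avg, counts = counts_total,
                 n_participants = length(mats)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> averaged over %d participant(s), %d shifts\n",
              x$n_participants, sum(x$counts)))
  print(round(x$P, 3))
  invisible(x)
}

#' Attention ratios of a gaze state
#'
#' `r_aoi` is the fraction of the state's duration the participant spent
#' dwelling on any defined AOI; `r_a_o` is the share of AOI dwell time
#' spent on the agent's face relative to face plus objects. Both lie in
#' `[0, 1]`; `r_a_o` is `NA` (undefined) when there is no dwell time on
#' face or objects.
#'
#' @param dwells Human dwell events of the state.
#' @param state_duration Total duration of the state in ms (> 0).
#' @param agent_aoi Name of the agent AOI (default `"A"`).
#' @param object_aois Names of the object AOIs.
#' @return List with `r_aoi` and `r_a_o`.
#' @export
attention_ratios <- function(dwells, state_duration, agent_aoi = "A",
                             object_aois = OBJECT_AOIS) {
  check_scalar_number(state_duration, "state_duration", lower = 1e-9)
  dt_agent <- sum(dwells$duration[dwells$aoi == agent_aoi])
  dt_object <- sum(dwells$duration[dwells$aoi %in% object_aois])
  dt_all <- sum(dwells$duration)
  r_aoi <- dt_all / state_duration
  r_a_o <- if (dt_agent + dt_object > 0) {
    dt_agent / (dt_agent + dt_object)
  } else {
    NA_real_
  }
  list(r_aoi = r_aoi, r_a_o = r_a_o)
}

#' Build a duration-weighted fixation heatmap
#'
#' Each fixation deposits a quadratic kernel `k(r) = max(0, 1 - (r/R)^2)`
#' centered on its position and scaled by its duration; the kernel radius
#' `R` is the pooled standard deviation of all fixation positions about
#' their mean (`sqrt((var_x + var_y)/2)`), falling back to `min_radius`
#' when positional variance is (near) zero. The accumulated mass — before
#' transformation proportional to total fixation duration — is compressed
#' with `log1p` for display.
#'
#' @param fixations Output of [detect_fixations()] (needs `x`, `y` and
#'   `duration` or `onset`/`offset`).
#' @param canvas `c(width, height)` in px.
#' @param cell Grid cell size in px (default 4; the grid is
#'   `canvas / cell`).
#' @param radius Kernel radius override in px (default: pooled SD).
#' @param min_radius Lower bound for the radius (default 10 px).
#' @return Object of class `gaze_heatmap`: list with `grid` (rows = y),
#'   `raw` (pre-log grid), `cell`, `radius`, `transform`, `total_mass`.
#' @export
build_heatmap <- function(fixations, canvas = c(1920, 1080), cell = 4,
                          radius = NULL, min_radius = 10) {
  stopifnot(is.data.frame(fixations), nrow(fixations) >= 1L)
  dur <- if ("duration" %in% names(fixations)) {
    fixations$duration
  } else {
    fixations$offset - fixations$onset
  }
  if (is.null(radius)) {
    vx <- stats::var(fixations$x)
    vy <- stats::var(fixations$y)
    if (nrow(fixations) < 2L || !is.finite(vx)) vx <- vy <- 0
    radius <- sqrt((vx + vy) / 2)
  }
  radius <- max(radius, min_radius)
  nx <- ceiling(canvas[1] / cell)
  ny <- ceiling(canvas[2] / cell)
  cx <- (seq_len(nx) - 0.5) * cell
  cy <- (seq_len(ny) - 0.5) * cell
  grid <- matrix(0, ny, nx)
  for (i in seq_len(nrow(fixations))) {
    ix <- which(abs(cx - fixations$x[i]) <= radius)
    iy <- which(abs(cy - fixations$y[i]) <= radius)
    if (!length(ix) || !length(iy)) next
    dx2 <- (cx[ix] - fixations$x[i])^2
    dy2 <- (cy[iy] - fixations$y[i])^2
    kern <- pmax(0, 1 - outer(dy2, dx2, "+") / radius^2)
    grid[iy, ix] <- grid[iy, ix] + dur[i] * kern
  }
  structure(list(grid = log1p(grid), raw = grid, cell = cell,
                 radius = radius, transform = "log1p",
                 total_mass = sum(grid)),
            class = "gaze_heatmap")
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat(sprintf("<gaze_heatmap> %dx%d cells (%g px), radius %.1f px, %s mass %.3g\n",
              nrow(x$grid), ncol(x$grid), x$cell, x$radius, x$transform,
              x$total_mass))
  invisible(x)
}
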