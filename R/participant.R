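# Synthetic participant: human-side gaze behavior at the event level
# (coupled to the agent's controllers) and at the raw-sample level (a
# tracker-like 2D sample stream rendered from the event stream).

#' Construct a synthetic participant profile
#'
#' Collects the statistical structure of human gaze behavior used by the
#' generator: the 11 timing laws (defaults: the reference estimates), the
#' AOI transition matrices for the non-interactive states (defaults: the
#' reference `OO`/`PO` matrices, row-renormalized, and a strongly
#' self-focused off-AOI chain for `INT`), the probability of answering a
#' joint-attention bid, and the probability of initiating the next bid
#' directly from object to object without gazing back at the agent.
#'
#' @param timing Named list of [duration_dist()] objects covering the 11
#'   timing parameters (see [reference_timing()]).
#' @param transitions Named list of generator matrices for `OO`, `PO`,
#'   `INT` (row-stochastic after renormalization; labels `O1..O4`, `A`
#'   and, for `INT`, `DOWN`).
#' @param response_probability Probability the human answers an agent bid
#'   with a gaze shift to the cued object (default 0.85).
#' @param direct_next_object_probability Probability that, after a followed
#'   own bid, the human fixates the next object directly instead of gazing
#'   back at the agent first (default 0.2; unmeasured free knob).
#' @param saccade_transit Constant between-AOI saccade duration in ms,
#'   inserted between dwells and excluded from dwell durations (default 30).
#' @param down_dwell [duration_dist()] for off-AOI downward dwells in the
#'   introspective state (default: the `t_agent_INT` law).
#' @return Object of class `participant_profile`.
#' @export
participant_profile <- function(timing = reference_timing(),
                                transitions = NULL,
                                response_probability = 0.85,
                                direct_next_object_probability = 0.2,
                                saccade_transit = 30,
                                down_dwell = NULL) {
  missing_t <- setdiff(TIMING_PARAMETERS, names(timing))
  if (length(missing_t)) {
    stop_input("profile timing is missing %s", paste(missing_t, collapse = ", "))
  }
  for (nm in TIMING_PARAMETERS) stopifnot(is_duration_dist(timing[[nm]]))
  check_probability(response_probability, "response_probability")
  check_probability(direct_next_object_probability,
                    "direct_next_object_probability")
  check_scalar_number(saccade_transit, "saccade_transit", lower = 0)
  if (is.null(transitions)) {
    transitions <- list(
      OO = reference_transitions("OO", renormalize = TRUE),
      PO = reference_transitions("PO", renormalize = TRUE),
      INT = default_int_matrix())
  }
  for (nm in c("OO", "PO", "INT")) {
    m <- transitions[[nm]]
    if (is.null(m)) stop_input("profile transitions is missing '%s'", nm)
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      stop_input("'%s' transition matrix is not row-stochastic", nm)
    }
  }
  if (is.null(down_dwell)) down_dwell <- timing$t_agent_INT
  structure(list(timing = timing, transitions = transitions,
                 response_probability = response_probability,
                 direct_next_object_probability = direct_next_object_probability,
                 saccade_transit = saccade_transit,
                 down_dwell = down_dwell),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "<participant_profile> response p=%.2f, direct-next-object p=%.2f, transit %g ms\n",
    x$response_probability, x$direct_next_object_probability,
    x$saccade_transit))
  invisible(x)
}

# default human introspective-state chain: mostly dwelling on an off-AOI
# downward target, with only occasional shifts to the agent or an object
default_int_matrix <- function() {
  labs <- c(OBJECT_AOIS, "A", "DOWN")
  P <- matrix(0, 6, 6, dimnames = list(labs, labs))
  P[, "DOWN"] <- 0.80
  P[, "A"] <- 0.08
  P[, OBJECT_AOIS] <- 0.03
  diag(P)[1:5] <- 0
  P / rowSums(P)
}

new_human_log <- function(onset, offset, target, macro, cause) {
  data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
             target = target, macro_state = macro, cause = cause)
}

#' Simulate one interaction block (agent and human jointly)
#'
#' Co-simulates the agent's controllers and the synthetic participant for
#' one block under a given instructed state, producing the paired event
#' logs from which the estimation pipeline extracts timing observations.
#' The human's dwell intervals are separated by the profile's constant
#' saccade transit; the agent's log is gapless.
#'
#' @param instructed One of `"IJA"`, `"RJA"`, `"PO"`, `"OO"`, `"INT"` — the
#'   state the human is instructed to show. Instructed `RJA` couples to an
#'   initiating (`IJA`) agent; instructed `IJA` to a responding (`RJA`)
#'   agent whose follow probability is `agent_params$pfRJA`; non-interactive
#'   instructions couple to the agent's matching non-interactive state.
#' @param profile A [participant_profile()].
#' @param agent_params Agent parameters ([default_agent_params()]).
#' @param duration Block duration in ms; alternatively give `n_bids`.
#' @param seed Optional master seed (agent and human streams are derived
#'   from it independently).
#' @param n_bids Stop after this many joint-attention bid cycles instead of
#'   after a fixed duration (interactive states only).
#' @return List with `human` and `agent` event logs and, for interactive
#'   states, `bids` (one row per bid cycle).
#' @export
simulate_block <- function(instructed, profile = participant_profile(),
                           agent_params = default_agent_params(),
                           duration = 30000, seed = NULL, n_bids = NULL) {
  instructed <- match.arg(instructed, MACRO_STATES)
  stopifnot(inherits(profile, "participant_profile"))
  if (instructed == "RJA") {
    sim_block_rja_instructed(profile, agent_params, duration, seed, n_bids)
  } else if (instructed == "IJA") {
    sim_block_ija_instructed(profile, agent_params, duration, seed, n_bids)
  } else {
    sim_block_noninteractive(instructed, profile, duration, seed)
  }
}

# human instructed to respond; agent initiates bids
sim_block_rja_instructed <- function(profile, params, duration, seed, n_bids) {
  tr <- profile$saccade_transit
  w <- params$response_window
  with_seed(derive_seed(seed, 1), {
    h_on <- 0        # start of the human's current dwell on the agent AOI
    prev_ret <- 0    # start of the agent's current straight gaze
    human <- list(); agent <- list(); bids <- list()
    i <- 0L
    repeat {
      i <- i + 1L
      if (!is.null(n_bids) && i > n_bids) break
      ws <- round_ms(sample_duration(params$d_straight, 1L))
      tb <- max(prev_ret, h_on) + ws
      if (!is.null(duration) && is.null(n_bids) && tb >= duration) break
      o <- sample(names(params$object_weights), 1L,
                  prob = params$object_weights)
      responded <- stats::runif(1) < profile$response_probability
      lat <- NA_real_
      if (responded) {
        lat <- max(round_ms(sample_duration(profile$timing$t_follow_RJA, 1L)),
                   tr + 1)
      }
      success <- responded && lat <= w
      if (success) {
        arrive <- tb + lat
        dh <- round_ms(sample_duration(profile$timing$t_object_RJA, 1L))
        human[[length(human) + 1L]] <-
          new_human_log(h_on, arrive - tr, "A", "RJA", "watch_agent")
        human[[length(human) + 1L]] <-
          new_human_log(arrive, arrive + dh, o, "RJA", "respond")
        h_on <- arrive + dh + tr
        agent_ret <- arrive + round_ms(sample_duration(params$d_object, 1L))
      } else {
        agent_ret <- tb + w
      }
      agent[[length(agent) + 1L]] <- new_agent_log(
        prev_ret, tb, "straight", "STRAIGHT", "IJA",
        if (prev_ret == 0) "entry" else "return")
      agent[[length(agent) + 1L]] <- new_agent_log(
        tb, agent_ret, paste0("bid_", o), o, "IJA", "bid")
      bids[[length(bids) + 1L]] <- data.frame(
        bid_onset = tb, target = o, responded = responded,
        response_latency = if (success) lat else NA_real_, success = success)
      prev_ret <- agent_ret
    }
    end <- if (is.null(n_bids)) duration else max(prev_ret, h_on)
    if (prev_ret < end) {
      agent[[length(agent) + 1L]] <- new_agent_log(
        prev_ret, end, "straight", "STRAIGHT", "IJA", "return")
    }
    if (h_on < end) {
      human[[length(human) + 1L]] <- new_human_log(
        h_on, end, "A", "RJA", "watch_agent")
    }
    finalize_block(human, agent, bids, end)
  })
}

# human instructed to initiate; agent responds with probability pfRJA
sim_block_ija_instructed <- function(profile, params, duration, seed, n_bids) {
  tr <- profile$saccade_transit
  w <- params$response_window
  with_seed(derive_seed(seed, 1), {
    h_on <- 0
    armed_at <- 0
    prev_ret <- 0
    human <- list(); agent <- list(); bids <- list()
    pending_direct <- FALSE
    leave_prev <- 0
    prev_obj <- NULL
    i <- 0L
    repeat {
      i <- i + 1L
      if (!is.null(n_bids) && i > n_bids) break
      if (pending_direct) {
        tb <- leave_prev + tr
        choices <- setdiff(OBJECT_AOIS, prev_obj)
      } else {
        ts <- round_ms(sample_duration(profile$timing$t_straight_IJA, 1L))
        tb <- h_on + ts + tr
        if (!is.null(duration) && is.null(n_bids) && tb >= duration) break
        human[[length(human) + 1L]] <-
          new_human_log(h_on, h_on + ts, "A", "IJA", "pre_bid")
        choices <- OBJECT_AOIS
      }
      if (!is.null(duration) && is.null(n_bids) && tb >= duration) break
      o <- sample(choices, 1L)
      followed <- FALSE
      ta <- NA_real_
      if (tb >= armed_at && stats::runif(1) < params$pfRJA) {
        df_ <- round_ms(sample_duration(params$d_follow, 1L))
        if (df_ <= w) {
          followed <- TRUE
          ta <- tb + df_
          da <- round_ms(sample_duration(params$d_object, 1L))
          agent[[length(agent) + 1L]] <- new_agent_log(
            prev_ret, ta, "ready", "STRAIGHT", "RJA",
            if (prev_ret == 0) "entry" else "re_arm")
          agent[[length(agent) + 1L]] <- new_agent_log(
            ta, ta + da, paste0("follow_", o), o, "RJA", "follow")
          prev_ret <- ta + da
          armed_at <- ta + da
        }
      }
      if (followed) {
        to <- round_ms(sample_duration(profile$timing$t_object_IJA, 1L))
        leave <- ta + to
      } else {
        tbk <- round_ms(sample_duration(profile$timing$t_back_IJA, 1L))
        leave <- tb + tbk
      }
      human[[length(human) + 1L]] <-
        new_human_log(tb, leave, o, "IJA", "own_bid")
      bids[[length(bids) + 1L]] <- data.frame(
        bid_onset = tb, target = o, followed = followed, follow_onset = ta)
      pending_direct <- followed &&
        stats::runif(1) < profile$direct_next_object_probability
      leave_prev <- leave
      prev_obj <- o
      if (!pending_direct) h_on <- leave + tr
    }
    last_h <- if (length(human)) max(human[[length(human)]]$offset) else 0
    end <- if (is.null(n_bids)) duration else max(last_h, prev_ret) + 500
    if (!pending_direct && h_on < end) {
      human[[length(human) + 1L]] <-
        new_human_log(h_on, end, "A", "IJA", "pre_bid")
    }
    if (prev_ret < end) {
      agent[[length(agent) + 1L]] <- new_agent_log(
        prev_ret, end, "ready", "STRAIGHT", "RJA",
        if (prev_ret == 0) "entry" else "re_arm")
    }
    finalize_block(human, agent, bids, end)
  })
}

sim_block_noninteractive <- function(state, profile, duration, seed) {
  tr <- profile$saccade_transit
  timing <- profile$timing
  P <- profile$transitions[[state]]
  labs <- rownames(P)
  laws <- lapply(labs, function(lab) {
    if (lab %in% OBJECT_AOIS) {
      timing[[paste0("t_object_", state)]]
    } else if (lab == "A") {
      timing[[paste0("t_agent_", state)]]
    } else {
      profile$down_dwell
    }
  })
  names(laws) <- labs
  start <- if (state == "PO") "A" else if (state == "INT") "DOWN" else "O1"
  walk <- markov_controller(P, laws, duration = duration, start = start,
                            seed = derive_seed(seed, 1))
  # merge consecutive identical targets, then insert transits between dwells
  keep <- c(TRUE, walk$target[-1] != walk$target[-nrow(walk)])
  grp <- cumsum(keep)
  durs <- as.numeric(tapply(walk$duration, grp, sum))
  targets <- walk$target[keep]
  onset <- cumsum(c(0, durs[-length(durs)] + tr))
  offset <- onset + durs
  ok <- onset < duration
  onset <- onset[ok]; offset <- pmin(offset[ok], duration)
  human <- new_human_log(onset, offset, targets[ok], state, "markov")
  agent_log <- run_block(default_agent_macro(state), duration = duration,
                         seed = derive_seed(seed, 2))
  list(human = human, agent = agent_log, bids = NULL)
}

finalize_block <- function(human, agent, bids, duration) {
  hl <- do.call(rbind, human)
  hl <- hl[order(hl$onset), , drop = FALSE]
  hl <- hl[hl$onset < duration, , drop = FALSE]
  hl$offset <- pmin(hl$offset, duration)
  hl <- hl[hl$offset > hl$onset, , drop = FALSE]
  al <- do.call(rbind, agent)
  al <- al[order(al$onset), , drop = FALSE]
  al <- al[al$onset < duration & al$offset > al$onset, , drop = FALSE]
  al$offset <- pmin(al$offset, duration)
  rownames(hl) <- rownames(al) <- NULL
  bd <- if (length(bids)) do.call(rbind, bids) else NULL
  list(human = hl, agent = al, bids = bd)
}

#' Simulate a participant's gaze event stream under an instructed state
#'
#' Convenience wrapper around [simulate_block()] returning the human event
#' stream, with the agent's log and the bid table attached as attributes
#' `"agent_log"` and `"bids"`.
#'
#' @inheritParams simulate_block
#' @param agent Optional [macro_state()] for the agent side; by default the
#'   instructed state's canonical partner (initiating agent for instructed
#'   `RJA`, responding agent for instructed `IJA`, matching non-interactive
#'   state otherwise).
#' @return Human event log `data.frame(onset, offset, target, macro_state,
#'   cause)` with attributes `agent_log` and `bids`.
#' @export
simulate_participant <- function(instructed, profile = participant_profile(),
                                 agent = NULL, duration = 30000, seed = NULL,
                                 n_bids = NULL) {
  instructed <- match.arg(instructed, MACRO_STATES)
  agent_params <- if (!is.null(agent)) {
    stopifnot(inherits(agent, "macro_state"))
    agent$params
  } else {
    default_agent_params()
  }
  sim <- simulate_block(instructed, profile, agent_params, duration, seed,
                        n_bids)
  structure(sim$human, agent_log = sim$agent, bids = sim$bids)
}

#' Render raw gaze samples from an event stream
#'
#' Stands in for the eye tracker: converts a human gaze event stream into a
#' regularly sampled 2D gaze stream. Samples jitter around the active
#' target's anchor point with per-sample Gaussian noise plus a slower
#' within-AOI micro-saccadic jitter (a new offset every `jitter_interval`
#' ms), are linearly interpolated during saccade transits between dwells,
#' and are invalid (coordinates `NA`) with probability `dropout`.
#'
#' @param events Human event log (from [simulate_participant()] or
#'   [simulate_block()]).
#' @param layout An [aoi_layout()]; every event target must resolve to an
#'   anchor.
#' @param rate Sampling rate in Hz (> 0; default 60).
#' @param noise_sd Per-sample Gaussian noise SD in px (default 2).
#' @param dropout Probability a sample is invalid (default 0).
#' @param jitter_sd Micro-saccadic within-AOI jitter SD in px (default 6).
#' @param jitter_interval Interval between micro-saccadic offsets in ms.
#' @param seed Optional seed.
#' @return `data.frame(t, x, y, valid)` with `floor(rate * duration / 1000)`
#'   equally spaced samples; sampling rate kept in `attr(, "rate")`.
#' @export
render_samples <- function(events, layout = default_layout(), rate = 60,
                           noise_sd = 2, dropout = 0, jitter_sd = 6,
                           jitter_interval = 300, seed = NULL) {
  if (rate <= 0) stop_input("sampling rate must be > 0")
  check_probability(dropout, "dropout")
  stopifnot(is.data.frame(events), all(c("onset", "offset", "target")
                                       %in% names(events)))
  duration <- max(events$offset)
  n <- floor(rate * duration / 1000)
  period <- 1000 / rate
  ts <- (seq_len(n) - 1L) * period
  anchors <- lapply(unique(events$target), function(tg) aoi_anchor(layout, tg))
  names(anchors) <- unique(events$target)
  with_seed(seed, {
    x <- rep(NA_real_, n)
    y <- rep(NA_real_, n)
    for (i in seq_len(nrow(events))) {
      idx <- which(ts >= events$onset[i] & ts < events$offset[i])
      if (!length(idx)) next
      a <- anchors[[events$target[i]]]
      nseg <- max(1L, ceiling((events$offset[i] - events$onset[i]) /
                                jitter_interval))
      jx <- stats::rnorm(nseg, 0, jitter_sd)
      jy <- stats::rnorm(nseg, 0, jitter_sd)
      seg <- pmin(floor((ts[idx] - events$onset[i]) / jitter_interval) + 1L,
                  nseg)
      x[idx] <- a[1] + jx[seg]
      y[idx] <- a[2] + jy[seg]
    }
    # saccade transits and edges: interpolate between neighboring anchors
    gap <- which(is.na(x))
    if (length(gap)) {
      ev_prev <- findInterval(ts[gap], events$onset)
      for (k in seq_along(gap)) {
        i0 <- ev_prev[k]
        if (i0 == 0) {
          a <- anchors[[events$target[1]]]
          x[gap[k]] <- a[1]; y[gap[k]] <- a[2]
        } else if (i0 >= nrow(events)) {
          a <- anchors[[events$target[nrow(events)]]]
          x[gap[k]] <- a[1]; y[gap[k]] <- a[2]
        } else {
          a0 <- anchors[[events$target[i0]]]
          a1 <- anchors[[events$target[i0 + 1L]]]
          f <- (ts[gap[k]] - events$offset[i0]) /
            max(events$onset[i0 + 1L] - events$offset[i0], 1e-9)
          f <- min(max(f, 0), 1)
          x[gap[k]] <- a0[1] + f * (a1[1] - a0[1])
          y[gap[k]] <- a0[2] + f * (a1[2] - a0[2])
        }
      }
    }
    if (noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, noise_sd)
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    valid <- stats::runif(n) >= dropout
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    structure(data.frame(t = ts, x = x, y = y, valid = valid), rate = rate)
  })
}
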