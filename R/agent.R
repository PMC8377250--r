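# Event-driven agent engine: micro/macro state containers, the interactive
# joint-attention controllers, the Markov controller for non-interactive
# states, block simulation and blink superposition.

#' Construct a micro state
#'
#' The atomic behavioral unit of the agent: one gaze direction together with
#' a duration law, transition probabilities toward successor micro states,
#' and optional gaze-contingent triggers. Transition probabilities may be
#' empty when exit from the state is purely trigger-driven (interactive
#' states).
#'
#' @param id Label, unique within its macro state.
#' @param gaze_target AOI name (`O1..O4`), or one of `STRAIGHT`, `DOWN`,
#'   `CLOSED`.
#' @param duration_dist Optional [duration_dist()] for the state's dwell.
#' @param transitions Named numeric vector of successor probabilities
#'   (must sum to 1 within 1e-9), or `NULL`/empty for trigger-driven exit.
#' @param triggers List of [gaze_trigger()] objects.
#' @return Object of class `micro_state`.
#' @export
micro_state <- function(id, gaze_target, duration_dist = NULL,
                        transitions = NULL, triggers = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(gaze_target), length(gaze_target) == 1L)
  if (!is.null(duration_dist)) stopifnot(is_duration_dist(duration_dist))
  if (!is.null(transitions) && length(transitions)) {
    if (is.null(names(transitions)) || any(!nzchar(names(transitions)))) {
      stop_input("micro state '%s': transitions must be named by successor id", id)
    }
    if (any(transitions < 0) || abs(sum(transitions) - 1) > 1e-9) {
      stop_input("micro state '%s': transition probabilities must be >= 0 and sum to 1", id)
    }
  }
  stopifnot(is.list(triggers))
  structure(list(id = id, gaze_target = gaze_target,
                 duration_dist = duration_dist,
                 transitions = transitions, triggers = triggers),
            class = "micro_state")
}

#' Construct a gaze-contingent trigger
#'
#' Declares that while its micro state is active, a human dwell onset on any
#' of the `watched` targets fires with probability `fire_probability` after
#' a delay drawn from `delay_dist`, moving the agent to the `action` micro
#' state. `EYE_CONTACT` watches the agent AOI while the agent gazes
#' straight.
#'
#' @param watched Character vector of AOI names or `"EYE_CONTACT"`.
#' @param fire_probability Probability in `[0, 1]` that a bid is acted on.
#' @param delay_dist [duration_dist()] for the reaction delay.
#' @param action Successor micro-state id.
#' @param window Optional maximum wait in ms (> 0).
#' @return Object of class `gaze_trigger`.
#' @export
gaze_trigger <- function(watched, fire_probability, delay_dist, action,
                         window = NULL) {
  stopifnot(is.character(watched), length(watched) >= 1L)
  check_probability(fire_probability, "fire_probability")
  stopifnot(is_duration_dist(delay_dist), is.character(action))
  if (!is.null(window)) check_scalar_number(window, "window", lower = 1e-9)
  structure(list(watched = watched, fire_probability = fire_probability,
                 delay_dist = delay_dist, action = action, window = window),
            class = "gaze_trigger")
}

#' Construct a macro state
#'
#' A persistent higher-order behavioral state of the agent (one of `IJA`,
#' `RJA`, `PO`, `OO`, `INT`), realized as a stochastic sequence of micro
#' states. Validates that the entry state and every transition target exist.
#'
#' @param id One of `"IJA"`, `"RJA"`, `"PO"`, `"OO"`, `"INT"`.
#' @param micro_states List of [micro_state()] objects.
#' @param entry Id of the entry micro state.
#' @param params Agent-side parameter list (see [default_agent_params()]).
#' @return Object of class `macro_state`.
#' @seealso [default_agent_macro()] for ready-made canonical states.
#' @export
macro_state <- function(id, micro_states, entry, params = list()) {
  id <- match.arg(id, MACRO_STATES)
  stopifnot(is.list(micro_states), length(micro_states) >= 1L)
  ids <- vapply(micro_states, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_input("duplicate micro-state ids")
  names(micro_states) <- ids
  if (!entry %in% ids) stop_input("entry micro state '%s' not defined", entry)
  for (ms in micro_states) {
    tgt <- names(ms$transitions)
    if (length(tgt) && !all(tgt %in% ids)) {
      stop_input("micro state '%s' has transitions to undefined state(s) %s",
                 ms$id, paste(setdiff(tgt, ids), collapse = ", "))
    }
    for (tr in ms$triggers) {
      if (!tr$action %in% ids) {
        stop_input("trigger in micro state '%s' targets undefined state '%s'",
                   ms$id, tr$action)
      }
    }
  }
  structure(list(id = id, micro_states = micro_states, entry = entry,
                 params = params),
            class = "macro_state")
}

#' @export
print.macro_state <- function(x, ...) {
  cat(sprintf("<macro_state %s> %d micro state(s), entry '%s'\n",
              x$id, length(x$micro_states), x$entry))
  invisible(x)
}

#' Default agent-side parameters
#'
#' Timing laws and probabilities governing the agent (the d-quantities of
#' the interaction grammar). In the absence of a published a-priori agent
#' configuration they default to the reference human laws: the straight
#' wait before an initiating bid uses the human pre-bid dwell law, the
#' following delay uses the human gaze-following latency law, and the
#' object dwell uses the human post-bid dwell law. All are overridable.
#'
#' @param pfRJA Probability that the responding agent follows a human bid
#'   (1.0 for the high-responsiveness variant, 0.33 for the low one).
#' @param response_window Window in ms within which a gaze shift counts as
#'   an answer to a bid (both directions; default 2000).
#' @param object_weights Named weights for the initiating agent's object
#'   choice (default uniform over `O1..O4`).
#' @return Named list of parameters.
#' @export
default_agent_params <- function(pfRJA = 1.0, response_window = 2000,
                                 object_weights = NULL) {
  check_probability(pfRJA, "pfRJA")
  check_scalar_number(response_window, "response_window", lower = 1)
  timing <- reference_timing()
  if (is.null(object_weights)) {
    object_weights <- stats::setNames(rep(1, 4), OBJECT_AOIS)
  }
  list(
    d_straight = timing$t_straight_IJA,
    d_follow = timing$t_follow_RJA,
    d_object = timing$t_object_RJA,
    pfRJA = pfRJA,
    response_window = response_window,
    object_weights = object_weights / sum(object_weights),
    blink = default_blink_dist()
  )
}

# transition matrix + dwell laws for the agent's non-interactive states
agent_markov_config <- function(id, params) {
  timing <- reference_timing()
  if (id == "INT") {
    labs <- c(OBJECT_AOIS, "STRAIGHT", "DOWN")
    P <- matrix(0, 6, 6, dimnames = list(labs, labs))
    P[, "DOWN"] <- 0.80
    P[, "STRAIGHT"] <- 0.08
    P[, OBJECT_AOIS] <- 0.03
    diag(P)[1:5] <- 0
    P <- P / rowSums(P)
    laws <- c(
      stats::setNames(rep(list(timing$t_object_INT), 4), OBJECT_AOIS),
      list(STRAIGHT = timing$t_agent_INT, DOWN = timing$t_agent_INT))
  } else {
    ref <- reference_transitions(id, renormalize = TRUE)
    labs <- c(OBJECT_AOIS, "STRAIGHT")
    P <- ref
    dimnames(P) <- list(labs, labs)
    obj_law <- timing[[paste0("t_object_", id)]]
    agent_law <- timing[[paste0("t_agent_", id)]]
    laws <- c(stats::setNames(rep(list(obj_law), 4), OBJECT_AOIS),
              list(STRAIGHT = agent_law))
  }
  list(P = P, dwell_laws = laws)
}

#' Build one of the five canonical agent macro states
#'
#' Constructs the macro state used in the reference paradigm: `IJA` (agent
#' initiates joint-attention bids), `RJA` (agent follows the human's bids
#' with probability `pfRJA`), or a non-interactive Markov state (`PO`
#' partner-oriented, `OO` object-oriented, `INT` introspective). The
#' non-interactive states use the reference transition matrices (`OO`,
#' `PO`, row-renormalized) or a strongly self-focused downward-gaze chain
#' (`INT`).
#'
#' @param id Macro-state id.
#' @param pfRJA Follow probability for the `RJA` macro state.
#' @param params Agent parameters, see [default_agent_params()].
#' @return A [macro_state()].
#' @export
default_agent_macro <- function(id = MACRO_STATES, pfRJA = 1.0,
                                params = default_agent_params(pfRJA = pfRJA)) {
  id <- match.arg(id)
  params$pfRJA <- pfRJA
  if (id %in% c("PO", "OO", "INT")) {
    cfg <- agent_markov_config(id, params)
    states <- lapply(rownames(cfg$P), function(lab) {
      micro_state(id = lab, gaze_target = lab,
                  duration_dist = cfg$dwell_laws[[lab]],
                  transitions = cfg$P[lab, ])
    })
    entry <- if (id == "OO") "O1" else if (id == "PO") "STRAIGHT" else "DOWN"
    return(macro_state(id, states, entry,
                       params = c(params, list(markov = cfg))))
  }
  if (id == "IJA") {
    bid_states <- lapply(OBJECT_AOIS, function(o) {
      micro_state(paste0("bid_", o), gaze_target = o)
    })
    straight <- micro_state(
      "straight", "STRAIGHT",
      duration_dist = params$d_straight,
      triggers = list(gaze_trigger(
        "EYE_CONTACT", 1.0, params$d_straight, "bid_O1",
        window = NULL)))
    return(macro_state("IJA", c(list(straight), bid_states), "straight",
                       params = params))
  }
  # RJA: ready state watching the objects, one follow state per object
  follow_states <- lapply(OBJECT_AOIS, function(o) {
    micro_state(paste0("follow_", o), gaze_target = o,
                duration_dist = params$d_object,
                transitions = c(ready = 1))
  })
  ready <- micro_state(
    "ready", "STRAIGHT",
    triggers = lapply(OBJECT_AOIS, function(o) {
      gaze_trigger(o, params$pfRJA, params$d_follow, paste0("follow_", o))
    }))
  macro_state("RJA", c(list(ready), follow_states), "ready", params = params)
}

new_agent_log <- function(onset, offset, micro, target, macro, cause) {
  data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
             micro_state = micro, gaze_target = target,
             macro_state = macro, cause = cause)
}

#' Validate an agent event log
#'
#' Checks the timeline invariants: strictly increasing onsets, gapless
#' coverage of `[0, duration]` (each offset equals the next onset), and
#' exactly one active state at every instant.
#'
#' @param log Agent event log (`data.frame` from [run_block()]).
#' @param duration Block duration in ms, or `NULL` to skip the endpoint
#'   check.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_event_log <- function(log, duration = NULL) {
  need <- c("onset", "offset", "micro_state", "gaze_target", "macro_state")
  if (!is.data.frame(log) || !all(need %in% names(log))) {
    stop_input("event log must contain columns %s", paste(need, collapse = ", "))
  }
  if (nrow(log) == 0L) stop_input("empty event log")
  if (log$onset[1] != 0) stop_input("event log must start at t = 0")
  if (any(diff(log$onset) <= 0)) stop_input("onsets must be strictly increasing")
  if (any(log$offset <= log$onset)) stop_input("zero/negative-length event span")
  if (nrow(log) > 1L &&
      any(abs(log$offset[-nrow(log)] - log$onset[-1]) > 1e-9)) {
    stop_input("event log has gaps or overlaps")
  }
  if (!is.null(duration) && abs(log$offset[nrow(log)] - duration) > 1e-9) {
    stop_input("event log ends at %s, expected %s",
               format(log$offset[nrow(log)]), format(duration))
  }
  invisible(TRUE)
}

#' Markov micro-state controller
#'
#' Runs the generic Markov process of the non-interactive macro states: the
#' successor of the current micro state is drawn from its transition row and
#' the dwell duration from the successor's duration law. Used both for the
#' agent's non-interactive behavior and the synthetic participant's
#' non-interactive gaze walks.
#'
#' @param P Row-stochastic transition matrix with dimnames (self-transitions
#'   allowed in generator matrices; consecutive identical targets merge into
#'   one longer dwell downstream).
#' @param dwell_laws Named list of [duration_dist()] per state label.
#' @param steps Number of transitions to draw (mutually exclusive with
#'   `duration`).
#' @param duration Keep walking until cumulative dwell time reaches this
#'   many ms.
#' @param start Starting label (default: first row).
#' @param seed Optional seed.
#' @return `data.frame(target, duration)`; with `duration` given, the last
#'   dwell is truncated so total time equals `duration`.
#' @export
markov_controller <- function(P, dwell_laws, steps = NULL, duration = NULL,
                              start = NULL, seed = NULL) {
  stopifnot(is.matrix(P), !is.null(rownames(P)),
            identical(rownames(P), colnames(P)))
  if (any(P < 0)) stop_input("transition matrix has negative entries")
  rs <- rowSums(P)
  if (any(rs <= 0)) {
    stop_input("transition row '%s' has no outgoing probability",
               rownames(P)[which(rs <= 0)[1]])
  }
  if (any(abs(rs - 1) > 1e-9)) P <- P / rs
  labs <- rownames(P)
  missing_laws <- setdiff(labs, names(dwell_laws))
  if (length(missing_laws)) {
    stop_input("no dwell law for state(s) %s", paste(missing_laws, collapse = ", "))
  }
  if (is.null(steps) == is.null(duration)) {
    stop_input("give exactly one of 'steps' or 'duration'")
  }
  if (is.null(start)) start <- labs[1]
  stopifnot(start %in% labs)
  with_seed(seed, {
    cur <- start
    targets <- character(0)
    durs <- numeric(0)
    total <- 0
    i <- 0L
    repeat {
      i <- i + 1L
      if (!is.null(steps) && i > steps) break
      nxt <- sample(labs, 1L, prob = P[cur, ])
      d <- round_ms(sample_duration(dwell_laws[[nxt]], 1L))
      targets[i] <- nxt
      durs[i] <- d
      total <- total + d
      cur <- nxt
      if (!is.null(duration) && total >= duration) {
        durs[i] <- d - (total - duration)
        break
      }
    }
    data.frame(target = targets, duration = durs)
  })
}

#' Responding-to-joint-attention controller
#'
#' Processes a stream of human joint-attention bids (object dwell onsets):
#' each bid arriving while the agent is ready is followed with probability
#' `pfRJA` after a delay drawn from `d_follow`; the agent then dwells on the
#' object for a draw from `d_object` before re-arming. Bids arriving while
#' the agent is mid-follow or mid-dwell are ignored (not queued); a declined
#' bid leaves the agent armed.
#'
#' @param bids `data.frame(t, target)` of human object-dwell onsets (ms,
#'   increasing), or a numeric vector of onsets (targets then default to
#'   `O1`).
#' @param pfRJA Follow probability in `[0, 1]`.
#' @param d_follow,d_object [duration_dist()]s for the follow delay and the
#'   object dwell (defaults: reference laws).
#' @param seed Optional seed.
#' @return `data.frame(bid_onset, target, armed, followed, follow_onset,
#'   release)`; `follow_onset`/`release` are `NA` for unfollowed bids.
#' @export
rja_controller <- function(bids, pfRJA, d_follow = NULL, d_object = NULL,
                           seed = NULL) {
  check_probability(pfRJA, "pfRJA")
  if (is.numeric(bids)) bids <- data.frame(t = bids, target = "O1")
  stopifnot(is.data.frame(bids), all(c("t", "target") %in% names(bids)))
  if (is.unsorted(bids$t)) stop_input("bid onsets must be non-decreasing")
  params <- default_agent_params(pfRJA = pfRJA)
  if (is.null(d_follow)) d_follow <- params$d_follow
  if (is.null(d_object)) d_object <- params$d_object
  n <- nrow(bids)
  with_seed(seed, {
    armed <- logical(n)
    followed <- logical(n)
    follow_onset <- rep(NA_real_, n)
    release <- rep(NA_real_, n)
    ready_at <- 0
    for (i in seq_len(n)) {
      if (bids$t[i] < ready_at) next
      armed[i] <- TRUE
      if (stats::runif(1) >= pfRJA) next
      followed[i] <- TRUE
      follow_onset[i] <- bids$t[i] + round_ms(sample_duration(d_follow, 1L))
      release[i] <- follow_onset[i] + round_ms(sample_duration(d_object, 1L))
      ready_at <- release[i]
    }
    data.frame(bid_onset = bids$t, target = as.character(bids$target),
               armed = armed, followed = followed,
               follow_onset = follow_onset, release = release)
  })
}

#' Initiating-joint-attention controller
#'
#' Generates the agent's bid cycle: gaze straight waiting for eye contact or
#' a maximum duration drawn from `d_straight`, then shift to an object drawn
#' from `object_weights`. A bid is a joint-attention success iff the human's
#' dwell on that object begins within `response_window` ms of the shift
#' onset; the agent gazes back straight after a draw from `d_object`
#' following the human's arrival (success) or after the window elapses
#' (failure).
#'
#' @param responder Human response model: a list with elements
#'   `response_probability` and `latency` (a [duration_dist()]), or a
#'   function `(bid_onset, target) -> latency ms or NA`.
#' @param n_bids Number of bid cycles to simulate.
#' @param params Agent parameters ([default_agent_params()]).
#' @param seed Optional seed.
#' @return `data.frame(bid_onset, target, response_latency, success,
#'   return_onset)`; `response_latency` is `NA` for non-responses.
#' @export
ija_controller <- function(responder, n_bids, params = default_agent_params(),
                           seed = NULL) {
  check_scalar_number(n_bids, "n_bids", lower = 1)
  w <- params$response_window
  with_seed(seed, {
    t <- 0
    out <- vector("list", n_bids)
    for (i in seq_len(n_bids)) {
      tb <- t + round_ms(sample_duration(params$d_straight, 1L))
      o <- sample(names(params$object_weights), 1L,
                  prob = params$object_weights)
      lat <- if (is.function(responder)) {
        responder(tb, o)
      } else if (stats::runif(1) < responder$response_probability) {
        round_ms(sample_duration(responder$latency, 1L))
      } else {
        NA_real_
      }
      success <- !is.na(lat) && lat <= w
      ret <- if (success) {
        tb + lat + round_ms(sample_duration(params$d_object, 1L))
      } else {
        tb + w
      }
      out[[i]] <- data.frame(bid_onset = tb, target = o,
                             response_latency = if (success) lat else NA_real_,
                             success = success, return_onset = ret)
      t <- ret
    }
    do.call(rbind, out)
  })
}

#' Simulate one block of agent behavior
#'
#' Runs the agent's macro state for `duration` ms and returns its event log
#' (columns `onset`, `offset`, `micro_state`, `gaze_target`, `macro_state`,
#' `cause`), gapless over `[0, duration]`. Interactive macro states need a
#' human side: for `RJA` a scripted stream of human bids
#' (`data.frame(t, target)`) or a [participant_profile()]; for `IJA` a
#' responder list/function (see [ija_controller()]) or a profile. When a
#' profile is supplied the block is co-simulated and the human event log is
#' attached as `attr(, "human_log")`.
#'
#' Identical seeds and inputs yield identical logs.
#'
#' @param macro A [macro_state()].
#' @param human Human side (see Details); unused for non-interactive states.
#' @param duration Block duration in ms (> 0).
#' @param seed Optional master seed for the block.
#' @param blinks If `TRUE`, superimpose eye blinks via [blink_overlay()].
#' @return Agent event log `data.frame`.
#' @export
run_block <- function(macro, human = NULL, duration = 30000, seed = NULL,
                      blinks = FALSE) {
  stopifnot(inherits(macro, "macro_state"))
  check_scalar_number(duration, "duration", lower = 1)
  log <- if (macro$id %in% c("PO", "OO", "INT")) {
    run_block_markov(macro, duration, derive_seed(seed, 1))
  } else if (inherits(human, "participant_profile")) {
    instructed <- if (macro$id == "IJA") "RJA" else "IJA"
    sim <- simulate_block(instructed, human, macro$params, duration, seed)
    structure(sim$agent, human_log = sim$human)
  } else if (macro$id == "RJA") {
    run_block_rja_scripted(macro, human, duration, derive_seed(seed, 1))
  } else {
    run_block_ija_responder(macro, human, duration, derive_seed(seed, 1))
  }
  if (blinks) {
    log <- blink_overlay(log, macro$params$blink, seed = derive_seed(seed, 3))
  }
  log
}

run_block_markov <- function(macro, duration, seed) {
  cfg <- macro$params$markov
  entry_target <- macro$micro_states[[macro$entry]]$gaze_target
  walk <- markov_controller(cfg$P, cfg$dwell_laws, duration = duration,
                            start = entry_target, seed = seed)
  onsets <- cumsum(c(0, walk$duration[-nrow(walk)]))
  # merge consecutive identical targets (self-transitions extend the dwell)
  keep <- c(TRUE, walk$target[-1] != walk$target[-nrow(walk)])
  grp <- cumsum(keep)
  onset <- onsets[keep]
  offset <- as.numeric(tapply(onsets + walk$duration, grp, max))
  target <- walk$target[keep]
  new_agent_log(onset, offset, target, target, macro$id, "markov")
}

run_block_rja_scripted <- function(macro, bids, duration, seed) {
  if (!is.data.frame(bids) || !all(c("t", "target") %in% names(bids))) {
    stop_input("RJA macro needs scripted human bids: data.frame(t, target) or a participant_profile")
  }
  bids <- bids[bids$t < duration, , drop = FALSE]
  bad <- setdiff(unique(bids$target), OBJECT_AOIS)
  if (length(bad)) {
    stop_input("bid target(s) %s not resolvable against the layout",
               paste(bad, collapse = ", "))
  }
  ctrl <- rja_controller(bids, macro$params$pfRJA, macro$params$d_follow,
                         macro$params$d_object, seed = seed)
  fol <- ctrl[ctrl$followed & !is.na(ctrl$follow_onset) &
                ctrl$follow_onset < duration, , drop = FALSE]
  onset <- 0
  rows <- list()
  for (i in seq_len(nrow(fol))) {
    rows[[length(rows) + 1L]] <- new_agent_log(
      onset, fol$follow_onset[i], "ready", "STRAIGHT", "RJA",
      if (onset == 0) "entry" else "re_arm")
    end <- min(fol$release[i], duration)
    rows[[length(rows) + 1L]] <- new_agent_log(
      fol$follow_onset[i], end, paste0("follow_", fol$target[i]),
      fol$target[i], "RJA", "follow")
    onset <- end
  }
  if (onset < duration) {
    rows[[length(rows) + 1L]] <- new_agent_log(
      onset, duration, "ready", "STRAIGHT", "RJA",
      if (onset == 0) "entry" else "re_arm")
  }
  log <- do.call(rbind, rows)
  attr(log, "controller") <- ctrl
  log
}

run_block_ija_responder <- function(macro, responder, duration, seed) {
  if (is.null(responder)) {
    stop_input("IJA macro needs a responder (list/function) or a participant_profile")
  }
  # draw generously many bids, then truncate to the block duration
  n_guess <- max(10, ceiling(duration / 500))
  ctrl <- ija_controller(responder, n_guess, macro$params, seed = seed)
  ctrl <- ctrl[ctrl$bid_onset < duration, , drop = FALSE]
  onset <- 0
  rows <- list()
  for (i in seq_len(nrow(ctrl))) {
    rows[[length(rows) + 1L]] <- new_agent_log(
      onset, ctrl$bid_onset[i], "straight", "STRAIGHT", "IJA",
      if (onset == 0) "entry" else "return")
    end <- min(ctrl$return_onset[i], duration)
    rows[[length(rows) + 1L]] <- new_agent_log(
      ctrl$bid_onset[i], end, paste0("bid_", ctrl$target[i]),
      ctrl$target[i], "IJA", "bid")
    onset <- end
    if (onset >= duration) break
  }
  if (onset < duration) {
    rows[[length(rows) + 1L]] <- new_agent_log(
      onset, duration, "straight", "STRAIGHT", "IJA",
      if (onset == 0) "entry" else "return")
  }
  log <- do.call(rbind, rows)
  attr(log, "controller") <- ctrl
  log
}

#' Superimpose eye blinks on an agent event log
#'
#' Inserts closed-eye segments of exactly `blink_duration` ms (default 100)
#' at inter-blink intervals drawn from `blink_dist`. Blinks overlay the
#' display only: the underlying micro-state clock keeps running and every
#' scheduled transition is preserved, so a blink may span a state change. A
#' drawn blink that would overlap the previous one is dropped.
#'
#' @param log Agent event log from [run_block()].
#' @param blink_dist [duration_dist()] of inter-blink intervals, with mean
#'   at least `2 * blink_duration`; `NULL` disables blinking and returns the
#'   log unchanged.
#' @param seed Optional seed.
#' @param blink_duration Closed-eye duration in ms.
#' @return Event log with additional `CLOSED` segments (cause `"blink"`,
#'   continuation segments cause `"blink_resume"`).
#' @export
blink_overlay <- function(log, blink_dist = default_blink_dist(), seed = NULL,
                          blink_duration = 100) {
  if (is.null(blink_dist)) return(log)
  stopifnot(is_duration_dist(blink_dist))
  validate_event_log(log)
  if (dist_moments(blink_dist)[["mean"]] < 2 * blink_duration) {
    stop_input("blink interval mean below %d ms would allow overlapping blinks",
               2 * blink_duration)
  }
  total <- log$offset[nrow(log)]
  with_seed(seed, {
    n_guess <- max(4, ceiling(2 * total / dist_moments(blink_dist)[["mean"]]) + 8)
    gaps <- round_ms(sample_duration(blink_dist, n_guess))
    while (sum(gaps) < total) {
      gaps <- c(gaps, round_ms(sample_duration(blink_dist, n_guess)))
    }
    starts <- cumsum(gaps)
    starts <- starts[starts + blink_duration <= total]
    # drop blinks overlapping the previous one
    keep <- logical(length(starts))
    last_end <- -Inf
    for (i in seq_along(starts)) {
      if (starts[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- starts[i] + blink_duration
      }
    }
    starts <- starts[keep]
    if (!length(starts)) return(log)
    cuts <- sort(unique(c(log$onset, total, starts, starts + blink_duration)))
    seg_on <- cuts[-length(cuts)]
    seg_off <- cuts[-1]
    base_idx <- findInterval(seg_on, log$onset)
    in_blink <- vapply(seg_on, function(t) {
      any(t >= starts & t < starts + blink_duration)
    }, logical(1))
    # merge segments split only by an underlying (hidden) state boundary:
    # consecutive blink segments belong to the same blink (no overlaps)
    grp <- cumsum(c(TRUE, diff(in_blink) != 0 |
                      (!in_blink[-1] & diff(base_idx) != 0)))
    first <- !duplicated(grp)
    last_off <- as.numeric(tapply(seg_off, grp, max))
    out <- new_agent_log(
      seg_on[first], last_off,
      ifelse(in_blink[first], "blink", log$micro_state[base_idx[first]]),
      ifelse(in_blink[first], "CLOSED", log$gaze_target[base_idx[first]]),
      log$macro_state[base_idx[first]],
      ifelse(in_blink[first], "blink",
             ifelse(seg_on[first] == log$onset[base_idx[first]],
                    log$cause[base_idx[first]], "blink_resume")))
    attr(out, "underlying") <- log
    out
  })
}
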