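# Experiment orchestration: block scheduling with balanced instructed
# states, whole-experiment simulation, rendering/parsing of every block and
# the end-to-end estimation that reproduces the summary tables from
# simulated data.

#' Build an experiment configuration
#'
#' Bundles everything that defines a simulated gaze-interaction experiment:
#' the block schedule (count and duration, with the five instructed states
#' evenly balanced), the agent parameters including the two responsiveness
#' variants used when the human initiates, the participant profile, the
#' screen layout, the tracker-emulation settings and the parsing
#' thresholds.
#'
#' @param n_blocks Number of blocks per participant (multiple of 5;
#'   default 60, i.e. 12 per instructed state).
#' @param block_duration Block duration in ms (default 30000).
#' @param pfRJA_high,pfRJA_low Follow probabilities of the two responding-
#'   agent variants (defaults 1.0 and 0.33), assigned 50/50 to the blocks
#'   in which the human initiates.
#' @param profile A [participant_profile()].
#' @param agent_params Agent parameters ([default_agent_params()]).
#' @param layout An [aoi_layout()].
#' @param rate,noise_sd,dropout Sample-rendering settings
#'   (see [render_samples()]).
#' @param parsing List of parsing thresholds: `dispersion`, `min_duration`,
#'   `gap_bridge` (see [detect_fixations()]).
#' @param blinks Superimpose agent eye blinks (default `TRUE`).
#' @param seed Master seed for the experiment.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_blocks = 60, block_duration = 30000,
                              pfRJA_high = 1.0, pfRJA_low = 0.33,
                              profile = participant_profile(),
                              agent_params = default_agent_params(),
                              layout = default_layout(),
                              rate = 60, noise_sd = 2, dropout = 0,
                              parsing = list(dispersion = 40,
                                             min_duration = 60,
                                             gap_bridge = 75),
                              blinks = TRUE, seed = 1) {
  check_scalar_number(n_blocks, "n_blocks", lower = 5)
  if (n_blocks %% 5 != 0) {
    stop_input("'n_blocks' must be a multiple of 5 so instructed states balance")
  }
  check_scalar_number(block_duration, "block_duration", lower = 1000)
  check_probability(pfRJA_high, "pfRJA_high")
  check_probability(pfRJA_low, "pfRJA_low")
  stopifnot(inherits(profile, "participant_profile"),
            inherits(layout, "aoi_layout"))
  structure(list(n_blocks = as.integer(n_blocks),
                 block_duration = block_duration,
                 pfRJA_high = pfRJA_high, pfRJA_low = pfRJA_low,
                 profile = profile, agent_params = agent_params,
                 layout = layout, rate = rate, noise_sd = noise_sd,
                 dropout = dropout, parsing = parsing, blinks = blinks,
                 seed = seed),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d blocks x %g s, pfRJA %g/%g, %g Hz, noise %g px, seed %s\n",
    x$n_blocks, x$block_duration / 1000, x$pfRJA_high, x$pfRJA_low,
    x$rate, x$noise_sd, format(x$seed)))
  invisible(x)
}

#' Balanced block schedule for one participant
#'
#' Randomly orders the blocks with each instructed state appearing exactly
#' `n_blocks / 5` times. The human's instructed state determines the agent
#' macro state: instructed responding pairs with an initiating agent,
#' instructed initiating with a responding agent (its follow probability
#' alternating 50/50 between the high and low variant), and non-interactive
#' instructions pair with the agent's matching non-interactive state.
#'
#' @param config An [experiment_config()].
#' @param seed Optional seed.
#' @return `data.frame(block, instructed, agent_macro, pfRJA)`.
#' @export
block_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  per <- config$n_blocks / 5
  with_seed(seed, {
    instructed <- sample(rep(MACRO_STATES, per))
    agent_macro <- ifelse(instructed == "RJA", "IJA",
                          ifelse(instructed == "IJA", "RJA", instructed))
    pfRJA <- rep(NA_real_, config$n_blocks)
    ija_idx <- which(instructed == "IJA")
    variants <- sample(rep(c(config$pfRJA_high, config$pfRJA_low),
                           length.out = length(ija_idx)))
    pfRJA[ija_idx] <- variants
    data.frame(block = seq_len(config$n_blocks), instructed = instructed,
               agent_macro = agent_macro, pfRJA = pfRJA)
  })
}

#' Simulate a full experiment
#'
#' Runs every block of every participant through [simulate_block()] under
#' a balanced schedule, producing paired agent/human event logs (with eye
#' blinks superimposed on the agent when configured).
#'
#' @param config An [experiment_config()].
#' @param participants Number of participants or a character vector of ids.
#' @param seed Master seed (default: the config's seed).
#' @return Object of class `gaze_experiment`: list with `config` and
#'   `participants` — per participant a list with `schedule` and `blocks`
#'   (each block: `instructed`, `pfRJA`, `human`, `agent`, `bids`).
#' @export
simulate_experiment <- function(config, participants = 1,
                                seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  ids <- if (is.character(participants)) {
    participants
  } else {
    sprintf("p%02d", seq_len(participants))
  }
  res <- lapply(seq_along(ids), function(pi) {
    pseed <- derive_seed(seed, pi)
    sched <- block_schedule(config, seed = derive_seed(pseed, 1000))
    blocks <- lapply(seq_len(nrow(sched)), function(b) {
      params <- config$agent_params
      if (!is.na(sched$pfRJA[b])) params$pfRJA <- sched$pfRJA[b]
      sim <- simulate_block(sched$instructed[b], config$profile, params,
                            duration = config$block_duration,
                            seed = derive_seed(pseed, b))
      if (config$blinks) {
        sim$agent <- blink_overlay(sim$agent, params$blink,
                                   seed = derive_seed(pseed, 10000 + b))
      }
      c(sim, list(instructed = sched$instructed[b], pfRJA = sched$pfRJA[b]))
    })
    list(id = ids[pi], schedule = sched, blocks = blocks)
  })
  names(res) <- ids
  structure(list(config = config, participants = res),
            class = "gaze_experiment")
}

#' @export
print.gaze_experiment <- function(x, ...) {
  cat(sprintf("<gaze_experiment> %d participant(s) x %d blocks\n",
              length(x$participants), x$config$n_blocks))
  invisible(x)
}

#' Render and parse every block of a simulated experiment
#'
#' Converts each block's human event stream into raw samples
#' ([render_samples()]), applies the block data-quality rule
#' ([block_quality()]) and parses samples into fixations and AOI dwells
#' ([detect_fixations()], [merge_to_dwells()]).
#'
#' @param experiment A `gaze_experiment` from [simulate_experiment()].
#' @param seed Seed for the rendering noise (default: config seed + 1).
#' @return List with `dwells` (`data.frame` incl. `participant`, `block`,
#'   `instructed`) and `quality` (per-block valid fraction and include
#'   flag).
#' @export
parse_experiment <- function(experiment, seed = NULL) {
  stopifnot(inherits(experiment, "gaze_experiment"))
  cfg <- experiment$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 999)
  dw <- list()
  qu <- list()
  for (p in experiment$participants) {
    for (b in seq_along(p$blocks)) {
      blk <- p$blocks[[b]]
      smp <- render_samples(blk$human, cfg$layout, rate = cfg$rate,
                            noise_sd = cfg$noise_sd, dropout = cfg$dropout,
                            seed = derive_seed(seed, b * 131 +
                                                 match(p$id, names(experiment$participants))))
      q <- block_quality(smp)
      qu[[length(qu) + 1L]] <- data.frame(
        participant = p$id, block = b, instructed = blk$instructed,
        valid_fraction = q$valid_fraction, include = q$include)
      if (!q$include) next
      fx <- detect_fixations(smp, dispersion = cfg$parsing$dispersion,
                             min_duration = cfg$parsing$min_duration,
                             gap_bridge = cfg$parsing$gap_bridge)
      d <- merge_to_dwells(fx, cfg$layout)
      if (nrow(d)) {
        d$participant <- p$id
        d$block <- b
        d$instructed <- blk$instructed
        dw[[length(dw) + 1L]] <- d
      }
    }
  }
  list(dwells = if (length(dw)) do.call(rbind, dw) else NULL,
       quality = do.call(rbind, qu))
}

#' Estimate all behavioral parameters from a parsed experiment
#'
#' The end-to-end estimation: per included block, timing observations are
#' extracted with the instructed state's event grammar; the 11 timing
#' parameters are fitted per participant and summarized across
#' participants; transition matrices are estimated from the object-oriented
#' and partner-oriented blocks; attention ratios are averaged per
#' instructed state; and the interaction rates are computed from the
#' initiating-agent blocks.
#'
#' @param experiment A `gaze_experiment`.
#' @param parsed Output of [parse_experiment()].
#' @param min_n Minimum per-participant sample size for fitting.
#' @return List with `observations`, `summary` (a `timing_summary`),
#'   `transitions` (list `OO`, `PO`), `ratios` (per state) and `rates`.
#' @export
estimate_experiment <- function(experiment, parsed, min_n = 10) {
  stopifnot(inherits(experiment, "gaze_experiment"))
  cfg <- experiment$config
  dwells <- parsed$dwells
  obs <- list()
  ratio_rows <- list()
  n_bids <- 0L
  n_resp <- 0L
  ija_minutes <- 0
  for (p in experiment$participants) {
    for (b in seq_along(p$blocks)) {
      blk <- p$blocks[[b]]
      d <- dwells[dwells$participant == p$id & dwells$block == b, ,
                  drop = FALSE]
      if (!nrow(d)) next
      o <- extract_timing(blk$agent, d, blk$instructed,
                          response_window = cfg$agent_params$response_window)
      if (nrow(o)) {
        o$participant <- p$id
        o$block <- b
        obs[[length(obs) + 1L]] <- o
      }
      r <- attention_ratios(d, cfg$block_duration)
      ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
        participant = p$id, instructed = blk$instructed,
        r_aoi = r$r_aoi, r_a_o = r$r_a_o)
      if (blk$instructed == "RJA") {
        rates_b <- estimate_rates(blk$agent, d,
                                  cfg$agent_params$response_window)
        nb <- sum(collapse_blinks(blk$agent)$gaze_target %in% OBJECT_AOIS)
        n_bids <- n_bids + nb
        if (!is.na(rates_b$response_fraction)) {
          n_resp <- n_resp + round(rates_b$response_fraction * nb)
        }
        ija_minutes <- ija_minutes + cfg$block_duration / 60000
      }
    }
  }
  observations <- bind_obs(obs)
  ratios <- do.call(rbind, ratio_rows)
  ratio_summary <- do.call(rbind, lapply(split(ratios, ratios$instructed),
    function(g) data.frame(instructed = g$instructed[1],
                           r_aoi = mean(g$r_aoi, na.rm = TRUE),
                           r_a_o = mean(g$r_a_o, na.rm = TRUE))))
  transitions <- lapply(c(OO = "OO", PO = "PO"), function(st) {
    d <- dwells[dwells$instructed == st, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    estimate_transition_matrix(d)
  })
  list(observations = observations,
       summary = fit_summary_table(observations, min_n = min_n),
       transitions = transitions,
       ratios = ratio_summary,
       rates = list(
         bids_per_min = if (ija_minutes > 0) n_bids / ija_minutes else NA_real_,
         response_fraction = if (n_bids > 0) n_resp / n_bids else NA_real_))
}

# collapse a blink-overlaid display log back to the underlying schedule;
# uses the attached schedule when present (a blink can hide a state
# boundary, in which case reconstruction from the display alone shifts
# that boundary to the blink's end)
collapse_blinks <- function(agent_log) {
  underlying <- attr(agent_log, "underlying")
  if (!is.null(underlying)) return(underlying)
  keep <- agent_log$gaze_target != "CLOSED"
  log <- agent_log[keep, , drop = FALSE]
  if (nrow(log) < 2L) return(log)
  same <- c(FALSE, log$micro_state[-1] == log$micro_state[-nrow(log)] &
              log$gaze_target[-1] == log$gaze_target[-nrow(log)])
  grp <- cumsum(!same)
  res <- do.call(rbind, lapply(split(seq_len(nrow(log)), grp), function(idx) {
    r <- log[idx[1], , drop = FALSE]
    r$offset <- log$offset[idx[length(idx)]]
    r
  }))
  rownames(res) <- NULL
  res
}
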