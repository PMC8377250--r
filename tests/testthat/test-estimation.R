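# Timing extraction grammar, rates, summary fitting, transition matrices,
# attention ratios and heatmaps.

test_that("gaze-following latency is the dwell onset minus the bid onset", {
  agent <- tiny_ija_log(bid_onset = 1000, target = "O3", bid_end = 3000)
  dwells <- dwell_df(c("A", "O3"), c(0, 1463), c(1400, 2500))
  obs <- extract_timing(agent, dwells, "RJA")
  expect_equal(obs$value[obs$parameter == "t_follow_RJA"], 463)
  expect_equal(obs$value[obs$parameter == "t_object_RJA"], 2500 - 1463)
})

test_that("responses outside the window and repeat responses are discarded", {
  agent <- tiny_ija_log(bid_onset = 1000, target = "O3")
  late <- dwell_df("O3", 3500, 4400) # 2500 ms after the bid
  expect_equal(nrow(extract_timing(agent, late, "RJA")), 0L)
  two <- dwell_df(c("O3", "O3"), c(1400, 2600), c(2000, 2900))
  obs <- extract_timing(agent, two, "RJA")
  # only the first dwell on the cued object counts
  expect_equal(sum(obs$parameter == "t_follow_RJA"), 1L)
  expect_equal(obs$value[obs$parameter == "t_follow_RJA"], 400)
})

test_that("every bid yields at most one response: counts conserve bids", {
  sim <- simulate_block("RJA", duration = 120000, seed = 101)
  h <- sim$human
  dwells <- dwell_df(h$target, h$onset, h$offset)
  obs <- extract_timing(sim$agent, dwells, "RJA")
  n_bids <- nrow(sim$bids)
  n_resp <- sum(obs$parameter == "t_follow_RJA")
  expect_equal(n_resp, sum(sim$bids$success))
  expect_lte(n_resp, n_bids)
})

test_that("unanswered own bids are measured as back-to-agent dwells", {
  # human initiates toward O1 at 2000 and holds until 3590; agent never follows
  agent <- data.frame(onset = 0, offset = 6000, micro_state = "ready",
                      gaze_target = "STRAIGHT", macro_state = "RJA",
                      cause = "entry")
  dwells <- dwell_df(c("A", "O1"), c(0, 2000), c(1970, 3590))
  obs <- extract_timing(agent, dwells, "IJA")
  expect_equal(obs$value[obs$parameter == "t_back_IJA"], 1590)
  expect_equal(obs$value[obs$parameter == "t_straight_IJA"], 1970)
})

test_that("followed own bids anchor the object dwell on the agent's arrival", {
  agent <- data.frame(
    onset = c(0, 2450, 3500), offset = c(2450, 3500, 6000),
    micro_state = c("ready", "follow_O2", "ready"),
    gaze_target = c("STRAIGHT", "O2", "STRAIGHT"),
    macro_state = "RJA", cause = c("entry", "follow", "re_arm"))
  dwells <- dwell_df(c("A", "O2"), c(0, 2000), c(1970, 3338))
  obs <- extract_timing(agent, dwells, "IJA")
  expect_equal(obs$value[obs$parameter == "t_object_IJA"], 3338 - 2450)
  expect_false("t_back_IJA" %in% obs$parameter)
})

test_that("non-interactive dwells map onto their state's parameters", {
  agent <- run_block(default_agent_macro("OO"), duration = 10000, seed = 1)
  dwells <- dwell_df(c("O1", "A", "O2"), c(0, 1500, 3500),
                     c(1400, 3300, 4100))
  obs <- extract_timing(agent, dwells, "OO")
  expect_equal(sort(obs$value[obs$parameter == "t_object_OO"]), c(600, 1400))
  expect_equal(obs$value[obs$parameter == "t_agent_OO"], 1800)
})

test_that("interaction rates follow their definitions", {
  agent <- tiny_ija_log(bid_onset = 1000, bid_end = 3000, duration = 30000)
  agent9 <- do.call(rbind, lapply(0:8, function(k) {
    a <- tiny_ija_log(bid_onset = 400, target = "O1", bid_end = 2000,
                      duration = 10000 / 3)
    a$onset <- a$onset + k * 10000 / 3
    a$offset <- a$offset + k * 10000 / 3
    a
  }))
  agent9 <- agent9[order(agent9$onset), ]
  rates <- estimate_rates(agent9, dwells = dwell_df("O4", 1, 2))
  expect_equal(rates$bids_per_min, 18)
  expect_equal(rates$response_fraction, 0)
  expect_error(estimate_rates(agent9[0, ]), "log|empty")
})

test_that("simulated response probability is recovered from the logs", {
  n_resp <- 0; n_bids <- 0
  for (b in 1:6) {
    sim <- simulate_block("RJA", duration = 120000, seed = 200 + b)
    h <- sim$human
    dwells <- dwell_df(h$target, h$onset, h$offset)
    r <- estimate_rates(sim$agent, dwells)
    n_bids <- n_bids + nrow(sim$bids)
    n_resp <- n_resp + r$response_fraction * nrow(sim$bids)
  }
  expect_gt(n_bids, 150)
  expect_lt(abs(n_resp / n_bids - 0.85), 0.06)
})

test_that("the summary table fits, selects and labels each parameter", {
  gen <- list(t_follow_RJA = duration_dist("exgauss", 350, 34.2, 124),
              t_object_RJA = duration_dist("lnorm", 6.84, 0.27))
  obs <- do.call(rbind, lapply(names(gen), function(p) {
    do.call(rbind, lapply(1:5, function(pid) {
      data.frame(parameter = p, participant = paste0("p", pid),
                 value = sample_duration(gen[[p]], 400,
                                         seed = derive_seed(300 + pid,
                                                            match(p, names(gen)))))
    }))
  }))
  tab <- fit_summary_table(obs)
  expect_setequal(tab$parameter, names(gen))
  rj <- tab[tab$parameter == "t_follow_RJA", ]
  expect_identical(rj$family, "exgauss")
  expect_lt(abs(rj$est_mean - 474), 10)
  ob <- tab[tab$parameter == "t_object_RJA", ]
  expect_identical(ob$family, "lnorm")
  expect_lt(abs(ob$est_mean - 986), 25)
  expect_lt(abs(ob$raw_mean - 986), 25)
})

test_that("parameters without enough data are reported, not dropped", {
  obs <- data.frame(parameter = "t_agent_PO", participant = "p1",
                    value = rlnorm(4, 7, 0.5))
  tab <- fit_summary_table(obs)
  expect_true(is.na(tab$est_mean))
  expect_match(tab$note, "insufficient")
})

test_that("forced dwell sequences give degenerate transition probabilities", {
  d <- dwell_df(c("O1", "O2", "O1", "O2"), c(0, 1, 2, 3), c(0.5, 1.5, 2.5, 3.5))
  d$participant <- "p1"
  tm <- estimate_transition_matrix(d)
  expect_equal(tm$P["O1", "O2"], 1)
  expect_equal(tm$P["O2", "O1"], 1)
  expect_true(all(is.na(tm$P["O3", ])))
  rs <- rowSums(tm$P, na.rm = TRUE)
  expect_true(all(abs(rs[c("O1", "O2")] - 1) < 1e-9))
})

test_that("participant matrices are averaged entry-wise then renormalized", {
  d1 <- dwell_df(c("O1", "O2"), c(0, 1), c(0.5, 1.5)) # p(O1->O2) = 1
  d1$participant <- "p1"
  d2 <- dwell_df(c("O1", "A", "O1", "A"), c(0, 1, 2, 3),
                 c(0.5, 1.5, 2.5, 3.5)) # p(O1->A) = 1
  d2$participant <- "p2"
  tm <- estimate_transition_matrix(rbind(d1, d2))
  expect_equal(tm$P["O1", "O2"], 0.5)
  expect_equal(tm$P["O1", "A"], 0.5)
  expect_equal(tm$n_participants, 2)
})

test_that("transitions never span block boundaries", {
  d <- dwell_df(c("O1", "O2"), c(0, 1), c(0.5, 1.5))
  d$participant <- "p1"
  d$block <- c(1, 2)
  expect_error(estimate_transition_matrix(d), "no dwell transitions")
})

test_that("simulated object-oriented gaze recovers the published matrix", {
  # two long blocks give > 1e4 AOI shifts
  d <- do.call(rbind, lapply(1:2, function(b) {
    sim <- simulate_block("OO", duration = 3e7, seed = 400 + b)
    h <- sim$human
    out <- dwell_df(h$target, h$onset, h$offset)
    out$participant <- "p1"
    out$block <- b
    out
  }))
  tm <- estimate_transition_matrix(d)
  expect_gt(sum(tm$counts), 1e4)
  ref <- reference_transitions("OO")
  expect_lt(max(abs(tm$P - ref), na.rm = TRUE), 0.03)
  rs <- rowSums(tm$P)
  expect_true(all(abs(rs - 1) < 1e-9))
})

test_that("simulated partner-oriented gaze recovers the O4->A entry", {
  d <- do.call(rbind, lapply(1:2, function(b) {
    sim <- simulate_block("PO", duration = 1e7, seed = 410 + b)
    h <- sim$human
    out <- dwell_df(h$target, h$onset, h$offset)
    out$participant <- "p1"
    out$block <- b
    out
  }))
  tm <- estimate_transition_matrix(d)
  expect_lt(abs(tm$P["O4", "A"] - 0.84), 0.03)
})

test_that("attention ratios are forced arithmetic on dwell time", {
  d <- dwell_df(c("O1", "A"), c(0, 10000), c(6000, 29200))
  r <- attention_ratios(d, 30000)
  expect_equal(r$r_aoi, 25200 / 30000)
  d2 <- dwell_df("A", 0, 5000)
  expect_equal(attention_ratios(d2, 10000)$r_a_o, 1)
  d3 <- dwell_df(c("A", "O2"), c(0, 3000), c(2000, 9000))
  expect_equal(attention_ratios(d3, 10000)$r_a_o, 0.25)
  # undefined when no face/object dwell time exists
  expect_true(is.na(attention_ratios(dwell_df("O1", 1, 1)[0, ],
                                     1000)$r_a_o))
})

test_that("attention ratios are invariant under time translation", {
  d <- dwell_df(c("A", "O3", "O1"), c(100, 4000, 9000), c(3000, 7000, 12000))
  r0 <- attention_ratios(d, 15000)
  shifted <- d
  shifted$onset <- shifted$onset + 5000
  shifted$offset <- shifted$offset + 5000
  r1 <- attention_ratios(shifted, 15000)
  expect_equal(r0, r1)
})

test_that("heatmaps peak at fixations and scale linearly with duration", {
  fx <- data.frame(x = 480, y = 540, duration = 500)
  hm <- build_heatmap(fx, cell = 8)
  peak <- which(hm$grid == max(hm$grid), arr.ind = TRUE)
  expect_lt(abs(peak[1, "col"] * 8 - 4 - 480), 8)
  expect_lt(abs(peak[1, "row"] * 8 - 4 - 540), 8)
  # duration-weighted mass: 300 ms vs 600 ms deposit 1:2
  fx2 <- data.frame(x = c(400, 1400), y = c(540, 540),
                    duration = c(300, 600))
  hm2 <- build_heatmap(fx2, cell = 8, radius = 60)
  left <- sum(hm2$raw[, 1:100])
  right <- sum(hm2$raw[, 141:240])
  expect_equal(right / left, 2, tolerance = 1e-6)
})

test_that("heatmaps are symmetric for mirrored equal fixations", {
  fx <- data.frame(x = c(480, 1440), y = c(540, 540), duration = c(400, 400))
  hm <- build_heatmap(fx, cell = 4, radius = 50)
  expect_equal(hm$grid, hm$grid[, rev(seq_len(ncol(hm$grid)))],
               tolerance = 1e-12)
  # zero positional variance falls back to the configured minimum radius
  same <- data.frame(x = c(300, 300), y = c(300, 300), duration = c(1, 1))
  expect_equal(build_heatmap(same, cell = 8)$radius, 10)
})
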