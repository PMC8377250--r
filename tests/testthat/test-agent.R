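# Agent engine: state containers, controllers, block simulation, blink
# superposition.

test_that("micro/macro state validation catches malformed definitions", {
  expect_error(micro_state("a", "O1", transitions = c(b = 0.5, c = 0.4)),
               "sum to 1")
  ok <- micro_state("a", "O1", transitions = c(a = 1))
  expect_error(macro_state("OO", list(ok), entry = "zz"), "entry")
  bad <- micro_state("b", "O2", transitions = c(nowhere = 1))
  expect_error(macro_state("OO", list(ok, bad), entry = "a"), "undefined")
  expect_error(gaze_trigger("O1", 1.5, duration_dist("norm", 100, 10), "a"),
               "fire_probability")
})

test_that("block timelines are gapless, closed and deterministic", {
  for (id in c("PO", "OO", "INT")) {
    m <- default_agent_macro(id)
    log <- run_block(m, duration = 30000, seed = 9)
    expect_true(validate_event_log(log, 30000))
    expect_identical(log, run_block(m, duration = 30000, seed = 9))
    expect_false(identical(log, run_block(m, duration = 30000, seed = 10)))
  }
})

test_that("a single self-transitioning micro state fills the whole block", {
  d <- duration_dist("norm", 400, 50)
  ms <- micro_state("only", "O2", duration_dist = d, transitions = c(only = 1))
  macro <- macro_state("OO", list(ms), entry = "only",
                       params = list(markov = list(
                         P = matrix(1, 1, 1, dimnames = list("O2", "O2")),
                         dwell_laws = list(O2 = d))))
  log <- run_block(macro, duration = 30000, seed = 3)
  expect_true(all(log$gaze_target == "O2"))
  expect_true(validate_event_log(log, 30000))
})

test_that("markov controller follows its transition row exactly when forced", {
  P <- matrix(c(0, 1, 0,
                0, 0, 1,
                1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  laws <- setNames(rep(list(duration_dist("norm", 100, 1)), 3),
                   c("a", "b", "c"))
  walk <- markov_controller(P, laws, steps = 9, start = "a", seed = 1)
  expect_identical(walk$target, rep(c("b", "c", "a"), 3))
  expect_error(markov_controller(P * 0, laws, steps = 3), "outgoing")
})

test_that("a symmetric two-state chain splits occupancy evenly", {
  P <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  laws <- list(x = duration_dist("norm", 300, 10),
               y = duration_dist("norm", 300, 10))
  walk <- markov_controller(P, laws, steps = 1e5, start = "x", seed = 2)
  expect_lt(abs(mean(walk$target == "x") - 0.5), 0.01)
})

test_that("long runs reproduce the object-oriented transition matrix", {
  P <- reference_transitions("OO", renormalize = TRUE)
  labs <- rownames(P)
  laws <- setNames(rep(list(duration_dist("norm", 300, 30)), 5), labs)
  walk <- markov_controller(P, laws, steps = 1e5, start = "O1", seed = 4)
  from <- c("O1", walk$target[-nrow(walk)])
  emp <- prop.table(table(factor(from, labs), factor(walk$target, labs)), 1)
  expect_lt(max(abs(emp - P)), 0.01)
  # the headline entry also sits at its printed value
  expect_lt(abs(emp["O1", "O2"] - 0.65), 0.03)
})

test_that("the responding agent gates bids by its follow probability", {
  bids <- data.frame(t = seq(0, by = 3000, length.out = 10000), target = "O2")
  none <- rja_controller(bids, pfRJA = 0, seed = 1)
  expect_equal(sum(none$followed), 0)
  all_f <- rja_controller(bids, pfRJA = 1,
                          d_follow = duration_dist("norm", 400, 30),
                          d_object = duration_dist("norm", 900, 50), seed = 2)
  expect_true(all(all_f$followed[all_f$armed]))
  expect_true(all(all_f$follow_onset[all_f$followed] >
                    all_f$bid_onset[all_f$followed]))
  low <- rja_controller(bids, pfRJA = 0.33, seed = 3)
  expect_lt(abs(mean(low$followed) - 0.33), 0.02)
})

test_that("bids arriving while the agent is busy are ignored, not queued", {
  bids <- data.frame(t = seq(0, by = 200, length.out = 50), target = "O1")
  ctrl <- rja_controller(bids, pfRJA = 1,
                         d_follow = duration_dist("norm", 400, 10),
                         d_object = duration_dist("norm", 900, 10), seed = 5)
  expect_gt(sum(!ctrl$armed), 0)
  expect_true(all(!ctrl$followed[!ctrl$armed]))
})

test_that("initiating-agent bids classify responses by the window", {
  params <- default_agent_params()
  always <- ija_controller(function(tb, o) 450, n_bids = 20, params, seed = 1)
  expect_true(all(always$success))
  never <- ija_controller(function(tb, o) NA_real_, n_bids = 20, params,
                          seed = 2)
  expect_false(any(never$success))
  expect_equal(never$return_onset - never$bid_onset,
               rep(params$response_window, 20))
  probed <- ija_controller(
    list(response_probability = 0.85,
         latency = duration_dist("exgauss", 350, 34.2, 124)),
    n_bids = 1000, params, seed = 3)
  expect_lt(abs(mean(probed$success) - 0.85), 0.03)
})

test_that("a fully responsive agent never gazes at an object unprompted", {
  bids <- data.frame(t = cumsum(round(runif(200, 2500, 4000))),
                     target = sample(c("O1", "O2", "O3", "O4"), 200,
                                     replace = TRUE))
  macro <- default_agent_macro("RJA", pfRJA = 1)
  log <- run_block(macro, human = bids, duration = max(bids$t) + 5000,
                   seed = 6)
  obj_rows <- log[log$gaze_target %in% c("O1", "O2", "O3", "O4"), ]
  for (i in seq_len(nrow(obj_rows))) {
    preceding <- bids[bids$t < obj_rows$onset[i] &
                        bids$target == obj_rows$gaze_target[i], ]
    expect_gt(nrow(preceding), 0)
  }
  expect_true(validate_event_log(log, max(bids$t) + 5000))
})

test_that("blink overlay inserts 100 ms closed segments and preserves the schedule", {
  m <- default_agent_macro("PO")
  log <- run_block(m, duration = 120000, seed = 7)
  expect_identical(blink_overlay(log, NULL), log)
  ovl <- blink_overlay(log, default_blink_dist(), seed = 8)
  closed <- ovl[ovl$gaze_target == "CLOSED", ]
  expect_gt(nrow(closed), 0)
  expect_true(all(abs(closed$offset - closed$onset - 100) < 1e-9))
  expect_true(validate_event_log(ovl, 120000))
  # underlying micro-state schedule is unchanged by the overlay
  restored <- socialgaze:::collapse_blinks(ovl)
  expect_equal(restored$onset, log$onset)
  expect_equal(restored$offset, log$offset)
  expect_equal(restored$gaze_target, log$gaze_target)
  expect_error(blink_overlay(log, duration_dist("norm", 150, 10)),
               "overlap")
})

test_that("blink rate matches the configured inter-blink interval", {
  m <- default_agent_macro("PO")
  minutes <- 60
  log <- run_block(m, duration = minutes * 60000, seed = 11)
  ovl <- blink_overlay(log, default_blink_dist(), seed = 12)
  n_blinks <- sum(ovl$gaze_target == "CLOSED")
  expect_lt(abs(n_blinks / minutes - 60000 / 3529), 1)
})
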