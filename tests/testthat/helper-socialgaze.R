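# Shared fixtures: hand-built sample streams, tiny layouts and event logs
# used across the test files.

# a constant-position sample stream at `pos`, `rate` Hz, `duration` ms
constant_stream <- function(pos, duration = 1000, rate = 60, valid = TRUE) {
  n <- floor(rate * duration / 1000)
  t <- (seq_len(n) - 1) * 1000 / rate
  data.frame(t = t, x = rep(pos[1], n), y = rep(pos[2], n),
             valid = rep(valid, length.out = n))
}

# concatenate streams in time (shifts each subsequent stream after the last)
concat_streams <- function(...) {
  parts <- list(...)
  out <- parts[[1]]
  for (p in parts[-1]) {
    gap <- 1000 / 60
    p$t <- p$t + max(out$t) + gap
    out <- rbind(out, p)
  }
  out
}

# minimal agent log: one straight span, one bid span, one return span
tiny_ija_log <- function(bid_onset = 1000, target = "O3", bid_end = 3000,
                         duration = 6000) {
  data.frame(
    onset = c(0, bid_onset, bid_end),
    offset = c(bid_onset, bid_end, duration),
    micro_state = c("straight", paste0("bid_", target), "straight"),
    gaze_target = c("STRAIGHT", target, "STRAIGHT"),
    macro_state = "IJA",
    cause = c("entry", "bid", "return"))
}

# dwell data.frame builder
dwell_df <- function(aoi, onset, offset) {
  data.frame(aoi = aoi, onset = onset, offset = offset,
             duration = offset - onset, n_fixations = 1L)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
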