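# Published reference parameters: the empirically estimated human timing
# laws and AOI transition matrices that serve as generator defaults for the
# synthetic participant and (in the absence of the original a-priori agent
# configuration) for the agent's own d-distributions.

TIMING_PARAMETERS <- c(
  "t_straight_IJA", "t_object_IJA", "t_back_IJA",
  "t_follow_RJA", "t_object_RJA",
  "t_object_PO", "t_agent_PO",
  "t_object_OO", "t_agent_OO",
  "t_object_INT", "t_agent_INT")

MACRO_STATES <- c("IJA", "RJA", "PO", "OO", "INT")
OBJECT_AOIS <- c("O1", "O2", "O3", "O4")

#' Reference human timing laws
#'
#' The empirically estimated duration laws for the 11 timing parameters of
#' gaze interaction: per macro state, the human's dwell times on the agent's
#' face and on objects, the gaze-following latency when responding to a
#' joint-attention bid, and the dwell times around initiating bids. These
#' are the defaults of [participant_profile()] and of the agent-side
#' duration laws in [default_agent_params()].
#'
#' Note one known inconsistency carried over from the source estimates: the
#' normal law for `t_agent_PO` has `mu = 2480` while its published estimated
#' mean is 1,860 ms; under this package's conventions the closed-form mean
#' of a normal law is `mu`, so no attempt is made to force agreement.
#'
#' @return Named list of 11 [duration_dist()] objects keyed by parameter
#'   label.
#' @examples
#' reference_timing()[["t_follow_RJA"]]
#' @export
reference_timing <- function() {
  list(
    t_straight_IJA = duration_dist("lnorm", 6.72, 0.46),
    t_object_IJA   = duration_dist("lnorm", 6.50, 0.58),
    t_back_IJA     = duration_dist("lnorm", 7.26, 0.44),
    t_follow_RJA   = duration_dist("exgauss", 350, 34.2, 124),
    t_object_RJA   = duration_dist("lnorm", 6.84, 0.27),
    t_object_PO    = duration_dist("lnorm", 5.92, 0.53),
    t_agent_PO     = duration_dist("norm", 2480, 1670),
    t_object_OO    = duration_dist("exgauss", 566, 358, 824),
    t_agent_OO     = duration_dist("lnorm", 6.27, 0.67),
    t_object_INT   = duration_dist("lnorm", 6.04, 0.59),
    t_agent_INT    = duration_dist("lnorm", 7.27, 1.04)
  )
}

#' Reference AOI transition matrices
#'
#' Empirical gaze-shift probabilities between the four object AOIs and the
#' agent AOI (`A`), estimated separately for the object-oriented (`OO`) and
#' partner-oriented (`PO`) states. Rows are origins, columns destinations;
#' the diagonal is zero because a merged dwell cannot follow itself. Rows
#' are reported as printed (sums 0.97-1.03 for `OO` due to rounding); set
#' `renormalize = TRUE` to rescale each row to sum exactly to 1, as the
#' simulator does. The introspective state (`INT`) has no published matrix;
#' its default (strong self-focus on an off-AOI downward target) is built in
#' [participant_profile()].
#'
#' @param state `"OO"` or `"PO"`.
#' @param renormalize Rescale rows to unit sum (default `FALSE`).
#' @return 5x5 row matrix with dimnames `O1..O4, A`.
#' @export
reference_transitions <- function(state = c("OO", "PO"), renormalize = FALSE) {
  state <- match.arg(state)
  labs <- c(OBJECT_AOIS, "A")
  m <- if (state == "OO") {
    matrix(c(
      0.00, 0.65, 0.08, 0.09, 0.15,
      0.38, 0.00, 0.50, 0.04, 0.08,
      0.05, 0.45, 0.00, 0.43, 0.08,
      0.15, 0.10, 0.55, 0.00, 0.23,
      0.28, 0.31, 0.19, 0.21, 0.00), 5, 5, byrow = TRUE,
      dimnames = list(labs, labs))
  } else {
    matrix(c(
      0.00, 0.17, 0.01, 0.06, 0.76,
      0.27, 0.00, 0.42, 0.02, 0.29,
      0.00, 0.33, 0.00, 0.21, 0.46,
      0.03, 0.01, 0.12, 0.00, 0.84,
      0.35, 0.15, 0.07, 0.43, 0.00), 5, 5, byrow = TRUE,
      dimnames = list(labs, labs))
  }
  if (renormalize) m <- m / rowSums(m)
  m
}

#' Default blink-interval law
#'
#' Log-normal inter-blink interval whose mean matches a blink rate of 17
#' blinks per minute (mean interval 60000/17 = 3529 ms) with a log-scale SD
#' of 0.3: `mu = log(3529) - 0.3^2/2`.
#'
#' @return A [duration_dist()].
#' @export
default_blink_dist <- function() {
  duration_dist("lnorm", log(60000 / 17) - 0.3^2 / 2, 0.3)
}
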