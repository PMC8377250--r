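# Screen areas of interest: rectangular regions used for hit-testing gaze
# samples and anchoring synthetic gaze positions.

#' Define a set of areas of interest (AOIs)
#'
#' AOIs are axis-aligned rectangles in screen pixels with 0-based, half-open
#' extents `[x0, x1) x [y0, y1)`, origin at the top-left of the screen.
#' Overlapping regions are permitted and resolved by declaration order
#' (first match wins). Each AOI also carries an anchor point (its center)
#' used by the sample renderer.
#'
#' @param regions `data.frame` with columns `name`, `x0`, `y0`, `x1`, `y1`
#'   (one row per AOI, unique names, `x1 > x0`, `y1 > y0`).
#' @param canvas Screen size in pixels, `c(width, height)`.
#' @param anchors Optional named list of `c(x, y)` anchor points for
#'   off-AOI gaze targets (e.g. a downward rest position).
#' @return Object of class `aoi_layout`.
#' @seealso [default_layout()], [aoi_hit()]
#' @export
aoi_layout <- function(regions, canvas = c(1920, 1080), anchors = list()) {
  need <- c("name", "x0", "y0", "x1", "y1")
  if (!is.data.frame(regions) || !all(need %in% names(regions))) {
    stop_input("'regions' must be a data.frame with columns %s",
               paste(need, collapse = ", "))
  }
  regions <- as.data.frame(regions)[, need]
  rownames(regions) <- NULL
  regions$name <- as.character(regions$name)
  if (anyDuplicated(regions$name)) stop_input("AOI names must be unique")
  if (any(regions$x1 <= regions$x0) || any(regions$y1 <= regions$y0)) {
    stop_input("degenerate AOI rectangle (need x1 > x0 and y1 > y0)")
  }
  structure(list(regions = regions, canvas = as.numeric(canvas),
                 anchors = anchors),
            class = "aoi_layout")
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf("<aoi_layout> %d region(s) on %gx%g px canvas\n",
              nrow(x$regions), x$canvas[1], x$canvas[2]))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Default screen layout
#'
#' A 1920x1080 canvas with the agent's face centered (`A`) and four object
#' AOIs at left (`O1`), up-left (`O2`), right (`O3`) and up-right (`O4`),
#' plus an off-AOI `DOWN` anchor below the face used for introspective
#' gaze. All regions are 300x300 px.
#'
#' @return An [aoi_layout()].
#' @export
default_layout <- function() {
  half <- 150
  centers <- rbind(
    A  = c(960, 540),
    O1 = c(310, 540),
    O2 = c(560, 190),
    O3 = c(1610, 540),
    O4 = c(1360, 190))
  regions <- data.frame(
    name = rownames(centers),
    x0 = centers[, 1] - half, y0 = centers[, 2] - half,
    x1 = centers[, 1] + half, y1 = centers[, 2] + half)
  aoi_layout(regions, canvas = c(1920, 1080),
             anchors = list(DOWN = c(960, 1000)))
}

#' Resolve screen coordinates to AOI names
#'
#' Vectorized point-in-rectangle test honoring declaration order: when AOIs
#' overlap, the earliest declared region containing the point wins.
#'
#' @param layout An [aoi_layout()].
#' @param x,y Pixel coordinates (vectors of equal length).
#' @return Character vector of AOI names, `NA` where no region contains the
#'   point.
#' @export
aoi_hit <- function(layout, x, y) {
  stopifnot(inherits(layout, "aoi_layout"), length(x) == length(y))
  out <- rep(NA_character_, length(x))
  r <- layout$regions
  for (i in rev(seq_len(nrow(r)))) { # reverse so earlier rows overwrite
    inside <- !is.na(x) & x >= r$x0[i] & x < r$x1[i] &
      !is.na(y) & y >= r$y0[i] & y < r$y1[i]
    out[inside] <- r$name[i]
  }
  out
}

#' Anchor point of a gaze target
#'
#' Center of the named AOI, or a configured off-AOI anchor (e.g. `DOWN`).
#' The agent-side target `STRAIGHT` maps to the agent AOI `A` (mutual-gaze
#' position).
#'
#' @param layout An [aoi_layout()].
#' @param target Target name.
#' @return `c(x, y)` in pixels.
#' @export
aoi_anchor <- function(layout, target) {
  stopifnot(inherits(layout, "aoi_layout"))
  if (target == "STRAIGHT") target <- "A"
  r <- layout$regions
  i <- match(target, r$name)
  if (!is.na(i)) {
    return(c((r$x0[i] + r$x1[i]) / 2, (r$y0[i] + r$y1[i]) / 2))
  }
  if (!is.null(layout$anchors[[target]])) {
    return(as.numeric(layout$anchors[[target]]))
  }
  stop_input("gaze target '%s' is not resolvable against the layout", target)
}
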