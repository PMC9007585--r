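#' Detect calcium transients and summarise oscillation metrics
#'
#' Local maxima of each normalised trace are kept when their topographic
#' prominence reaches `min_prominence`; of peaks closer than
#' `min_spacing_frames`, only the highest is retained. Peak duration is the
#' width at half prominence (linear interpolation between frames),
#' converted to seconds via the frame interval. Event frequency is
#' `60 * n_events / (n_frames * frame_interval_s)` per minute.
#'
#' @param ntraces a [normalize_traces()] result (operating on normalised
#'   traces makes the detection invariant to positive affine transforms of
#'   the raw fluorescence).
#' @param min_prominence minimum prominence, normalised units.
#' @param min_spacing_frames minimum spacing between retained peaks.
#' @return A list of class `spike_metrics`: `events` (cell_id, peak_frame
#'   1-based, height, prominence, duration_s), `summary` (cell_id,
#'   n_events, frequency_per_min, mean_height, mean_duration_s), plus the
#'   detection parameters and window label.
#' @export
detect_events <- function(ntraces, min_prominence = 0.2,
                          min_spacing_frames = 2) {
  x <- ntraces$values
  if (ncol(x) < 3) stop_isletconn("too_few_frames", "need >= 3 frames")
  dt <- ntraces$frame_interval_s
  ev <- lapply(seq_len(nrow(x)), function(i) {
    pk <- find_peaks(x[i, ], min_prominence, min_spacing_frames)
    if (nrow(pk) > 0) cbind(cell = i, pk) else NULL
  })
  ev <- do.call(rbind, ev)
  nf <- ncol(x)
  if (is.null(ev)) {
    events <- data.frame(cell_id = character(0), peak_frame = integer(0),
                         height = numeric(0), prominence = numeric(0),
                         duration_s = numeric(0))
  } else {
    events <- data.frame(cell_id = ntraces$cell_id[ev$cell],
                         peak_frame = ev$frame, height = ev$height,
                         prominence = ev$prominence,
                         duration_s = ev$width_frames * dt)
  }
  counts <- table(factor(events$cell_id, levels = ntraces$cell_id))
  summarise <- function(v, id) if (length(v) == 0) NA_real_ else mean(v)
  summary <- data.frame(
    cell_id = ntraces$cell_id,
    n_events = as.integer(counts),
    frequency_per_min = 60 * as.integer(counts) / (nf * dt),
    mean_height = vapply(ntraces$cell_id, function(id)
      summarise(events$height[events$cell_id == id]), numeric(1)),
    mean_duration_s = vapply(ntraces$cell_id, function(id)
      summarise(events$duration_s[events$cell_id == id]), numeric(1)),
    row.names = NULL)
  structure(list(events = events, summary = summary,
                 window = ntraces$window,
                 min_prominence = min_prominence,
                 min_spacing_frames = as.integer(min_spacing_frames)),
            class = "spike_metrics")
}

# local maxima (plateaus collapse to their first frame; trace endpoints
# are not peaks), with topographic prominence and half-prominence width
find_peaks <- function(x, min_prominence, min_spacing) {
  n <- length(x)
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1L || i == k) next
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]) {
      cand <- c(cand, starts[i])
    }
  }
  if (length(cand) == 0) {
    return(data.frame(frame = integer(0), height = numeric(0),
                      prominence = numeric(0), width_frames = numeric(0)))
  }
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1 && min_spacing > 1) {
    ord <- order(-x[cand], cand)       # highest first, earliest on ties
    selected <- logical(length(cand))
    taken <- integer(0)
    for (j in ord) {
      if (all(abs(cand[j] - taken) >= min_spacing)) {
        selected[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- cand[selected]; prom <- prom[selected]
  }
  o <- order(cand)
  cand <- cand[o]; prom <- prom[o]
  width <- vapply(seq_along(cand), function(j)
    half_prominence_width(x, cand[j], prom[j]), numeric(1))
  data.frame(frame = cand, height = x[cand], prominence = prom,
             width_frames = width)
}

# prominence: drop from the peak to the higher of the two key saddles
# (minima between the peak and the nearest higher ground on each side)
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- x[seq_len(p - 1)]
  higher_l <- which(left > h)
  lmin <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) + 1
                           else 1, to = p - 1)])
  right <- x[(p + 1):length(x)]
  higher_r <- which(right > h)
  rmin <- min(right[seq.int(from = 1,
                            to = if (length(higher_r)) min(higher_r) - 1
                            else length(right))])
  h - max(lmin, rmin)
}

# width (in frames) where the trace crosses height - prominence/2,
# linearly interpolated on both flanks
half_prominence_width <- function(x, p, prom) {
  level <- x[p] - prom / 2
  n <- length(x)
  li <- p
  while (li > 1 && x[li - 1] >= level && x[li - 1] <= x[li]) li <- li - 1
  left <- if (li > 1 && x[li - 1] < level) {
    (li - 1) + (level - x[li - 1]) / (x[li] - x[li - 1])
  } else li
  ri <- p
  while (ri < n && x[ri + 1] >= level && x[ri + 1] <= x[ri]) ri <- ri + 1
  right <- if (ri < n && x[ri + 1] < level) {
    ri + (x[ri] - level) / (x[ri] - x[ri + 1])
  } else ri
  max(right - left, .Machine$double.eps)
}

#' @export
print.spike_metrics <- function(x, ...) {
  cat("<spike_metrics>", nrow(x$events), "events across",
      nrow(x$summary), "cells, window", x$window, "\n")
  invisible(x)
}
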