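#' Normalize traces within one condition window
#'
#' Per-cell min-max scaling computed within the window only (default), so
#' each non-constant cell spans exactly \[0, 1\] there; constant cells map
#' to all-zeros and are flagged. Pearson correlation is unaffected by this
#' per-cell affine map; it matters for binarisation and peak heights.
#'
#' @param traces a [trace_set()].
#' @param window a window label present in `traces$windows`.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @param detrend remove a per-cell linear trend (least squares) before
#'   scaling; off by default.
#' @return A list of class `normalized_traces`: `values` (cells x frames),
#'   `window`, `frame_interval_s`, `cell_id`, `record` (per-cell scaling
#'   constants), `constant` (logical flag per cell).
#' @export
normalize_traces <- function(traces, window, method = c("minmax", "zscore"),
                             detrend = FALSE) {
  method <- match.arg(method)
  w <- traces$windows[traces$windows$label == window, , drop = FALSE]
  if (nrow(w) == 0) {
    stop_isletconn("unknown_window", "no window labelled '", window, "'")
  }
  fr <- (w$start_frame[1] + 1):w$end_frame[1]
  if (length(fr) < 2) stop_isletconn("window_too_short",
                                     "window needs >= 2 frames")
  x <- traces$fluorescence[, fr, drop = FALSE]
  if (isTRUE(detrend)) {
    t0 <- seq_len(ncol(x))
    x <- t(apply(x, 1, function(r) stats::lsfit(t0, r)$residuals))
  }
  if (method == "minmax") {
    lo <- apply(x, 1, min); hi <- apply(x, 1, max)
    constant <- (hi - lo) <= 0
    rng <- ifelse(constant, 1, hi - lo)
    values <- (x - lo) / rng
    values[constant, ] <- 0
    record <- data.frame(cell_id = traces$cell_id, min = lo, max = hi)
  } else {
    mu <- rowMeans(x); sdv <- apply(x, 1, stats::sd)
    constant <- sdv <= 0
    values <- (x - mu) / ifelse(constant, 1, sdv)
    values[constant, ] <- 0
    record <- data.frame(cell_id = traces$cell_id, mean = mu, sd = sdv)
  }
  structure(list(values = values, window = window,
                 frame_interval_s = traces$frame_interval_s,
                 cell_id = traces$cell_id,
                 method = method, record = record,
                 constant = as.logical(constant)),
            class = "normalized_traces")
}

#' Binarize normalized traces into active/silent states
#'
#' A frame is `active` where the normalised value exceeds `threshold`
#' (a fraction of the min-max range), `silent` otherwise; flagged-constant
#' cells are all-silent.
#'
#' @param ntraces a [normalize_traces()] result (min-max method).
#' @param threshold fraction of the normalised range in (0, 1);
#'   default 0.25.
#' @return A list of class `binary_states`: `states` (logical cells x
#'   frames matrix, `TRUE` = active), `threshold`, `window`, `cell_id`.
#' @export
binarize_traces <- function(ntraces, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_isletconn("bad_threshold", "threshold must be in (0, 1)")
  }
  states <- ntraces$values > threshold
  states[ntraces$constant, ] <- FALSE
  structure(list(states = states, threshold = threshold,
                 window = ntraces$window, cell_id = ntraces$cell_id,
                 frame_interval_s = ntraces$frame_interval_s),
            class = "binary_states")
}

#' Split a trace set by condition window
#'
#' @param traces a [trace_set()].
#' @return named list (window label -> [trace_set()] restricted to that
#'   window, carrying a single window record starting at frame 0).
#' @export
split_windows <- function(traces) {
  out <- list()
  for (i in seq_len(nrow(traces$windows))) {
    w <- traces$windows[i, ]
    fr <- (w$start_frame + 1):w$end_frame
    sub <- trace_set(traces$fluorescence[, fr, drop = FALSE],
                     frame_interval_s = traces$frame_interval_s,
                     windows = data.frame(label = w$label, start_frame = 0,
                                          end_frame = length(fr)),
                     cell_id = traces$cell_id)
    out[[as.character(w$label)]] <- sub
  }
  out
}
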