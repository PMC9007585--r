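#' Cell types recognised by the data model
#'
#' The closed vocabulary of cell-type labels: the three endocrine types
#' (beta, alpha, delta), peri-islet neurons, and "unknown" for islet cells
#' that could not be assigned a type.
#' @export
CELL_TYPES <- c("beta", "alpha", "delta", "neuron", "unknown")

#' Endocrine cell types
#' @export
ENDOCRINE_TYPES <- c("beta", "alpha", "delta")

#' Condition-window labels
#'
#' `LG` basal (low glucose), `HG` glucose-stimulated, `HGa` post-ablation,
#' `HGlambda` post-photoinhibition.
#' @export
WINDOW_LABELS <- c("LG", "HG", "HGa", "HGlambda")

#' Construct a validated per-cell table for one islet/animal
#'
#' The spatial skeleton of one imaged islet: one row per segmented cell with
#' its type label and 3D centroid in micrometres.
#'
#' @param animal_id single string identifying the animal/islet.
#' @param cell_id character vector, unique within the animal.
#' @param cell_type character vector drawn from [CELL_TYPES].
#' @param x_um,y_um,z_um finite numeric centroid coordinates (micrometres).
#' @param neuron_driven optional logical vector: ground-truth flag (used by
#'   the simulator) marking endocrine cells that receive neuron drive.
#' @return A `data.frame` of class `islet_cells`.
#' @export
islet_cells <- function(animal_id, cell_id, cell_type, x_um, y_um, z_um,
                        neuron_driven = NULL) {
  cells <- data.frame(
    animal_id = as.character(animal_id),
    cell_id = as.character(cell_id),
    cell_type = as.character(cell_type),
    x_um = as.numeric(x_um), y_um = as.numeric(y_um), z_um = as.numeric(z_um),
    stringsAsFactors = FALSE
  )
  if (!is.null(neuron_driven)) cells$neuron_driven <- as.logical(neuron_driven)
  class(cells) <- c("islet_cells", "data.frame")
  validate_islet_cells(cells)
}

#' @rdname islet_cells
#' @param cells an `islet_cells` object (or plain data.frame with its columns).
#' @export
validate_islet_cells <- function(cells) {
  required <- c("animal_id", "cell_id", "cell_type", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop_isletconn("missing_columns",
                   "cell table is missing columns: ",
                   paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cells$cell_id) > 0) {
    dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
    stop_isletconn("duplicate_cell_ids",
                   "duplicate cell_id within animal: ",
                   paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(cells$cell_type), CELL_TYPES)
  if (length(bad) > 0) {
    stop_isletconn("unknown_cell_type",
                   "cell_type not in {", paste(CELL_TYPES, collapse = ", "),
                   "}: ", paste(bad, collapse = ", "))
  }
  coords <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(coords))) {
    stop_isletconn("nonfinite_coordinates", "all coordinates must be finite")
  }
  if (length(unique(cells$animal_id)) > 1) {
    stop_isletconn("multiple_animals",
                   "a cell table holds exactly one animal_id")
  }
  if (!inherits(cells, "islet_cells")) {
    class(cells) <- c("islet_cells", class(cells))
  }
  cells
}

#' Construct a validated fluorescence trace set
#'
#' Raw fluorescence traces for the cells of one animal, cells as rows and
#' frames as columns, with the frame interval and labelled condition windows.
#' Row order must match the corresponding [islet_cells()] table.
#'
#' @param fluorescence numeric matrix (cells x frames), arbitrary units >= 0.
#' @param frame_interval_s frame interval in seconds (default 5, the
#'   acquisition interval of the imaging protocol this package targets).
#' @param windows data.frame with columns `label` (in [WINDOW_LABELS]),
#'   `start_frame`, `end_frame`; half-open 0-based frame ranges `[start, end)`,
#'   non-overlapping, each at least 2 frames.
#' @param cell_id character vector of row identities (same order as the cell
#'   table).
#' @return A list of class `trace_set` with elements `fluorescence`,
#'   `frame_interval_s`, `windows`, `cell_id`.
#' @export
trace_set <- function(fluorescence, frame_interval_s = 5, windows,
                      cell_id = rownames(fluorescence)) {
  fluorescence <- as.matrix(fluorescence)
  if (is.null(cell_id)) {
    cell_id <- paste0("cell", seq_len(nrow(fluorescence)))
  }
  ts <- structure(
    list(fluorescence = fluorescence,
         frame_interval_s = frame_interval_s,
         windows = as.data.frame(windows),
         cell_id = as.character(cell_id)),
    class = "trace_set"
  )
  validate_trace_set(ts)
}

#' @rdname trace_set
#' @param ts a `trace_set` object.
#' @export
validate_trace_set <- function(ts) {
  fl <- ts$fluorescence
  if (!is.matrix(fl) || !is.numeric(fl)) {
    stop_isletconn("bad_traces", "fluorescence must be a numeric matrix")
  }
  if (any(!is.finite(fl)) || any(fl < 0)) {
    stop_isletconn("bad_traces",
                   "fluorescence must be finite and non-negative")
  }
  if (length(ts$cell_id) != nrow(fl)) {
    stop_isletconn("trace_cell_mismatch",
                   "cell_id length (", length(ts$cell_id),
                   ") does not match trace rows (", nrow(fl), ")")
  }
  if (!is.numeric(ts$frame_interval_s) || ts$frame_interval_s <= 0) {
    stop_isletconn("bad_frame_interval", "frame_interval_s must be > 0")
  }
  w <- ts$windows
  required <- c("label", "start_frame", "end_frame")
  if (!all(required %in% names(w))) {
    stop_isletconn("missing_columns", "windows need columns: ",
                   paste(required, collapse = ", "))
  }
  if (nrow(w) > 0) {
    bad <- setdiff(unique(as.character(w$label)), WINDOW_LABELS)
    if (length(bad) > 0) {
      stop_isletconn("unknown_window_label", "window label not in {",
                     paste(WINDOW_LABELS, collapse = ", "), "}: ",
                     paste(bad, collapse = ", "))
    }
    if (any(w$start_frame < 0) || any(w$end_frame > ncol(fl))) {
      stop_isletconn("window_out_of_range",
                     "windows must lie within [0, n_frames)")
    }
    if (any(w$end_frame - w$start_frame < 2)) {
      stop_isletconn("window_too_short", "each window needs >= 2 frames")
    }
    o <- order(w$start_frame)
    if (any(w$start_frame[o][-1] < w$end_frame[o][-nrow(w)])) {
      stop_isletconn("overlapping_windows", "windows must not overlap")
    }
  }
  ts
}

#' Check that a cell table and a trace set describe the same cells
#'
#' @param cells an [islet_cells()] table.
#' @param traces a [trace_set()].
#' @return invisibly `TRUE`; raises a `trace_cell_mismatch` error otherwise.
#' @export
check_alignment <- function(cells, traces) {
  if (nrow(cells) != nrow(traces$fluorescence)) {
    stop_isletconn("trace_cell_mismatch",
                   "trace set has ", nrow(traces$fluorescence),
                   " rows but cell table has ", nrow(cells), " cells")
  }
  if (!identical(as.character(cells$cell_id), traces$cell_id)) {
    stop_isletconn("trace_cell_mismatch",
                   "cell_id order differs between cell table and traces")
  }
  invisible(TRUE)
}

#' Analysis configuration
#'
#' Houses the analysis constants that the correlation, binarisation,
#' distance-rank and peak-detection stages use, so that every output can
#' echo the exact settings it was produced under.
#'
#' @param connection_threshold correlation threshold above which an endocrine
#'   cell counts as having a neural activity connection (and above which
#'   graph edges are drawn); in (0, 1).
#' @param binarize_threshold active/silent threshold as a fraction of the
#'   normalised (min-max) range; in (0, 1).
#' @param n_ranks number of pairwise-distance rank bins (1 = closest).
#' @param min_prominence minimum peak prominence (normalised units) for
#'   transient detection.
#' @param min_spacing_frames minimum spacing between detected peaks, frames.
#' @param normalization `"minmax"` (default) or `"zscore"`.
#' @param detrend remove a per-cell linear trend before normalisation.
#' @param seed seed for any resampling (e.g. the shuffle guard).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(connection_threshold = 0.5,
                            binarize_threshold = 0.25,
                            n_ranks = 10,
                            min_prominence = 0.2,
                            min_spacing_frames = 2,
                            normalization = c("minmax", "zscore"),
                            detrend = FALSE,
                            seed = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(connection_threshold > 0, connection_threshold < 1,
            binarize_threshold > 0, binarize_threshold < 1,
            n_ranks >= 1, min_prominence > 0, min_spacing_frames >= 1)
  structure(list(connection_threshold = connection_threshold,
                 binarize_threshold = binarize_threshold,
                 n_ranks = as.integer(n_ranks),
                 min_prominence = min_prominence,
                 min_spacing_frames = as.integer(min_spacing_frames),
                 normalization = normalization,
                 detrend = isTRUE(detrend),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @export
print.islet_cells <- function(x, ...) {
  tab <- table(factor(x$cell_type, levels = CELL_TYPES))
  cat("<islet_cells> animal", unique(x$animal_id), "-", nrow(x), "cells (",
      paste(paste0(names(tab), ":", as.integer(tab)), collapse = " "), ")\n")
  invisible(x)
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", nrow(x$fluorescence), "cells x", ncol(x$fluorescence),
      "frames @", x$frame_interval_s, "s/frame\n")
  if (nrow(x$windows) > 0) {
    cat("  windows:",
        paste(sprintf("%s [%d,%d)", x$windows$label, x$windows$start_frame,
                      x$windows$end_frame), collapse = ", "), "\n")
  }
  invisible(x)
}

# condition-prefixed errors so callers can distinguish validation failures
stop_isletconn <- function(class, ...) {
  stop(structure(class = c(paste0("isletconn_", class), "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
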