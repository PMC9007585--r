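#' Pairwise Pearson correlation matrix of cell activity
#'
#' Pearson product-moment correlation between all cell pairs within one
#' condition window, computed on normalised traces (the per-cell affine
#' normalisation leaves Pearson correlation unchanged). Constant-trace
#' cells have undefined correlations; their entries are recorded as `NA`
#' and excluded from all downstream averages.
#'
#' @param ntraces a [normalize_traces()] result.
#' @param cells optional [islet_cells()] table supplying type annotations.
#' @return A list of class `correlation_result`: `R` (symmetric matrix,
#'   unit diagonal), `window`, `cell_id`, `cell_type`.
#' @export
correlation_matrix <- function(ntraces, cells = NULL) {
  x <- ntraces$values
  if (nrow(x) < 2) stop_isletconn("too_few_cells", "need >= 2 cells")
  if (ncol(x) < 3) stop_isletconn("too_few_frames", "need >= 3 frames")
  R <- suppressWarnings(stats::cor(t(x)))
  if (any(ntraces$constant)) {
    R[ntraces$constant, ] <- NA_real_
    R[, ntraces$constant] <- NA_real_
  }
  diag(R) <- 1
  R <- (R + t(R)) / 2   # enforce exact symmetry against rounding
  dimnames(R) <- NULL
  ct <- if (!is.null(cells)) {
    if (!identical(as.character(cells$cell_id), ntraces$cell_id)) {
      stop_isletconn("trace_cell_mismatch",
                     "cell table does not match trace rows")
    }
    as.character(cells$cell_type)
  } else rep("unknown", nrow(x))
  structure(list(R = R, window = ntraces$window,
                 cell_id = ntraces$cell_id, cell_type = ct),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result>", nrow(x$R), "cells, window", x$window, "\n")
  invisible(x)
}

# row indices of valid (typed, non-constant) cells of a given type
cells_of_type <- function(corr, type) {
  which(corr$cell_type == type)
}

# unordered distinct index pairs (i < j) of composition type_a-type_b
composition_pairs <- function(corr, type_a, type_b) {
  ia <- cells_of_type(corr, type_a)
  ib <- cells_of_type(corr, type_b)
  if (type_a == type_b) {
    if (length(ia) < 2) return(cbind(i = integer(0), j = integer(0)))
    cmb <- utils::combn(ia, 2)
    cbind(i = cmb[1, ], j = cmb[2, ])
  } else {
    g <- expand.grid(i = ia, j = ib)
    cbind(i = g$i, j = g$j)
  }
}

#' Average correlation coefficient (R_avg) for one type pair
#'
#' The arithmetic mean of R over all unordered distinct pairs of the given
#' type composition, the standard coupling summary for islet recordings.
#' `unknown`-type cells are excluded from typed summaries (but remain in
#' the full matrix); pairs involving constant-trace cells are dropped.
#'
#' @param corr a [correlation_matrix()] result with type annotations.
#' @param type_a,type_b cell types (e.g. `"beta","beta"` for homotypic
#'   beta coupling).
#' @return scalar R_avg (`NA` when no valid pair exists), with attribute
#'   `n_pairs` (number of valid pairs averaged).
#' @export
r_avg <- function(corr, type_a, type_b) {
  idx <- composition_pairs(corr, type_a, type_b)
  vals <- corr$R[idx]
  vals <- vals[!is.na(vals)]
  structure(if (length(vals) == 0) NA_real_ else mean(vals),
            n_pairs = length(vals))
}

#' Per-type-pair R_avg summary table
#'
#' @param corr a [correlation_matrix()] result.
#' @param animal_id optional id column for cohort-level stacking.
#' @return data.frame: `animal_id`, `window`, `type_pair`, `r_avg`,
#'   `n_pairs`, one row per endocrine type pair plus `neuron-X` couplings.
#' @export
r_avg_summary <- function(corr, animal_id = NA_character_) {
  tp <- type_pairs(ENDOCRINE_TYPES)
  rows <- lapply(seq_len(nrow(tp)), function(k) {
    v <- r_avg(corr, tp$type_a[k], tp$type_b[k])
    data.frame(animal_id = animal_id, window = corr$window,
               type_pair = paste(tp$type_a[k], tp$type_b[k], sep = "-"),
               r_avg = as.numeric(v), n_pairs = attr(v, "n_pairs"))
  })
  # neuron-endocrine couplings, when neurons were imaged
  if (any(corr$cell_type == "neuron")) {
    for (t2 in ENDOCRINE_TYPES) {
      v <- r_avg(corr, "neuron", t2)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = animal_id, window = corr$window,
        type_pair = paste("neuron", t2, sep = "-"),
        r_avg = as.numeric(v), n_pairs = attr(v, "n_pairs"))
    }
  }
  do.call(rbind, rows)
}

#' Classify endocrine cells with neural activity connection
#'
#' An endocrine cell counts as connected when its best correlation with
#' any imaged peri-islet neuron reaches `threshold`. Optionally a
#' significance guard additionally requires the observed best correlation
#' to beat the `1 - alpha` quantile of a circular-shift null built from
#' the cell's own trace.
#'
#' @param corr a [correlation_matrix()] result.
#' @param threshold correlation criterion (default 0.5).
#' @param ntraces normalised traces; only required when `shuffle_guard`.
#' @param shuffle_guard enable the circular-shift significance guard.
#' @param n_shifts,alpha guard parameters (default 1000 shifts, 0.05).
#' @param seed seed for the guard's random shifts.
#' @return A list of class `neural_connection`: `labels` (data.frame
#'   `cell_id`, `cell_type`, `connected`, `best_neuron_r`),
#'   `percent_connected` (per endocrine type, normalised to the number of
#'   cells of that type imaged), `threshold`. When no neuron is present,
#'   an object with `no_neurons = TRUE` and empty labels.
#' @export
classify_neural_connection <- function(corr, threshold = 0.5,
                                       ntraces = NULL,
                                       shuffle_guard = FALSE,
                                       n_shifts = 1000, alpha = 0.05,
                                       seed = 1L) {
  neuron_rows <- which(corr$cell_type == "neuron")
  endo_rows <- which(corr$cell_type %in% ENDOCRINE_TYPES)
  if (length(neuron_rows) == 0) {
    return(structure(list(no_neurons = TRUE,
                          labels = data.frame(cell_id = character(0),
                                              cell_type = character(0),
                                              connected = logical(0),
                                              best_neuron_r = numeric(0)),
                          percent_connected = NULL,
                          threshold = threshold),
                     class = "neural_connection"))
  }
  best <- apply(corr$R[endo_rows, neuron_rows, drop = FALSE], 1,
                function(v) if (all(is.na(v))) NA_real_ else max(v,
                                                                 na.rm = TRUE))
  connected <- !is.na(best) & best >= threshold
  if (isTRUE(shuffle_guard)) {
    if (is.null(ntraces)) {
      stop_isletconn("missing_traces",
                     "shuffle_guard needs the normalised traces")
    }
    crit <- shift_null_quantile(ntraces, endo_rows, neuron_rows,
                                n_shifts, alpha, seed)
    connected <- connected & !is.na(best) & best >= crit
  }
  labels <- data.frame(cell_id = corr$cell_id[endo_rows],
                       cell_type = corr$cell_type[endo_rows],
                       connected = connected, best_neuron_r = best)
  pct <- vapply(ENDOCRINE_TYPES, function(tp) {
    n_obs <- sum(labels$cell_type == tp)
    if (n_obs == 0) return(NA_real_)
    100 * sum(labels$connected[labels$cell_type == tp]) / n_obs
  }, numeric(1))
  structure(list(no_neurons = FALSE, labels = labels,
                 percent_connected = pct, threshold = threshold),
            class = "neural_connection")
}

# per-cell (1 - alpha) quantile of max-over-neurons correlation under
# random circular shifts of the endocrine trace
shift_null_quantile <- function(ntraces, endo_rows, neuron_rows,
                                n_shifts, alpha, seed) {
  set.seed(seed)
  x <- ntraces$values
  nf <- ncol(x)
  nt <- t(x[neuron_rows, , drop = FALSE])
  vapply(endo_rows, function(i) {
    shifts <- sample.int(nf - 1, min(n_shifts, nf - 1), replace =
                           n_shifts > nf - 1)
    null_max <- vapply(shifts, function(s) {
      xs <- x[i, c((s + 1):nf, 1:s)]
      max(suppressWarnings(stats::cor(xs, nt)), na.rm = TRUE)
    }, numeric(1))
    stats::quantile(null_max, 1 - alpha, names = FALSE, na.rm = TRUE)
  }, numeric(1))
}

#' Homotypic coupling split by neural-connection status
#'
#' For one endocrine type, the mean homotypic correlation is computed
#' separately for cells with and without a neural connection: each cell of
#' the type indexes all its homotypic pairs (the partner may have either
#' status), and pairs are averaged within the index cell's group. The two
#' values per animal are suitable for a paired test across animals.
#'
#' @param corr a [correlation_matrix()] result.
#' @param labels a [classify_neural_connection()] result.
#' @param type endocrine type.
#' @return data.frame with one row: `type`, `r_avg_connected`,
#'   `r_avg_unconnected`, `n_connected`, `n_unconnected` (cell counts);
#'   group means are `NA` when the group is empty.
#' @export
split_homotypic_by_connection <- function(corr, labels, type) {
  rows <- cells_of_type(corr, type)
  lab <- labels$labels
  status <- lab$connected[match(corr$cell_id[rows], lab$cell_id)]
  group_mean <- function(want) {
    idx <- rows[which(status == want)]
    if (length(idx) == 0 || length(rows) < 2) return(NA_real_)
    vals <- unlist(lapply(idx, function(i) {
      partners <- setdiff(rows, i)
      corr$R[i, partners]
    }))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  data.frame(type = type,
             r_avg_connected = group_mean(TRUE),
             r_avg_unconnected = group_mean(FALSE),
             n_connected = sum(status, na.rm = TRUE),
             n_unconnected = sum(!status, na.rm = TRUE))
}

#' Build a thresholded connectivity graph
#'
#' Nodes are valid (non-constant) cells with their positions, types and
#' degrees; edges are exactly the pairs with `R >= threshold` (self-edges
#' excluded), weighted by R — the structure drawn in islet connectivity
#' maps (line shade = correlation strength, circle size = degree).
#'
#' @param corr a [correlation_matrix()] result.
#' @param cells the matching [islet_cells()] table.
#' @param threshold edge criterion on R.
#' @return A list of class `connectivity_graph`: `nodes` (cell_id, type,
#'   x/y/z, degree), `edges` (cell_a, cell_b, r), `threshold`.
#' @export
build_graph <- function(corr, cells, threshold) {
  check <- identical(as.character(cells$cell_id), corr$cell_id)
  if (!check) stop_isletconn("trace_cell_mismatch",
                             "cell table does not match correlation rows")
  n <- nrow(corr$R)
  idx <- which(upper.tri(corr$R), arr.ind = TRUE)
  keep <- !is.na(corr$R[idx]) & corr$R[idx] >= threshold
  idx <- idx[keep, , drop = FALSE]
  edges <- data.frame(cell_a = corr$cell_id[idx[, 1]],
                      cell_b = corr$cell_id[idx[, 2]],
                      r = corr$R[idx])
  degree <- tabulate(c(idx[, 1], idx[, 2]), nbins = n)
  nodes <- data.frame(cell_id = corr$cell_id,
                      cell_type = corr$cell_type,
                      x_um = cells$x_um, y_um = cells$y_um,
                      z_um = cells$z_um, degree = degree)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "connectivity_graph")
}
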