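#' Read a cell table, trace matrix and window annotation from CSV files
#'
#' Expected schemas (one header row each):
#' * `cells.csv`: `animal_id, cell_id, cell_type, x_um, y_um, z_um`
#'   (optional `neuron_driven` for simulated data)
#' * `traces.csv`: `cell_id`, then one column per frame (`f0000, f0001, ...`),
#'   cells as rows in the same order as the cell table
#' * `windows.csv`: `label, start_frame, end_frame` (half-open, 0-based)
#'
#' @param cells_path,traces_path,windows_path file paths.
#' @return A list with elements `cells` ([islet_cells()]) and `traces`
#'   ([trace_set()]), validated and mutually aligned.
#' @export
read_islet_dataset <- function(cells_path, traces_path, windows_path) {
  for (p in c(cells_path, traces_path, windows_path)) {
    if (!file.exists(p)) stop_isletconn("missing_file", "no such file: ", p)
  }
  cdf <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  cells <- validate_islet_cells(cdf)

  tdf <- utils::read.csv(traces_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"cell_id" %in% names(tdf)) {
    stop_isletconn("missing_columns", "traces.csv needs a cell_id column")
  }
  frame_cols <- grep("^f[0-9]+$", names(tdf), value = TRUE)
  if (length(frame_cols) == 0) {
    stop_isletconn("missing_columns",
                   "traces.csv needs frame columns f0000, f0001, ...")
  }
  fl <- as.matrix(tdf[, frame_cols, drop = FALSE])
  rownames(fl) <- NULL

  wdf <- utils::read.csv(windows_path, stringsAsFactors = FALSE)
  meta_path <- sub("\\.csv$", "_meta.json", traces_path)
  interval <- 5
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$frame_interval_s)) interval <- meta$frame_interval_s
  }
  traces <- trace_set(fl, frame_interval_s = interval, windows = wdf,
                      cell_id = tdf$cell_id)
  check_alignment(cells, traces)
  list(cells = cells, traces = traces)
}

#' Write one simulated/loaded dataset as the CSV file set
#'
#' Writes `cells.csv`, `traces.csv`, `windows.csv` and a
#' `traces_meta.json` sidecar (frame interval, package version) into `dir`.
#'
#' @param cells,traces as returned by [read_islet_dataset()] or the simulator.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_islet_dataset <- function(cells, traces, dir) {
  check_alignment(cells, traces)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cells.csv", "traces.csv", "windows.csv",
                            "traces_meta.json"))
  write_table_precise(as.data.frame(unclass(cells)), paths[1])
  fl <- traces$fluorescence
  tdf <- data.frame(cell_id = traces$cell_id, stringsAsFactors = FALSE)
  colnames(fl) <- sprintf("f%04d", seq_len(ncol(fl)) - 1)
  tdf <- cbind(tdf, as.data.frame(fl))
  write_table_precise(tdf, paths[2])
  write_table_precise(traces$windows, paths[3])
  jsonlite::write_json(
    list(frame_interval_s = traces$frame_interval_s,
         package_version = as.character(utils::packageVersion("isletconn"))),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write an analysis result as delimited text with a metadata sidecar
#'
#' Every result table is written as CSV at full double precision, together
#' with a `<name>_meta.json` sidecar recording the result class, the
#' analysis settings it was produced under, and the package version, so a
#' written result round-trips losslessly through [read_islet_results()].
#'
#' @param x a result object (`correlation_result`, `fraction_time_result`,
#'   `distance_coupling`, `spike_metrics`, `comparison_result`,
#'   `connectivity_graph`, or a plain data.frame).
#' @param dir output directory.
#' @param name base file name (defaults to the result class).
#' @param config optional [analysis_config()] echoed into the sidecar.
#' @return invisibly, a character vector of files written (the manifest).
#' @export
write_islet_results <- function(x, dir, name = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  UseMethod("write_islet_results")
}

result_sidecar <- function(dir, name, x, config, extra = list()) {
  meta <- c(list(class = class(x)[1],
                 package_version =
                   as.character(utils::packageVersion("isletconn")),
                 config = config_as_list(config)),
            extra)
  p <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, null = "null")
  p
}

config_as_list <- function(config) {
  if (is.null(config)) return(NULL)
  lapply(unclass(config), function(v) v)
}

#' @export
write_islet_results.correlation_result <- function(x, dir, name = NULL,
                                                   config = NULL) {
  name <- name %||% paste0("corr_matrix_", x$window)
  mat_path <- file.path(dir, paste0(name, ".csv"))
  m <- as.data.frame(x$R)
  names(m) <- x$cell_id
  write_table_precise(cbind(data.frame(cell_id = x$cell_id), m), mat_path)
  meta <- result_sidecar(dir, name, x, config,
                         list(window = x$window,
                              cell_type = as.list(x$cell_type)))
  invisible(c(mat_path, meta))
}

#' @export
write_islet_results.fraction_time_result <- function(x, dir, name = NULL,
                                                     config = NULL) {
  name <- name %||% "fraction_time"
  p <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(x$fractions, p)
  meta <- result_sidecar(dir, name, x, config,
                         list(window = x$window, n_frames = x$n_frames))
  invisible(c(p, meta))
}

#' @export
write_islet_results.distance_coupling <- function(x, dir, name = NULL,
                                                  config = NULL) {
  name <- name %||% "distance_coupling"
  p1 <- file.path(dir, paste0(name, "_pairs.csv"))
  p2 <- file.path(dir, paste0(name, "_ranks.csv"))
  write_table_precise(x$pairs, p1)
  write_table_precise(x$rank_means, p2)
  meta <- result_sidecar(dir, name, x, config,
                         list(type_pair = x$type_pair, n_ranks = x$n_ranks,
                              window = x$window))
  invisible(c(p1, p2, meta))
}

#' @export
write_islet_results.data.frame <- function(x, dir, name = NULL,
                                           config = NULL) {
  name <- name %||% "table"
  p <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(x, p)
  meta <- result_sidecar(dir, name, x, config)
  invisible(c(p, meta))
}

#' @export
write_islet_results.spike_metrics <- function(x, dir, name = NULL,
                                              config = NULL) {
  name <- name %||% "spike_metrics"
  p1 <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(x$summary, p1)
  p2 <- file.path(dir, paste0(name, "_events.csv"))
  write_table_precise(x$events, p2)
  meta <- result_sidecar(dir, name, x, config,
                         list(window = x$window,
                              min_prominence = x$min_prominence,
                              min_spacing_frames = x$min_spacing_frames))
  invisible(c(p1, p2, meta))
}

#' @export
write_islet_results.connectivity_graph <- function(x, dir, name = NULL,
                                                   config = NULL) {
  name <- name %||% "graph"
  p1 <- file.path(dir, paste0(name, "_nodes.csv"))
  p2 <- file.path(dir, paste0(name, "_edges.csv"))
  write_table_precise(x$nodes, p1)
  write_table_precise(x$edges, p2)
  meta <- result_sidecar(dir, name, x, config,
                         list(threshold = x$threshold))
  invisible(c(p1, p2, meta))
}

#' @export
write_islet_results.comparison_result <- function(x, dir, name = NULL,
                                                  config = NULL) {
  name <- name %||% "comparisons"
  p <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(x$contrasts, p)
  meta <- result_sidecar(dir, name, x, config,
                         list(test = x$test, adjust = x$adjust))
  invisible(c(p, meta))
}

#' Read back a result written by [write_islet_results()]
#'
#' @param dir directory holding the files.
#' @param name the base name used when writing.
#' @return the reconstructed object (class restored from the sidecar).
#' @export
read_islet_results <- function(dir, name) {
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  if (!file.exists(meta_path)) {
    stop_isletconn("missing_file", "no sidecar: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cls <- meta$class
  if (identical(cls, "correlation_result")) {
    df <- utils::read.csv(file.path(dir, paste0(name, ".csv")),
                          check.names = FALSE)
    R <- as.matrix(df[, -1, drop = FALSE])
    dimnames(R) <- NULL
    structure(list(R = R, window = meta$window, cell_id = df$cell_id,
                   cell_type = unlist(meta$cell_type)),
              class = "correlation_result")
  } else if (identical(cls, "fraction_time_result")) {
    structure(list(fractions = utils::read.csv(
                     file.path(dir, paste0(name, ".csv"))),
                   window = meta$window, n_frames = meta$n_frames),
              class = "fraction_time_result")
  } else if (identical(cls, "distance_coupling")) {
    structure(list(pairs = utils::read.csv(
                     file.path(dir, paste0(name, "_pairs.csv"))),
                   rank_means = utils::read.csv(
                     file.path(dir, paste0(name, "_ranks.csv"))),
                   type_pair = unlist(meta$type_pair),
                   n_ranks = meta$n_ranks, window = meta$window),
              class = "distance_coupling")
  } else {
    utils::read.csv(file.path(dir, paste0(name, ".csv")))
  }
}

# CSV writer preserving full double precision (%.17g survives a
# write/read round trip bit-exactly)
write_table_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
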