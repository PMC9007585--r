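#' Distance of every islet cell to the islet core
#'
#' The core is the unweighted centroid of all islet (non-neuron) cell
#' positions; distances are 3D Euclidean, in micrometres. Per-type mean and
#' SEM summarise the core/mantle architecture (beta cells central, alpha
#' cells peripheral).
#'
#' @param cells an [islet_cells()] table.
#' @return A list of class `core_distance`: `per_cell` (cell_id, cell_type,
#'   distance_um), `per_type` (cell_type, mean_um, sem_um, n), `core`
#'   (3-vector).
#' @export
distance_to_core <- function(cells) {
  endo <- cells$cell_type != "neuron"
  if (!any(endo)) stop_isletconn("no_endocrine_cells",
                                 "no endocrine cells in table")
  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  core <- colMeans(pos[endo, , drop = FALSE])
  d <- sqrt(rowSums(sweep(pos, 2, core)^2))
  per_cell <- data.frame(cell_id = cells$cell_id,
                         cell_type = cells$cell_type, distance_um = d)
  agg <- lapply(split(d[endo], cells$cell_type[endo]), function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  per_type <- data.frame(cell_type = names(agg),
                         mean_um = vapply(agg, `[[`, numeric(1), "mean"),
                         sem_um = vapply(agg, `[[`, numeric(1), "sem"),
                         n = vapply(agg, `[[`, numeric(1), "n"),
                         row.names = NULL)
  structure(list(per_cell = per_cell, per_type = per_type, core = core),
            class = "core_distance")
}

#' Rank cell pairs by physical distance and attach their correlations
#'
#' All unordered pairs of the requested type composition are ranked by 3D
#' Euclidean distance within the animal and split into `n_ranks`
#' (near-)equal-count quantile bins, 1 = closest, `n_ranks` = farthest —
#' the per-animal distance axis of coupling-versus-distance plots. Ties are
#' broken by the stable pair ordering (row order of the cell table).
#'
#' @param cells an [islet_cells()] table.
#' @param corr the matching [correlation_matrix()] result.
#' @param type_a,type_b pair composition (e.g. beta, beta).
#' @param n_ranks number of bins (default 10). If there are fewer pairs
#'   than ranks, the number of ranks is reduced with a warning and the
#'   reduction is recorded in the result.
#' @return A list of class `distance_coupling`: `pairs` (cell_a, cell_b,
#'   type_pair, distance_um, rank, r), `rank_means` (rank, mean_r,
#'   mean_distance_um, n_pairs), `type_pair`, `n_ranks`, `window`.
#' @export
rank_distances <- function(cells, corr, type_a, type_b, n_ranks = 10) {
  if (!identical(as.character(cells$cell_id), corr$cell_id)) {
    stop_isletconn("trace_cell_mismatch",
                   "cell table does not match correlation rows")
  }
  idx <- composition_pairs(corr, type_a, type_b)
  if (nrow(idx) == 0) {
    stop_isletconn("too_few_pairs", "no pairs of composition ",
                   type_a, "-", type_b)
  }
  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  d <- sqrt(rowSums((pos[idx[, 1], , drop = FALSE] -
                       pos[idx[, 2], , drop = FALSE])^2))
  r <- corr$R[idx]
  keep <- !is.na(r)
  idx <- idx[keep, , drop = FALSE]; d <- d[keep]; r <- r[keep]
  n <- length(d)
  if (n < n_ranks) {
    warning("only ", n, " valid pairs; reducing ranks from ", n_ranks,
            " to ", n)
    n_ranks <- n
  }
  if (n_ranks < 1) stop_isletconn("too_few_pairs", "no valid pairs")
  ord <- order(d)                       # stable: ties keep pair order
  rank <- integer(n)
  rank[ord] <- floor((seq_len(n) - 1) * n_ranks / n) + 1L
  pairs <- data.frame(cell_a = corr$cell_id[idx[, 1]],
                      cell_b = corr$cell_id[idx[, 2]],
                      type_pair = paste(type_a, type_b, sep = "-"),
                      distance_um = d, rank = rank, r = r)
  agg <- split(seq_len(n), rank)
  rank_means <- data.frame(
    rank = as.integer(names(agg)),
    mean_r = vapply(agg, function(i) mean(r[i]), numeric(1)),
    mean_distance_um = vapply(agg, function(i) mean(d[i]), numeric(1)),
    n_pairs = lengths(agg), row.names = NULL)
  structure(list(pairs = pairs, rank_means = rank_means,
                 type_pair = c(type_a, type_b), n_ranks = n_ranks,
                 window = corr$window),
            class = "distance_coupling")
}

#' Compare coupling-versus-distance regressions between two groups
#'
#' Fits ordinary least squares of mean R on distance rank for each group
#' and tests for a slope difference and, under a common slope, for an
#' elevation (intercept) difference — the classic two-phase comparison of
#' simple linear regressions.
#'
#' Two comparison methods are provided. `"animal"` (default) summarises
#' each animal by its own OLS slope and by its elevation (mean R across its
#' ranks, i.e. the fitted value at the centre of the rank axis), then
#' compares groups by two-sample t-tests on these per-animal summaries;
#' because each animal contributes one observation per test, the test is
#' calibrated when animals are the independent units. `"pooled"` fits
#' group-wise OLS to all animal-by-rank points and tests the
#' slope-by-group interaction, then the group term in the common-slope
#' model — the comparison as typically run in graphing software, which
#' treats every point as independent.
#'
#' @param group_a,group_b each a list of [rank_distances()] results (one
#'   per animal) or a data.frame with columns `animal_id`, `rank`,
#'   `mean_r`.
#' @param labels group names.
#' @param method `"animal"` (default) or `"pooled"`; see Details.
#' @return A list of class `coupling_regression`: `fits` (per group:
#'   slope, intercept, 95% CIs), `p_slope`, `p_elevation`, `method`,
#'   `data` (the rank-mean points used).
#' @export
coupling_regression <- function(group_a, group_b = NULL,
                                labels = c("A", "B"),
                                method = c("animal", "pooled")) {
  method <- match.arg(method)
  da <- rank_points(group_a, labels[1])
  db <- if (!is.null(group_b)) rank_points(group_b, labels[2]) else NULL
  pts <- rbind(da, db)
  if (length(unique(pts$rank)) < 3) {
    stop_isletconn("too_few_ranks", "need >= 3 distance ranks")
  }
  fits <- do.call(rbind, lapply(split(pts, pts$group), function(g) {
    fit <- stats::lm(mean_r ~ rank, data = g)
    ci <- stats::confint(fit)
    data.frame(group = g$group[1],
               slope = stats::coef(fit)[["rank"]],
               slope_lo = ci["rank", 1], slope_hi = ci["rank", 2],
               intercept = stats::coef(fit)[["(Intercept)"]],
               intercept_lo = ci["(Intercept)", 1],
               intercept_hi = ci["(Intercept)", 2],
               row.names = NULL)
  }))
  p_slope <- NA_real_; p_elev <- NA_real_
  if (!is.null(db)) {
    if (method == "pooled") {
      full <- stats::lm(mean_r ~ rank * group, data = pts)
      p_slope <- stats::coef(summary(full))["rank:group" %p%
                                              sort(unique(pts$group))[2],
                                            "Pr(>|t|)"]
      common <- stats::lm(mean_r ~ rank + group, data = pts)
      p_elev <- stats::coef(summary(common))["group" %p%
                                               sort(unique(pts$group))[2],
                                             "Pr(>|t|)"]
    } else {
      per_animal <- lapply(split(pts, interaction(pts$group,
                                                  pts$animal_id,
                                                  drop = TRUE)),
                           function(g) {
        fit <- stats::lm(mean_r ~ rank, data = g)
        data.frame(group = g$group[1], animal_id = g$animal_id[1],
                   slope = stats::coef(fit)[["rank"]],
                   elevation = mean(g$mean_r))
      })
      pa <- do.call(rbind, per_animal)
      sa <- split(pa, pa$group)
      p_slope <- stats::t.test(sa[[1]]$slope, sa[[2]]$slope,
                               var.equal = TRUE)$p.value
      p_elev <- stats::t.test(sa[[1]]$elevation, sa[[2]]$elevation,
                              var.equal = TRUE)$p.value
    }
  }
  structure(list(fits = fits, p_slope = as.numeric(p_slope),
                 p_elevation = as.numeric(p_elev), method = method,
                 data = pts),
            class = "coupling_regression")
}

`%p%` <- function(a, b) paste0(a, b)

# normalise group input to (animal_id, rank, mean_r, group)
rank_points <- function(group, label) {
  if (is.data.frame(group)) {
    stopifnot(all(c("animal_id", "rank", "mean_r") %in% names(group)))
    df <- group[, c("animal_id", "rank", "mean_r")]
  } else {
    df <- do.call(rbind, lapply(seq_along(group), function(i) {
      dc <- group[[i]]
      data.frame(animal_id = names(group)[i] %||% sprintf("a%02d", i),
                 rank = dc$rank_means$rank, mean_r = dc$rank_means$mean_r)
    }))
  }
  df$group <- label
  df
}

#' @export
print.coupling_regression <- function(x, ...) {
  cat("<coupling_regression> method:", x$method, "\n")
  print(x$fits, row.names = FALSE)
  if (!is.na(x$p_slope)) {
    cat(sprintf("p(slope diff) = %.4g, p(elevation diff) = %.4g\n",
                x$p_slope, x$p_elevation))
  }
  invisible(x)
}
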