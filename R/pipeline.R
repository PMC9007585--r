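#' Run the full islet-connectivity pipeline on a simulated cohort
#'
#' Orchestrates simulate -> preprocess -> connectivity -> spatial ->
#' fraction-time -> spike metrics for every animal and window, optionally
#' against a second (perturbed) cohort, and writes every stage's tables
#' plus a JSON run manifest. All randomness derives from `seed`, so a
#' rerun with the same arguments reproduces every CSV byte-identically.
#'
#' @param config a [simulation_config()].
#' @param analysis an [analysis_config()].
#' @param n_animals animals per cohort.
#' @param out_dir output directory.
#' @param perturbed also simulate a perturbed cohort (using
#'   `config$perturbation_factor` and `config$perturbation_mode`) and add
#'   group comparisons (beta-beta R_avg contrast, coupling-regression
#'   elevation test).
#' @param seed master seed (default `config$seed`).
#' @param make_figures render diagnostic figures (trace raster,
#'   correlation heat map, connectivity map, distance-coupling fit,
#'   fraction-time summary) as PNG files for the first animal.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_islet_pipeline <- function(config = simulation_config(),
                               analysis = analysis_config(),
                               n_animals = 4, out_dir,
                               perturbed = FALSE,
                               seed = config$seed,
                               make_figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stages <- character(0)
  cohorts <- list(intact = make_cohort(config, n_animals,
                                       perturbed = FALSE, seed = seed))
  if (perturbed) {
    cohorts$perturbed <- make_cohort(config, n_animals, perturbed = TRUE,
                                     seed = seed + 1L)
  }
  stages <- c(stages, "simulate")

  ravg_rows <- list(); ft_rows <- list(); spike_rows <- list()
  nc_rows <- list(); dc_by_group <- list()

  for (grp in names(cohorts)) {
    for (i in seq_along(cohorts[[grp]])) {
      an <- cohorts[[grp]][[i]]
      aid <- paste0(grp, "_", unique(an$cells$animal_id))
      adir <- file.path(out_dir, aid)
      files <- c(files, write_islet_dataset(an$cells, an$traces, adir))
      for (wlab in unique(an$traces$windows$label)) {
        nt <- normalize_traces(an$traces, wlab,
                               method = analysis$normalization,
                               detrend = analysis$detrend)
        corr <- correlation_matrix(nt, an$cells)
        files <- c(files,
                   write_islet_results(corr, adir, config = analysis))
        ravg_rows[[length(ravg_rows) + 1]] <-
          cbind(group = grp, r_avg_summary(corr, animal_id = aid))
        if (any(an$cells$cell_type == "neuron")) {
          nc <- classify_neural_connection(
            corr, threshold = analysis$connection_threshold)
          if (nrow(nc$labels) > 0) {
            nc_rows[[length(nc_rows) + 1]] <-
              cbind(group = grp, animal_id = aid, window = wlab,
                    nc$labels)
          }
        }
        bb <- tryCatch(
          rank_distances(an$cells, corr, "beta", "beta",
                         n_ranks = analysis$n_ranks),
          error = function(e) NULL)
        if (!is.null(bb)) {
          dc_by_group[[grp]] <- c(dc_by_group[[grp]],
                                  stats::setNames(list(bb), aid))
          files <- c(files, write_islet_results(
            bb, adir, name = paste0("distance_coupling_", wlab),
            config = analysis))
        }
        bstates <- binarize_traces(nt, analysis$binarize_threshold)
        for (tp in list(c("delta", "beta"), c("alpha", "delta"),
                        c("alpha", "beta"))) {
          prs <- nearest_pairs(an$cells, tp[1], tp[2])
          if (nrow(prs) > 0) {
            ft <- fraction_time(bstates, prs)
            ft_rows[[length(ft_rows) + 1]] <-
              cbind(group = grp, animal_id = aid, window = wlab,
                    ft$fractions)
          }
        }
        sm <- detect_events(nt, analysis$min_prominence,
                            analysis$min_spacing_frames)
        spike_rows[[length(spike_rows) + 1]] <-
          cbind(group = grp, animal_id = aid, window = wlab,
                cell_type = an$cells$cell_type, sm$summary)
      }
      if (make_figures && i == 1) {
        files <- c(files, render_figures(an, analysis, adir))
      }
    }
  }
  stages <- c(stages, "preprocess", "connectivity", "spatial",
              "fraction_time", "spike_metrics")

  ravg <- do.call(rbind, ravg_rows)
  files <- c(files, write_islet_results(ravg, out_dir,
                                        name = "r_avg_summary",
                                        config = analysis))
  if (length(ft_rows) > 0) {
    files <- c(files, write_islet_results(do.call(rbind, ft_rows),
                                          out_dir, name = "fraction_time",
                                          config = analysis))
  }
  files <- c(files, write_islet_results(do.call(rbind, spike_rows),
                                        out_dir, name = "spike_metrics",
                                        config = analysis))
  if (length(nc_rows) > 0) {
    files <- c(files, write_islet_results(do.call(rbind, nc_rows),
                                          out_dir,
                                          name = "neural_connection",
                                          config = analysis))
  }

  if (perturbed) {
    bb <- ravg[ravg$type_pair == "beta-beta", ]
    cmp <- compare_groups(bb, "r_avg", "group", design = "anova2",
                          factor2 = "window")
    files <- c(files, write_islet_results(cmp, out_dir,
                                          name = "comparisons",
                                          config = analysis))
    if (length(dc_by_group) == 2) {
      reg <- coupling_regression(dc_by_group$intact,
                                 dc_by_group$perturbed,
                                 labels = c("intact", "perturbed"))
      files <- c(files, write_islet_results(
        reg$fits, out_dir, name = "distance_coupling_fit",
        config = analysis))
      files <- c(files, write_islet_results(
        data.frame(p_slope = reg$p_slope,
                   p_elevation = reg$p_elevation, method = reg$method),
        out_dir, name = "distance_coupling_comparison",
        config = analysis))
    }
    stages <- c(stages, "compare")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("isletconn")),
    seed = seed, n_animals = n_animals, perturbed = perturbed,
    simulation_config = config_as_list(config)[
      setdiff(names(config), "coupling")],
    coupling = as.vector(config$coupling),
    analysis_config = config_as_list(analysis),
    stages = stages,
    files = sort(unique(sub(paste0("^", out_dir, "/?"), "",
                            unname(files)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

render_figures <- function(animal, analysis, dir) {
  out <- character(0)
  wlab <- animal$traces$windows$label[1]
  nt <- normalize_traces(animal$traces, wlab)
  corr <- correlation_matrix(nt, animal$cells)
  fig <- function(name, expr) {
    p <- file.path(dir, paste0(name, ".png"))
    grDevices::png(p, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    p
  }
  out <- c(out, fig("traces", plot_trace_raster(nt)))
  out <- c(out, fig("corr_matrix", plot_correlation_heatmap(corr)))
  g <- build_graph(corr, animal$cells, analysis$connection_threshold)
  out <- c(out, fig("connectivity_map", plot_connectivity_graph(g)))
  out
}

#' Raster plot of normalised traces, stacked by cell
#' @param ntraces a [normalize_traces()] result.
#' @param gap vertical offset between cells.
#' @export
plot_trace_raster <- function(ntraces, gap = 1.1) {
  v <- ntraces$values
  n <- nrow(v)
  t_min <- (seq_len(ncol(v)) - 1) * ntraces$frame_interval_s / 60
  graphics::plot(NA, xlim = range(t_min), ylim = c(0, n * gap + 1),
                 xlab = "time (min)", ylab = "cell",
                 yaxt = "n", main = paste("normalised traces,",
                                          ntraces$window))
  for (i in seq_len(n)) {
    graphics::lines(t_min, v[i, ] + (n - i) * gap, lwd = 0.5)
  }
  invisible(NULL)
}

#' Heat map of a correlation matrix (optionally two windows as triangles)
#' @param corr a [correlation_matrix()] result.
#' @param corr_upper optional second window shown in the upper triangle.
#' @export
plot_correlation_heatmap <- function(corr, corr_upper = NULL) {
  R <- corr$R
  if (!is.null(corr_upper)) {
    R[upper.tri(R)] <- corr_upper$R[upper.tri(R)]
  }
  n <- nrow(R)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(R[n:1, ]),
                  zlim = c(-1, 1), col = pal, xlab = "", ylab = "",
                  main = paste("correlation matrix,", corr$window))
  invisible(NULL)
}

#' Connectivity map: cells at their coordinates, edges shaded by R,
#' node size by degree
#' @param graph a [build_graph()] result.
#' @export
plot_connectivity_graph <- function(graph) {
  nd <- graph$nodes
  graphics::plot(nd$x_um, nd$y_um, type = "n", asp = 1,
                 xlab = "x (µm)", ylab = "y (µm)",
                 main = sprintf("connectivity map (R >= %.2f)",
                                graph$threshold))
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$cell_a, nd$cell_id)
    ib <- match(graph$edges$cell_b, nd$cell_id)
    shade <- grDevices::gray(1 - pmin(1, pmax(0, graph$edges$r)))
    graphics::segments(nd$x_um[ia], nd$y_um[ia], nd$x_um[ib], nd$y_um[ib],
                       col = shade)
  }
  cols <- c(beta = "#1b9e77", alpha = "#d95f02", delta = "#7570b3",
            neuron = "#e7298a", unknown = "grey50")
  graphics::points(nd$x_um, nd$y_um, pch = 19,
                   cex = 0.8 + 0.15 * sqrt(nd$degree),
                   col = cols[nd$cell_type])
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.8)
  invisible(NULL)
}

#' Mean R versus distance rank with fitted regression lines
#' @param reg a [coupling_regression()] result.
#' @export
plot_distance_coupling <- function(reg) {
  pts <- reg$data
  grp <- factor(pts$group)
  cols <- c("#1b9e77", "#d95f02")[as.integer(grp)]
  graphics::plot(pts$rank, pts$mean_r, col = cols, pch = 19,
                 xlab = "distance rank (1 = close)", ylab = "mean R",
                 main = "coupling vs distance")
  for (i in seq_len(nrow(reg$fits))) {
    graphics::abline(reg$fits$intercept[i], reg$fits$slope[i],
                     col = c("#1b9e77", "#d95f02")[i], lwd = 2)
  }
  graphics::legend("topright", legend = reg$fits$group,
                   col = c("#1b9e77", "#d95f02")[seq_len(nrow(reg$fits))],
                   lwd = 2)
  invisible(NULL)
}

#' Bar summary of fraction-time joint states
#' @param ft a [fraction_time()] result (or stacked fractions data.frame).
#' @export
plot_fraction_time <- function(ft) {
  fr <- if (inherits(ft, "fraction_time_result")) ft$fractions else ft
  m <- vapply(split(fr, fr$type_pair), function(g) {
    colMeans(g[, c("f_both_active", "f_both_silent",
                   "f_a_active_b_silent", "f_a_silent_b_active")])
  }, numeric(4))
  graphics::barplot(m, beside = TRUE,
                    legend.text = c("both active", "both silent",
                                    "A act / B sil", "A sil / B act"),
                    ylab = "fraction of time",
                    main = "joint-state occupancy")
  invisible(NULL)
}
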