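test_that("geometry reproduces the core/mantle architecture and seed contract", {
  cfg <- simulation_config(n_beta = 20, n_alpha = 12, n_delta = 6,
                           islet_radius_um = 20, seed = 1)
  cells <- generate_geometry(cfg)
  d <- distance_to_core(cells)$per_type
  expect_lt(d$mean_um[d$cell_type == "beta"],
            d$mean_um[d$cell_type == "alpha"])
  # degenerate single cell
  cfg1 <- simulation_config(n_beta = 1, n_alpha = 0, n_delta = 0,
                            n_neuron = 0, seed = 1)
  one <- generate_geometry(cfg1)
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(as.matrix(one[, c("x_um", "y_um", "z_um")]))))
  expect_lte(sqrt(sum(as.matrix(one[, c("x_um", "y_um", "z_um")])^2)),
             0.6 * 20)
  # seed contract
  expect_identical(generate_geometry(cfg, seed = 1),
                   generate_geometry(cfg, seed = 1))
  g2 <- generate_geometry(cfg, seed = 2)
  expect_false(identical(cells$x_um, g2$x_um))
  expect_error(generate_geometry(simulation_config(n_beta = 0,
                                                   n_alpha = 0,
                                                   n_delta = 0,
                                                   n_neuron = 0)),
               class = "isletconn_empty_islet")
})

test_that("simulated traces are deterministic, non-negative and windowed", {
  cfg <- simulation_config(n_beta = 8, n_alpha = 4, n_delta = 2, seed = 3,
                           windows = data.frame(label = c("LG", "HG"),
                                                n_frames = c(40L, 50L)))
  cells <- generate_geometry(cfg)
  t1 <- simulate_traces(cells, cfg)
  t2 <- simulate_traces(cells, cfg)
  expect_identical(t1$fluorescence, t2$fluorescence)
  expect_true(all(t1$fluorescence >= 0))
  expect_equal(ncol(t1$fluorescence), 90)
  expect_equal(t1$windows$label, c("LG", "HG"))
  expect_equal(t1$windows$end_frame, c(40, 90))
  # mismatched table rejected
  expect_error(simulate_traces(cells[1:5, ], cfg),
               class = "isletconn_config_mismatch")
})

test_that("simulated coupling matches the analytic shared-drive correlation", {
  # single homotypic drive, no neuron, no noise, long recording
  w <- 0.9
  cpl <- matrix(0, 3, 3); cpl[1, 1] <- w
  cfg <- simulation_config(
    n_beta = 20, n_alpha = 0, n_delta = 0, n_neuron = 0,
    coupling = cpl, noise_sd = 0, neuron_drive_frac = 0,
    windows = data.frame(label = "HG", n_frames = 2000L), seed = 9)
  cells <- generate_geometry(cfg)
  tr <- simulate_traces(cells, cfg)
  corr <- animal_corr(list(cells = cells, traces = tr), "HG")

  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  core <- colMeans(pos)
  dvec <- sqrt(rowSums(sweep(pos, 2, core)^2))
  s <- cfg$rate_hg * cfg$frame_interval_s / 60
  u <- s * cfg$private_frac
  q <- w * exp(-dvec / cfg$lambda_um)
  cmb <- utils::combn(20, 2)
  expected <- mapply(function(i, j) shared_drive_corr(u, s, q[i], q[j]),
                     cmb[1, ], cmb[2, ])
  observed <- corr$R[t(cmb)]
  # the analytic value is a high plateau; simulation agrees within
  # Monte-Carlo error of the pair-mean
  expect_gt(mean(expected), 0.3)
  expect_lt(abs(mean(observed) - mean(expected)), 0.04)
  expect_gt(cor(observed, expected), 0.5)
})

test_that("uncoupled cells are uncorrelated and factor algebra holds", {
  base <- list(n_beta = 12, n_alpha = 0, n_delta = 0, n_neuron = 0,
               neuron_drive_frac = 0,
               windows = data.frame(label = "HG", n_frames = 720L))
  cfg0 <- do.call(simulation_config,
                  c(base, list(coupling = matrix(0, 3, 3), seed = 5)))
  cells <- generate_geometry(cfg0)
  r0 <- animal_corr(list(cells = cells,
                         traces = simulate_traces(cells, cfg0)), "HG")
  off0 <- r0$R[upper.tri(r0$R)]
  expect_lt(abs(mean(off0)), 3 / sqrt(720))

  # perturbation_factor = 0 with strong coupling behaves like coupling 0
  cplS <- matrix(0.9, 3, 3)
  cfgP <- do.call(simulation_config,
                  c(base, list(coupling = cplS, perturbation_factor = 0,
                               seed = 6)))
  cellsP <- generate_geometry(cfgP)
  trP <- simulate_traces(cellsP, cfgP)
  rP <- animal_corr(list(cells = cellsP, traces = trP), "HG")
  expect_lt(abs(mean(rP$R[upper.tri(rP$R)])), 3 / sqrt(720))
})

test_that("coupling and perturbation monotonically raise beta-beta R_avg", {
  ravg_at <- function(w, pf, seed) {
    cpl <- matrix(0, 3, 3); cpl[1, 1] <- w
    cfg <- simulation_config(
      n_beta = 15, n_alpha = 0, n_delta = 0, n_neuron = 0,
      coupling = cpl, perturbation_factor = pf, neuron_drive_frac = 0,
      windows = data.frame(label = "HG", n_frames = 1000L), seed = seed)
    cells <- generate_geometry(cfg)
    corr <- animal_corr(list(cells = cells,
                             traces = simulate_traces(cells, cfg)), "HG")
    as.numeric(r_avg(corr, "beta", "beta"))
  }
  by_w <- vapply(c(0.2, 0.5, 0.8), ravg_at, numeric(1), pf = 1, seed = 11)
  expect_true(all(diff(by_w) > 0))
  by_pf <- vapply(c(0.2, 0.6, 1), function(pf)
    ravg_at(0.8, pf, seed = 12), numeric(1))
  expect_true(all(diff(by_pf) > 0))
})

test_that("pair correlation decays with inter-cell distance", {
  cfg <- simulation_config(seed = 21)
  coh <- make_cohort(cfg, 5, seed = 21)
  dcs <- lapply(coh, function(an)
    rank_distances(an$cells, animal_corr(an), "beta", "beta"))
  reg <- coupling_regression(dcs)
  expect_lt(reg$fits$slope[1], 0)
  pooled <- do.call(rbind, lapply(dcs, `[[`, "rank_means"))
  expect_lt(cor(pooled$rank, pooled$mean_r, method = "spearman"), 0)
})

test_that("neuron-driven cells correlate with the neuron trace; others do not", {
  cfg <- simulation_config(seed = 31)
  cells <- generate_geometry(cfg)
  corr <- animal_corr(list(cells = cells,
                           traces = simulate_traces(cells, cfg)), "HG")
  nrow_i <- which(cells$cell_type == "neuron")
  endo <- which(cells$cell_type != "neuron")
  rn <- corr$R[endo, nrow_i]
  expect_gt(mean(rn[cells$neuron_driven[endo]]),
            mean(rn[!cells$neuron_driven[endo]]) + 0.3)
})

test_that("cohorts fan out reproducibly and honour perturbation modes", {
  cfg <- simulation_config(n_beta = 6, n_alpha = 3, n_delta = 2, seed = 7,
                           windows = data.frame(label = c("LG", "HG"),
                                                n_frames = c(30L, 30L)))
  c1 <- make_cohort(cfg, 6, seed = 7)
  c2 <- make_cohort(cfg, 6, seed = 7)
  expect_identical(c1[[3]]$traces$fluorescence,
                   c2[[3]]$traces$fluorescence)
  expect_false(identical(c1[[1]]$traces$fluorescence,
                         c1[[2]]$traces$fluorescence))
  expect_equal(length(c1), 6)

  # chronic: both windows attenuated; acute: only the post window
  w3 <- data.frame(label = c("LG", "HG", "HGa"),
                   n_frames = c(200L, 200L, 200L))
  mk <- function(mode) {
    cfg <- simulation_config(n_beta = 20, n_alpha = 0, n_delta = 0,
                             n_neuron = 0, neuron_drive_frac = 0,
                             windows = w3, perturbation_factor = 0.2,
                             perturbation_mode = mode, seed = 13)
    an <- make_cohort(cfg, 1, perturbed = TRUE, seed = 13)[[1]]
    vapply(c("HG", "HGa"), function(wl)
      as.numeric(r_avg(animal_corr(an, wl), "beta", "beta")), numeric(1))
  }
  acute <- mk("acute")
  chronic <- mk("chronic")
  expect_gt(acute["HG"], acute["HGa"] + 0.1)     # only post window drops
  expect_lt(chronic["HG"], acute["HG"] - 0.1)    # chronic drops HG too
})
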