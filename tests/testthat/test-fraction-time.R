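states_from <- function(m, ids = paste0("c", seq_len(nrow(m)))) {
  structure(list(states = m == 1, threshold = 0.25, window = "HG",
                 cell_id = ids, frame_interval_s = 5),
            class = "binary_states")
}

pairs_of <- function(a, b, tp = "delta-beta") {
  structure(data.frame(cell_a = a, cell_b = b, type_pair = tp,
                       distance_um = 1),
            class = c("pair_list", "data.frame"))
}

test_that("nearest pairing picks the closest partner with id tie-break", {
  cells <- islet_cells("a", c("d1", "b1", "b2"),
                       c("delta", "beta", "beta"),
                       x_um = c(0, 3, 5), y_um = 0, z_um = 0)
  p <- nearest_pairs(cells, "delta", "beta")
  expect_equal(p$cell_b, "b1")
  expect_equal(p$distance_um, 3)
  # equidistant partners -> lowest id wins, deterministically
  cells2 <- islet_cells("a", c("d1", "b9", "b2"),
                        c("delta", "beta", "beta"),
                        x_um = c(0, 4, -4), y_um = 0, z_um = 0)
  expect_equal(nearest_pairs(cells2, "delta", "beta")$cell_b, "b2")
  # missing type -> empty with reason
  p0 <- nearest_pairs(cells[cells$cell_type == "beta", ],
                      "delta", "beta")
  expect_equal(nrow(p0), 0)
  expect_match(attr(p0, "reason"), "delta")
})

test_that("nearest pairing matches exhaustive search on random geometry", {
  for (seed in 1:5) {
    cfg <- simulation_config(n_beta = 12, n_alpha = 6, n_delta = 5,
                             seed = seed)
    cells <- generate_geometry(cfg)
    p <- nearest_pairs(cells, "delta", "beta")
    pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
    for (k in seq_len(nrow(p))) {
      i <- match(p$cell_a[k], cells$cell_id)
      betas <- which(cells$cell_type == "beta")
      dd <- sqrt(rowSums((pos[betas, , drop = FALSE] -
                            matrix(pos[i, ], length(betas), 3,
                                   byrow = TRUE))^2))
      expect_equal(p$distance_um[k], min(dd))
    }
  }
})

test_that("fraction time reproduces hand and brute-force counts", {
  # constant states
  st <- states_from(rbind(rep(1, 10), rep(1, 10)))
  ft <- fraction_time(st, pairs_of("c1", "c2"))
  expect_equal(ft$fractions$f_both_active, 1)
  expect_equal(ft$fractions$f_both_silent, 0)
  # alternation
  st2 <- states_from(rbind(c(1, 0), c(0, 1)))
  ft2 <- fraction_time(st2, pairs_of("c1", "c2"))
  expect_equal(ft2$fractions$f_a_active_b_silent, 0.5)
  expect_equal(ft2$fractions$f_a_silent_b_active, 0.5)
  expect_equal(ft2$fractions$f_both_active, 0)
  # brute-force frame counting on a long random pair
  set.seed(9)
  m <- matrix(rbinom(2 * 1000, 1, 0.4), 2, 1000)
  ft3 <- fraction_time(states_from(m), pairs_of("c1", "c2"))
  a <- m[1, ] == 1; b <- m[2, ] == 1
  expect_equal(ft3$fractions$f_both_active, sum(a & b) / 1000)
  expect_equal(ft3$fractions$f_a_active_b_silent, sum(a & !b) / 1000)
  expect_equal(ft3$fractions$f_a_silent_b_active, sum(!a & b) / 1000)
})

test_that("fractions conserve exactly and swap symmetrically", {
  set.seed(10)
  for (rep in 1:200) {
    nf <- sample(c(3, 7, 360, 999), 1)
    m <- matrix(rbinom(2 * nf, 1, runif(1, 0.05, 0.95)), 2, nf)
    st <- states_from(m)
    f_ab <- fraction_time(st, pairs_of("c1", "c2"))$fractions
    f_ba <- fraction_time(st, pairs_of("c2", "c1"))$fractions
    # exact conservation, not just to tolerance
    expect_true(f_ab$f_both_silent +
                  (f_ab$f_both_active +
                     (f_ab$f_a_active_b_silent +
                        f_ab$f_a_silent_b_active)) == 1)
    # swapping members swaps the mixed states, fixes the concordant ones
    expect_identical(f_ab$f_a_active_b_silent, f_ba$f_a_silent_b_active)
    expect_identical(f_ab$f_a_silent_b_active, f_ba$f_a_active_b_silent)
    expect_identical(f_ab$f_both_active, f_ba$f_both_active)
    expect_identical(f_ab$f_both_silent, f_ba$f_both_silent)
  }
})

test_that("stronger coupling raises chance-corrected joint-state concordance", {
  # raising a coupling weight also raises the cells' marginal activity,
  # so raw concordance is compared against its independence expectation
  # computed from the same marginals
  conc_at <- function(w, seed) {
    cpl <- default_coupling()
    cpl["delta", "beta"] <- cpl["beta", "delta"] <- w
    cfg <- simulation_config(coupling = cpl, n_neuron = 0,
                             neuron_drive_frac = 0, seed = seed,
                             windows = data.frame(label = "HG",
                                                  n_frames = 720L))
    an <- make_cohort(cfg, 3, seed = seed)
    mean(vapply(an, function(x) {
      st <- binarize_traces(normalize_traces(x$traces, "HG"))
      prs <- nearest_pairs(x$cells, "delta", "beta")
      ft <- fraction_time(st, prs)$fractions
      act <- rowMeans(st$states)
      pa <- act[match(prs$cell_a, st$cell_id)]
      pb <- act[match(prs$cell_b, st$cell_id)]
      conc <- ft$f_both_active + ft$f_both_silent
      conc_indep <- pa * pb + (1 - pa) * (1 - pb)
      mean(conc - conc_indep)
    }, numeric(1)))
  }
  expect_gt(conc_at(0.9, 31), conc_at(0.05, 31))
})

test_that("chronic attenuation lowers the alpha-beta both-active state", {
  both_active <- function(perturbed) {
    cfg <- simulation_config(perturbation_factor = 0.3, seed = 41)
    coh <- make_cohort(cfg, 4, perturbed = perturbed, seed = 41)
    mean(vapply(coh, function(x) {
      nt <- normalize_traces(x$traces, "HG")
      ft <- fraction_time(binarize_traces(nt),
                          nearest_pairs(x$cells, "alpha", "beta"))
      mean(ft$fractions$f_both_active)
    }, numeric(1)))
  }
  expect_gt(both_active(FALSE), both_active(TRUE))
})
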