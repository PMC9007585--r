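ntr <- function(m, window = "HG") {
  m <- m - min(m)    # traces are stored non-negative; Pearson unaffected
  ts <- trace_set(m, windows = data.frame(label = window, start_frame = 0,
                                          end_frame = ncol(m)),
                  cell_id = paste0("c", seq_len(nrow(m))))
  normalize_traces(ts, window)
}

test_that("correlation matrix handles identity, negation and a hand case", {
  base <- c(3, 1, 4, 1, 5, 9, 2, 6)
  m <- rbind(base, base * 2 + 1, 10 - base)
  corr <- correlation_matrix(ntr(m))
  expect_equal(corr$R[1, 2], 1)
  expect_equal(corr$R[1, 3], -1)
  # 4-frame hand computation: r = 0.6
  m2 <- rbind(c(0, 1, 2, 3), c(1, 0, 3, 2))
  expect_equal(correlation_matrix(ntr(m2))$R[1, 2], 0.6)
  expect_error(correlation_matrix(ntr(matrix(1:8, 1, 8))),
               class = "isletconn_too_few_cells")
})

test_that("correlation matrix agrees with the brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(10 * 200), 10, 200)
    corr <- correlation_matrix(ntr(m))
    expect_lt(max(abs(corr$R - corr_oracle_matrix(m))), 1e-10)
    expect_identical(corr$R, t(corr$R))
    expect_true(all(diag(corr$R) == 1))
  }
})

test_that("constant cells become missing entries excluded from averages", {
  m <- rbind(rnorm(20), rnorm(20), rep(2, 20))
  nt <- ntr(m)
  corr <- correlation_matrix(nt)
  corr$cell_type <- c("beta", "beta", "beta")
  expect_true(all(is.na(corr$R[3, -3])))
  v <- r_avg(corr, "beta", "beta")
  expect_equal(attr(v, "n_pairs"), 1)       # only the non-constant pair
  expect_equal(as.numeric(v), corr$R[1, 2])
})

test_that("r_avg equals the enumeration oracle and handles empty sets", {
  set.seed(8)
  R <- corr_oracle_matrix(matrix(rnorm(8 * 50), 8, 50))
  types <- c("beta", "beta", "beta", "alpha", "alpha", "delta", "unknown",
             "neuron")
  corr <- make_corr(R, types)
  # 3 beta cells with known pairwise values
  expect_equal(as.numeric(r_avg(corr, "beta", "beta")),
               mean(c(R[1, 2], R[1, 3], R[2, 3])))
  expect_equal(as.numeric(r_avg(corr, "beta", "alpha")),
               mean(R[1:3, 4:5]))
  # unknown excluded entirely; single delta has no homotypic pair
  v <- r_avg(corr, "delta", "delta")
  expect_true(is.na(v))
  expect_equal(attr(v, "n_pairs"), 0)
  # simple arithmetic-mean example
  R3 <- diag(3); R3[1, 2] <- R3[2, 1] <- 0.2
  R3[1, 3] <- R3[3, 1] <- 0.4; R3[2, 3] <- R3[3, 2] <- 0.6
  expect_equal(as.numeric(r_avg(make_corr(R3, rep("beta", 3)),
                                "beta", "beta")), 0.4)
  # summary table covers all endocrine pairs and neuron couplings
  s <- r_avg_summary(corr, "a1")
  expect_setequal(s$type_pair,
                  c("beta-beta", "beta-alpha", "beta-delta", "alpha-alpha",
                    "alpha-delta", "delta-delta", "neuron-beta",
                    "neuron-alpha", "neuron-delta"))
})

test_that("neural-connection labels follow the threshold criterion", {
  R <- diag(4)
  R[1, 4] <- R[4, 1] <- 0.9    # beta strongly follows the neuron
  R[2, 4] <- R[4, 2] <- 0.2
  R[3, 4] <- R[4, 3] <- 0.5
  corr <- make_corr(R, c("beta", "beta", "delta", "neuron"))
  nc <- classify_neural_connection(corr, threshold = 0.5)
  expect_equal(nc$labels$connected, c(TRUE, FALSE, TRUE))
  expect_equal(unname(nc$percent_connected["beta"]), 50)
  expect_equal(unname(nc$percent_connected["delta"]), 100)
  expect_true(is.na(nc$percent_connected["alpha"]))
  # no neurons: explicit empty result, not zeros
  nc0 <- classify_neural_connection(make_corr(R, rep("beta", 4)), 0.5)
  expect_true(nc0$no_neurons)
  expect_equal(nrow(nc0$labels), 0)
  expect_null(nc0$percent_connected)
})

test_that("classification recovers the simulator's driven cells", {
  cfg <- simulation_config(seed = 17)
  cells <- generate_geometry(cfg)
  corr <- animal_corr(list(cells = cells,
                           traces = simulate_traces(cells, cfg)), "HG")
  nc <- classify_neural_connection(corr, 0.5)
  truth <- cells$neuron_driven[match(nc$labels$cell_id, cells$cell_id)]
  dl <- nc$labels$cell_type == "delta"
  # half the delta cells receive drive; recovery within binomial error
  expect_equal(mean(nc$labels$connected[dl]), 0.5, tolerance = 0.25)
  expect_gt(mean(nc$labels$connected[truth]), 0.8)
  expect_lt(mean(nc$labels$connected[!truth]), 0.2)
})

test_that("homotypic split by connection matches hand-computed group means", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.8; R[1, 3] <- R[3, 1] <- 0.6
  R[2, 3] <- R[3, 2] <- 0.4
  R[1, 4] <- R[4, 1] <- 0.9; R[2, 4] <- R[4, 2] <- 0.1
  R[3, 4] <- R[4, 3] <- 0.1
  corr <- make_corr(R, c("delta", "delta", "delta", "neuron"))
  nc <- classify_neural_connection(corr, 0.5)   # only cell 1 connected
  sp <- split_homotypic_by_connection(corr, nc, "delta")
  expect_equal(sp$r_avg_connected, mean(c(0.8, 0.6)))
  expect_equal(sp$r_avg_unconnected, mean(c(0.8, 0.4, 0.6, 0.4)))
  # all cells connected -> unconnected side missing
  nc2 <- classify_neural_connection(corr, 0.05)
  sp2 <- split_homotypic_by_connection(corr, nc2, "delta")
  expect_true(is.na(sp2$r_avg_unconnected))
  expect_equal(sp2$n_connected, 3)
})

test_that("graph construction is an exact threshold filter", {
  cells <- tiny_cells()
  set.seed(10)
  m <- matrix(rexp(7 * 60, 1 / 40), 7, 60)
  nt <- ntr(m)
  nt$cell_id <- cells$cell_id
  corr <- correlation_matrix(nt, cells)
  g <- build_graph(corr, cells, threshold = 0.2)
  # enumeration oracle
  expected <- 0
  for (i in 1:6) for (j in (i + 1):7) {
    if (corr$R[i, j] >= 0.2) expected <- expected + 1
  }
  expect_equal(nrow(g$edges), expected)
  expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
  # empty and complete extremes
  expect_equal(nrow(build_graph(corr, cells, 1.01)$edges), 0)
  expect_equal(nrow(build_graph(corr, cells, -1)$edges), choose(7, 2))
})
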