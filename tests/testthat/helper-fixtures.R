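# shared fixtures and independent oracles used across test files

# tiny hand-positioned islet: 3 beta, 2 alpha, 1 delta, 1 neuron
tiny_cells <- function() {
  islet_cells(
    animal_id = "t1",
    cell_id = c("b1", "b2", "b3", "a1", "a2", "d1", "n1"),
    cell_type = c("beta", "beta", "beta", "alpha", "alpha", "delta",
                  "neuron"),
    x_um = c(0, 2, -1, 10, -9, 4, 22),
    y_um = c(0, 1, -2, 3, -8, 4, 0),
    z_um = c(0, -1, 1, 2, 5, 0, 0))
}

random_trace_set <- function(n_cells, n_frames, seed,
                             windows = data.frame(label = "HG",
                                                  start_frame = 0,
                                                  end_frame = n_frames)) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_cells * n_frames, 1 / 50), n_cells, n_frames)
  trace_set(m, frame_interval_s = 5, windows = windows,
            cell_id = paste0("c", seq_len(n_cells)))
}

# textbook Pearson correlation: explicit sums, no cor()
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# full-matrix brute force
corr_oracle_matrix <- function(m) {
  n <- nrow(m)
  R <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      R[i, j] <- R[j, i] <- pearson_oracle(m[i, ], m[j, ])
    }
  }
  R
}

# build a correlation_result directly from a matrix + type vector
make_corr <- function(R, types, window = "HG",
                      ids = sprintf("c%02d", seq_len(nrow(R)))) {
  structure(list(R = R, window = window, cell_id = ids,
                 cell_type = types),
            class = "correlation_result")
}

# analytic event-level correlation for the shared-drive model with one
# homotypic drive, no neuron, no noise: A_i = U_i | (S & B_i) with
# U ~ Bern(u), S ~ Bern(s), B_i ~ Bern(q_i).  Closed form from joint
# absence probabilities; the indicator kernel (common linear filter on
# frame-wise-independent trains) leaves the correlation unchanged.
shared_drive_corr <- function(u, s, q_i, q_j) {
  p_i <- 1 - (1 - u) * (1 - s * q_i)
  p_j <- 1 - (1 - u) * (1 - s * q_j)
  p_none <- (1 - u)^2 * (1 - s * (q_i + q_j - q_i * q_j))
  p_both <- 1 - (1 - p_i) - (1 - p_j) + p_none
  cov <- p_both - p_i * p_j
  cov / sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
}

# helper to go from simulated animal to correlation_result in one window
animal_corr <- function(an, window = "HG") {
  nt <- normalize_traces(an$traces, window)
  correlation_matrix(nt, an$cells)
}
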