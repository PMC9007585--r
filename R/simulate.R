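#' Configuration of the synthetic islet generator
#'
#' The generator emulates one imaged islet: a beta-cell core with an
#' alpha-cell mantle and interspersed delta cells, a peri-islet neuron, and
#' per-cell calcium event trains whose coordination is produced by shared
#' event trains ("drives") per cell-type pair. Per frame, each cell fires
#' through three routes: (a) a private Bernoulli event, (b) acceptance of
#' the type-pair drive event with probability
#' `coupling[a,b] * exp(-d_i / lambda_um) * perturbation_factor`
#' (where `d_i` is the cell's distance to the islet core), and (c) for
#' neuron-driven cells, acceptance of the neuron's event train with
#' probability `neuron_drive_weight`. The binary event train is convolved
#' with a double-exponential calcium-indicator kernel and Gaussian noise is
#' added. Glucose stimulation (HG windows) raises the event rate;
#' perturbation (chronic or acute neural inhibition) multiplies all coupling
#' and drive weights by `perturbation_factor`.
#'
#' @param n_beta,n_alpha,n_delta,n_neuron cell counts.
#' @param islet_radius_um islet radius (micrometres).
#' @param frame_interval_s frame interval (seconds).
#' @param windows data.frame `label`, `n_frames`: the window plan, executed
#'   in order (default: LG then HG, 360 frames = 30 min each).
#' @param rate_lg,rate_hg event rate of the drive and private trains, per
#'   cell per minute, under basal (LG) and glucose-stimulated (HG/HGa/
#'   HGlambda) conditions.
#' @param private_frac private event rate as a fraction of the condition
#'   rate. Islet cells are strongly coordinated, so most activity is shared.
#' @param coupling symmetric 3x3 matrix (beta/alpha/delta) of type-pair
#'   shared-drive weights in \[0,1\].
#' @param lambda_um distance-decay length of the coupling multiplier
#'   `exp(-d/lambda)`.
#' @param neuron_drive_frac fraction of each endocrine type receiving the
#'   neuron's event train.
#' @param neuron_drive_weight acceptance probability of neuron events by
#'   driven cells.
#' @param neuron_rate_factor neuron event rate relative to the endocrine
#'   drive rate of the same window; peri-islet neurons fire faster than
#'   the slow endocrine calcium oscillation, which also makes the neuron
#'   train the dominant activity component of driven cells.
#' @param perturbation_factor multiplier in \[0,1\] applied to all coupling
#'   and drive weights in perturbed windows (1 = intact).
#' @param perturbation_mode `"chronic"` (all windows perturbed) or
#'   `"acute"` (only post-baseline HGa/HGlambda windows perturbed).
#' @param tau_rise_s,tau_decay_s indicator kernel time constants (GCaMP6s
#'   order of magnitude at 5-s sampling); rise must be < decay.
#' @param noise_sd additive Gaussian noise SD as a fraction of the peak
#'   single-event amplitude.
#' @param baseline_au,amplitude_au baseline fluorescence and single-event
#'   amplitude (arbitrary units).
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_beta = 40, n_alpha = 12, n_delta = 8,
                              n_neuron = 1,
                              islet_radius_um = 20,
                              frame_interval_s = 5,
                              windows = data.frame(
                                label = c("LG", "HG"),
                                n_frames = c(360L, 360L)),
                              rate_lg = 0.8, rate_hg = 2,
                              private_frac = 0.15,
                              coupling = default_coupling(),
                              lambda_um = 15,
                              neuron_drive_frac = 0.5,
                              neuron_drive_weight = 0.8,
                              neuron_rate_factor = 2,
                              perturbation_factor = 1,
                              perturbation_mode = c("chronic", "acute"),
                              tau_rise_s = 0.5, tau_decay_s = 2.5,
                              noise_sd = 0.05,
                              baseline_au = 20, amplitude_au = 100,
                              seed = 1L) {
  perturbation_mode <- match.arg(perturbation_mode)
  coupling <- as.matrix(coupling)
  stopifnot(
    n_beta >= 0, n_alpha >= 0, n_delta >= 0, n_neuron >= 0,
    islet_radius_um > 0, frame_interval_s > 0,
    all(c("label", "n_frames") %in% names(windows)),
    rate_lg >= 0, rate_hg >= 0,
    private_frac >= 0,
    identical(dim(coupling), c(3L, 3L)),
    isTRUE(all.equal(coupling, t(coupling))),
    all(coupling >= 0 & coupling <= 1),
    lambda_um > 0,
    neuron_drive_frac >= 0, neuron_drive_frac <= 1,
    neuron_drive_weight >= 0, neuron_drive_weight <= 1,
    neuron_rate_factor > 0,
    perturbation_factor >= 0, perturbation_factor <= 1,
    tau_rise_s > 0, tau_rise_s < tau_decay_s,
    noise_sd >= 0, baseline_au >= 0, amplitude_au > 0
  )
  dimnames(coupling) <- list(ENDOCRINE_TYPES, ENDOCRINE_TYPES)
  structure(list(
    n_beta = as.integer(n_beta), n_alpha = as.integer(n_alpha),
    n_delta = as.integer(n_delta), n_neuron = as.integer(n_neuron),
    islet_radius_um = islet_radius_um,
    frame_interval_s = frame_interval_s,
    windows = data.frame(label = as.character(windows$label),
                         n_frames = as.integer(windows$n_frames)),
    rate_lg = rate_lg, rate_hg = rate_hg,
    private_frac = private_frac,
    coupling = coupling, lambda_um = lambda_um,
    neuron_drive_frac = neuron_drive_frac,
    neuron_drive_weight = neuron_drive_weight,
    neuron_rate_factor = neuron_rate_factor,
    perturbation_factor = perturbation_factor,
    perturbation_mode = perturbation_mode,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    noise_sd = noise_sd,
    baseline_au = baseline_au, amplitude_au = amplitude_au,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default type-pair coupling weights
#'
#' Homotypic beta coupling is the strongest, mirroring the prominence of
#' beta-beta coordination in islet recordings; heterotypic pairs couple at
#' intermediate weight so the heterotypic analyses see signal.
#' @return symmetric 3x3 matrix over beta/alpha/delta.
#' @export
default_coupling <- function() {
  m <- matrix(c(
    0.8, 0.4, 0.5,   # beta  - beta/alpha/delta
    0.4, 0.3, 0.3,   # alpha
    0.5, 0.3, 0.4),  # delta
    3, 3, byrow = TRUE,
    dimnames = list(ENDOCRINE_TYPES, ENDOCRINE_TYPES))
  m
}

#' Generate the core/mantle geometry of one synthetic islet
#'
#' Beta cells are placed uniformly within the inner core (0.6 x radius),
#' alpha cells on the mantle shell (0.85-1.0 x radius), delta cells
#' uniformly across the whole islet, and neurons just outside the surface
#' (1.05-1.15 x radius). This reproduces the qualitative core/mantle
#' architecture: mean distance to the islet centre orders beta < delta <
#' alpha in expectation. If neurons are present, a fraction
#' `neuron_drive_frac` of each endocrine type is flagged `neuron_driven`
#' (ground truth for the classification stage).
#'
#' @param config a [simulation_config()].
#' @param animal_id identifier for the generated animal.
#' @param seed overrides `config$seed` if given.
#' @return an [islet_cells()] table.
#' @export
generate_geometry <- function(config, animal_id = "sim1",
                              seed = config$seed) {
  n_total <- config$n_beta + config$n_alpha + config$n_delta +
    config$n_neuron
  if (n_total == 0) stop_isletconn("empty_islet", "zero total cells")
  set.seed(seed)
  R <- config$islet_radius_um
  pos <- rbind(
    runif_ball(config$n_beta, 0, 0.6 * R),
    runif_ball(config$n_alpha, 0.85 * R, R),
    runif_ball(config$n_delta, 0, R),
    runif_ball(config$n_neuron, 1.05 * R, 1.15 * R)
  )
  type <- rep(c("beta", "alpha", "delta", "neuron"),
              times = c(config$n_beta, config$n_alpha, config$n_delta,
                        config$n_neuron))
  # stable ids per type: b01..., a01..., d01..., n01...
  idx <- stats::ave(seq_along(type), type, FUN = seq_along)
  id <- sprintf("%s%03d", substr(type, 1, 1), idx)
  driven <- rep(FALSE, n_total)
  if (config$n_neuron > 0 && config$neuron_drive_frac > 0) {
    for (tp in ENDOCRINE_TYPES) {
      rows <- which(type == tp)
      k <- round(config$neuron_drive_frac * length(rows))
      if (k > 0) driven[sample(rows, k)] <- TRUE
    }
  }
  islet_cells(animal_id, id, type,
              pos[, 1], pos[, 2], pos[, 3], neuron_driven = driven)
}

# n points uniform (in volume) in the spherical shell r_in <= r <= r_out
runif_ball <- function(n, r_in, r_out) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  r <- (r_in^3 + (r_out^3 - r_in^3) * stats::runif(n))^(1 / 3)
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(r * s * cos(phi), r * s * sin(phi), r * z)
}

#' Simulate calcium traces for a synthetic islet
#'
#' Implements the generative model described in [simulation_config()].
#' The first neuron's event train is the drive received by `neuron_driven`
#' cells; neuron traces are their own event trains rendered through the
#' same kernel.
#'
#' @param cells geometry from [generate_geometry()] (or compatible; needs a
#'   `neuron_driven` column when neuron drive is configured).
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed` if given.
#' @return a [trace_set()]; ground-truth event trains are attached as
#'   attribute `"events"` (cells x frames 0/1 matrix).
#' @export
simulate_traces <- function(cells, config, seed = config$seed) {
  n <- nrow(cells)
  if (n == 0) stop_isletconn("empty_islet", "no cells to simulate")
  expected <- config$n_beta + config$n_alpha + config$n_delta +
    config$n_neuron
  if (n != expected) {
    stop_isletconn("config_mismatch", "cell table has ", n,
                   " cells but config describes ", expected)
  }
  set.seed(seed + 1L)
  type <- cells$cell_type
  d_core <- core_distances(cells)
  n_frames_total <- sum(config$windows$n_frames)
  events <- matrix(0L, n, n_frames_total)

  # per-window frame ranges and effective rates / perturbation
  starts <- cumsum(c(0L, config$windows$n_frames))
  dt <- config$frame_interval_s
  neuron_rows <- which(type == "neuron")
  driven <- if ("neuron_driven" %in% names(cells)) {
    cells$neuron_driven
  } else rep(FALSE, n)

  for (w in seq_len(nrow(config$windows))) {
    lab <- config$windows$label[w]
    fr <- (starts[w] + 1):(starts[w + 1])
    nf <- length(fr)
    rate <- if (lab == "LG") config$rate_lg else config$rate_hg
    p_frame <- min(1, rate * dt / 60)
    pert <- if (perturbed_window(lab, w, config)) {
      config$perturbation_factor
    } else 1
    # (a) private events
    p_priv <- min(1, p_frame * config$private_frac)
    ev <- matrix(stats::rbinom(n * nf, 1L, p_priv), n, nf)
    # (b) shared type-pair drives (endocrine cells only)
    pairs <- type_pairs(ENDOCRINE_TYPES)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$type_a[k]; b <- pairs$type_b[k]
      members <- which(type %in% c(a, b))
      if (length(members) == 0) next
      S <- stats::rbinom(nf, 1L, p_frame)
      hot <- which(S == 1L)
      if (length(hot) == 0) next
      q <- pmin(1, config$coupling[a, b] * exp(-d_core[members] /
                                                 config$lambda_um) * pert)
      acc <- matrix(stats::rbinom(length(members) * length(hot), 1L,
                                  rep(q, times = length(hot))),
                    length(members), length(hot))
      ev[members, hot] <- pmax(ev[members, hot, drop = FALSE], acc)
    }
    # (c) neuron trains: the neuron's own events, plus thinned copies in
    # driven endocrine cells
    if (length(neuron_rows) > 0) {
      p_neuron <- min(1, p_frame * config$neuron_rate_factor)
      for (j in seq_along(neuron_rows)) {
        N <- stats::rbinom(nf, 1L, p_neuron)
        ev[neuron_rows[j], ] <- N
        if (j == 1L && any(driven)) {
          hot <- which(N == 1L)
          tgt <- which(driven & type != "neuron")
          if (length(hot) > 0 && length(tgt) > 0) {
            qn <- min(1, config$neuron_drive_weight * pert)
            acc <- matrix(stats::rbinom(length(tgt) * length(hot), 1L, qn),
                          length(tgt), length(hot))
            ev[tgt, hot] <- pmax(ev[tgt, hot, drop = FALSE], acc)
          }
        }
      }
    }
    events[, fr] <- ev
  }

  k <- calcium_kernel(config)
  conv <- convolve_events(events, k)
  noise <- matrix(stats::rnorm(n * n_frames_total, 0,
                               config$noise_sd * config$amplitude_au),
                  n, n_frames_total)
  fl <- config$baseline_au + config$amplitude_au * conv + noise
  fl[fl < 0] <- 0
  wdf <- data.frame(label = config$windows$label,
                    start_frame = starts[-length(starts)],
                    end_frame = starts[-1])
  ts <- trace_set(fl, frame_interval_s = dt, windows = wdf,
                  cell_id = cells$cell_id)
  attr(ts, "events") <- events
  ts
}

perturbed_window <- function(label, index, config) {
  if (config$perturbation_factor >= 1) return(FALSE)
  if (config$perturbation_mode == "chronic") return(TRUE)
  label %in% c("HGa", "HGlambda")
}

type_pairs <- function(types) {
  idx <- which(upper.tri(diag(length(types)), diag = TRUE), arr.ind = TRUE)
  data.frame(type_a = types[idx[, 1]], type_b = types[idx[, 2]],
             stringsAsFactors = FALSE)
}

# distance of every cell to the endocrine centroid (the islet core)
core_distances <- function(cells) {
  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  endo <- cells$cell_type != "neuron"
  if (!any(endo)) stop_isletconn("no_endocrine_cells",
                                 "no endocrine cells in table")
  core <- colMeans(pos[endo, , drop = FALSE])
  sqrt(rowSums(sweep(pos, 2, core)^2))
}

#' Double-exponential calcium indicator kernel, sampled per frame
#'
#' `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` sampled at the middle of
#' each frame and normalised to peak 1; truncated where the tail drops
#' below 1e-3 of the peak.
#' @param config a [simulation_config()].
#' @return numeric vector of kernel taps.
#' @export
calcium_kernel <- function(config) {
  dt <- config$frame_interval_s
  L <- ceiling(7 * config$tau_decay_s / dt)
  t <- (0:L) * dt + dt / 2
  k <- exp(-t / config$tau_decay_s) - exp(-t / config$tau_rise_s)
  k <- k / max(k)
  k[seq_len(max(which(k > 1e-3)))]
}

convolve_events <- function(events, k) {
  out <- matrix(0, nrow(events), ncol(events))
  nf <- ncol(events)
  for (j in seq_along(k)) {
    lag <- j - 1
    if (lag >= nf) break
    out[, (1 + lag):nf] <- out[, (1 + lag):nf] +
      k[j] * events[, 1:(nf - lag), drop = FALSE]
  }
  out
}

#' Simulate a cohort of independent islets
#'
#' Per-animal seeds are derived deterministically from the master seed, so
#' a cohort is reproducible while its animals are independent.
#'
#' @param config a [simulation_config()].
#' @param n_animals number of animals.
#' @param perturbed apply `config$perturbation_factor` (per
#'   `config$perturbation_mode`); when `FALSE` the factor is forced to 1.
#' @param seed master seed (default `config$seed`).
#' @return a list of `n_animals` elements, each `list(cells, traces)`.
#' @export
make_cohort <- function(config, n_animals, perturbed = FALSE,
                        seed = config$seed) {
  stopifnot(n_animals >= 1)
  if (!perturbed) config$perturbation_factor <- 1
  set.seed(seed)
  animal_seeds <- sample.int(.Machine$integer.max - 1L, n_animals)
  lapply(seq_len(n_animals), function(i) {
    cells <- generate_geometry(config, animal_id = sprintf("sim%02d", i),
                               seed = animal_seeds[i])
    traces <- simulate_traces(cells, config, seed = animal_seeds[i])
    list(cells = cells, traces = traces)
  })
}
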