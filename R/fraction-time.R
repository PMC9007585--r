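#' Nearest heterotypic cell pairs
#'
#' For each cell of `type_a`, its Euclidean-nearest partner of `type_b`
#' (partners may serve several cells); ties are broken by the lowest
#' partner `cell_id`. Pairing is directional from the first-listed type,
#' so pair counts equal the number of `type_a` cells.
#'
#' @param cells an [islet_cells()] table.
#' @param type_a,type_b distinct cell types.
#' @return A data.frame of class `pair_list`: `cell_a`, `cell_b`,
#'   `type_pair`, `distance_um`. Zero rows (with attribute `reason`) when
#'   either type is absent.
#' @export
nearest_pairs <- function(cells, type_a, type_b) {
  stopifnot(type_a != type_b)
  ia <- which(cells$cell_type == type_a)
  ib <- which(cells$cell_type == type_b)
  empty <- data.frame(cell_a = character(0), cell_b = character(0),
                      type_pair = character(0), distance_um = numeric(0))
  class(empty) <- c("pair_list", "data.frame")
  if (length(ia) == 0 || length(ib) == 0) {
    attr(empty, "reason") <- paste0("no cells of type ",
                                    if (length(ia) == 0) type_a else type_b)
    return(empty)
  }
  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  # order candidates by cell_id so which.min resolves ties to lowest id
  ib <- ib[order(cells$cell_id[ib])]
  nearest <- vapply(ia, function(i) {
    d <- sqrt(colSums((t(pos[ib, , drop = FALSE]) - pos[i, ])^2))
    ib[which.min(d)]
  }, integer(1))
  d <- sqrt(rowSums((pos[ia, , drop = FALSE] -
                       pos[nearest, , drop = FALSE])^2))
  out <- data.frame(cell_a = cells$cell_id[ia],
                    cell_b = cells$cell_id[nearest],
                    type_pair = paste(type_a, type_b, sep = "-"),
                    distance_um = d)
  class(out) <- c("pair_list", "data.frame")
  out
}

#' Fraction of time pairs spend in each joint active/silent state
#'
#' For each pair, the occupancy fraction of the four joint states over the
#' window: both active, both silent, A active/B silent, A silent/B active.
#' The two mixed states are kept directional (delta-active/beta-silent is
#' distinct from delta-silent/beta-active). The four fractions sum to 1
#' exactly for every pair.
#'
#' @param states a [binarize_traces()] result.
#' @param pairs a [nearest_pairs()] pair list.
#' @return A list of class `fraction_time_result`: `fractions`
#'   (cell_a, cell_b, type_pair, f_both_active, f_both_silent,
#'   f_a_active_b_silent, f_a_silent_b_active, n_frames), `window`,
#'   `n_frames`.
#' @export
fraction_time <- function(states, pairs) {
  nf <- ncol(states$states)
  if (nf == 0) stop_isletconn("zero_frames", "no frames in state matrix")
  ia <- match(pairs$cell_a, states$cell_id)
  ib <- match(pairs$cell_b, states$cell_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop_isletconn("trace_cell_mismatch",
                   "pair cells missing from state matrix")
  }
  f <- t(vapply(seq_len(nrow(pairs)), function(k) {
    joint_fractions(states$states[ia[k], ], states$states[ib[k], ], nf)
  }, numeric(4)))
  fractions <- data.frame(cell_a = pairs$cell_a, cell_b = pairs$cell_b,
                          type_pair = pairs$type_pair,
                          f_both_active = f[, 1], f_both_silent = f[, 2],
                          f_a_active_b_silent = f[, 3],
                          f_a_silent_b_active = f[, 4],
                          n_frames = nf)
  structure(list(fractions = fractions, window = states$window,
                 n_frames = nf),
            class = "fraction_time_result")
}

# Occupancy fractions of the four joint states. Three fractions are plain
# count/n ratios; both-silent is the complement of a swap-invariant partial
# sum, so conservation (the four sum to exactly 1) and A/B swap symmetry
# hold exactly in floating point, not just to tolerance.
joint_fractions <- function(a, b, nf) {
  f_aa <- sum(a & b) / nf
  f_as <- sum(a & !b) / nf
  f_sa <- sum(!a & b) / nf
  f_ss <- 1 - (f_aa + (f_as + f_sa))
  if (f_ss < 0) {
    f_ss <- 0
    f_aa <- 1 - (f_as + f_sa)
    if (f_aa < 0) { f_aa <- 0; f_as <- 1 - f_sa }
  }
  c(f_aa, f_ss, f_as, f_sa)
}

#' @export
print.fraction_time_result <- function(x, ...) {
  cat("<fraction_time_result>", nrow(x$fractions), "pairs, window",
      x$window, "(", x$n_frames, "frames )\n")
  invisible(x)
}
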