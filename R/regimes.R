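#' Stage regimes for the synthetic cohort generator
#'
#' A regime parameterises the gaze statistics of one driving stage. Fixation
#' targets live on a fixed square lattice of grid cells spaced 3 degrees of
#' visual angle apart on the reference plane; the scan path is a first-order
#' Markov chain over the `m = max(2, round(dispersion * grid_size^2))` active
#' cells, mixing a deterministic serpentine cycle with uniform jumps:
#' `T = (1 - eps) * P_cycle + eps * U` (the uniform part excludes
#' self-transitions, since a zero-amplitude "saccade" between two fixations in
#' the same cell is not a recoverable event). `dispersion` therefore controls
#' stationary spread (how many cells are visited, hence SGE) and
#' `regularity_eps` controls scan-path randomness (hence GTE), independently.
#'
#' @name stage-regimes
NULL

STAGE_LABELS <- c("HighwayDriving", "HighwayNback", "UrbanDriving", "UrbanNback")

#' Construct a stage regime
#'
#' @param stage_label one of `HighwayDriving`, `HighwayNback`,
#'   `UrbanDriving`, `UrbanNback`.
#' @param fix_dur_mu,fix_dur_sigma log-scale mean and sd of fixation duration
#'   (ms, lognormal).
#' @param grid_size cells per axis of the target lattice (>= 2).
#' @param dispersion stationary spread in `[0, 1]`: fraction of lattice cells
#'   that are active.
#' @param regularity_eps mixing weight in `[0, 1]` between the deterministic
#'   cycle (0) and uniform jumps (1).
#' @param saccade_peak_gain saccade speed gain; larger values give faster,
#'   shorter saccades (deg/s of measured velocity per degree is of order
#'   `gain`).
#' @param blink_rate blinks per minute (>= 0).
#' @param dropout_rate per-frame probability of an invalid (tracking-loss)
#'   frame.
#' @param tlx_load latent workload offset driving the stage's TLX answers.
#' @param blink_frames_invalid flag blink frames as invalid tracker frames
#'   too; default `FALSE` so the blink detector is exercised.
#' @return a `stage_regime` list.
#' @export
stage_regime <- function(stage_label,
                         fix_dur_mu = log(400), fix_dur_sigma = 0.3,
                         grid_size = 8, dispersion = 0.5,
                         regularity_eps = 0.3, saccade_peak_gain = 30,
                         blink_rate = 15, dropout_rate = 0, tlx_load = 0,
                         blink_frames_invalid = FALSE) {
  stage_label <- match.arg(stage_label, STAGE_LABELS)
  stopifnot(fix_dur_sigma > 0, grid_size >= 2,
            dispersion >= 0, dispersion <= 1,
            regularity_eps >= 0, regularity_eps <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            blink_rate >= 0, is.finite(tlx_load))
  structure(list(stage_label = stage_label, fix_dur_mu = fix_dur_mu,
                 fix_dur_sigma = fix_dur_sigma, grid_size = grid_size,
                 dispersion = dispersion, regularity_eps = regularity_eps,
                 saccade_peak_gain = saccade_peak_gain, blink_rate = blink_rate,
                 dropout_rate = dropout_rate, tlx_load = tlx_load,
                 blink_frames_invalid = blink_frames_invalid),
            class = "stage_regime")
}

#' Default regimes for the four driving stages
#'
#' Calibrated to reproduce the ordinal between-stage pattern of the gaze
#' metrics (not magnitudes): fixation duration and blink rate higher on the
#' highway and raised by the N-Back task; saccade speed reduced by load on
#' either axis; gaze dispersion (SGE) higher in urban driving and reduced by
#' the N-Back task; scan-path randomness (GTE) higher on the highway, reduced
#' by the N-Back task on the highway but raised by it in urban driving.
#' Latent TLX load orders the stages HighwayDriving < UrbanDriving <
#' HighwayNback < UrbanNback.
#'
#' @param dropout_rate per-frame invalid probability applied to every stage;
#'   default 0.02.
#' @return named list of four [stage_regime()] objects.
#' @export
default_regimes <- function(dropout_rate = 0.02) {
  list(
    HighwayDriving = stage_regime("HighwayDriving", fix_dur_mu = log(420),
                                  dispersion = 0.35, regularity_eps = 0.65,
                                  saccade_peak_gain = 30, blink_rate = 20,
                                  dropout_rate = dropout_rate, tlx_load = -1.5),
    HighwayNback = stage_regime("HighwayNback", fix_dur_mu = log(520),
                                dispersion = 0.25, regularity_eps = 0.12,
                                saccade_peak_gain = 20, blink_rate = 26,
                                dropout_rate = dropout_rate, tlx_load = 1.5),
    UrbanDriving = stage_regime("UrbanDriving", fix_dur_mu = log(310),
                                dispersion = 0.85, regularity_eps = 0.25,
                                saccade_peak_gain = 24, blink_rate = 12,
                                dropout_rate = dropout_rate, tlx_load = 0),
    UrbanNback = stage_regime("UrbanNback", fix_dur_mu = log(390),
                              dispersion = 0.6, regularity_eps = 0.45,
                              saccade_peak_gain = 17, blink_rate = 16,
                              dropout_rate = dropout_rate, tlx_load = 2)
  )
}

# serpentine (boustrophedon) cell order over a g x g lattice; returns an
# m x 2 matrix of cell (col, row) indices for the first m cells
serpentine_cells <- function(grid_size, m) {
  g <- grid_size
  rows <- rep(0:(g - 1), each = g)
  cols <- unlist(lapply(0:(g - 1), function(j) if (j %% 2 == 0) 0:(g - 1) else (g - 1):0))
  cbind(col = cols[seq_len(m)], row = rows[seq_len(m)])
}

# Active-cell centres in plane cm, centred on the plane origin. Cells sit on
# a lattice spaced a whole number of entropy bins apart and offset to bin
# centres, so generator cells coincide with detector bins (with the default
# px_per_cm = 32 and bin_px = 30 the spacing is 5.625 cm, about 2.9 degrees
# at 112 cm - comfortably above the 1 degree/sample saccade gate).
active_cell_positions <- function(regime, distance = 112, px_per_cm = 32,
                                  bin_px = 30, spacing_bins = 6) {
  g <- regime$grid_size
  m <- max(2L, as.integer(round(regime$dispersion * g^2)))
  cells <- serpentine_cells(g, m)
  spacing_cm <- spacing_bins * bin_px / px_per_cm
  half_bin_cm <- bin_px / 2 / px_per_cm
  cbind(u = (cells[, 1] - (g - 1) / 2) * spacing_cm + half_bin_cm,
        v = (cells[, 2] - (g - 1) / 2) * spacing_cm + half_bin_cm)
}

#' Expected transition entropy of a regime's Markov kernel
#'
#' Analytic conditional entropy (bits) of
#' `T = (1 - eps) * P_cycle + eps * U` over `n_states` active cells, with the
#' uniform part excluding self-transitions - the kernel the generator
#' simulates. Strictly increasing in `eps` for `n_states >= 3`.
#'
#' @param regularity_eps mixing weight in `[0, 1]`.
#' @param n_states number of active cells (>= 2).
#' @return entropy in bits.
#' @export
expected_transition_entropy <- function(regularity_eps, n_states) {
  stopifnot(n_states >= 2, regularity_eps >= 0, regularity_eps <= 1)
  m <- n_states
  eps <- regularity_eps
  if (m == 2 || eps == 0) {
    p_succ <- if (m == 2) 1 else 1 - eps
    return(if (p_succ == 1) 0 else NA_real_)  # unreachable guard
  }
  p_succ <- (1 - eps) + eps / (m - 1)
  p_other <- eps / (m - 1)
  h <- -p_succ * log2(p_succ)
  if (p_other > 0) h <- h - (m - 2) * p_other * log2(p_other)
  h
}
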