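#' Windowed gaze metrics and quality control
#'
#' Metrics are computed over overlapping 30 s windows advanced in 1 s steps
#' through each 300 s driving stage. A window is usable only when strictly
#' more than 50% of its raw frames are valid; per-metric values from usable
#' windows are averaged into stage means. Participants are retained only if
#' no more than 35% of their windows (across all four stages) are low
#' quality.
#'
#' @name gaze-metrics
NULL

#' Lay out overlapping analysis windows over a stage
#'
#' @param stage_duration_s stage length in seconds (>= `window_s`).
#' @param window_s window length in seconds, default 30.
#' @param step_s step between window starts, default 1.
#' @param sampling_rate Hz, default 60.
#' @return tibble: `start_s`, `end_s`, `frame_start`, `frame_end` (1-based,
#'   inclusive). A 300 s stage yields 271 windows.
#' @export
make_windows <- function(stage_duration_s, window_s = 30, step_s = 1,
                         sampling_rate = 60) {
  if (stage_duration_s < window_s)
    stop("stage shorter than one analysis window")
  starts <- seq(0, stage_duration_s - window_s, by = step_s)
  tibble::tibble(
    start_s = starts,
    end_s = starts + window_s,
    frame_start = as.integer(round(starts * sampling_rate)) + 1L,
    frame_end = as.integer(round((starts + window_s) * sampling_rate))
  )
}

#' Window validity fraction and usability
#'
#' @param windows a [make_windows()] tibble.
#' @param invalid_frame_indices integer indices of invalid frames.
#' @return the input windows with `valid_fraction` and `usable`
#'   (`valid_fraction > 0.5`, strict) columns appended.
#' @export
window_quality <- function(windows, invalid_frame_indices) {
  inv <- sort(unique(as.integer(invalid_frame_indices)))
  n_inv <- findInterval(windows$frame_end, inv) -
    findInterval(windows$frame_start - 1L, inv)
  span <- windows$frame_end - windows$frame_start + 1L
  vf <- 1 - n_inv / span
  dplyr::mutate(windows, valid_fraction = vf, usable = vf > 0.5)
}

#' Per-window metrics for one stage
#'
#' Events are assigned to windows by their temporal midpoint (half-open on
#' the right), so an event is counted once per window despite the overlap.
#' Windows with no fixations have missing (not zero) entropy and duration
#' metrics; they are excluded from the stage mean of that metric.
#'
#' @param windows output of [window_quality()].
#' @param fixations,saccades,blinks event tibbles from the detectors, with
#'   fixation centroids in pixels.
#' @param bin_px entropy grid cell edge in pixels, default 30.
#' @param sampling_rate Hz, default 60.
#' @return windows with `mean_fixation_duration_ms`, `mean_saccade_velocity`,
#'   `blink_count`, `sge_bits`, `gte_bits` appended (`NA` metrics on
#'   non-usable windows).
#' @export
compute_window_metrics <- function(windows, fixations, saccades, blinks,
                                   bin_px = 30, sampling_rate = 60) {
  mid_s <- function(ev) (ev$start_frame + ev$end_frame - 1) / 2 / sampling_rate
  fx_mid <- mid_s(fixations)
  sc_mid <- mid_s(saccades)
  bl_mid <- mid_s(blinks)
  fx_ord <- order(fx_mid)
  fx_mid_o <- fx_mid[fx_ord]
  fx_dur_o <- fixations$duration_ms[fx_ord]
  fx_bin_o <- bin_fixations(fixations$centroid_u_px[fx_ord],
                            fixations$centroid_v_px[fx_ord], bin_px)
  sc_mid_o <- sort(sc_mid)
  sc_vel_o <- saccades$mean_velocity_deg_s[order(sc_mid)]
  bl_mid_o <- sort(bl_mid)
  # prefix sums for O(1) per-window means
  cs_dur <- c(0, cumsum(fx_dur_o))
  cs_vel <- c(0, cumsum(sc_vel_o))

  nw <- nrow(windows)
  mfd <- msv <- sge <- gte <- rep(NA_real_, nw)
  nbl <- rep(NA_integer_, nw)
  fx_lo <- findInterval(windows$start_s, fx_mid_o, left.open = TRUE) + 1L
  fx_hi <- findInterval(windows$end_s, fx_mid_o, left.open = TRUE)
  sc_lo <- findInterval(windows$start_s, sc_mid_o, left.open = TRUE) + 1L
  sc_hi <- findInterval(windows$end_s, sc_mid_o, left.open = TRUE)
  bl_lo <- findInterval(windows$start_s, bl_mid_o, left.open = TRUE) + 1L
  bl_hi <- findInterval(windows$end_s, bl_mid_o, left.open = TRUE)
  for (k in seq_len(nw)) {
    if (!windows$usable[k]) next
    nf <- fx_hi[k] - fx_lo[k] + 1L
    if (nf > 0) {
      mfd[k] <- (cs_dur[fx_hi[k] + 1L] - cs_dur[fx_lo[k]]) / nf
      b <- fx_bin_o[fx_lo[k]:fx_hi[k]]
      sge[k] <- stationary_gaze_entropy(b)
      if (nf > 1) gte[k] <- gaze_transition_entropy(b)
    }
    ns <- sc_hi[k] - sc_lo[k] + 1L
    if (ns > 0) msv[k] <- (cs_vel[sc_hi[k] + 1L] - cs_vel[sc_lo[k]]) / ns
    nbl[k] <- max(0L, bl_hi[k] - bl_lo[k] + 1L)
  }
  dplyr::mutate(windows,
                mean_fixation_duration_ms = mfd,
                mean_saccade_velocity = msv,
                blink_count = nbl,
                sge_bits = sge,
                gte_bits = gte)
}

# midpoint convention: window [start_s, end_s) half-open; events whose
# midpoint falls exactly on end_s belong to the next window.

#' Participant-level quality control
#'
#' @param usable logical vector of window usability across all four stages of
#'   one participant.
#' @param max_low_quality maximum tolerated fraction of low-quality windows,
#'   default 0.35.
#' @return list with `n_windows`, `n_low_quality`, `low_quality_fraction`,
#'   `include` (FALSE iff the fraction is strictly above the cap).
#' @export
participant_qc <- function(usable, max_low_quality = 0.35) {
  n <- length(usable)
  if (!n) stop("no windows supplied")
  nl <- sum(!usable)
  frac <- nl / n
  list(n_windows = n, n_low_quality = nl, low_quality_fraction = frac,
       include = frac <= max_low_quality)
}

#' Average window metrics into stage means
#'
#' @param window_metrics output of [compute_window_metrics()].
#' @param stage_label stage name carried into the result.
#' @return one-row tibble with the unweighted mean of each metric over usable
#'   windows where that metric is defined (denominators may differ), plus
#'   `n_usable_windows` and `n_total_windows`.
#' @export
aggregate_stage <- function(window_metrics, stage_label) {
  us <- window_metrics[window_metrics$usable, , drop = FALSE]
  if (nrow(us) == 0) {
    return(tibble::tibble(stage = stage_label,
                          fixation_duration = NA_real_, saccade_velocity = NA_real_,
                          blink_number = NA_real_, sge = NA_real_, gte = NA_real_,
                          n_usable_windows = 0L,
                          n_total_windows = nrow(window_metrics)))
  }
  m <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  tibble::tibble(
    stage = stage_label,
    fixation_duration = m(us$mean_fixation_duration_ms),
    saccade_velocity = m(us$mean_saccade_velocity),
    blink_number = m(us$blink_count),
    sge = m(us$sge_bits),
    gte = m(us$gte_bits),
    n_usable_windows = nrow(us),
    n_total_windows = nrow(window_metrics)
  )
}

#' Full single-stage analysis: projection, events, windowed metrics
#'
#' Convenience orchestration used by [run_study()] and the command line
#' interface: project the frames, detect blinks on the eyelid channel, mask
#' blink frames (default), segment fixations and saccades, window the stage
#' and compute per-window metrics.
#'
#' @param frames gaze-frame tibble (see [read_gaze_csv()]).
#' @param config a [run_config()] list.
#' @return list: `windows` (metrics tibble), `fixations`, `saccades`,
#'   `blinks`, `invalid_frames`, `n_frames`.
#' @export
analyze_stage <- function(frames, config = run_config()) {
  n <- nrow(frames)
  proj <- project_frames(frames,
                         distance = config$plane_distance_cm,
                         px_per_cm = config$px_per_cm,
                         quality_threshold = config$quality_threshold)
  blinks <- detect_blinks(frames$eyelid_open,
                          min_frames = config$blink_min_frames,
                          max_frames = config$blink_max_frames)
  valid <- rep(FALSE, n)
  valid[proj$points$frame_index] <- TRUE
  if (isTRUE(config$exclude_blink_frames) && nrow(blinks)) {
    for (k in seq_len(nrow(blinks)))
      valid[blinks$start_frame[k]:blinks$end_frame[k]] <- FALSE
  }
  # per-frame aligned gaze directions and plane coordinates
  dirs <- cbind(frames$gazedir_x, frames$gazedir_y, frames$gazedir_z)
  pts <- data.frame(u_px = rep(NA_real_, n), v_px = rep(NA_real_, n))
  pts$u_px[proj$points$frame_index] <- proj$points$u_px
  pts$v_px[proj$points$frame_index] <- proj$points$v_px
  fixations <- detect_fixations(dirs, valid, pts,
                                threshold_deg = config$fixation_threshold_deg,
                                min_frames = config$fixation_min_frames,
                                max_frames = config$fixation_max_frames,
                                sampling_rate = config$sampling_rate_hz)
  saccades <- detect_saccades(dirs, valid,
                              threshold_deg = config$fixation_threshold_deg,
                              min_frames = config$saccade_min_frames,
                              max_frames = config$saccade_max_frames,
                              max_amplitude_deg = config$saccade_max_amplitude_deg,
                              max_avr = config$saccade_max_avr,
                              min_peak_velocity = config$saccade_min_peak_velocity,
                              sampling_rate = config$sampling_rate_hz)
  wins <- make_windows(n / config$sampling_rate_hz,
                       window_s = config$window_s, step_s = config$step_s,
                       sampling_rate = config$sampling_rate_hz)
  wins <- window_quality(wins, proj$invalid_frames)
  wins <- compute_window_metrics(wins, fixations, saccades, blinks,
                                 bin_px = config$bin_px,
                                 sampling_rate = config$sampling_rate_hz)
  list(windows = wins, fixations = fixations, saccades = saccades,
       blinks = blinks, invalid_frames = proj$invalid_frames, n_frames = n)
}
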