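#' Oculomotor event detection
#'
#' Threshold-based segmentation of the 60 Hz gaze-direction sequence and
#' eyelid-opening signal into fixations, saccades and blinks:
#'
#' * fixations: inter-sample gaze direction change < 1 degree for at least 6
#'   consecutive frames (>= 100 ms), capped at 1200 frames (20 s); longer
#'   stable runs are truncated at the cap and a new fixation begins.
#' * saccades: runs of inter-sample changes >= 1 degree lasting 2-12 frames
#'   (about 30-200 ms), total amplitude <= 60 degrees, amplitude-to-peak-
#'   velocity ratio (AVR) <= 10, and peak velocity above a configurable floor.
#' * blinks: eyelid-signal closures bounded by large negative then positive
#'   discrete derivatives, lasting 5-180 frames (about 83-3000 ms).
#'
#' Frames flagged invalid terminate fixation/saccade runs; no interpolation is
#' performed. Short stable runs that qualify as neither event are left
#' unlabelled rather than forced into a class.
#'
#' @name oculomotor-events
NULL

#' Angular change between two gaze directions
#'
#' @param dir_a,dir_b unit length-3 vectors.
#' @return angle in degrees (`acos` of the clamped dot product).
#' @examples
#' angular_change(c(0, 0, 1), c(0, 1, 0))  # 90
#' @export
angular_change <- function(dir_a, dir_b) {
  na <- sqrt(sum(dir_a^2)); nb <- sqrt(sum(dir_b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length direction vector")
  d <- sum(dir_a * dir_b) / (na * nb)
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

# inter-sample angular changes (degrees) for an n x 3 matrix of directions
angular_steps <- function(directions) {
  n <- nrow(directions)
  if (is.null(n) || n < 2) return(numeric(0))
  dirs <- directions / sqrt(rowSums(directions^2))
  d <- rowSums(dirs[-n, , drop = FALSE] * dirs[-1, , drop = FALSE])
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

# maximal runs of TRUE in a logical vector -> matrix [from, to] (step indices)
true_runs <- function(x) {
  if (!length(x)) return(cbind(from = integer(), to = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(from = starts[keep], to = ends[keep])
}

#' Detect fixations
#'
#' @param directions n x 3 matrix of gaze direction vectors, time ordered at
#'   the given sampling rate.
#' @param valid_mask logical length n; invalid frames break runs. Default all
#'   valid.
#' @param points optional data frame with per-frame `u_px`, `v_px` (aligned to
#'   `directions` rows, `NA` where unavailable) used for centroids.
#' @param threshold_deg stability threshold, default 1 degree.
#' @param min_frames,max_frames fixation length gates in frames (6 and 1200).
#' @param sampling_rate Hz, default 60.
#' @return tibble: `start_frame`, `end_frame`, `n_frames`, `duration_ms`,
#'   `centroid_u_px`, `centroid_v_px`.
#' @export
detect_fixations <- function(directions, valid_mask = NULL, points = NULL,
                             threshold_deg = 1, min_frames = 6,
                             max_frames = 1200, sampling_rate = 60) {
  directions <- as.matrix(directions)
  n <- nrow(directions)
  empty <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                          n_frames = integer(), duration_ms = numeric(),
                          centroid_u_px = numeric(), centroid_v_px = numeric())
  if (n < 2) return(empty)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  steps <- angular_steps(directions)
  stable <- steps < threshold_deg & valid_mask[-n] & valid_mask[-1]
  runs <- true_runs(stable)
  out <- list()
  for (k in seq_len(nrow(runs))) {
    f0 <- unname(runs[k, 1])   # frames f0 .. f1 (run of steps spans steps+1 frames)
    f1 <- unname(runs[k, 2]) + 1L
    len <- f1 - f0 + 1L
    if (len < min_frames) next
    # truncate-and-restart at the cap
    starts <- seq(f0, f1, by = max_frames)
    for (s in starts) {
      e <- min(s + max_frames - 1L, f1)
      if (e - s + 1L >= min_frames) out[[length(out) + 1L]] <- c(s, e)
    }
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  cu <- cv <- rep(NA_real_, nrow(m))
  if (!is.null(points)) {
    for (k in seq_len(nrow(m))) {
      span <- m[k, 1]:m[k, 2]
      cu[k] <- mean(points$u_px[span], na.rm = TRUE)
      cv[k] <- mean(points$v_px[span], na.rm = TRUE)
    }
  }
  nf <- m[, 2] - m[, 1] + 1L
  tibble::tibble(start_frame = as.integer(m[, 1]), end_frame = as.integer(m[, 2]),
                 n_frames = as.integer(nf),
                 duration_ms = nf * 1000 / sampling_rate,
                 centroid_u_px = cu, centroid_v_px = cv)
}

#' Detect saccades
#'
#' Duration is counted in inter-sample steps of >= `threshold_deg` (2-12 at
#' 60 Hz is roughly 30-200 ms of motion). The reported frame span excludes
#' boundary frames that belong to an adjacent stable run, so fixation and
#' saccade spans never overlap.
#'
#' @inheritParams detect_fixations
#' @param min_frames,max_frames saccadic-step count gates (2 and 12).
#' @param max_amplitude_deg total amplitude gate (60 degrees).
#' @param max_avr amplitude / peak-velocity gate (10).
#' @param min_peak_velocity velocity floor in degrees per frame; default 0.5
#'   (30 deg/s at 60 Hz).
#' @return tibble: `start_frame`, `end_frame`, `duration_frames`,
#'   `amplitude_deg`, `peak_velocity` (deg/frame), `mean_velocity_deg_s`, `avr`.
#' @export
detect_saccades <- function(directions, valid_mask = NULL, threshold_deg = 1,
                            min_frames = 2, max_frames = 12,
                            max_amplitude_deg = 60, max_avr = 10,
                            min_peak_velocity = 0.5, sampling_rate = 60) {
  directions <- as.matrix(directions)
  n <- nrow(directions)
  empty <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                          duration_frames = integer(), amplitude_deg = numeric(),
                          peak_velocity = numeric(), mean_velocity_deg_s = numeric(),
                          avr = numeric())
  if (n < 2) return(empty)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  steps <- angular_steps(directions)
  pairs_valid <- valid_mask[-n] & valid_mask[-1]
  sacc <- steps >= threshold_deg & pairs_valid
  stable <- steps < threshold_deg & pairs_valid
  runs <- true_runs(sacc)
  out <- list()
  for (k in seq_len(nrow(runs))) {
    a <- unname(runs[k, 1]); b <- unname(runs[k, 2])
    dur <- b - a + 1L
    if (dur < min_frames || dur > max_frames) next
    amp <- sum(steps[a:b])
    peak <- max(steps[a:b])
    avr <- amp / peak
    if (amp > max_amplitude_deg || avr > max_avr || peak < min_peak_velocity) next
    # frame span a .. b+1; give boundary frames back to adjacent stable runs
    s <- if (a > 1L && isTRUE(stable[a - 1L])) a + 1L else a
    e <- if (b < length(steps) && isTRUE(stable[b + 1L])) b else b + 1L
    out[[length(out) + 1L]] <-
      c(s, e, dur, amp, peak, amp / dur * sampling_rate, avr)
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  tibble::tibble(start_frame = as.integer(m[, 1]), end_frame = as.integer(m[, 2]),
                 duration_frames = as.integer(m[, 3]), amplitude_deg = m[, 4],
                 peak_velocity = m[, 5], mean_velocity_deg_s = m[, 6],
                 avr = m[, 7])
}

#' Detect blinks from the eyelid-opening signal
#'
#' A candidate closure opens where the discrete derivative falls below
#' `-d_thr` and closes at the next rise above `+d_thr`; closures lasting
#' 5-180 frames are retained. `d_thr` defaults to a quarter of the signal's
#' interquartile range over the stage (scale free), which presumes a smooth,
#' band-limited baseline.
#'
#' @param eyelid_signal numeric vector, eyelid opening (arbitrary units >= 0).
#' @param valid_mask unused placeholder for interface symmetry (blinks are
#'   detected from the eyelid channel regardless of gaze validity).
#' @param d_thr derivative threshold; default `0.25 * IQR(eyelid_signal)`.
#' @param min_frames,max_frames closure duration gates (5 and 180).
#' @return tibble: `start_frame`, `end_frame`, `duration_frames`.
#' @export
detect_blinks <- function(eyelid_signal, valid_mask = NULL, d_thr = NULL,
                          min_frames = 5, max_frames = 180) {
  empty <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                          duration_frames = integer())
  n <- length(eyelid_signal)
  if (n < 2) return(empty)
  if (is.null(d_thr)) d_thr <- 0.25 * stats::IQR(eyelid_signal, na.rm = TRUE)
  if (!is.finite(d_thr) || d_thr <= 0) return(empty)
  dv <- diff(eyelid_signal)
  closing <- which(dv < -d_thr)
  opening <- which(dv > d_thr)
  out <- list()
  i <- 1L
  while (i <= length(closing)) {
    cl <- closing[i]
    op <- opening[opening > cl]
    if (!length(op)) break
    op <- op[1L]
    dur <- op - cl
    if (dur >= min_frames && dur <= max_frames) {
      out[[length(out) + 1L]] <- c(cl + 1L, op, dur)
    }
    # resume after the reopening, skipping closings inside this closure
    i <- which(closing > op)[1L]
    if (is.na(i)) break
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  tibble::tibble(start_frame = as.integer(m[, 1]), end_frame = as.integer(m[, 2]),
                 duration_frames = as.integer(m[, 3]))
}
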