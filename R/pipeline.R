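#' End-to-end study pipeline
#'
#' [run_study()] ties the stages together: projection onto the mobile
#' reference plane, event detection, windowed metrics, window- and
#' participant-level quality control, stage means, TLX scoring,
#' expected-direction accuracy tables, Spearman correlations and CCC
#' coherence, with a filter log recording every exclusion and its reason.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' All study constants are configuration with the published values as
#' defaults; nothing is hard coded at call sites. Configurations round-trip
#' through YAML unchanged ([read_run_config()] / [write_run_config()]).
#'
#' @param sampling_rate_hz tracker rate, default 60.
#' @param plane_distance_cm reference-plane distance, default 112.
#' @param px_per_cm plane pixel scale, default 32.
#' @param quality_threshold minimum per-frame tracking quality, default 1.0.
#' @param window_s,step_s analysis window length and step (30 s / 1 s).
#' @param bin_px entropy grid cell edge, default 30 px.
#' @param participant_low_quality_max maximum tolerated fraction of
#'   low-quality windows per participant, default 0.35.
#' @param nback_min_correct minimum N-Back fraction correct (strict), 0.5.
#' @param alpha significance level, default 0.05.
#' @param fixation_threshold_deg,fixation_min_frames,fixation_max_frames
#'   fixation gates (1 deg, 6, 1200).
#' @param saccade_min_frames,saccade_max_frames,saccade_max_amplitude_deg,saccade_max_avr,saccade_min_peak_velocity
#'   saccade gates (2, 12, 60 deg, 10, 0.5 deg/frame).
#' @param blink_min_frames,blink_max_frames blink gates (5, 180).
#' @param exclude_blink_frames mask blink frames before fixation/saccade
#'   segmentation, default TRUE.
#' @param direction_table expected-direction overrides; `NULL` means
#'   [default_direction_table()].
#' @param seed integer seed recorded with the run.
#' @return a `gaze_run_config` list.
#' @export
run_config <- function(sampling_rate_hz = 60, plane_distance_cm = 112,
                       px_per_cm = 32, quality_threshold = 1.0,
                       window_s = 30, step_s = 1, bin_px = 30,
                       participant_low_quality_max = 0.35,
                       nback_min_correct = 0.5, alpha = 0.05,
                       fixation_threshold_deg = 1, fixation_min_frames = 6,
                       fixation_max_frames = 1200,
                       saccade_min_frames = 2, saccade_max_frames = 12,
                       saccade_max_amplitude_deg = 60, saccade_max_avr = 10,
                       saccade_min_peak_velocity = 0.5,
                       blink_min_frames = 5, blink_max_frames = 180,
                       exclude_blink_frames = TRUE, direction_table = NULL,
                       seed = 1L) {
  cfg <- list(sampling_rate_hz = sampling_rate_hz,
              plane_distance_cm = plane_distance_cm, px_per_cm = px_per_cm,
              quality_threshold = quality_threshold, window_s = window_s,
              step_s = step_s, bin_px = bin_px,
              participant_low_quality_max = participant_low_quality_max,
              nback_min_correct = nback_min_correct, alpha = alpha,
              fixation_threshold_deg = fixation_threshold_deg,
              fixation_min_frames = fixation_min_frames,
              fixation_max_frames = fixation_max_frames,
              saccade_min_frames = saccade_min_frames,
              saccade_max_frames = saccade_max_frames,
              saccade_max_amplitude_deg = saccade_max_amplitude_deg,
              saccade_max_avr = saccade_max_avr,
              saccade_min_peak_velocity = saccade_min_peak_velocity,
              blink_min_frames = blink_min_frames,
              blink_max_frames = blink_max_frames,
              exclude_blink_frames = exclude_blink_frames,
              direction_table = direction_table, seed = seed)
  validate_run_config(cfg)
  structure(cfg, class = "gaze_run_config")
}

validate_run_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("config error: ", msg)
  chk(cfg$sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  chk(cfg$plane_distance_cm > 0, "plane_distance_cm must be positive")
  chk(cfg$px_per_cm > 0, "px_per_cm must be positive")
  chk(cfg$quality_threshold >= 0 && cfg$quality_threshold <= 1,
      "quality_threshold must be in [0, 1]")
  chk(cfg$window_s > 0 && cfg$step_s > 0, "window_s and step_s must be positive")
  chk(cfg$bin_px > 0, "bin_px must be positive")
  chk(cfg$participant_low_quality_max >= 0 && cfg$participant_low_quality_max <= 1,
      "participant_low_quality_max must be in [0, 1]")
  chk(cfg$nback_min_correct >= 0 && cfg$nback_min_correct <= 1,
      "nback_min_correct must be in [0, 1]")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$fixation_min_frames >= 2, "fixation_min_frames must be >= 2")
  chk(cfg$fixation_max_frames >= cfg$fixation_min_frames,
      "fixation_max_frames must be >= fixation_min_frames")
  chk(cfg$saccade_max_frames >= cfg$saccade_min_frames,
      "saccade_max_frames must be >= saccade_min_frames")
  chk(cfg$blink_max_frames >= cfg$blink_min_frames,
      "blink_max_frames must be >= blink_min_frames")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return [read_run_config()]: a `gaze_run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dt <- raw$direction_table
  raw$direction_table <- NULL
  cfg <- do.call(run_config, raw)
  if (!is.null(dt))
    cfg$direction_table <- tibble::tibble(measure = vapply(dt, `[[`, "", "measure"),
                                          pair = vapply(dt, `[[`, "", "pair"),
                                          higher = vapply(dt, `[[`, "", "higher"))
  cfg
}

#' @rdname read_run_config
#' @param config a [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$direction_table)) {
    dt <- x$direction_table
    x$direction_table <- lapply(seq_len(nrow(dt)), function(i)
      list(measure = dt$measure[i], pair = dt$pair[i], higher = dt$higher[i]))
  } else {
    x$direction_table <- NULL
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a gaze-frames CSV
#'
#' Strict schema validation of the documented dialect (header row, UTF-8,
#' `.` decimal): all 17 columns must be present and timestamps strictly
#' increasing.
#'
#' @param path CSV path.
#' @return tibble of gaze frames.
#' @export
read_gaze_csv <- function(path) {
  req <- c("t_s", "head_x_cm", "head_y_cm", "head_z_cm",
           "headdir_x", "headdir_y", "headdir_z",
           "gazeorig_x_cm", "gazeorig_y_cm", "gazeorig_z_cm",
           "gazedir_x", "gazedir_y", "gazedir_z",
           "eyelid_open", "head_q", "gaze_q", "valid")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- !vapply(x[req], is.numeric, logical(1))
  if (any(bad))
    stop("schema error in ", path, ": non-numeric column(s) ",
         paste(req[bad], collapse = ", "))
  if (any(diff(x$t_s) <= 0)) stop("non-monotone timestamps in ", path)
  if (any(x$head_q < 0 | x$head_q > 1 | x$gaze_q < 0 | x$gaze_q > 1))
    stop("schema error in ", path, ": quality values outside [0, 1]")
  x
}

#' Write a study report as JSON
#'
#' @param report the list returned by [run_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# read a cohort-style CSV directory into the structures run_study needs
read_cohort_dir <- function(dir) {
  stages_path <- file.path(dir, "stages.csv")
  if (!file.exists(stages_path)) stop("no stages.csv in ", dir)
  stages <- readr::read_csv(stages_path, show_col_types = FALSE, progress = FALSE)
  tlx <- readr::read_csv(file.path(dir, "tlx.csv"), show_col_types = FALSE,
                         progress = FALSE)
  nb_path <- file.path(dir, "nback.csv")
  nback <- if (file.exists(nb_path))
    readr::read_csv(nb_path, show_col_types = FALSE, progress = FALSE)
  else tibble::tibble(participant = character(), stage = character(),
                      fraction_correct = numeric())
  list(stages = stages, tlx = tlx, nback = nback, dir = dir)
}

#' Run the full study analysis
#'
#' Accepts either an in-memory synthetic cohort ([simulate_cohort()]) or a
#' directory of CSV files in the cohort dialect ([write_cohort_csv()]).
#' Gaze frames are processed one participant-stage at a time.
#'
#' @param cohort a `gaze_cohort`, or `NULL` when `input_dir` is given.
#' @param input_dir directory with `stages.csv`, `tlx.csv`, `nback.csv` and
#'   per-stage gaze CSVs.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `stage_means.csv`, `accuracy.csv`, `correlations.csv`,
#'   `coherence.csv` and `exclusions.csv` (existing files are overwritten
#'   atomically, never partially).
#' @param verbose log per-participant QC decisions with [message()].
#' @return report list: `config`, `n_participants`, `included`, `exclusions`
#'   (with reasons), `filter_log` (frames/windows discarded per cell),
#'   `stage_means`, `stage_summary`, `accuracy`, `correlations`, `coherence`.
#' @export
run_study <- function(cohort = NULL, input_dir = NULL, config = run_config(),
                      out_dir = NULL, verbose = FALSE) {
  validate_run_config(config)
  if (is.null(cohort) && is.null(input_dir))
    stop("supply a cohort or an input_dir")
  from_dir <- is.null(cohort)
  src <- if (from_dir) read_cohort_dir(input_dir) else NULL
  cells <- if (from_dir) src$stages[, c("participant", "stage")] else
    cohort$plan[, c("participant", "stage")]
  tlx <- if (from_dir) src$tlx else cohort$tlx
  nback <- if (from_dir) src$nback else cohort$nback
  participants <- unique(cells$participant)

  stage_rows <- list(); usable_by_part <- list(); log_rows <- list()
  for (p in participants) {
    p_cells <- cells[cells$participant == p, ]
    us <- logical(0)
    for (k in seq_len(nrow(p_cells))) {
      st <- p_cells$stage[k]
      frames <- if (from_dir) {
        f <- src$stages$file[src$stages$participant == p & src$stages$stage == st]
        read_gaze_csv(file.path(src$dir, f))
      } else {
        cohort_stage_frames(cohort, p, st)$frames
      }
      res <- analyze_stage(frames, config)
      us <- c(us, res$windows$usable)
      stage_rows[[length(stage_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(participant = p), aggregate_stage(res$windows, st))
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        participant = p, stage = st, n_frames = res$n_frames,
        n_frames_discarded = length(res$invalid_frames),
        n_windows = nrow(res$windows),
        n_windows_dropped = sum(!res$windows$usable),
        n_fixations = nrow(res$fixations), n_saccades = nrow(res$saccades),
        n_blinks = nrow(res$blinks))
    }
    usable_by_part[[p]] <- us
  }
  stage_means <- dplyr::bind_rows(stage_rows)
  filter_log <- dplyr::bind_rows(log_rows)

  ## participant-level QC ----------------------------------------------------
  exclusions <- list()
  included <- character(0)
  for (p in participants) {
    qc <- participant_qc(usable_by_part[[p]],
                         max_low_quality = config$participant_low_quality_max)
    nb <- nback[nback$participant == p, ]
    nb_ok <- !nrow(nb) || all(nb$fraction_correct > config$nback_min_correct)
    if (!qc$include) {
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        participant = p, reason = "low_quality_windows_above_0.35",
        detail = sprintf("%d/%d low-quality windows", qc$n_low_quality,
                         qc$n_windows))
      if (verbose) message(p, " excluded: gaze QC")
    } else if (!nb_ok) {
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        participant = p, reason = "nback_below_0.5",
        detail = sprintf("min fraction correct %.2f", min(nb$fraction_correct)))
      if (verbose) message(p, " excluded: N-Back performance")
    } else {
      included <- c(included, p)
    }
  }
  exclusions <- if (length(exclusions)) dplyr::bind_rows(exclusions) else
    tibble::tibble(participant = character(), reason = character(),
                   detail = character())

  keep <- stage_means$participant %in% included
  sm <- stage_means[keep, c("participant", "stage", "fixation_duration",
                            "saccade_velocity", "blink_number", "sge", "gte")]
  tlx_in <- tlx[tlx$participant %in% included, ]

  dt <- if (is.null(config$direction_table)) default_direction_table() else
    config$direction_table
  if (length(included)) {
    acc_gaze <- accuracy_table(sm, dt,
                               measures = c("fixation_duration", "saccade_velocity",
                                            "blink_number", "sge", "gte"))
    acc_tlx <- accuracy_table(tlx_in, dt,
                              measures = c("mental", "physical", "temporal",
                                           "performance", "effort", "frustration",
                                           "averaged_answer"))
    correlations <- spearman_by_stage(sm, tlx_in)
    coherence <- coherence_analysis(sm, tlx_in, alpha = config$alpha)
  } else {
    acc_gaze <- acc_tlx <- tibble::tibble(
      measure = character(), pair = character(), n = integer(),
      n_expected = integer(), accuracy = numeric())
    correlations <- tibble::tibble(metric = character(), scale = character(),
                                   stage = character(), n = integer(),
                                   rho = numeric(), p = numeric(),
                                   band = character())
    coherence <- tibble::tibble(pairing = character(), pair = character(),
                                mean_abs = numeric(), min_abs = numeric(),
                                max_abs = numeric(), n_components = integer())
  }
  stage_summary <- sm |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(dplyr::across(c("fixation_duration", "saccade_velocity",
                                     "blink_number", "sge", "gte"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n = dplyr::n(), .groups = "drop")

  report <- list(
    config = unclass(config)[setdiff(names(config), "direction_table")],
    n_participants = length(participants),
    included = included,
    exclusions = exclusions,
    filter_log = filter_log,
    stage_means = sm,
    stage_summary = stage_summary,
    accuracy = list(gaze = acc_gaze, tlx = acc_tlx),
    correlations = correlations,
    coherence = coherence
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    readr::write_csv(sm, file.path(out_dir, "stage_means.csv"))
    readr::write_csv(dplyr::bind_rows(gaze = acc_gaze, tlx = acc_tlx,
                                      .id = "family"),
                     file.path(out_dir, "accuracy.csv"))
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    readr::write_csv(coherence, file.path(out_dir, "coherence.csv"))
    readr::write_csv(exclusions, file.path(out_dir, "exclusions.csv"))
  }
  report
}
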