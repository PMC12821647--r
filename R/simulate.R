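#' Seeded synthetic cohorts with ground-truth oculomotor events
#'
#' The generator emulates 60 Hz remote-tracker frames for four 300 s driving
#' stages with condition-dependent fixation dispersion, scan-path regularity,
#' saccade dynamics, blink rate and tracking dropouts, plus ordinal NASA-TLX
#' responses and N-Back performance. Every generated fixation, saccade and
#' blink is recorded as ground truth so that detector recovery can be tested.
#'
#' @name synthetic-data
NULL

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# angle (degrees) between plane positions p and q (cm) seen from the origin
# of a plane at `distance` cm
plane_angle_deg <- function(p, q, distance) {
  a <- c(p[1], p[2], distance); b <- c(q[1], q[2], distance)
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Simulate one driving stage of gaze frames
#'
#' Alternating fixation-saccade process: fixation cells follow the regime's
#' Markov kernel; fixation durations are lognormal (clamped to the 6-1200
#' frame detector range); within-fixation jitter is uniform within +/-0.25
#' degrees per axis, so inter-sample change never reaches the 1 degree
#' threshold; saccades move linearly in plane coordinates over
#' `clamp(min(round(60/gain), floor(A/1.8)), 2, 12)` frames so every
#' inter-sample step clears 1 degree; blinks are a Poisson process placed
#' inside sufficiently long fixations (splitting them in the ground truth),
#' zeroing the eyelid signal while gaze holds its last value; dropout frames
#' are flagged invalid. The eyelid baseline is a slow sinusoidal drift plus
#' small noise, as the derivative-threshold blink detector presumes a
#' band-limited signal.
#'
#' @param regime a [stage_regime()].
#' @param duration_s stage length in seconds (> 0); 300 in the study design.
#' @param seed integer seed; the same regime and seed reproduce the stage
#'   exactly.
#' @param distance,px_per_cm reference-plane geometry used to emit gaze rays.
#' @return a `synthetic_stage` list: `frames` (gaze CSV dialect tibble),
#'   `truth_fixations`, `truth_saccades`, `truth_blinks`, `regime`, `seed`.
#' @export
simulate_gaze_stage <- function(regime, duration_s = 300, seed = 1,
                                distance = 112, px_per_cm = 32) {
  stopifnot(inherits(regime, "stage_regime"))
  if (duration_s <= 0) stop("duration_s must be positive")
  rate <- 60
  n_total <- as.integer(round(duration_s * rate))
  pos <- active_cell_positions(regime, distance, px_per_cm)
  m <- nrow(pos)
  eps <- regime$regularity_eps
  gain <- regime$saccade_peak_gain

  with_seed(seed, {
    ## 1. event schedule -----------------------------------------------------
    ev_kind <- integer(0)     # 1 fixation, 2 saccade
    ev_len <- integer(0)      # frames (fixation) / steps (saccade)
    ev_state <- integer(0)    # fixation cell, or saccade target cell
    ev_from <- integer(0)
    cur <- sample.int(m, 1)
    frames_used <- 0L
    while (frames_used < n_total) {
      dur_ms <- stats::rlnorm(1, regime$fix_dur_mu, regime$fix_dur_sigma)
      fl <- as.integer(clamp(round(dur_ms * rate / 1000), 6, 1200))
      ev_kind <- c(ev_kind, 1L); ev_len <- c(ev_len, fl)
      ev_state <- c(ev_state, cur); ev_from <- c(ev_from, cur)
      frames_used <- frames_used + fl
      if (frames_used >= n_total) break
      nxt <- if (m == 2) {
        if (cur == 1L) 2L else 1L
      } else if (stats::runif(1) < 1 - eps) {
        cur %% m + 1L
      } else {
        j <- sample.int(m - 1L, 1)
        if (j >= cur) j + 1L else j
      }
      amp <- plane_angle_deg(pos[cur, ], pos[nxt, ], distance)
      sd_ <- as.integer(clamp(min(round(rate / gain), floor(amp / 1.8)), 2, 12))
      ev_kind <- c(ev_kind, 2L); ev_len <- c(ev_len, sd_)
      ev_state <- c(ev_state, nxt); ev_from <- c(ev_from, cur)
      frames_used <- frames_used + (sd_ - 1L)   # interior samples only
      cur <- nxt
    }

    ## 2. materialise plane coordinates and ground truth ---------------------
    n_ev <- length(ev_kind)
    xs <- vector("list", n_ev); ys <- vector("list", n_ev)
    jit_cm <- distance * tan(0.25 * pi / 180)
    fr <- 1L
    tf <- ts <- list()
    for (k in seq_len(n_ev)) {
      if (ev_kind[k] == 1L) {
        fl <- ev_len[k]
        xs[[k]] <- pos[ev_state[k], 1] + stats::runif(fl, -jit_cm, jit_cm)
        ys[[k]] <- pos[ev_state[k], 2] + stats::runif(fl, -jit_cm, jit_cm)
        tf[[length(tf) + 1L]] <- c(fr, fr + fl - 1L, ev_state[k])
        fr <- fr + fl
      } else {
        d <- ev_len[k]
        frac <- seq_len(d - 1L) / d
        a <- pos[ev_from[k], ]; b <- pos[ev_state[k], ]
        xs[[k]] <- a[1] + frac * (b[1] - a[1])
        ys[[k]] <- a[2] + frac * (b[2] - a[2])
        amp <- plane_angle_deg(a, b, distance)
        ts[[length(ts) + 1L]] <- c(fr, fr + d - 2L, d, amp)
        fr <- fr + d - 1L
      }
    }
    x <- unlist(xs); y <- unlist(ys)
    x <- x[seq_len(n_total)]; y <- y[seq_len(n_total)]
    truth_fix <- do.call(rbind, tf)
    truth_sac <- if (length(ts)) do.call(rbind, ts) else
      matrix(numeric(0), ncol = 4)
    keep_f <- truth_fix[, 2] <= n_total
    truth_fix <- truth_fix[keep_f, , drop = FALSE]
    if (nrow(truth_sac)) truth_sac <- truth_sac[truth_sac[, 2] <= n_total, , drop = FALSE]

    ## 3. blinks: carve out of long-enough fixations -------------------------
    n_blinks <- stats::rpois(1, regime$blink_rate * duration_s / 60)
    bl <- list()
    if (n_blinks > 0 && nrow(truth_fix)) {
      durs <- sample(6:12, n_blinks, replace = TRUE)
      margin <- 6L
      avail <- which(truth_fix[, 2] - truth_fix[, 1] + 1 >= max(durs) + 2L * margin)
      avail <- avail[sample.int(length(avail))]
      n_place <- min(n_blinks, length(avail))
      new_fix <- list()
      used <- rep(FALSE, nrow(truth_fix))
      for (i in seq_len(n_place)) {
        fi <- avail[i]
        f0 <- truth_fix[fi, 1]; f1 <- truth_fix[fi, 2]
        L <- durs[i]
        b0 <- f0 + margin +
          sample.int(f1 - f0 + 1L - L - 2L * margin + 1L, 1) - 1L
        bl[[length(bl) + 1L]] <- c(b0, b0 + L - 1L, L)
        new_fix[[length(new_fix) + 1L]] <- c(f0, b0 - 1L, truth_fix[fi, 3])
        new_fix[[length(new_fix) + 1L]] <- c(b0 + L, f1, truth_fix[fi, 3])
        used[fi] <- TRUE
      }
      if (length(new_fix))
        truth_fix <- rbind(truth_fix[!used, , drop = FALSE],
                           do.call(rbind, new_fix))
      truth_fix <- truth_fix[order(truth_fix[, 1]), , drop = FALSE]
    }
    blink_mask <- rep(FALSE, n_total)
    for (b in bl) blink_mask[b[1]:b[2]] <- TRUE
    if (any(blink_mask)) {
      # gaze holds its last open-eye value during the blink
      hold <- which(blink_mask)
      src <- cummax(ifelse(blink_mask, 0L, seq_len(n_total)))
      x[hold] <- x[src[hold]]; y[hold] <- y[src[hold]]
    }

    ## 4. eyelid signal, dropouts, frame table --------------------------------
    t_s <- (seq_len(n_total) - 1) / rate
    eyelid <- 9 + 0.5 * sin(2 * pi * t_s / 13 + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n_total, 0, 0.01)
    eyelid[blink_mask] <- 0.2
    valid <- rep(1L, n_total)
    gaze_q <- rep(1, n_total)
    if (regime$dropout_rate > 0) {
      drop <- stats::runif(n_total) < regime$dropout_rate
      valid[drop] <- 0L
      gaze_q[drop] <- 0.5
    }
    if (regime$blink_frames_invalid) valid[blink_mask] <- 0L

    plane <- build_reference_plane(c(0, 0, 0), c(0, 0, 1), distance)
    p3 <- matrix(plane$point, n_total, 3, byrow = TRUE) +
      outer(x, plane$basis_u) + outer(y, plane$basis_v)
    gd <- p3 / sqrt(rowSums(p3^2))
    frames <- tibble::tibble(
      t_s = t_s,
      head_x_cm = 0, head_y_cm = 0, head_z_cm = 0,
      headdir_x = 0, headdir_y = 0, headdir_z = 1,
      gazeorig_x_cm = 0, gazeorig_y_cm = 0, gazeorig_z_cm = 0,
      gazedir_x = gd[, 1], gazedir_y = gd[, 2], gazedir_z = gd[, 3],
      eyelid_open = eyelid, head_q = 1, gaze_q = gaze_q, valid = valid
    )
    truth_fixations <- tibble::tibble(
      start_frame = as.integer(truth_fix[, 1]),
      end_frame = as.integer(truth_fix[, 2]),
      cell = as.integer(truth_fix[, 3]),
      u_px = pos[truth_fix[, 3], 1] * px_per_cm,
      v_px = pos[truth_fix[, 3], 2] * px_per_cm
    )
    truth_saccades <- tibble::tibble(
      start_frame = as.integer(truth_sac[, 1]),
      end_frame = as.integer(truth_sac[, 2]),
      duration_frames = as.integer(truth_sac[, 3]),
      amplitude_deg = as.numeric(truth_sac[, 4])
    )
    truth_blinks <- tibble::tibble(
      start_frame = vapply(bl, `[`, numeric(1), 1),
      end_frame = vapply(bl, `[`, numeric(1), 2),
      duration_frames = vapply(bl, `[`, numeric(1), 3)
    )
    structure(list(frames = frames, truth_fixations = truth_fixations,
                   truth_saccades = truth_saccades, truth_blinks = truth_blinks,
                   regime = regime, seed = seed),
              class = "synthetic_stage")
  })
}

#' Simulate one NASA-TLX response
#'
#' Each scale is `clip(round(tlx_load + subject_offset + scale_offset +
#' noise), -4, +4)`; the performance scale loads negatively on the latent
#' load (higher load, lower rated performance). Gaussian noise on the latent
#' scale before rounding, sd 1 by default.
#'
#' @param regime a [stage_regime()] supplying `tlx_load`.
#' @param seed integer seed.
#' @param noise_sd latent noise sd; 0 gives the deterministic mapping.
#' @param subject_offset per-participant latent intercept.
#' @param scale_offsets named numeric offsets per scale (default all 0).
#' @return one-row tibble from [score_tlx()] (six scales plus
#'   `averaged_answer`).
#' @export
simulate_tlx <- function(regime, seed = 1, noise_sd = 1, subject_offset = 0,
                         scale_offsets = NULL) {
  stopifnot(inherits(regime, "stage_regime"), is.finite(regime$tlx_load))
  scales <- c("mental", "physical", "temporal", "performance", "effort",
              "frustration")
  off <- stats::setNames(rep(0, 6), scales)
  if (!is.null(scale_offsets)) off[names(scale_offsets)] <- scale_offsets
  with_seed(seed, {
    noise <- stats::rnorm(6, 0, noise_sd)
    lat <- regime$tlx_load + subject_offset
    ans <- vapply(seq_along(scales), function(i) {
      load <- if (scales[i] == "performance") -lat else lat
      clamp(round(load + off[i] + noise[i]), -4, 4)
    }, numeric(1))
    score_tlx(ans[1], ans[2], ans[3], ans[4], ans[5], ans[6])
  })
}

#' N-Back block schedule
#'
#' Eight blocks of ten letters at roughly 2.5 s spacing, difficulty sequence
#' 1-2-3-2-1-2-3-1.
#'
#' @return tibble: `block`, `level`, `n_letters`, `spacing_s`.
#' @export
nback_schedule <- function() {
  tibble::tibble(block = 1:8, level = c(1, 2, 3, 2, 1, 2, 3, 1),
                 n_letters = 10L, spacing_s = 2.5)
}

#' Simulate N-Back performance
#'
#' Bernoulli(`p_correct`) per item. The cohort builder applies the inclusion
#' rule: participants are retained only when the fraction correct exceeds
#' 0.5.
#'
#' @param level N-Back level in 1, 2, 3 (recorded, does not alter
#'   `p_correct` - callers encode difficulty in `p_correct`).
#' @param p_correct per-item success probability in `[0, 1]`.
#' @param n_items number of scored items (>= 1); 80 across the full schedule.
#' @param seed integer seed.
#' @return fraction of correct answers.
#' @export
simulate_nback_performance <- function(level, p_correct, n_items = 80, seed = 1) {
  if (!level %in% c(1, 2, 3)) stop("level must be 1, 2 or 3")
  if (is.na(p_correct) || p_correct < 0 || p_correct > 1)
    stop("p_correct must be in [0, 1]")
  stopifnot(n_items >= 1)
  with_seed(seed, mean(stats::rbinom(n_items, 1, p_correct)))
}

#' Simulate a cohort plan
#'
#' Per participant: a randomised stage order, slightly jittered copies of the
#' four stage regimes (individual differences), per-stage generator seeds,
#' TLX responses with a subject latent intercept, and N-Back performance for
#' the two N-Back stages. Gaze frames are *not* stored: they are regenerated
#' deterministically on demand with [cohort_stage_frames()], which keeps
#' cohort objects small.
#'
#' @param n_participants cohort size.
#' @param regimes named list of four [stage_regime()]s, one per stage label.
#' @param seed cohort seed; drives every downstream draw.
#' @param duration_s stage length, default 300.
#' @param tlx_noise_sd latent TLX noise, default 1.
#' @param subject_sd sd of the subject TLX intercept, default 0.8.
#' @param p_correct_range range of per-subject N-Back item accuracy.
#' @return a `gaze_cohort` list: `participants`, `plan` (one row per
#'   participant x stage with jittered regime parameters and seed), `tlx`,
#'   `nback`, `duration_s`, `seed`.
#' @export
simulate_cohort <- function(n_participants, regimes = default_regimes(),
                            seed = 1, duration_s = 300, tlx_noise_sd = 1,
                            subject_sd = 0.8, p_correct_range = c(0.7, 0.95)) {
  miss <- setdiff(STAGE_LABELS, names(regimes))
  if (length(miss)) stop("missing stage regime(s): ", paste(miss, collapse = ", "))
  stopifnot(n_participants >= 1)
  with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n_participants))
    plan <- list(); tlx <- list(); nback <- list(); parts <- list()
    for (i in seq_len(n_participants)) {
      order_i <- sample(STAGE_LABELS)
      tlx_int <- stats::rnorm(1, 0, subject_sd)
      p_corr <- stats::runif(1, p_correct_range[1], p_correct_range[2])
      jit <- list(dispersion = stats::runif(1, -0.03, 0.03),
                  eps = stats::runif(1, -0.03, 0.03),
                  mu = stats::rnorm(1, 0, 0.05),
                  gain = stats::runif(1, -1.5, 1.5),
                  blink = stats::runif(1, -2, 2))
      parts[[i]] <- tibble::tibble(participant = ids[i],
                                   stage_order = paste(order_i, collapse = ","),
                                   tlx_intercept = tlx_int, p_correct = p_corr)
      for (st in STAGE_LABELS) {
        rg <- regimes[[st]]
        sseed <- sample.int(.Machine$integer.max - 1L, 1)
        plan[[length(plan) + 1L]] <- tibble::tibble(
          participant = ids[i], stage = st,
          position = match(st, order_i),
          fix_dur_mu = rg$fix_dur_mu + jit$mu,
          fix_dur_sigma = rg$fix_dur_sigma,
          grid_size = rg$grid_size,
          dispersion = clamp(rg$dispersion + jit$dispersion, 0.05, 1),
          regularity_eps = clamp(rg$regularity_eps + jit$eps, 0, 1),
          saccade_peak_gain = max(5, rg$saccade_peak_gain + jit$gain),
          blink_rate = max(0, rg$blink_rate + jit$blink),
          dropout_rate = rg$dropout_rate,
          tlx_load = rg$tlx_load,
          blink_frames_invalid = rg$blink_frames_invalid,
          seed = sseed)
        tseed <- sample.int(.Machine$integer.max - 1L, 1)
        tlx[[length(tlx) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(participant = ids[i], stage = st),
          simulate_tlx(rg, seed = tseed, noise_sd = tlx_noise_sd,
                       subject_offset = tlx_int))
        if (grepl("Nback", st)) {
          nseed <- sample.int(.Machine$integer.max - 1L, 1)
          nback[[length(nback) + 1L]] <- tibble::tibble(
            participant = ids[i], stage = st,
            fraction_correct = simulate_nback_performance(2, p_corr, 80, nseed))
        }
      }
    }
    structure(list(participants = dplyr::bind_rows(parts),
                   plan = dplyr::bind_rows(plan),
                   tlx = dplyr::bind_rows(tlx),
                   nback = dplyr::bind_rows(nback),
                   duration_s = duration_s, seed = seed),
              class = "gaze_cohort")
  })
}

# rebuild the stage_regime stored in one plan row
plan_regime <- function(row) {
  stage_regime(row$stage, fix_dur_mu = row$fix_dur_mu,
               fix_dur_sigma = row$fix_dur_sigma, grid_size = row$grid_size,
               dispersion = row$dispersion, regularity_eps = row$regularity_eps,
               saccade_peak_gain = row$saccade_peak_gain,
               blink_rate = row$blink_rate, dropout_rate = row$dropout_rate,
               tlx_load = row$tlx_load,
               blink_frames_invalid = row$blink_frames_invalid)
}

#' Regenerate one participant-stage of gaze frames from a cohort plan
#'
#' @param cohort a [simulate_cohort()] object.
#' @param participant participant id (e.g. `"P001"`).
#' @param stage stage label.
#' @return the [simulate_gaze_stage()] `synthetic_stage` for that cell,
#'   identical on every call.
#' @export
cohort_stage_frames <- function(cohort, participant, stage) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  row <- cohort$plan[cohort$plan$participant == participant &
                       cohort$plan$stage == stage, ]
  if (nrow(row) != 1) stop("no plan entry for ", participant, " / ", stage)
  simulate_gaze_stage(plan_regime(row), duration_s = cohort$duration_s,
                      seed = row$seed)
}

#' Write a cohort to CSV files
#'
#' Emits the documented CSV dialects: one gaze-frames file and one
#' truth-events file per participant x stage, plus `stages.csv` (stage
#' annotation table), `tlx.csv` and `nback.csv`.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  for (i in seq_len(nrow(cohort$plan))) {
    row <- cohort$plan[i, ]
    st <- cohort_stage_frames(cohort, row$participant, row$stage)
    base <- paste0(row$participant, "_", row$stage)
    readr::write_csv(st$frames, file.path(dir, paste0("gaze_", base, ".csv")))
    ev <- dplyr::bind_rows(
      dplyr::mutate(st$truth_fixations[, c("start_frame", "end_frame")],
                    kind = "fixation"),
      dplyr::mutate(st$truth_saccades[, c("start_frame", "end_frame")],
                    kind = "saccade"),
      dplyr::mutate(st$truth_blinks[, c("start_frame", "end_frame")],
                    kind = "blink"))
    readr::write_csv(ev, file.path(dir, paste0("truth_", base, ".csv")))
    stages[[i]] <- tibble::tibble(participant = row$participant,
                                  stage = row$stage, start_s = 0,
                                  end_s = cohort$duration_s,
                                  file = paste0("gaze_", base, ".csv"))
  }
  readr::write_csv(dplyr::bind_rows(stages), file.path(dir, "stages.csv"))
  readr::write_csv(cohort$tlx, file.path(dir, "tlx.csv"))
  readr::write_csv(cohort$nback, file.path(dir, "nback.csv"))
  invisible(dir)
}
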