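test_that("window layout follows the 30 s / 1 s overlapping scheme", {
  w <- make_windows(300)
  expect_equal(nrow(w), 271)
  expect_equal(w$start_s[1:3], c(0, 1, 2))
  expect_equal(w$end_s[271], 300)
  expect_equal(w$frame_start[1], 1L)
  expect_equal(w$frame_end[1], 1800L)
  expect_equal(nrow(make_windows(30)), 1)
  expect_equal(nrow(make_windows(31)), 2)
  expect_error(make_windows(29), "shorter")
})

test_that("window usability is strict: more than half the frames must be valid", {
  w <- make_windows(30)          # one 1800-frame window
  # exactly half valid -> NOT usable
  wq <- window_quality(w, invalid_frame_indices = 1:900)
  expect_equal(wq$valid_fraction, 0.5)
  expect_false(wq$usable)
  # 1000/1800 valid -> usable
  wq <- window_quality(w, invalid_frame_indices = 1:800)
  expect_equal(wq$valid_fraction, 1000 / 1800, tolerance = 1e-12)
  expect_true(wq$usable)
  # fully valid
  wq <- window_quality(w, integer(0))
  expect_equal(wq$valid_fraction, 1)
  expect_true(wq$usable)
  # invalid indices only count inside the window span
  w2 <- make_windows(31)
  wq <- window_quality(w2, invalid_frame_indices = 1801:1860)
  expect_equal(wq$valid_fraction, c(1, 1740 / 1800))
})

test_that("participant retention boundary sits exactly at 35% low-quality windows", {
  qc <- participant_qc(c(rep(FALSE, 380), rep(TRUE, 704)))   # 380/1084
  expect_false(qc$include)
  expect_equal(qc$low_quality_fraction, 380 / 1084, tolerance = 1e-12)
  qc <- participant_qc(c(rep(FALSE, 379), rep(TRUE, 705)))   # 379/1084
  expect_true(qc$include)
  expect_true(participant_qc(rep(TRUE, 1084))$include)
  expect_error(participant_qc(logical(0)), "no windows")
})

test_that("window metrics assign events by midpoint and leave empty metrics missing", {
  w <- window_quality(make_windows(40), integer(0))   # 11 windows
  fx <- tibble::tibble(start_frame = c(301L, 601L), end_frame = c(312L, 624L),
                       n_frames = c(12L, 24L), duration_ms = c(200, 400),
                       centroid_u_px = c(10, 40), centroid_v_px = c(10, 10))
  sc <- tibble::tibble(start_frame = 500L, end_frame = 502L,
                       duration_frames = 3L, amplitude_deg = 6,
                       peak_velocity = 2, mean_velocity_deg_s = 120, avr = 3)
  bl <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                       duration_frames = integer())
  m <- compute_window_metrics(w, fx, sc, bl)
  # window [0, 30): both fixations inside -> mean 300 ms, 2 bins
  expect_equal(m$mean_fixation_duration_ms[1], 300)
  expect_equal(m$sge_bits[1], 1)
  expect_equal(m$gte_bits[1], 0)       # single deterministic transition
  expect_equal(m$blink_count[1], 0L)   # zero blinks is a true zero
  expect_equal(m$mean_saccade_velocity[1], 120)
  # window [10, 40): both fixation midpoints (5.1 s, 10.2 s) - only second inside
  expect_equal(m$mean_fixation_duration_ms[11], 400)
  expect_true(is.na(m$gte_bits[11]))   # one fixation: GTE missing
  # a window with no events keeps missing metrics but zero blinks
  w2 <- window_quality(make_windows(30), integer(0))
  m2 <- compute_window_metrics(w2, fx[0, ], sc[0, ], bl)
  expect_true(is.na(m2$mean_fixation_duration_ms))
  expect_true(is.na(m2$sge_bits))
  expect_equal(m2$blink_count, 0L)
})

test_that("stage aggregation averages usable windows per metric with its own denominator", {
  wm <- tibble::tibble(
    start_s = 0:3, end_s = 30:33, frame_start = 1L, frame_end = 1800L,
    valid_fraction = c(1, 1, 1, 0.2), usable = c(TRUE, TRUE, TRUE, FALSE),
    mean_fixation_duration_ms = c(200, 400, NA, 999),
    mean_saccade_velocity = c(100, 200, 300, 999),
    blink_count = c(1L, 2L, 3L, 99L),
    sge_bits = c(1, 2, NA, 99), gte_bits = c(0.5, NA, NA, 99))
  agg <- aggregate_stage(wm, "UrbanDriving")
  expect_equal(agg$stage, "UrbanDriving")
  expect_equal(agg$fixation_duration, 300)   # over two defined usable windows
  expect_equal(agg$saccade_velocity, 200)    # over three
  expect_equal(agg$blink_number, 2)
  expect_equal(agg$sge, 1.5)
  expect_equal(agg$gte, 0.5)
  expect_equal(agg$n_usable_windows, 3L)
  expect_equal(agg$n_total_windows, 4L)

  # identical windows: mean equals the common value
  wm2 <- wm[c(1, 1, 1), ]
  expect_equal(aggregate_stage(wm2, "x")$fixation_duration, 200)

  # zero usable windows: stage metrics missing
  wm3 <- wm; wm3$usable <- FALSE
  expect_true(is.na(aggregate_stage(wm3, "x")$sge))
  expect_equal(aggregate_stage(wm3, "x")$n_usable_windows, 0L)
})

test_that("windowed metrics agree with a whole-window independent recomputation", {
  st <- simulate_gaze_stage(test_regime(), 45, seed = 31)
  res <- analyze_stage(st$frames, run_config())
  k <- 8   # window [7, 37)
  w <- res$windows[k, ]
  mid <- (res$fixations$start_frame + res$fixations$end_frame - 1) / 2 / 60
  inw <- mid >= w$start_s & mid < w$end_s
  expect_equal(w$mean_fixation_duration_ms,
               mean(res$fixations$duration_ms[inw]))
  bins <- bin_fixations(res$fixations$centroid_u_px[inw],
                        res$fixations$centroid_v_px[inw])
  expect_equal(w$sge_bits, stationary_gaze_entropy(bins), tolerance = 1e-12)
  expect_equal(w$gte_bits, oracle_gte(bins), tolerance = 1e-12)
  midb <- (res$blinks$start_frame + res$blinks$end_frame - 1) / 2 / 60
  expect_equal(w$blink_count, sum(midb >= w$start_s & midb < w$end_s))
})
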