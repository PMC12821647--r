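test_that("regime invariants are enforced", {
  expect_error(stage_regime("HighwayDriving", dispersion = 1.2), "dispersion")
  expect_error(stage_regime("HighwayDriving", regularity_eps = -0.1))
  expect_error(stage_regime("HighwayDriving", fix_dur_sigma = 0))
  expect_error(stage_regime("HighwayDriving", grid_size = 1))
  expect_error(stage_regime("HighwayDriving", blink_rate = -2))
  expect_error(stage_regime("Motorway"))
  expect_error(simulate_gaze_stage(test_regime(), duration_s = 0), "positive")
})

test_that("a degenerate two-cell cycle alternates deterministically", {
  rg <- stage_regime("HighwayDriving", grid_size = 2, dispersion = 0.5,
                     regularity_eps = 0, blink_rate = 0, dropout_rate = 0)
  st <- simulate_gaze_stage(rg, 30, seed = 4)
  expect_equal(nrow(st$frames), 1800)
  expect_true(all(st$frames$valid == 1))
  expect_equal(nrow(st$truth_blinks), 0)
  cells <- st$truth_fixations$cell
  expect_true(all(sort(unique(cells)) == c(1, 2)))
  expect_true(all(abs(diff(cells)) == 1))        # strict A-B-A-B alternation
})

test_that("stage length and seeding are exact", {
  rg <- test_regime()
  st <- simulate_gaze_stage(rg, 300, seed = 12)
  expect_equal(nrow(st$frames), 18000)           # 300 s x 60 Hz
  st2 <- simulate_gaze_stage(rg, 300, seed = 12)
  expect_identical(st, st2)                      # byte-for-byte reproducible
  st3 <- simulate_gaze_stage(rg, 300, seed = 13)
  expect_false(identical(st$frames, st3$frames))
})

test_that("truth events respect their own invariants, frame by frame", {
  st <- simulate_gaze_stage(test_regime(blink_rate = 20), 120, seed = 9)
  tf <- st$truth_fixations
  expect_true(all(tf$end_frame - tf$start_frame + 1 >= 6))
  expect_true(all(tf$end_frame - tf$start_frame + 1 <= 1200))
  # event classes disjoint and inside the stage
  spans <- c(unlist(Map(seq, tf$start_frame, tf$end_frame)),
             unlist(Map(seq, st$truth_saccades$start_frame,
                        st$truth_saccades$end_frame)),
             unlist(Map(seq, st$truth_blinks$start_frame,
                        st$truth_blinks$end_frame)))
  expect_false(any(duplicated(spans)))
  expect_true(all(spans >= 1 & spans <= nrow(st$frames)))
  # within-fixation inter-sample angular change stays under 1 degree
  d <- cbind(st$frames$gazedir_x, st$frames$gazedir_y, st$frames$gazedir_z)
  step <- acos(pmin(1, rowSums(d[-nrow(d), ] * d[-1, ]))) * 180 / pi
  for (i in seq_len(nrow(tf))) {
    if (tf$end_frame[i] > tf$start_frame[i])
      expect_lt(max(step[tf$start_frame[i]:(tf$end_frame[i] - 1)]), 1)
  }
})

test_that("transition entropy grows with the regularity mixing weight", {
  # analytic, from the simulated kernel
  h <- vapply(c(0.1, 0.4, 0.8), expected_transition_entropy, numeric(1),
              n_states = 10)
  expect_true(all(diff(h) > 0))
  # empirical windowed GTE is non-decreasing over >= 100 windows per level
  mean_gte <- vapply(c(0.1, 0.4, 0.8), function(eps) {
    st <- simulate_gaze_stage(test_regime(regularity_eps = eps), 150, seed = 55)
    res <- analyze_stage(st$frames, run_config())
    mean(res$windows$gte_bits, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_gte) >= 0))
})

test_that("stage SGE rises strictly with dispersion across seeds", {
  seeds <- 1:10
  sge_at <- function(disp, s) {
    st <- simulate_gaze_stage(test_regime(dispersion = disp, grid_size = 6),
                              60, seed = s)
    res <- analyze_stage(st$frames, run_config())
    mean(res$windows$sge_bits, na.rm = TRUE)
  }
  low <- vapply(seeds, sge_at, numeric(1), disp = 0.1)
  mid <- vapply(seeds, sge_at, numeric(1), disp = 0.5)
  high <- vapply(seeds, sge_at, numeric(1), disp = 0.9)
  # sign test: every seed ordered (p = 2^-10 < 0.01 under the null per pair)
  expect_true(all(mid > low))
  expect_true(all(high > mid))
})

test_that("TLX simulation clips, inverts performance, and is seed-stable", {
  rg <- test_regime(tlx_load = 9)
  rec <- simulate_tlx(rg, seed = 1, noise_sd = 0)
  expect_equal(unlist(rec[c("mental", "physical", "temporal", "effort",
                            "frustration")]), rep(4, 5), ignore_attr = TRUE)
  expect_equal(rec$performance, -4L)
  rg0 <- test_regime(tlx_load = 0)
  rec0 <- simulate_tlx(rg0, seed = 1, noise_sd = 0)
  expect_equal(rec0$averaged_answer, 0)
  expect_identical(simulate_tlx(rg, seed = 7), simulate_tlx(rg, seed = 7))
})

test_that("N-Back performance is Bernoulli with the documented inclusion rule", {
  expect_equal(simulate_nback_performance(1, 1, 40, seed = 2), 1)
  expect_equal(simulate_nback_performance(3, 0, 40, seed = 2), 0)
  expect_error(simulate_nback_performance(4, 0.5, 40, 1), "level")
  expect_error(simulate_nback_performance(2, 1.5, 40, 1), "p_correct")
  # binomial expectation over many seeds
  fr <- vapply(1:1000, function(s)
    simulate_nback_performance(2, 0.7, 80, seed = s), numeric(1))
  se <- sqrt(0.7 * 0.3 / 80) / sqrt(1000)
  expect_lt(abs(mean(fr) - 0.7), 3 * se)
  expect_false(simulate_nback_performance(2, 0, 40, 1) > 0.5)
})

test_that("cohorts are seed-stable plans covering all four stages", {
  co <- simulate_cohort(3, seed = 99, duration_s = 60)
  expect_equal(nrow(co$plan), 12)
  expect_setequal(unique(co$plan$stage),
                  c("HighwayDriving", "HighwayNback", "UrbanDriving", "UrbanNback"))
  expect_equal(nrow(co$tlx), 12)
  expect_equal(nrow(co$nback), 6)       # two N-Back stages per participant
  expect_true(all(co$plan$seed < 2^31))
  co2 <- simulate_cohort(3, seed = 99, duration_s = 60)
  expect_identical(co, co2)
  # frames regenerate identically on demand
  f1 <- cohort_stage_frames(co, "P001", "UrbanDriving")
  f2 <- cohort_stage_frames(co, "P001", "UrbanDriving")
  expect_identical(f1, f2)
  # missing regime is an error
  expect_error(simulate_cohort(2, regimes = default_regimes()[1:3], seed = 1),
               "missing stage regime")
})
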