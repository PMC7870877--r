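test_that("R-wave detection finds impulse fiducials, clean and noisy", {
  fs <- 1000
  n <- 20 * fs
  pos <- seq(500, n - 500, by = fs)
  ecg <- numeric(n)
  ecg[pos] <- 1
  expect_equal(detect_rwaves(ecg, fs), pos)

  expect_identical(detect_rwaves(numeric(5 * fs), fs), integer(0))
  expect_error(detect_rwaves(numeric(fs), fs), "2 s")

  set.seed(7)
  noisy <- ecg + rnorm(n, 0, 0.1)
  found <- detect_rwaves(noisy, fs)
  expect_equal(length(found), length(pos))
  expect_true(all(abs(found - pos) <= 3))
})

test_that("beat segmentation is a fencepost-correct partition", {
  rec <- rec_vload_clean()
  r <- detect_rwaves(rec$channels$ecg, rec$fs)
  beats <- segment_beats(rec, r)
  expect_equal(length(beats), length(r) - 1)
  # partition: consecutive half-open ranges tile [r1, r_last)
  starts <- vapply(beats, function(b) b$start, numeric(1))
  ends <- vapply(beats, function(b) b$end, numeric(1))
  expect_equal(starts[-1], ends[-length(ends)])
  expect_equal(sum(ends - starts), max(r) - min(r))
  # at the simulator's 80 bpm the RR interval is 0.75 s
  expect_equal(mean(vapply(beats, function(b) b$rr_s, numeric(1))),
               0.75, tolerance = 1 / rec$fs / 0.75)
  expect_error(segment_beats(rec, 100L), "2 R-waves")
})

test_that("uniform synthetic R-waves give uniform rr", {
  rec <- rec_vload_clean()
  beats <- segment_beats(rec, seq(1, 15001, by = 1000))
  expect_equal(length(beats), 15)
  expect_true(all(vapply(beats, function(b) b$rr_s, numeric(1)) == 1))
})

test_that("extrasystole filter removes premature beats and their followers", {
  # constructed: regular 1 s beats with one 40%-short beat
  rr <- rep(1, 12)
  rr[6] <- 0.6
  r <- cumsum(c(1, rr * 1000))
  rec <- rec_vload_clean()
  beats <- segment_beats(rec, r)
  kept <- filter_extrasystoles(beats)
  expect_equal(length(kept), length(beats) - 2)
  dropped <- setdiff(vapply(beats, function(b) b$beat_idx, numeric(1)),
                     vapply(kept, function(b) b$beat_idx, numeric(1)))
  expect_equal(dropped, c(6, 7))

  # all-regular: unchanged; and the filter is idempotent
  reg <- segment_beats(rec, seq(1, 12001, by = 1000))
  expect_equal(length(filter_extrasystoles(reg)), length(reg))
  expect_equal(length(filter_extrasystoles(kept)), length(kept))
})

test_that("two injected simulator extrasystoles remove exactly four beats", {
  cfg <- sim_config(extrasystole_beats = c(4L, 9L), seed = 5L)
  rec <- distort_and_noise(simulate_run(cfg,
                                        make_protocol("vload_normal", cfg)))
  r <- detect_rwaves(rec$channels$ecg, rec$fs)
  beats <- segment_beats(rec, r)
  kept <- filter_extrasystoles(beats)
  expect_equal(length(beats) - length(kept), 4)
})

test_that("alpha is the conductance-to-flow stroke-volume ratio", {
  # constructed: two-sample ratio definition
  fs <- 1000
  fake <- function(sv_raw, sv_flow) {
    lvv <- c(seq(100, 100 - sv_raw, length.out = 250),
             seq(100 - sv_raw, 100, length.out = 250))
    flow <- c(rep(sv_flow / 0.25, 250), rep(0, 250))
    b <- make_beat(rep(50, 500), lvv, fs = fs)
    b$aoflow <- flow
    b
  }
  beats <- list(fake(40, 50), fake(40, 50), fake(40, 50))
  cal <- estimate_alpha(beats, 1:3, Vp = 0)
  expect_equal(cal$alpha, 0.8, tolerance = 1e-6)
  expect_error(estimate_alpha(beats[1:2], 1:2), "3 baseline")

  # round-trip against simulator truth at zero noise
  cfg <- sim_config(alpha_true = 0.8, Vp_true = 30, noise_sd = zero_noise)
  rec <- distort_and_noise(simulate_run(cfg,
                                        make_protocol("vload_normal", cfg)))
  an <- analyze_run(rec, lowpass_hz = NULL)
  expect_equal(an$calibration$alpha, 0.8, tolerance = 0.01)

  cfg1 <- sim_config(alpha_true = 1, Vp_true = 0, noise_sd = zero_noise)
  rec1 <- distort_and_noise(simulate_run(cfg1,
                                         make_protocol("vload_normal", cfg1)))
  an1 <- analyze_run(rec1, lowpass_hz = NULL)
  expect_equal(an1$calibration$alpha, 1, tolerance = 0.01)
})

test_that("volume calibration inverts the conductance distortion", {
  expect_equal(calibrate_volume(110, alpha = 0.8, Vp = 30), 100)
  expect_equal(calibrate_volume(c(1, 2, 3), alpha = 1, Vp = 0), c(1, 2, 3))
  expect_error(calibrate_volume(100, alpha = 0, Vp = 0), "positive")

  rec <- rec_vload_clean()
  back <- calibrate_volume(rec$channels$lvv_raw,
                           rec$config$alpha_true, rec$config$Vp_true)
  expect_lt(max(abs(back - rec$channels$lvv)), 1e-9)
})

test_that("intervention window tracks the load change", {
  rec <- rec_vload_clean()
  an <- analysis_vload_clean()
  # window beats fall inside the occlusion annotation +/- one beat
  iv <- rec$annotations[rec$annotations$label == "intervention", ]
  wb <- an$beats[an$window_idx]
  t0 <- vapply(wb, function(b) b$t0_s, numeric(1))
  expect_true(all(t0 >= iv$start_s - 0.8 & t0 <= iv$end_s + 0.8))
  expect_gte(length(wb), 5)

  # afterload window covers both phases
  an_p <- analysis_pload_sda()
  expect_gte(length(an_p$window_idx), 6)

  # constant-load recording raises
  beats <- an$beats
  flat_pes <- rep(80, length(beats))
  flat_ves <- rep(60, length(beats))
  expect_error(intervention_window(beats, flat_pes, flat_ves, iv),
               "no load change")
})
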