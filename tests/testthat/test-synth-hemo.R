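test_that("activation curve is normalized, starts at zero, integrates correctly", {
  p <- act_params()
  tt <- seq(0, 1 - 1e-4, length.out = 8192)
  e <- activation_curve(tt, p)
  expect_true(all(e >= 0 & e <= 1))
  expect_equal(max(e), 1, tolerance = 1e-6)
  expect_lte(activation_curve(0, p), 0.01)

  # quadrature oracle: adaptive quadrature vs trapezoid of the same curve
  oracle <- stats::integrate(function(x) activation_curve(x, p),
                             0, 1 - 1e-9, rel.tol = 1e-10)$value
  trap <- sum((e[-1] + e[-length(e)]) / 2 * diff(tt)) +
    e[length(e)] * (1 - tt[length(tt)])
  expect_equal(trap, oracle, tolerance = 1e-6)

  expect_error(activation_curve(0.5, act_params(tau1 = -1)), "positive")
  expect_error(activation_curve(1.0, p), "\\[0, 1\\)")
})

test_that("sda_v0 applies the affine afterload law", {
  expect_equal(sda_v0(0, a = -24.2, b = 23), 23)
  expect_equal(sda_v0(1, a = -24.2, b = 23), -1.2)
  # disabled-slope limit: intercept only, for any Ea
  expect_equal(sda_v0(c(0, 1, 3.7), a = 0, b = 12), rep(12, 3))
  expect_error(sda_v0(-1), "non-negative")
})

test_that("protocols honor the intervention timing constraints", {
  cfg <- sim_config()
  pl <- make_protocol("pload", cfg)
  expect_equal(nrow(pl$schedule), 1)
  expect_equal(pl$schedule$param, "Rp")
  expect_gte(pl$schedule$ramp_s, 1)
  expect_lte(pl$schedule$ramp_s, 2)

  vl <- make_protocol("vload_normal", cfg)
  occ <- vl$schedule[vl$schedule$param == "Rv_return", ]
  expect_lt(diff(occ$start_s), 10)

  vh <- make_protocol("vload_high", cfg)
  rp_ev <- vh$schedule[vh$schedule$param == "Rp", ]
  rv_ev <- vh$schedule[vh$schedule$param == "Rv_return", ]
  expect_true(all(rp_ev$start_s < min(rv_ev$start_s)))
  # afterload held during the occlusion: no Rp event overlaps it
  expect_true(all(rp_ev$start_s + rp_ev$ramp_s < min(rv_ev$start_s)))

  expect_error(make_protocol("nonsense", cfg))
  expect_error(make_protocol("pload", cfg, pload_ramp_s = 3), "\\[1, 2\\]")
})

test_that("closed loop conserves blood volume to rounding error", {
  for (rec in list(rec_vload_clean(), rec_pload_sda())) {
    drift <- max(abs(rec$total_ml - rec$config$total_volume)) /
      rec$config$total_volume
    expect_lt(drift, 1e-9)
  }
})

test_that("SDA-off end-systolic points lie on the true ESPVR line", {
  rec <- rec_vload_clean()
  tr <- rec$truth
  steady <- tr[tr$t_start_s > 3 & !is.na(tr$pes_mmhg), ]
  pred <- rec$config$Ees_true * (steady$ves_ml - rec$config$V0_base)
  expect_lt(max(abs(steady$pes_mmhg - pred) / steady$pes_mmhg), 0.01)
})

test_that("per-beat ejected volume matches integrated aortic flow", {
  rec <- rec_vload_clean()
  tr <- rec$truth
  fs <- rec$fs
  for (b in c(6, 8, 10)) {
    i0 <- round(tr$t_start_s[b] * fs) + 1
    i1 <- round(tr$t_start_s[b + 1] * fs)
    sv_flow <- sum(pmax(rec$channels$aoflow[i0:i1], 0)) / fs
    sv_loop <- max(rec$channels$lvv[i0:i1]) - min(rec$channels$lvv[i0:i1])
    expect_equal(sv_flow, sv_loop, tolerance = 0.01)
  }
})

test_that("SDA-on afterload response is biphasic in the ground-truth log", {
  rec <- rec_pload_sda()
  tr <- rec$truth
  onset <- 8
  ramp <- which(tr$t_start_s >= onset)[1:3]
  late <- which(tr$t_start_s >= onset + 4 &
                  tr$t_start_s <= rec$protocol$total_duration - 0.8)
  # phase 1: V0 falls while Ea rises; Ved constant within 1 mL; SV falls
  expect_lt(tr$v0_eff_ml[max(ramp) + 1], tr$v0_eff_ml[ramp[1]])
  expect_gt(tr$ea_mmhg_ml[max(ramp)], tr$ea_mmhg_ml[ramp[1] - 1])
  base_ved <- tr$ved_ml[ramp[1] - 1]
  expect_lt(max(abs(tr$ved_ml[ramp] - base_ved)), 1)
  sv <- tr$ved_ml - tr$ves_ml
  expect_lt(sv[max(ramp)], sv[ramp[1] - 1] - 2)
  # phase 2: once V0 is set, the ventricle dilates over the following
  # beats (Frank-Starling recovery) ...
  expect_gt(tr$ved_ml[max(late)], min(tr$ved_ml[late]) + 0.3)
  expect_gt(which.max(tr$ved_ml[late]), which.min(tr$ved_ml[late]))
  # ... and the end-systolic trajectory ascends along the true ESPVR
  # slope at the frozen V0
  frozen <- late[tr$v0_eff_ml[late] == tr$v0_eff_ml[max(late)]]
  dpes <- tr$pes_mmhg[max(frozen)] - tr$pes_mmhg[min(frozen)]
  dves <- tr$ves_ml[max(frozen)] - tr$ves_ml[min(frozen)]
  expect_equal(dpes / dves, rec$config$Ees_true, tolerance = 0.02)
})

test_that("with SDA off the effective V0 never leaves V0_base", {
  rec <- rec_vload_clean()
  expect_true(all(rec$truth$v0_eff_ml == rec$config$V0_base))
})

test_that("conductance distortion is exact and noise is seed-deterministic", {
  cfg <- sim_config(alpha_true = 1, Vp_true = 0, noise_sd = zero_noise)
  rec <- distort_and_noise(simulate_run(cfg, make_protocol("pload", cfg)))
  expect_equal(rec$channels$lvv_raw, rec$channels$lvv)

  cfg2 <- sim_config(alpha_true = 0.8, Vp_true = 30,
                     noise_sd = zero_noise)
  rec2 <- distort_and_noise(simulate_run(cfg2, make_protocol("pload", cfg2)))
  back <- calibrate_volume(rec2$channels$lvv_raw, 0.8, 30)
  expect_lt(max(abs(back - rec2$channels$lvv)), 1e-9)

  cfg3 <- sim_config(seed = 42L)
  base <- simulate_run(cfg3, make_protocol("pload", cfg3))
  n1 <- distort_and_noise(base)
  n2 <- distort_and_noise(base)
  expect_identical(n1$channels, n2$channels)
})

test_that("halving the integration step leaves beat indices unchanged", {
  cfg1 <- sim_config(noise_sd = zero_noise, fs = 1000)
  cfg2 <- sim_config(noise_sd = zero_noise, fs = 2000)
  t1 <- simulate_run(cfg1, make_protocol("vload_normal", cfg1))$truth
  t2 <- simulate_run(cfg2, make_protocol("vload_normal", cfg2))$truth
  sel <- 3:20
  expect_lt(max(abs(t2$pes_mmhg[sel] - t1$pes_mmhg[sel]) /
                  t1$pes_mmhg[sel]), 0.005)
  expect_lt(max(abs(t2$ves_ml[sel] - t1$ves_ml[sel]) /
                  t1$ves_ml[sel]), 0.005)
})

test_that("unstable configurations fail with an informative error", {
  cfg <- sim_config(total_volume = 300, noise_sd = zero_noise)
  expect_error(simulate_run(cfg, make_protocol("pload", cfg)),
               "unstable|too small")
})

test_that("recordings round-trip through CSV + JSON sidecar", {
  rec <- rec_vload_clean()
  prefix <- file.path(tempdir(), "pv_test_run")
  write_recording(rec, prefix)
  expect_true(file.exists(paste0(prefix, ".csv")))
  back <- read_recording(prefix)
  expect_equal(back$channels$lvp, rec$channels$lvp, tolerance = 1e-9)
  expect_equal(back$channels$lvv_raw, rec$channels$lvv_raw,
               tolerance = 1e-9)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$truth$pes_mmhg, rec$truth$pes_mmhg, tolerance = 1e-9)
  expect_equal(back$config$Ees_true, rec$config$Ees_true)
  an <- analyze_run(back)
  expect_equal(an$linear$Ees, analysis_vload_clean()$linear$Ees,
               tolerance = 1e-6)
  unlink(paste0(prefix, c(".csv", ".json")))
})
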