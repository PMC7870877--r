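#' Run the closed-loop hemodynamic simulator
#'
#' Integrates a three-compartment closed loop - venous reservoir, mitral
#' valve, time-varying-elastance (TVE) left ventricle, aortic valve,
#' three-element Windkessel - with a fixed-step classical Runge-Kutta
#' scheme at `1/fs` and returns a ground-truth annotated recording of
#' all channels.
#'
#' Ventricular pressure is
#' `P = e(t) * Ees * (V - V0_eff) + (1 - e(t)) * A * (exp(B * (V - V0d)) - 1)`
#' with the double-Hill activation `e(t)` of [activation_curve()]. When
#' shortening deactivation is enabled, `V0_eff` is updated once per beat
#' from the previous beat's effective arterial elastance via [sda_v0()]
#' (a one-beat lag; there is no within-beat algebraic loop). Valves are
#' ideal diodes with series resistance. Total blood volume is conserved
#' by construction; the per-sample total is returned for verification.
#'
#' @param config a [sim_config()].
#' @param protocol a [make_protocol()] result.
#' @return an object of class `pv_recording`: list with `fs`, `time_s`,
#'   `channels` (data frame `lvp`, `lvv`, `lvv_raw`, `aop`, `aoflow`,
#'   `ecg`), `annotations`, `truth` (per-beat ground-truth log with the
#'   effective V0, true end-systole time, Ved/Ves/Pes and Ea),
#'   `total_ml` (per-sample total loop volume), `config`, `protocol`.
#'   The `lvv_raw` channel is the exact affine conductance distortion
#'   `alpha_true * lvv + Vp_true`; add noise with [distort_and_noise()].
#' @examples
#' cfg <- sim_config()
#' rec <- simulate_run(cfg, make_protocol("vload_normal", cfg))
#' rec
#' @export
simulate_run <- function(config, protocol) {
  stopifnot(inherits(config, "pv_sim_config"),
            inherits(protocol, "pv_protocol"))
  fs <- config$fs
  n <- round(protocol$total_duration * fs)
  t <- (0:(n - 1)) / fs

  sched <- beat_schedule(config, protocol$total_duration)
  info <- act_shape_info(config$act)
  es_sample <- sched$start + as.integer(round(info$t_peak *
                                                sched$period_s * fs))
  es_sample[es_sample >= n] <- -1L

  rpF <- param_factors(protocol, "Rp", t)
  rvF <- param_factors(protocol, "Rv_return", t)
  rcF <- param_factors(protocol, "Rc", t)

  core <- simulate_core(
    n = n, fs = fs,
    beat_onset = sched$onset_s, beat_period = sched$period_s,
    beat_amp = sched$amp, beat_start = sched$start,
    es_sample = es_sample,
    sda_active = sda_active_beats(sched, protocol, config),
    Ees = config$Ees_true, V0_base = config$V0_base,
    sda_a = config$sda_slope_a, sda_b = config$sda_intercept_b,
    sda_on = config$sda_enabled, sda_gain = config$sda_gain,
    edA = config$edpvr_A, edB = config$edpvr_B, edV0d = config$edpvr_V0d,
    Rc = config$Rc, Rp = config$Rp, Ca = config$Ca, Cv = config$Cv,
    Cvc = config$Cvc, Rm = config$Rm, Rv = config$Rv_return,
    tau1 = config$act$tau1, tau2 = config$act$tau2,
    m1 = config$act$m1, m2 = config$act$m2, act_norm = info$norm,
    Vlv0 = config$Vlv_init, Pa0 = config$Pa_init,
    total_volume = config$total_volume,
    rpF = rpF, rvF = rvF, rcF = rcF)

  channels <- data.frame(
    lvp = core$lvp, lvv = core$lvv,
    lvv_raw = config$alpha_true * core$lvv + config$Vp_true,
    aop = core$aop, aoflow = core$aoflow,
    ecg = ecg_trace(n, fs, sched$start))

  truth <- core$truth
  truth$extrasystole <- seq_len(nrow(truth)) %in% config$extrasystole_beats

  structure(list(fs = fs, time_s = t, channels = channels,
                 annotations = protocol$annotations, truth = truth,
                 total_ml = core$total, config = config,
                 protocol = protocol),
            class = "pv_recording")
}

#' @export
print.pv_recording <- function(x, ...) {
  cat(sprintf("<pv_recording> %s: %.1f s @ %g Hz, %d beats\n",
              x$protocol$kind, length(x$time_s) / x$fs, x$fs,
              nrow(x$truth)))
  invisible(x)
}

# Beat clock. Extrasystolic beats are premature (rr = 0.65 T) with
# reduced activation amplitude; the following beat carries a partial
# compensatory pause (rr = 1.15 T). Onsets are quantized to the sample
# grid so activation timing and the integrator agree exactly.
beat_schedule <- function(config, total_duration) {
  fs <- config$fs
  T0 <- 60 / config$heart_rate
  start <- integer(0); period <- numeric(0); amp <- numeric(0)
  s <- 0L; j <- 1L
  n <- round(total_duration * fs)
  while (s < n) {
    p <- T0; a <- 1
    if (j %in% config$extrasystole_beats) {
      p <- 0.65 * T0; a <- 0.7
    } else if ((j - 1L) %in% config$extrasystole_beats) {
      p <- 1.15 * T0
    }
    ps <- as.integer(round(p * fs))
    start <- c(start, s); period <- c(period, ps / fs)
    amp <- c(amp, a)
    s <- s + ps; j <- j + 1L
  }
  list(start = start, onset_s = start / fs, period_s = period, amp = amp)
}

# Beats during which the SDA V0 update is active: an initial
# equilibration window, plus beats starting while an afterload
# parameter (Rp or Rc) is scheduled to change or within two beats
# after. While the afterload is held, the deactivation state - and so
# the effective V0 - is stable; preload maneuvers (venous-return
# events) do not re-engage it.
sda_active_beats <- function(sched, protocol, config, settle_s = 6) {
  t0 <- sched$onset_s
  act <- t0 < settle_s
  evs <- protocol$schedule
  evs <- evs[evs$param %in% c("Rp", "Rc"), , drop = FALSE]
  T0 <- 60 / config$heart_rate
  post <- if (is.null(config$sda_post_beats)) 1L else config$sda_post_beats
  if (nrow(evs) > 0) {
    for (k in seq_len(nrow(evs))) {
      lo <- evs$start_s[k] - T0
      hi <- evs$start_s[k] + evs$ramp_s[k] + post * T0
      act <- act | (t0 >= lo & t0 <= hi)
    }
  }
  as.integer(act)
}

# Synthetic ECG: Gaussian R-wave (8 ms SD, 1.2 mV) centered on each beat
# onset. The R-wave is the only fiducial the analysis uses.
ecg_trace <- function(n, fs, beat_start, amp = 1.2, sd_s = 0.008) {
  ecg <- numeric(n)
  w <- as.integer(ceiling(4 * sd_s * fs))
  for (s in beat_start) {
    idx <- max(0L, s - w):min(n - 1L, s + w)
    ecg[idx + 1L] <- ecg[idx + 1L] +
      amp * exp(-0.5 * ((idx - s) / (sd_s * fs))^2)
  }
  ecg
}

#' Apply conductance distortion and measurement noise
#'
#' Produces the raw conductance-volume channel
#' `lvv_raw = alpha_true * lvv + Vp_true` from the true volume (the
#' exact inverse of [calibrate_volume()]) and adds seeded Gaussian noise
#' to every measured channel (`lvp`, `lvv_raw`, `aop`, `aoflow`,
#' `ecg`). The true `lvv` channel and the ground-truth log are left
#' untouched. Two calls with the same config produce bit-identical
#' output.
#'
#' @param recording a `pv_recording` from [simulate_run()].
#' @param config the [sim_config()] supplying `alpha_true`, `Vp_true`,
#'   `noise_sd` and `seed`; defaults to the recording's own config.
#' @return the recording with noisy measured channels.
#' @export
distort_and_noise <- function(recording, config = recording$config) {
  stopifnot(inherits(recording, "pv_recording"))
  ch <- recording$channels
  n <- nrow(ch)
  sd <- config$noise_sd
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  ch$lvv_raw <- config$alpha_true * ch$lvv + config$Vp_true +
    rnorm(n, 0, sd[["lvv_raw"]])
  ch$lvp <- ch$lvp + rnorm(n, 0, sd[["lvp"]])
  ch$aop <- ch$aop + rnorm(n, 0, sd[["aop"]])
  ch$aoflow <- ch$aoflow + rnorm(n, 0, sd[["aoflow"]])
  ch$ecg <- ch$ecg + rnorm(n, 0, sd[["ecg"]])
  recording$channels <- ch
  recording
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds one row per sample with columns `time_s, lvp_mmhg,
#' lvv_ml, lvv_raw_ml, aop_mmhg, aoflow_ml_s, ecg_mv`. The sidecar JSON
#' stores the simulator configuration, protocol, annotations and the
#' per-beat ground-truth log.
#'
#' @param recording a `pv_recording`.
#' @param prefix path prefix; files `<prefix>.csv` and `<prefix>.json`
#'   are written.
#' @return `write_recording` returns the prefix invisibly;
#'   `read_recording` returns a `pv_recording`.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "pv_recording"))
  ch <- recording$channels
  df <- data.frame(time_s = recording$time_s,
                   lvp_mmhg = ch$lvp, lvv_ml = ch$lvv,
                   lvv_raw_ml = ch$lvv_raw, aop_mmhg = ch$aop,
                   aoflow_ml_s = ch$aoflow, ecg_mv = ch$ecg)
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(fs = recording$fs,
               config = unclass(recording$config),
               protocol = unclass(recording$protocol),
               annotations = recording$annotations,
               truth = recording$truth)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$extrasystole_beats <- as.integer(unlist(cfg$extrasystole_beats))
  cfg$noise_sd <- unlist(cfg$noise_sd)
  class(cfg) <- "pv_sim_config"
  proto <- side$protocol
  class(proto) <- "pv_protocol"
  structure(list(fs = side$fs, time_s = df$time_s,
                 channels = data.frame(lvp = df$lvp_mmhg, lvv = df$lvv_ml,
                                       lvv_raw = df$lvv_raw_ml,
                                       aop = df$aop_mmhg,
                                       aoflow = df$aoflow_ml_s,
                                       ecg = df$ecg_mv),
                 annotations = side$annotations, truth = side$truth,
                 total_ml = NULL, config = cfg, protocol = proto),
            class = "pv_recording")
}
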