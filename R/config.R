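#' Simulator configuration
#'
#' Ground-truth parameters for the closed-loop time-varying-elastance
#' simulator: ventricular properties (end-systolic elastance `Ees_true`,
#' unstressed volume `V0_base`, exponential end-diastolic pressure-volume
#' relation), the shortening-deactivation (SDA) law that makes the
#' effective V0 an affine function of the previous beat's arterial
#' elastance, a three-element Windkessel afterload, a venous reservoir,
#' valve resistances, the activation shape, and the conductance-catheter
#' distortion (`alpha_true`, `Vp_true`) that the calibration stage must
#' undo.
#'
#' Defaults describe a healthy ~50 kg pig: heart rate 80 beats/min,
#' end-diastolic volume near 110 mL, end-systolic pressure 75-90 mmHg,
#' end-diastolic pressure 5-10 mmHg.
#'
#' @param heart_rate beats per minute, in \[40, 200\].
#' @param Ees_true end-systolic elastance, mmHg/mL.
#' @param V0_base ESPVR volume intercept used when SDA is disabled, mL.
#' @param sda_slope_a,sda_intercept_b coefficients of the SDA law
#'   V0_eff = a * Ea + b (mL per (mmHg/mL), mL).
#' @param sda_enabled logical; if `FALSE` the effective V0 is `V0_base`
#'   on every beat.
#' @param sda_gain per-beat fractional relaxation of the effective V0
#'   toward the SDA law's target, in (0, 1\]. A value below 1 spreads
#'   the deactivation response over a few beats, which also keeps the
#'   beat-to-beat update stable at small stroke volumes where the raw
#'   one-beat-delay map would oscillate.
#' @param sda_post_beats number of beats after the end of an afterload
#'   ramp during which the V0 update remains active before the
#'   deactivation state is held.
#' @param edpvr_A,edpvr_B,edpvr_V0d exponential EDPVR
#'   P_ed = A * (exp(B * (V - V0d)) - 1); mmHg, 1/mL, mL.
#' @param Rc characteristic (proximal aortic) resistance, mmHg s/mL.
#' @param Rp peripheral resistance, mmHg s/mL.
#' @param Ca arterial compliance, mL/mmHg.
#' @param Cv peripheral venous reservoir compliance, mL/mmHg.
#' @param Cvc central venous (atrial inflow) compliance, mL/mmHg; the
#'   small compartment between the venous-return resistance and the
#'   mitral valve whose charging mediates the beat-to-beat preload
#'   (Frank-Starling) adaptation.
#' @param Rm mitral (inflow) resistance, mmHg s/mL.
#' @param Rv_return venous-return resistance (the vena-cava occlusion
#'   balloon acts here), mmHg s/mL.
#' @param total_volume total stressed blood volume of the loop, mL.
#' @param act activation shape parameters, see [act_params()].
#' @param fs sampling/integration rate, Hz.
#' @param noise_sd named numeric vector of additive Gaussian noise SDs
#'   for the measured channels (`lvp`, `lvv_raw`, `aop`, `aoflow`,
#'   `ecg`), in channel units.
#' @param alpha_true conductance slope factor applied to the true volume
#'   to produce the raw conductance channel; dimensionless, > 0.
#' @param Vp_true parallel-conductance volume offset, mL.
#' @param extrasystole_beats integer beat numbers made extrasystolic
#'   (premature, weak); empty by default.
#' @param Vlv_init,Pa_init initial ventricular volume (mL) and arterial
#'   pressure (mmHg).
#' @param seed integer seed for the run's noise generator.
#' @return an object of class `pv_sim_config`.
#' @examples
#' cfg <- sim_config(sda_enabled = TRUE)
#' cfg$Ees_true
#' @export
sim_config <- function(heart_rate = 80,
                       Ees_true = 1.2,
                       V0_base = 10,
                       sda_slope_a = -24.2,
                       sda_intercept_b = 23,
                       sda_enabled = FALSE,
                       sda_gain = 1,
                       sda_post_beats = 3,
                       edpvr_A = 0.7, edpvr_B = 0.035, edpvr_V0d = 40,
                       Rc = 0.06, Rp = 0.65, Ca = 3.0, Cv = 60,
                       Cvc = 15, Rm = 0.01, Rv_return = 0.08,
                       total_volume = 1430,
                       act = act_params(),
                       fs = 1000,
                       noise_sd = c(lvp = 0.5, lvv_raw = 1, aop = 0.5,
                                    aoflow = 1, ecg = 0.02),
                       alpha_true = 0.8, Vp_true = 30,
                       extrasystole_beats = integer(0),
                       Vlv_init = 110, Pa_init = 70,
                       seed = 1L) {
  cfg <- list(heart_rate = heart_rate, Ees_true = Ees_true,
              V0_base = V0_base, sda_slope_a = sda_slope_a,
              sda_intercept_b = sda_intercept_b,
              sda_enabled = isTRUE(sda_enabled), sda_gain = sda_gain,
              sda_post_beats = as.integer(sda_post_beats),
              edpvr_A = edpvr_A, edpvr_B = edpvr_B, edpvr_V0d = edpvr_V0d,
              Rc = Rc, Rp = Rp, Ca = Ca, Cv = Cv, Cvc = Cvc,
              Rm = Rm, Rv_return = Rv_return,
              total_volume = total_volume, act = act, fs = fs,
              noise_sd = noise_sd, alpha_true = alpha_true,
              Vp_true = Vp_true,
              extrasystole_beats = as.integer(extrasystole_beats),
              Vlv_init = Vlv_init, Pa_init = Pa_init,
              seed = as.integer(seed))
  class(cfg) <- "pv_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("Ees_true", "edpvr_A", "edpvr_B", "Rc", "Rp", "Ca", "Cv",
           "Cvc", "Rm", "Rv_return", "total_volume", "fs", "alpha_true")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("sim_config: '%s' must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (cfg$heart_rate < 40 || cfg$heart_rate > 200) {
    stop("sim_config: heart_rate must lie in [40, 200] beats/min",
         call. = FALSE)
  }
  if (!is.finite(cfg$sda_gain) || cfg$sda_gain <= 0 || cfg$sda_gain > 1) {
    stop("sim_config: sda_gain must lie in (0, 1]", call. = FALSE)
  }
  if (any(cfg$noise_sd < 0)) {
    stop("sim_config: noise SDs must be non-negative", call. = FALSE)
  }
  check_act_params(cfg$act)
  cfg
}

#' @export
print.pv_sim_config <- function(x, ...) {
  cat("<pv_sim_config>\n")
  cat(sprintf("  HR %g bpm | Ees %g mmHg/mL | V0_base %g mL | SDA %s",
              x$heart_rate, x$Ees_true, x$V0_base,
              if (x$sda_enabled) {
                sprintf("on (V0 = %g Ea + %g)", x$sda_slope_a,
                        x$sda_intercept_b)
              } else "off"), "\n")
  cat(sprintf("  Windkessel Rc %g, Rp %g, Ca %g | venous Cv %g, Rv %g\n",
              x$Rc, x$Rp, x$Ca, x$Cv, x$Rv_return))
  cat(sprintf("  fs %g Hz | alpha %g, Vp %g mL | seed %d\n",
              x$fs, x$alpha_true, x$Vp_true, x$seed))
  invisible(x)
}

#' Shortening-deactivation V0 law
#'
#' The simulator's shortening-deactivation (SDA) mechanism shifts the
#' effective ESPVR volume intercept as an affine function of afterload:
#' `V0_eff = a * Ea + b`, where `Ea` is the effective arterial elastance
#' (Pes/SV) of the previous beat. With a negative slope `a`, higher
#' afterload shifts the ESPVR leftward, raising pressure generation
#' without ventricular dilation. The law is applied unclipped; negative
#' `V0_eff` values are legitimate (they occur at physiological Ea) and
#' are recorded in the ground-truth log.
#'
#' @param Ea_beat effective arterial elastance of the previous beat,
#'   mmHg/mL, non-negative.
#' @param a slope, mL per (mmHg/mL).
#' @param b intercept, mL.
#' @return effective volume intercept, mL.
#' @examples
#' sda_v0(1, a = -24.2, b = 23)  # -1.2 mL
#' @export
sda_v0 <- function(Ea_beat, a = -24.2, b = 23) {
  if (any(!is.finite(Ea_beat)) || any(Ea_beat < 0)) {
    stop("Ea_beat must be finite and non-negative", call. = FALSE)
  }
  a * Ea_beat + b
}
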