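#' Full pressure-volume analysis of one recording
#'
#' Runs the complete pipeline on a recording: R-wave detection, beat
#' segmentation, extrasystole exclusion, conductance calibration,
#' intervention-window selection, iterative Vd estimation,
#' maximal-elastance end-systole detection, linear and bilinear ESPVR
#' fits, PRSW, and the per-beat and per-phase index tables.
#'
#' Both the linear and the bilinear ESPVR are always computed. The
#' reported model follows the intervention kind - linear for the
#' preload interventions, bilinear for the afterload intervention -
#' unless `model` is forced or the data-driven override is enabled
#' (choose bilinear whenever `gm_r2 - r2_lin` exceeds `bilin_margin`).
#'
#' @param recording a `pv_recording` (simulated or read from disk).
#' @param alpha `"auto"` to estimate the conductance slope factor from
#'   baseline beats, or a numeric value.
#' @param Vp parallel-conductance volume, mL; defaults to the
#'   recording's ground-truth `Vp_true` (hypertonic-saline estimation
#'   is out of scope, so Vp is an input).
#' @param model `"auto"`, `"lin"` or `"bilin"`.
#' @param min_seg minimum points per bilinear segment.
#' @param bilin_margin data-driven override margin on `gm_r2 - r2_lin`;
#'   `NULL` (default) disables the override.
#' @param rr_tolerance extrasystole RR tolerance, see
#'   [filter_extrasystoles()].
#' @param min_delta_pes,min_delta_ves window thresholds, see
#'   [intervention_window()].
#' @param lowpass_hz corner frequency of the zero-phase low-pass
#'   (second-order Butterworth, forward-backward) applied to the
#'   hemodynamic channels before segmentation; `NULL` disables.
#'   Pressure and conductance-volume signals are physically
#'   band-limited well below 30 Hz, so the default removes broadband
#'   measurement noise without touching the waveforms.
#' @return list of class `pv_analysis`: `calibration`, `beats` (kept
#'   beats), `window_idx`, `vd`, `es_points`, `linear`, `bilinear`
#'   (or `NULL` if too few points), `model_used`, `prsw`, `landmarks`,
#'   `indices` (per-beat table for the window), `phases` (landmark
#'   summary), `kind`, `n_beats_total`, `n_beats_excluded`.
#' @export
analyze_run <- function(recording, alpha = "auto", Vp = NULL,
                        model = c("auto", "lin", "bilin"),
                        min_seg = 3, bilin_margin = NULL,
                        rr_tolerance = 0.20,
                        min_delta_pes = 2, min_delta_ves = 2,
                        lowpass_hz = 30) {
  model <- match.arg(model)
  if (!is.null(lowpass_hz)) {
    recording <- lowpass_channels(recording, lowpass_hz)
  }
  ch <- recording$channels
  fs <- recording$fs
  if (is.null(Vp)) Vp <- recording$config$Vp_true

  r_idx <- detect_rwaves(ch$ecg, fs)
  beats_all <- segment_beats(recording, r_idx)
  beats <- filter_extrasystoles(beats_all, rr_tolerance)

  base_idx <- baseline_beat_indices(recording, beats)
  cal <- if (identical(alpha, "auto")) {
    estimate_alpha(beats, base_idx, Vp = Vp)
  } else {
    structure(list(alpha = alpha, Vp = Vp, sv_cond_mean = NA_real_,
                   sv_flow_mean = NA_real_, n_beats = 0L),
              class = "pv_calibration")
  }
  beats <- calibrate_beats(beats, cal$alpha, Vp)

  prelim <- end_systolic_series(beats, Vd = 0)
  ann <- recording$annotations
  iv <- ann[ann$label == "intervention", , drop = FALSE]
  if (nrow(iv) == 0) stop("recording has no intervention annotation",
                          call. = FALSE)
  win_idx <- intervention_window(beats, prelim$pes_mmhg, prelim$ves_ml,
                                 iv, min_delta_pes, min_delta_ves)
  wb <- beats[win_idx]

  vd <- estimate_vd(wb)
  es <- end_systolic_series(wb, vd$Vd)
  lin <- fit_linear_espvr(es)
  bil <- if (nrow(es) >= 2 * min_seg) {
    tryCatch(fit_bilinear_espvr(es, min_seg), error = function(e) NULL)
  } else NULL

  kind <- recording$protocol$kind
  model_used <- switch(model,
    lin = "lin",
    bilin = "bilin",
    auto = {
      chosen <- if (kind == "pload") "bilin" else "lin"
      if (!is.null(bilin_margin) && !is.null(bil) &&
          bil$gm_r2 - lin$r2 > bilin_margin) chosen <- "bilin"
      if (is.null(bil)) chosen <- "lin"
      chosen
    })

  landmarks <- classify_phases(if (model_used == "bilin") bil else NULL,
                               length(wb))
  idx_tab <- indices_table(wb, es)
  prsw <- tryCatch(fit_prsw(idx_tab$ved_ml, idx_tab$sw_mmhg_ml),
                   error = function(e) NULL)
  phases <- phase_table(idx_tab, landmarks)

  structure(list(calibration = cal, beats = beats, window_idx = win_idx,
                 vd = vd, es_points = es, linear = lin, bilinear = bil,
                 model_used = model_used, prsw = prsw,
                 landmarks = landmarks, indices = idx_tab,
                 phases = phases, kind = kind,
                 n_beats_total = length(beats_all),
                 n_beats_excluded = length(beats_all) - length(beats)),
            class = "pv_analysis")
}

#' @export
print.pv_analysis <- function(x, ...) {
  cat(sprintf("<pv_analysis> %s: %d beats (%d excluded), window of %d beats\n",
              x$kind, x$n_beats_total, x$n_beats_excluded,
              length(x$window_idx)))
  print(x$vd)
  cat("  linear:   "); print(x$linear)
  if (!is.null(x$bilinear)) { cat("  bilinear:\n"); print(x$bilinear) }
  if (!is.null(x$prsw)) { cat("  PRSW:     "); print(x$prsw) }
  cat(sprintf("  model used: %s\n", x$model_used))
  invisible(x)
}


#' Low-pass filter the hemodynamic channels of a recording
#'
#' Applies a second-order Butterworth filter forward and backward
#' (zero phase) to `lvp`, `lvv_raw`, `aop` and `aoflow`. The ECG is
#' left untouched (R-wave detection needs its sharp edges), as is the
#' ground-truth `lvv` channel.
#'
#' @param recording a `pv_recording`.
#' @param hz corner frequency, Hz; must be below `fs / 2`.
#' @return the recording with filtered channels.
#' @export
lowpass_channels <- function(recording, hz) {
  stopifnot(hz > 0, hz < recording$fs / 2)
  bf <- signal::butter(2, hz / (recording$fs / 2), type = "low")
  ch <- recording$channels
  for (nm in c("lvp", "lvv_raw", "aop", "aoflow")) {
    ch[[nm]] <- as.numeric(signal::filtfilt(bf, ch[[nm]]))
  }
  recording$channels <- ch
  recording
}
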