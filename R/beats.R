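#' Detect R-waves in an ECG channel
#'
#' Simple fiducial detector for clean (synthetic or well-conditioned)
#' ECG: candidate samples are strict local maxima exceeding an adaptive
#' threshold - a fraction of a high-percentile amplitude of the signal -
#' and candidates are accepted in descending amplitude order subject to
#' a refractory period. The R-wave marks end-diastole and is the only
#' feature used downstream.
#'
#' @param ecg numeric ECG samples, mV.
#' @param fs sampling rate, Hz.
#' @param frac threshold as a fraction of the reference amplitude.
#' @param ref_quantile quantile of the signal used as the reference
#'   amplitude. The default (1, the signal maximum) makes the reference
#'   robust for sparse, narrow R-waves that occupy well under 1% of the
#'   samples; lower it for recordings with large isolated artifacts.
#' @param refractory_s minimum spacing between accepted peaks, s.
#' @return sorted integer vector of R-wave sample indices (1-based);
#'   empty when no sample exceeds the threshold.
#' @examples
#' ecg <- numeric(5000); ecg[seq(500, 4500, by = 1000)] <- 1
#' detect_rwaves(ecg, fs = 1000)
#' @export
detect_rwaves <- function(ecg, fs, frac = 0.4, ref_quantile = 1,
                          refractory_s = 0.2) {
  if (length(ecg) < 2 * fs) {
    stop("need at least 2 s of ECG signal", call. = FALSE)
  }
  ref <- stats::quantile(ecg, ref_quantile, names = FALSE)
  thr <- frac * ref
  if (!is.finite(thr) || ref <= 0) return(integer(0))
  n <- length(ecg)
  mid <- ecg[2:(n - 1)]
  is_peak <- mid > ecg[1:(n - 2)] & mid >= ecg[3:n] & mid > thr
  cand <- which(is_peak) + 1L
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(ecg[cand], decreasing = TRUE)]
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  sort(unique(keep))
}

#' Segment a recording into beats at R-wave fiducials
#'
#' Each beat spans the half-open sample interval from one R-wave to the
#' next, so end-diastolic values are read at the beat's first sample.
#' The trailing partial beat after the last R-wave is discarded.
#'
#' @param recording a `pv_recording` (channels `lvp`, `lvv_raw`,
#'   `aoflow` are sliced into the beats; the calibrated volume is
#'   attached later by [calibrate_beats()]).
#' @param r_indices R-wave sample indices from [detect_rwaves()].
#' @return list of `pv_beat` objects; each holds `start`, `end`
#'   (1-based, half-open), `t0_s`, `rr_s`, `fs`, and channel slices
#'   `lvp`, `lvv_raw`, `aoflow` (and `lvv` once calibrated).
#' @export
segment_beats <- function(recording, r_indices) {
  if (length(r_indices) < 2) {
    stop("need at least 2 R-waves to segment beats", call. = FALSE)
  }
  r <- sort(unique(as.integer(r_indices)))
  ch <- recording$channels
  fs <- recording$fs
  beats <- vector("list", length(r) - 1L)
  for (k in seq_len(length(r) - 1L)) {
    i0 <- r[k]; i1 <- r[k + 1L]
    idx <- i0:(i1 - 1L)
    beats[[k]] <- structure(
      list(beat_idx = k, start = i0, end = i1,
           t0_s = (i0 - 1L) / fs, rr_s = (i1 - i0) / fs, fs = fs,
           lvp = ch$lvp[idx], lvv_raw = ch$lvv_raw[idx],
           aoflow = ch$aoflow[idx], lvv = NULL),
      class = "pv_beat")
  }
  beats
}

#' @export
print.pv_beat <- function(x, ...) {
  cat(sprintf("<pv_beat> #%d @ %.3f s, rr %.3f s, %d samples\n",
              x$beat_idx, x$t0_s, x$rr_s, x$end - x$start))
  invisible(x)
}

#' Exclude extrasystoles by RR-interval deviation
#'
#' Beats whose RR interval deviates from the running median (window 5)
#' by more than `rr_tolerance` are removed together with the
#' immediately following (compensatory) beat. Removal of a follower
#' does not cascade: a beat removed only because it follows an
#' extrasystole does not itself trigger removal of its successor. The
#' filter is idempotent on its own output.
#'
#' @param beats list of `pv_beat` from [segment_beats()].
#' @param rr_tolerance fractional deviation from the running median
#'   beyond which a beat is flagged (default 0.20).
#' @return the filtered beat list, order preserved.
#' @export
filter_extrasystoles <- function(beats, rr_tolerance = 0.20) {
  if (length(beats) < 3) {
    stop("need at least 3 beats", call. = FALSE)
  }
  rr <- vapply(beats, function(b) b$rr_s, numeric(1))
  med <- running_median(rr, k = 5)
  dev <- abs(rr - med) / med
  bad <- dev > rr_tolerance
  drop <- bad
  follower <- c(FALSE, bad[-length(bad)])
  drop <- drop | follower
  beats[!drop]
}

running_median <- function(x, k = 5) {
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Estimate the conductance slope factor alpha
#'
#' The conductance-catheter volume is calibrated by the slope factor
#' alpha, the ratio of mean stroke volume measured by the conductance
#' signal to mean stroke volume measured by the aortic flow probe, over
#' baseline (pre-intervention) beats. Flow-probe stroke volume
#' integrates only positive aortic flow, so noise-induced negative
#' samples do not bias the denominator.
#'
#' @param beats list of `pv_beat` (raw conductance volume attached).
#' @param baseline_idx indices into `beats` of the baseline beats; by
#'   default taken from the recording annotation via
#'   [baseline_beat_indices()], falling back to the first 3 beats.
#' @param Vp parallel-conductance volume (mL), supplied externally
#'   (ground truth or user measurement); stored in the result.
#' @return list of class `pv_calibration`: `alpha`, `Vp`,
#'   `sv_cond_mean`, `sv_flow_mean`, `n_beats`.
#' @export
estimate_alpha <- function(beats, baseline_idx = seq_len(min(3, length(beats))),
                           Vp = NA_real_) {
  if (length(baseline_idx) < 3) {
    stop("need at least 3 baseline beats to estimate alpha", call. = FALSE)
  }
  bb <- beats[baseline_idx]
  sv_cond <- vapply(bb, function(b) max(b$lvv_raw) - min(b$lvv_raw),
                    numeric(1))
  sv_flow <- vapply(bb, function(b) sum(pmax(b$aoflow, 0)) / b$fs,
                    numeric(1))
  if (mean(sv_flow) <= 0) {
    stop("calibration error: non-positive flow-probe stroke volume",
         call. = FALSE)
  }
  structure(list(alpha = mean(sv_cond) / mean(sv_flow), Vp = Vp,
                 sv_cond_mean = mean(sv_cond),
                 sv_flow_mean = mean(sv_flow),
                 n_beats = length(bb)),
            class = "pv_calibration")
}

#' @export
print.pv_calibration <- function(x, ...) {
  cat(sprintf(
    "<pv_calibration> alpha = %.4f (SV cond %.1f / flow %.1f mL, %d beats), Vp = %g mL\n",
    x$alpha, x$sv_cond_mean, x$sv_flow_mean, x$n_beats, x$Vp))
  invisible(x)
}

#' Beats inside the recording's baseline annotation
#'
#' @param recording a `pv_recording` with annotations.
#' @param beats list of `pv_beat`.
#' @return integer indices into `beats` of beats whose span lies inside
#'   the `baseline` annotation; if the annotation is absent, the first
#'   three beats.
#' @export
baseline_beat_indices <- function(recording, beats) {
  ann <- recording$annotations
  row <- ann[ann$label == "baseline", , drop = FALSE]
  if (nrow(row) == 0) return(seq_len(min(3, length(beats))))
  t0 <- vapply(beats, function(b) b$t0_s, numeric(1))
  t1 <- t0 + vapply(beats, function(b) b$rr_s, numeric(1))
  idx <- which(t0 >= row$start_s[1] & t1 <= row$end_s[1])
  if (length(idx) < 3) idx <- seq_len(min(3, length(beats)))
  idx
}

#' Correct a raw conductance volume series
#'
#' Inverts the conductance distortion: `lvv = (lvv_raw - Vp) / alpha`.
#'
#' @param lvv_raw raw conductance volume series (mL-equivalent).
#' @param alpha slope factor, > 0.
#' @param Vp parallel-conductance volume, mL.
#' @return calibrated volume series, mL.
#' @examples
#' calibrate_volume(110, alpha = 0.8, Vp = 30)  # 100 mL
#' @export
calibrate_volume <- function(lvv_raw, alpha, Vp) {
  if (!is.finite(alpha) || alpha <= 0) {
    stop("alpha must be strictly positive", call. = FALSE)
  }
  (lvv_raw - Vp) / alpha
}

#' Attach a calibrated volume to segmented beats
#'
#' @param beats list of `pv_beat`.
#' @param alpha,Vp calibration parameters for [calibrate_volume()].
#' @return the beat list with `lvv` slices filled in.
#' @export
calibrate_beats <- function(beats, alpha, Vp) {
  lapply(beats, function(b) {
    b$lvv <- calibrate_volume(b$lvv_raw, alpha, Vp)
    b
  })
}

#' Select the analyzable intervention window
#'
#' Starting at the annotated intervention onset, keeps the contiguous
#' run of beats over which the beat-to-beat change in end-systolic
#' pressure or volume exceeds the thresholds; the window ends when both
#' changes stay below threshold for two consecutive beats, or at the
#' end of the annotation.
#'
#' @param beats list of `pv_beat`.
#' @param pes,ves per-beat preliminary end-systolic pressure (mmHg) and
#'   volume (mL), same length as `beats` (e.g. from [beat_emax()] with
#'   `Vd = 0`).
#' @param annotation one-row data frame (or list) with `start_s`,
#'   `end_s` of the intervention.
#' @param min_delta_pes,min_delta_ves thresholds, mmHg and mL.
#' @return integer indices into `beats` forming the window.
#' @export
intervention_window <- function(beats, pes, ves, annotation,
                                min_delta_pes = 2, min_delta_ves = 2) {
  stopifnot(length(pes) == length(beats), length(ves) == length(beats))
  t0 <- vapply(beats, function(b) b$t0_s, numeric(1))
  first <- which(t0 >= annotation$start_s[1])[1]
  if (is.na(first) || first < 2) first <- 2L
  last_ok <- max(which(t0 < annotation$end_s[1]), first)
  dpes <- abs(diff(pes)); dves <- abs(diff(ves))
  active <- function(i) dpes[i - 1] >= min_delta_pes ||
    dves[i - 1] >= min_delta_ves
  if (!any(vapply(first:last_ok, active, logical(1)))) {
    stop("no load change detected in the intervention window",
         call. = FALSE)
  }
  # start at the first active beat at/after onset
  start <- first
  while (start <= last_ok && !active(start)) start <- start + 1L
  end <- start
  quiet <- 0L
  i <- start
  while (i <= last_ok) {
    if (active(i)) {
      quiet <- 0L
      end <- i
    } else {
      quiet <- quiet + 1L
      if (quiet >= 2L) break
    }
    i <- i + 1L
  }
  start:end
}
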