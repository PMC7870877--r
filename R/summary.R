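#' Stroke work as pressure-volume loop area
#'
#' Absolute shoelace (polygon) area of the closed volume-pressure
#' trajectory of one beat, closing from the last sample back to the
#' first. Orientation-invariant; a degenerate loop returns 0.
#'
#' @param beat a `pv_beat` with calibrated volume (or any object with
#'   `lvp` and `lvv` numeric fields of equal length >= 4).
#' @return stroke work, mmHg mL.
#' @export
loop_area <- function(beat) {
  v <- beat$lvv; p <- beat$lvp
  if (length(v) < 4) stop("need at least 4 samples", call. = FALSE)
  j <- c(seq_along(v)[-1], 1L)
  abs(sum(v * p[j] - v[j] * p)) / 2
}

#' Per-beat hemodynamic indices
#'
#' End-diastolic pressure and volume are read at the beat's first
#' sample (the R-wave), end-systolic values come from the supplied
#' maximal-elastance point, stroke volume is `Ved - Ves`, stroke work
#' is the loop area, effective arterial elastance is `Pes / SV`, and
#' dP/dtmax is the maximum centered-difference derivative of
#' ventricular pressure within the beat.
#'
#' @param beat a calibrated `pv_beat`.
#' @param es the beat's `pv_espoint` from [beat_emax()].
#' @return list of class `pv_indices`: `Ped`, `Ved`, `Pes`, `Ves`,
#'   `SV`, `SW`, `Ea`, `dPdtmax`, `ea_undefined` (TRUE when SV <= 0, in
#'   which case `Ea` is `NA`).
#' @export
beat_indices <- function(beat, es) {
  ped <- beat$lvp[1]
  ved <- beat$lvv[1]
  sv <- ved - es$Ves
  ea_undef <- !is.finite(sv) || sv <= 0
  p <- beat$lvp
  n <- length(p)
  dpdt <- (p[3:n] - p[1:(n - 2)]) * beat$fs / 2
  structure(list(Ped = ped, Ved = ved, Pes = es$Pes, Ves = es$Ves,
                 SV = sv, SW = loop_area(beat),
                 Ea = if (ea_undef) NA_real_ else es$Pes / sv,
                 dPdtmax = max(dpdt), ea_undefined = ea_undef),
            class = "pv_indices")
}

#' Per-beat indices table for a beat window
#'
#' @param beats list of calibrated `pv_beat`.
#' @param es_points data frame from [end_systolic_series()] aligned
#'   with `beats`.
#' @return data frame, one row per beat: `beat_idx`, `t_start_s`,
#'   `rr_s`, `ped_mmhg`, `ved_ml`, `pes_mmhg`, `ves_ml`, `sv_ml`,
#'   `sw_mmhg_ml`, `ea_mmhg_ml`, `dpdtmax_mmhg_s`.
#' @export
indices_table <- function(beats, es_points) {
  stopifnot(length(beats) == nrow(es_points))
  rows <- lapply(seq_along(beats), function(i) {
    b <- beats[[i]]
    es <- list(Ves = es_points$ves_ml[i], Pes = es_points$pes_mmhg[i])
    ix <- beat_indices(b, es)
    data.frame(beat_idx = b$beat_idx, t_start_s = b$t0_s, rr_s = b$rr_s,
               ped_mmhg = ix$Ped, ved_ml = ix$Ved, pes_mmhg = ix$Pes,
               ves_ml = ix$Ves, sv_ml = ix$SV, sw_mmhg_ml = ix$SW,
               ea_mmhg_ml = ix$Ea, dpdtmax_mmhg_s = ix$dPdtmax)
  })
  do.call(rbind, rows)
}

#' Hemodynamic summary at the phase landmarks
#'
#' Reports the per-beat indices at the landmark beats `a` (start of
#' phase 1), `b` (end of phase 1 / bilinear split) and `c` (end of the
#' window). Each landmark value averages the landmark beat with its
#' immediate neighbors (`window = 1`) to damp single-beat measurement
#' noise; set `window = 0` for strictly single-beat values.
#'
#' @param idx_table per-beat indices from [indices_table()] for the
#'   window beats.
#' @param landmarks named vector `(a, b, c)` from [classify_phases()].
#' @param window number of neighbor beats averaged on each side.
#' @return data frame with one row per defined landmark and the index
#'   columns of `idx_table`.
#' @export
phase_table <- function(idx_table, landmarks, window = 1) {
  cols <- c("ped_mmhg", "ved_ml", "pes_mmhg", "ves_ml", "sv_ml",
            "sw_mmhg_ml", "ea_mmhg_ml", "dpdtmax_mmhg_s")
  rows <- lapply(names(landmarks), function(nm) {
    i <- landmarks[[nm]]
    if (is.na(i)) return(NULL)
    sel <- max(1, i - window):min(nrow(idx_table), i + window)
    out <- as.data.frame(lapply(idx_table[sel, cols, drop = FALSE],
                                mean))
    cbind(data.frame(landmark = nm,
                     beat_idx = idx_table$beat_idx[i]), out)
  })
  do.call(rbind, rows)
}
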