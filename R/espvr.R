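#' Linear ESPVR fit
#'
#' Ordinary least squares of end-systolic pressure on end-systolic
#' volume. The slope is the end-systolic elastance Ees and the
#' volume-axis intercept V0 = -b/m for the fitted line P = m V + b.
#'
#' @param points data frame with columns `ves_ml`, `pes_mmhg` (e.g.
#'   from [end_systolic_series()]).
#' @return list of class `pv_linfit`: `Ees`, `V0`, `r2`, `n_points`,
#'   `intercept`, and `nonphysiological` (TRUE when the slope is not
#'   positive; the fit is returned, not raised, since near-horizontal
#'   relations do occur under afterload loading).
#' @export
fit_linear_espvr <- function(points) {
  if (nrow(points) < 3) {
    stop("need at least 3 end-systolic points", call. = FALSE)
  }
  if (stats::sd(points$ves_ml) == 0) {
    stop("vertical ESPVR: all end-systolic volumes equal", call. = FALSE)
  }
  f <- ols_line(points$ves_ml, points$pes_mmhg)
  structure(list(Ees = f$m, V0 = -f$b / f$m, r2 = f$r2,
                 n_points = f$n, intercept = f$b,
                 nonphysiological = f$m <= 0),
            class = "pv_linfit")
}

#' @export
print.pv_linfit <- function(x, ...) {
  cat(sprintf("<pv_linfit> Ees = %.3f mmHg/mL, V0 = %.1f mL, r2 = %.4f (n = %d)%s\n",
              x$Ees, x$V0, x$r2, x$n_points,
              if (x$nonphysiological) " [non-physiological slope]" else ""))
  invisible(x)
}

#' Bilinear ESPVR fit by geometric-mean-r2 split search
#'
#' Fits every admissible contiguous split of the (time-ordered)
#' end-systolic points into two segments of at least `min_seg` points,
#' fits an OLS line to each, and selects the split maximizing the
#' geometric mean of the two coefficients of determination. Ties are
#' broken by the earlier split. The breakpoint is the analytic
#' intersection of the two fitted lines; if the lines are parallel the
#' midpoint between the last phase-1 and first phase-2 point is
#' returned and flagged.
#'
#' The split is searched over beat order (time), not volume order: the
#' two phases of the afterload response are temporal (shortening
#' deactivation first, Frank-Starling dilation second).
#'
#' @param points time-ordered data frame with `ves_ml`, `pes_mmhg`.
#' @param min_seg minimum points per segment (default 3; r2 of a
#'   two-parameter line is trivial below that).
#' @return list of class `pv_bilinfit`: `phase1`, `phase2`
#'   (`pv_linfit`s), `split_index` (last point of phase 1), `gm_r2`,
#'   `breakpoint` (list `V`, `P`, `parallel`).
#' @export
fit_bilinear_espvr <- function(points, min_seg = 3) {
  n <- nrow(points)
  if (n < 2 * min_seg) {
    stop(sprintf("need at least %d points for a bilinear fit", 2 * min_seg),
         call. = FALSE)
  }
  best <- NULL
  best_gm <- -Inf
  for (k in min_seg:(n - min_seg)) {
    p1 <- points[1:k, , drop = FALSE]
    p2 <- points[(k + 1):n, , drop = FALSE]
    if (stats::sd(p1$ves_ml) == 0 || stats::sd(p2$ves_ml) == 0) next
    f1 <- ols_line(p1$ves_ml, p1$pes_mmhg)
    f2 <- ols_line(p2$ves_ml, p2$pes_mmhg)
    gm <- sqrt(f1$r2 * f2$r2)
    if (gm > best_gm) {  # strict: keeps the earliest split on ties
      best_gm <- gm
      best <- list(k = k, f1 = f1, f2 = f2)
    }
  }
  if (is.null(best)) {
    stop("no admissible split (end-systolic volumes degenerate)",
         call. = FALSE)
  }
  lin <- function(f) {
    structure(list(Ees = f$m, V0 = -f$b / f$m, r2 = f$r2,
                   n_points = f$n, intercept = f$b,
                   nonphysiological = f$m <= 0),
              class = "pv_linfit")
  }
  k <- best$k
  bp <- intersection(c(best$f1$m, best$f1$b), c(best$f2$m, best$f2$b))
  if (bp$parallel) {
    bp$V <- (points$ves_ml[k] + points$ves_ml[k + 1]) / 2
    bp$P <- (points$pes_mmhg[k] + points$pes_mmhg[k + 1]) / 2
  }
  structure(list(phase1 = lin(best$f1), phase2 = lin(best$f2),
                 split_index = k, gm_r2 = best_gm, breakpoint = bp),
            class = "pv_bilinfit")
}

#' @export
print.pv_bilinfit <- function(x, ...) {
  cat(sprintf("<pv_bilinfit> split after point %d, gm_r2 = %.4f\n",
              x$split_index, x$gm_r2))
  cat("  phase 1: "); print(x$phase1)
  cat("  phase 2: "); print(x$phase2)
  cat(sprintf("  breakpoint: V* = %.1f mL, P* = %.1f mmHg%s\n",
              x$breakpoint$V, x$breakpoint$P,
              if (x$breakpoint$parallel) " [parallel fallback]" else ""))
  invisible(x)
}

#' Intersection of two regression lines
#'
#' @param line1,line2 numeric length-2 vectors `(m, b)` of slope and
#'   intercept.
#' @param tol relative slope difference below which the lines are
#'   treated as parallel.
#' @return list `V`, `P`, `parallel`; for parallel lines `V`/`P` are
#'   `NA` (the bilinear fit substitutes its midpoint fallback).
#' @examples
#' intersection(c(2, -100), c(1, -20))  # V* = 80, P* = 60
#' @export
intersection <- function(line1, line2, tol = 1e-9) {
  m1 <- line1[1]; b1 <- line1[2]
  m2 <- line2[1]; b2 <- line2[2]
  scale <- max(abs(m1), abs(m2), 1)
  if (abs(m1 - m2) <= tol * scale) {
    return(list(V = NA_real_, P = NA_real_, parallel = TRUE))
  }
  V <- (b2 - b1) / (m1 - m2)
  list(V = V, P = m1 * V + b1, parallel = FALSE)
}

#' Preload recruitable stroke work
#'
#' OLS of stroke work on end-diastolic volume over the window beats.
#' The slope Mw and volume-axis intercept Vw index contractility. A
#' non-positive or near-zero slope is flagged `not_meaningful` rather
#' than raised: under pure afterload loading the relation is expected
#' to be nearly horizontal.
#'
#' @param ved end-diastolic volumes, mL.
#' @param sw stroke work values, mmHg mL.
#' @param flat_slope slope magnitude (mmHg) below which the fit is
#'   flagged not meaningful.
#' @return list of class `pv_prsw`: `Mw`, `Vw`, `r2`, `n_points`,
#'   `not_meaningful`.
#' @export
fit_prsw <- function(ved, sw, flat_slope = 10) {
  if (length(ved) < 3) stop("need at least 3 beats", call. = FALSE)
  if (stats::sd(ved) == 0) {
    stop("PRSW undefined: no end-diastolic volume variation",
         call. = FALSE)
  }
  f <- ols_line(ved, sw)
  structure(list(Mw = f$m, Vw = -f$b / f$m, r2 = f$r2, n_points = f$n,
                 not_meaningful = f$m <= flat_slope),
            class = "pv_prsw")
}

#' @export
print.pv_prsw <- function(x, ...) {
  cat(sprintf("<pv_prsw> Mw = %.1f mmHg, Vw = %.1f mL, r2 = %.4f (n = %d)%s\n",
              x$Mw, x$Vw, x$r2, x$n_points,
              if (x$not_meaningful) " [not meaningful]" else ""))
  invisible(x)
}

#' Phase landmarks of an analyzed window
#'
#' Landmarks index the window beats: `a` is the first beat (start of
#' phase 1), `b` the last beat of phase 1 (the bilinear split), and `c`
#' the last beat of the window. For a linear-only analysis `b` is `NA`.
#'
#' @param bilinear a `pv_bilinfit`, or `NULL` for a linear-only window.
#' @param n_beats number of beats in the window.
#' @return named integer vector `(a, b, c)` of window-relative beat
#'   positions (1-based).
#' @export
classify_phases <- function(bilinear, n_beats) {
  b <- if (is.null(bilinear)) NA_integer_ else bilinear$split_index
  c(a = 1L, b = as.integer(b), c = as.integer(n_beats))
}
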