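#' Maximal-elastance end-systole detection for one beat
#'
#' End-systole is the sample maximizing the time-varying elastance
#' `Emax(t) = P(t) / (V(t) - Vd)` over samples where the denominator
#' exceeds a 0.5 mL guard band and pressure is positive. Ties are
#' broken by the earliest sample.
#'
#' @param beat a `pv_beat` with a calibrated `lvv` slice.
#' @param Vd slack volume, mL.
#' @param guard_ml denominator guard band, mL.
#' @return list of class `pv_espoint`: `beat_idx`, `t_es` (seconds,
#'   recording time), `Ves` (mL), `Pes` (mmHg), `Emax` (mmHg/mL).
#' @export
beat_emax <- function(beat, Vd, guard_ml = 0.5) {
  v <- beat$lvv
  if (is.null(v)) {
    stop("beat has no calibrated volume; run calibrate_beats() first",
         call. = FALSE)
  }
  p <- beat$lvp
  denom <- v - Vd
  ok <- denom > guard_ml & p > 0
  if (!any(ok)) {
    stop(sprintf("beat %d: no admissible sample for Emax (Vd = %.1f mL)",
                 beat$beat_idx, Vd), call. = FALSE)
  }
  e <- rep(-Inf, length(v))
  e[ok] <- p[ok] / denom[ok]
  i <- which.max(e)  # which.max returns the first maximum: earliest tie
  structure(list(beat_idx = beat$beat_idx,
                 t_es = beat$t0_s + (i - 1L) / beat$fs,
                 Ves = v[i], Pes = p[i], Emax = e[i]),
            class = "pv_espoint")
}

#' Iterative slack-volume (Vd) estimation
#'
#' Fixed-point iteration for the slack volume used in the
#' maximal-elastance equation: starting from `Vd = 0`, (i) locate each
#' beat's end-systolic point with the current Vd, (ii) fit an ordinary
#' least-squares line to the end-systolic pressure-volume points,
#' (iii) take the line's volume-axis intercept as the next Vd. The
#' iteration stops when consecutive estimates differ by less than `tol`
#' or after `max_iter` passes. At every step Vd is clamped to at least
#' 1 mL below the minimum observed volume so the elastance stays finite
#' throughout the window.
#'
#' @param beats window beats (list of `pv_beat`, calibrated) spanning a
#'   load change.
#' @param tol convergence tolerance, mL.
#' @param max_iter maximum iterations.
#' @param guard_ml guard band passed to [beat_emax()].
#' @return list of class `pv_vd`: `Vd`, `n_iterations`, `converged`,
#'   `history` (Vd per iteration, starting value included).
#' @export
estimate_vd <- function(beats, tol = 0.1, max_iter = 50, guard_ml = 0.5) {
  if (length(beats) < 3) {
    stop("need at least 3 beats with load variation", call. = FALSE)
  }
  vmin <- min(vapply(beats, function(b) min(b$lvv), numeric(1)))
  cap <- vmin - 1
  vd <- 0
  history <- vd
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    es <- lapply(beats, beat_emax, Vd = vd, guard_ml = guard_ml)
    ves <- vapply(es, function(p) p$Ves, numeric(1))
    pes <- vapply(es, function(p) p$Pes, numeric(1))
    if (stats::sd(ves) == 0) {
      stop("degenerate ESPVR: no load variation in end-systolic volume",
           call. = FALSE)
    }
    fit <- ols_line(ves, pes)
    if (fit$m <= 0) {
      stop("degenerate ESPVR: non-positive slope during Vd iteration",
           call. = FALSE)
    }
    vd_new <- min(-fit$b / fit$m, cap)
    history <- c(history, vd_new)
    if (abs(vd_new - vd) < tol) {
      vd <- vd_new
      converged <- TRUE
      break
    }
    vd <- vd_new
  }
  structure(list(Vd = vd, n_iterations = length(history) - 1L,
                 converged = converged, history = history),
            class = "pv_vd")
}

#' @export
print.pv_vd <- function(x, ...) {
  cat(sprintf("<pv_vd> Vd = %.2f mL after %d iterations (%s)\n",
              x$Vd, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' End-systolic point series for a beat window
#'
#' @param beats window beats (list of `pv_beat`, calibrated).
#' @param Vd slack volume from [estimate_vd()] (or supplied).
#' @return data frame with one row per beat: `beat_idx`, `t_es_s`,
#'   `ves_ml`, `pes_mmhg`, `emax_mmhg_ml`.
#' @export
end_systolic_series <- function(beats, Vd) {
  es <- lapply(beats, beat_emax, Vd = Vd)
  data.frame(beat_idx = vapply(es, function(p) p$beat_idx, numeric(1)),
             t_es_s = vapply(es, function(p) p$t_es, numeric(1)),
             ves_ml = vapply(es, function(p) p$Ves, numeric(1)),
             pes_mmhg = vapply(es, function(p) p$Pes, numeric(1)),
             emax_mmhg_ml = vapply(es, function(p) p$Emax, numeric(1)))
}

# Closed-form simple OLS of y on x (normal equations).
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("OLS: predictor has zero variance", call. = FALSE)
  sxy <- sum((x - mx) * (y - my))
  m <- sxy / sxx
  b <- my - m * mx
  syy <- sum((y - my)^2)
  sse <- syy - m * sxy
  r2 <- if (syy > 0) max(0, 1 - sse / syy) else 1
  list(m = m, b = b, r2 = r2, n = length(x))
}
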