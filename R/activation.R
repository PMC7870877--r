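#' Normalized double-Hill activation drive
#'
#' Time-varying elastance models drive ventricular contraction with a
#' normalized activation function e(t) in \[0, 1\]. This package uses the
#' standard double-Hill form: a rising Hill term (exponent `m1`, time
#' constant `tau1`) multiplied by a decaying Hill term (exponent `m2`,
#' time constant `tau2`), with time expressed as the fraction of the
#' cardiac cycle elapsed. The curve is normalized internally so its
#' maximum over one period is exactly 1 and its value at the cycle start
#' is (numerically) 0.
#'
#' @param t_norm numeric vector of normalized times in \[0, 1).
#' @param params list with elements `tau1`, `tau2` (fractions of the
#'   cycle) and `m1`, `m2` (dimensionless Hill exponents); all must be
#'   strictly positive.
#' @return numeric vector of activation values in \[0, 1\].
#' @examples
#' activation_curve(seq(0, 0.99, by = 0.01), act_params())
#' @export
activation_curve <- function(t_norm, params = act_params()) {
  check_act_params(params)
  if (any(t_norm < 0 | t_norm >= 1)) {
    stop("t_norm must lie in [0, 1)", call. = FALSE)
  }
  info <- act_shape_info(params)
  act_raw(t_norm, params) / info$norm
}

#' Default activation shape parameters
#'
#' Shape constants for the double-Hill drive, expressed as fractions of
#' the cardiac cycle so the waveform scales with the RR interval. The
#' defaults give a systolic activation peaking at about 40% of the cycle
#' with a sharp relaxation, a standard parameterization for large-mammal
#' ventricles.
#'
#' @param tau1,tau2 time constants, as fractions of the beat period.
#' @param m1,m2 Hill exponents of the rising and relaxing limbs.
#' @return list of the four shape parameters.
#' @export
act_params <- function(tau1 = 0.269, tau2 = 0.452, m1 = 1.32, m2 = 27.4) {
  list(tau1 = tau1, tau2 = tau2, m1 = m1, m2 = m2)
}

check_act_params <- function(params) {
  need <- c("tau1", "tau2", "m1", "m2")
  if (!all(need %in% names(params))) {
    stop("activation params must contain tau1, tau2, m1, m2", call. = FALSE)
  }
  v <- unlist(params[need])
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("activation shape parameters must be strictly positive",
         call. = FALSE)
  }
  invisible(params)
}

act_raw <- function(t_norm, params) {
  g1 <- (t_norm / params$tau1)^params$m1
  g2 <- (t_norm / params$tau2)^params$m2
  ifelse(t_norm <= 0, 0, (g1 / (1 + g1)) * (1 / (1 + g2)))
}

# Normalization constant and peak location on a dense grid; memoized per
# parameter set since the simulator asks for it once per run.
act_shape_info <- function(params, n_grid = 4096L) {
  check_act_params(params)
  tt <- seq(0, 1 - 1 / n_grid, length.out = n_grid)
  y <- act_raw(tt, params)
  i <- which.max(y)
  list(norm = y[i], t_peak = tt[i])
}
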