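#' Load-intervention protocols
#'
#' Builds the schedule of vascular-parameter changes for the three load
#' interventions studied with the simulator:
#'
#' * `vload_normal` - transient preload reduction (vena-cava occlusion):
#'   the venous-return resistance is ramped up and released within less
#'   than 10 s.
#' * `pload` - acute afterload increase: the peripheral resistance is
#'   ramped up over 1-2 s and held for the rest of the run.
#' * `vload_high` - preload reduction at an elevated afterload: the
#'   `pload` ramp first, then a vena-cava occlusion while the afterload
#'   is held.
#'
#' Schedule events are `(param, start_s, ramp_s, factor)`: the
#' multiplicative factor on the named base parameter ramps linearly from
#' its current value to `factor` over `ramp_s` seconds starting at
#' `start_s`, then holds until the next event for that parameter.
#'
#' @param kind one of `"vload_normal"`, `"pload"`, `"vload_high"`.
#' @param config a [sim_config()] (reserved for parameter-dependent
#'   scheduling; the default schedules only depend on `kind`).
#' @param total_duration run length in seconds (<= 30).
#' @param pload_ramp_s afterload ramp duration, seconds, in \[1, 2\].
#' @param pload_factor multiplicative target on the peripheral
#'   resistance.
#' @param occl_factor multiplicative target on the venous-return
#'   resistance during occlusion.
#' @return an object of class `pv_protocol` with fields `kind`,
#'   `schedule` (data frame), `total_duration`, and `annotations`
#'   (data frame of `label`, `start_s`, `end_s` incl. the `baseline` and
#'   `intervention` windows).
#' @examples
#' make_protocol("pload", sim_config())
#' @export
make_protocol <- function(kind, config = sim_config(),
                          total_duration = 20,
                          pload_ramp_s = 1.5,
                          pload_factor = 2.8,
                          occl_factor = 15) {
  kind <- match.arg(kind, c("vload_normal", "pload", "vload_high"))
  if (total_duration > 30) {
    stop("total_duration must be <= 30 s", call. = FALSE)
  }
  if (pload_ramp_s < 1 || pload_ramp_s > 2) {
    stop("pload ramp duration must lie in [1, 2] s", call. = FALSE)
  }
  ev <- function(param, start, ramp, factor) {
    data.frame(param = param, start_s = start, ramp_s = ramp,
               factor = factor, stringsAsFactors = FALSE)
  }
  # the baseline annotation starts after the integrator's initial
  # settling so calibration beats reflect the pre-intervention steady
  # state
  t_settle <- 3
  if (kind == "vload_normal") {
    t_on <- 8; t_off <- 15  # occlusion window: 7 s < 10 s
    schedule <- rbind(ev("Rv_return", t_on, 0.5, occl_factor),
                      ev("Rv_return", t_off, 0.5, 1))
    ann <- data.frame(label = c("baseline", "intervention"),
                      start_s = c(t_settle, t_on), end_s = c(t_on, t_off))
  } else if (kind == "pload") {
    t_on <- 8
    schedule <- ev("Rp", t_on, pload_ramp_s, pload_factor)
    ann <- data.frame(label = c("baseline", "intervention"),
                      start_s = c(t_settle, t_on),
                      end_s = c(t_on, total_duration))
  } else {
    t_p <- 4; t_on <- 10; t_off <- 17
    schedule <- rbind(ev("Rp", t_p, pload_ramp_s, pload_factor),
                      ev("Rv_return", t_on, 0.5, occl_factor),
                      ev("Rv_return", t_off, 0.5, 1))
    ann <- data.frame(label = c("baseline", "afterload_hold",
                                "intervention"),
                      start_s = c(t_settle, t_p, t_on),
                      end_s = c(t_p, t_on, t_off))
  }
  if (any(schedule$start_s < 0 |
          schedule$start_s + schedule$ramp_s > total_duration)) {
    stop("schedule events must lie within [0, total_duration]",
         call. = FALSE)
  }
  structure(list(kind = kind, schedule = schedule,
                 total_duration = total_duration, annotations = ann),
            class = "pv_protocol")
}

#' @export
print.pv_protocol <- function(x, ...) {
  cat(sprintf("<pv_protocol> %s, %g s\n", x$kind, x$total_duration))
  print(x$schedule, row.names = FALSE)
  invisible(x)
}

# Per-sample multiplicative factor on `param` implied by the protocol
# schedule, evaluated at `times` (seconds). Events compose sequentially.
param_factors <- function(protocol, param, times) {
  f <- rep(1, length(times))
  evs <- protocol$schedule[protocol$schedule$param == param, , drop = FALSE]
  if (nrow(evs) == 0) return(f)
  evs <- evs[order(evs$start_s), , drop = FALSE]
  for (k in seq_len(nrow(evs))) {
    prev <- if (k == 1) 1 else evs$factor[k - 1]
    w <- pmin(pmax((times - evs$start_s[k]) / evs$ramp_s[k], 0), 1)
    f <- ifelse(times < evs$start_s[k], f, prev + (evs$factor[k] - prev) * w)
  }
  f
}
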