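#' Cohort configuration
#'
#' Settings for a simulated study: number of animals, repeats per
#' intervention, between-animal parameter dispersion, and the master
#' seed from which every run's seed is derived.
#'
#' @param n_animals number of simulated animals, >= 2.
#' @param repeats repeats per intervention per animal, in \[1, 10\].
#' @param cv_ees lognormal coefficient of variation on the true
#'   end-systolic elastance between animals.
#' @param sd_v0 between-animal SD of the base volume intercept, mL.
#' @param cv_vascular lognormal CV applied to Rp, Ca and Rv_return.
#' @param cv_pload lognormal CV of the afterload ramp magnitude between
#'   animals (occluder placement and filling differ between animals but
#'   are fixed within one).
#' @param sd_hr between-animal SD of heart rate, beats/min.
#' @param sda_enabled whether the shortening-deactivation mechanism is
#'   active in the generated animals.
#' @param base_config template [sim_config()] the animals are drawn
#'   around.
#' @param master_seed integer master seed.
#' @return list of class `pv_cohort_config`.
#' @export
cohort_config <- function(n_animals = 10, repeats = 3,
                          cv_ees = 0.10, sd_v0 = 2,
                          cv_vascular = 0.10, cv_pload = 0.20,
                          sd_hr = 5,
                          sda_enabled = TRUE,
                          base_config = sim_config(sda_enabled = sda_enabled),
                          master_seed = 1L) {
  if (n_animals < 2) stop("n_animals must be >= 2", call. = FALSE)
  if (repeats < 1 || repeats > 10) {
    stop("repeats must lie in [1, 10]", call. = FALSE)
  }
  structure(list(n_animals = as.integer(n_animals),
                 repeats = as.integer(repeats),
                 cv_ees = cv_ees, sd_v0 = sd_v0,
                 cv_vascular = cv_vascular, cv_pload = cv_pload,
                 sd_hr = sd_hr,
                 sda_enabled = isTRUE(sda_enabled),
                 base_config = base_config,
                 master_seed = as.integer(master_seed)),
            class = "pv_cohort_config")
}

#' Simulate and analyze a cohort
#'
#' Draws per-animal parameters (lognormal dispersion around the base
#' configuration), runs all three load protocols with the configured
#' number of repeats per animal, analyzes every run with the full
#' pipeline, and returns a tidy result table alongside the generating
#' ground truth. Runs whose analysis fails are flagged, not dropped.
#'
#' @param config a [cohort_config()].
#' @param verbose print one status line per run to stderr.
#' @return list of class `pv_cohort`: `runs` (one row per run, wide:
#'   linear and bilinear fits, PRSW, landmark Ea values, Vd, `ok` flag
#'   and error message), `rows` (long: one row per run and fit type
#'   with `Ees`, `V0`, `r2`), `animals` (ground-truth parameter table),
#'   `config`.
#' @export
simulate_cohort <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pv_cohort_config"))
  base <- config$base_config
  set.seed(config$master_seed)
  animals <- data.frame(
    animal = seq_len(config$n_animals),
    Ees_true = base$Ees_true * stats::rlnorm(config$n_animals, 0,
                                             config$cv_ees),
    V0_base = base$V0_base + stats::rnorm(config$n_animals, 0,
                                          config$sd_v0),
    heart_rate = pmin(pmax(base$heart_rate +
                             stats::rnorm(config$n_animals, 0,
                                          config$sd_hr), 40), 200),
    f_rp = stats::rlnorm(config$n_animals, 0, config$cv_vascular),
    f_ca = stats::rlnorm(config$n_animals, 0, config$cv_vascular),
    f_rv = stats::rlnorm(config$n_animals, 0, config$cv_vascular),
    pload_factor = 2.8 * stats::rlnorm(config$n_animals, 0,
                                       config$cv_pload))
  animals$sda_slope_a <- base$sda_slope_a
  animals$sda_intercept_b <- base$sda_intercept_b

  kinds <- c("vload_normal", "pload", "vload_high")
  n_runs <- config$n_animals * length(kinds) * config$repeats
  run_seeds <- sample.int(.Machine$integer.max, n_runs)

  runs <- list()
  ri <- 0L
  for (a in seq_len(config$n_animals)) {
    an <- animals[a, ]
    cfg_a <- base
    cfg_a$heart_rate <- an$heart_rate
    cfg_a$Ees_true <- an$Ees_true
    cfg_a$V0_base <- an$V0_base
    cfg_a$sda_enabled <- config$sda_enabled
    cfg_a$Rp <- base$Rp * an$f_rp
    cfg_a$Ca <- base$Ca * an$f_ca
    cfg_a$Rv_return <- base$Rv_return * an$f_rv
    cfg_a <- validate_sim_config(cfg_a)
    for (kind in kinds) {
      for (rep in seq_len(config$repeats)) {
        ri <- ri + 1L
        cfg_a$seed <- run_seeds[ri]
        row <- analyze_one(cfg_a, kind, a, rep,
                           pload_factor = an$pload_factor)
        if (verbose) {
          message(sprintf("animal %d %s repeat %d: %s", a, kind, rep,
                          if (row$ok) "ok" else row$error))
        }
        runs[[ri]] <- row
      }
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(runs = runs, rows = cohort_long(runs),
                 animals = animals, config = config),
            class = "pv_cohort")
}

analyze_one <- function(cfg, kind, animal, rep, pload_factor = 2.4) {
  empty <- data.frame(
    animal = animal, kind = kind, rep = rep, ok = FALSE,
    error = NA_character_, n_window = NA_integer_, vd_ml = NA_real_,
    ees_lin = NA_real_, v0_lin = NA_real_, r2_lin = NA_real_,
    ees_b1 = NA_real_, v0_b1 = NA_real_, r2_b1 = NA_real_,
    ees_b2 = NA_real_, v0_b2 = NA_real_, r2_b2 = NA_real_,
    gm_r2 = NA_real_, split = NA_integer_,
    ves_b2_mean = NA_real_, pes_b2_mean = NA_real_,
    mw = NA_real_, vw = NA_real_,
    ea_a = NA_real_, ea_b = NA_real_, ea_c = NA_real_,
    ea_b_single = NA_real_, ea_b_prev = NA_real_,
    v0_true_end = NA_real_, ea_true_end = NA_real_,
    stringsAsFactors = FALSE)
  tryCatch({
    proto <- make_protocol(kind, cfg, pload_factor = pload_factor)
    rec <- distort_and_noise(simulate_run(cfg, proto))
    an <- analyze_run(rec)
    out <- empty
    out$ok <- TRUE
    out$n_window <- length(an$window_idx)
    out$vd_ml <- an$vd$Vd
    out$ees_lin <- an$linear$Ees; out$v0_lin <- an$linear$V0
    out$r2_lin <- an$linear$r2
    if (!is.null(an$bilinear)) {
      out$ees_b1 <- an$bilinear$phase1$Ees
      out$v0_b1 <- an$bilinear$phase1$V0
      out$r2_b1 <- an$bilinear$phase1$r2
      out$ees_b2 <- an$bilinear$phase2$Ees
      out$v0_b2 <- an$bilinear$phase2$V0
      out$r2_b2 <- an$bilinear$phase2$r2
      out$gm_r2 <- an$bilinear$gm_r2
      out$split <- an$bilinear$split_index
      p2 <- an$es_points[(an$bilinear$split_index + 1):nrow(an$es_points), ]
      out$ves_b2_mean <- mean(p2$ves_ml)
      out$pes_b2_mean <- mean(p2$pes_mmhg)
    }
    if (!is.null(an$prsw)) {
      out$mw <- an$prsw$Mw; out$vw <- an$prsw$Vw
    }
    ph <- an$phases
    for (nm in c("a", "b", "c")) {
      v <- ph$ea_mmhg_ml[ph$landmark == nm]
      if (length(v) == 1) out[[paste0("ea_", nm)]] <- v
    }
    if (!is.null(an$bilinear)) {
      k <- an$bilinear$split_index
      out$ea_b_single <- an$indices$ea_mmhg_ml[k]
      if (k > 1) out$ea_b_prev <- an$indices$ea_mmhg_ml[k - 1]
    }
    tr <- rec$truth
    out$v0_true_end <- tr$v0_eff_ml[nrow(tr)]
    out$ea_true_end <- tr$ea_mmhg_ml[nrow(tr) - 1]
    out
  }, error = function(e) {
    out <- empty
    out$error <- conditionMessage(e)
    out
  })
}

cohort_long <- function(runs) {
  pick <- function(ft, ees, v0, r2) {
    ok <- runs$ok & is.finite(runs[[ees]])
    data.frame(animal = runs$animal[ok], kind = runs$kind[ok],
               rep = runs$rep[ok], fit_type = ft,
               Ees = runs[[ees]][ok], V0 = runs[[v0]][ok],
               r2 = runs[[r2]][ok], stringsAsFactors = FALSE)
  }
  rbind(pick("lin", "ees_lin", "v0_lin", "r2_lin"),
        pick("bilin1", "ees_b1", "v0_b1", "r2_b1"),
        pick("bilin2", "ees_b2", "v0_b2", "r2_b2"))
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf("<pv_cohort> %d animals x 3 protocols x %d repeats: %d/%d runs ok\n",
              x$config$n_animals, x$config$repeats, sum(x$runs$ok),
              nrow(x$runs)))
  invisible(x)
}

#' Mean and SD of Ees and r2 by intervention and fit type
#'
#' @param cohort a `pv_cohort`.
#' @return data frame with `kind`, `fit_type`, `ees_mean`, `ees_sd`,
#'   `r2_mean`, `r2_sd`, `n`.
#' @export
aggregate_fit_table <- function(cohort) {
  rows <- cohort$rows
  agg <- do.call(rbind, lapply(split(rows, list(rows$kind, rows$fit_type),
                                     drop = TRUE), function(g) {
    data.frame(kind = g$kind[1], fit_type = g$fit_type[1],
               ees_mean = mean(g$Ees), ees_sd = stats::sd(g$Ees),
               r2_mean = mean(g$r2), r2_sd = stats::sd(g$r2),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$kind, agg$fit_type), ]
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return list `r`, `p` (two-sided, t distribution with n - 2 df),
#'   `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Afterload dependence of the ESPVR volume intercept
#'
#' Correlates the per-run effective arterial elastance at the phase
#' landmarks against the bilinear-fit slopes and volume intercepts of
#' the afterload runs, and fits the pooled line V0 (second phase)
#' versus Ea (end of the window). Under the shortening-deactivation
#' mechanism the V0-Ea correlations are negative while the Ees-Ea
#' correlations are near zero; the pooled line estimates the generating
#' V0 = a Ea + b law.
#'
#' @param cohort a `pv_cohort`.
#' @param ea_landmark which Ea enters the pooled line: a phase landmark
#'   (`"a"`, `"b"`, `"c"`, neighbor-averaged as in [phase_table()]) or
#'   `"b_lock"`, the single-beat Ea of the breakpoint beat itself -
#'   the afterload level that set the deactivation state (default).
#' @param v0_phase which phase's V0 enters the pooled line (default
#'   `"b2"`, the second phase).
#' @param average_by `"animal"` (default) averages the per-run values
#'   over each animal's repeats before pooling, mirroring the use of
#'   per-animal means in the correlation analysis; `"run"` pools raw
#'   runs.
#' @param v0_estimator how the second-phase volume intercept entering
#'   the pooled line is obtained. `"fixed_slope"` (default) reads V0
#'   off the phase-2 end-systolic centroid using the same animal's
#'   preload-run Ees as the fixed slope - the model's own premise that
#'   the second phase shares the preload slope - which avoids
#'   extrapolating a short noisy segment to the volume axis.
#'   `"bilinear"` uses the free bilinear fit's intercept.
#' @return list of class `pv_v0ea`: `correlations` (data frame `ea_at`,
#'   `target`, `r`, `p`, `n`), `line` (list `slope`, `intercept`, `r2`,
#'   `n`), `pairs` (data frame of the pooled Ea/V0 pairs).
#' @export
v0_ea_analysis <- function(cohort, ea_landmark = "b_lock", v0_phase = "b2",
                           average_by = c("animal", "run"),
                           v0_estimator = c("fixed_slope", "bilinear")) {
  average_by <- match.arg(average_by)
  v0_estimator <- match.arg(v0_estimator)
  runs <- cohort$runs
  pl <- runs[runs$ok & runs$kind == "pload" & is.finite(runs$ees_b1), ]
  if (v0_estimator == "fixed_slope") {
    vl <- runs[runs$ok & runs$kind == "vload_normal", ]
    ees_ref <- tapply(vl$ees_lin, vl$animal, mean, na.rm = TRUE)
    ref <- ees_ref[as.character(pl$animal)]
    pl$v0_fixed <- pl$ves_b2_mean - pl$pes_b2_mean / ref
  }
  if (nrow(pl) < 3) {
    stop("need at least 3 successful afterload runs with bilinear fits",
         call. = FALSE)
  }
  if (average_by == "animal") {
    # median over repeats: robust to an occasional misplaced split
    num <- c("ees_b1", "ees_b2", "v0_b1", "v0_b2", "ea_a", "ea_b",
             "ea_c", "ea_b_prev", "ea_b_single")
    if (v0_estimator == "fixed_slope") num <- c(num, "v0_fixed")
    pl <- do.call(rbind, lapply(split(pl, pl$animal), function(g) {
      out <- g[1, , drop = FALSE]
      for (nm in num) out[[nm]] <- stats::median(g[[nm]], na.rm = TRUE)
      out
    }))
  }
  targets <- c("ees_b1", "ees_b2", "v0_b1", "v0_b2")
  eas <- c(a = "ea_a", b = "ea_b", c = "ea_c")
  cors <- do.call(rbind, lapply(names(eas), function(lm) {
    do.call(rbind, lapply(targets, function(tg) {
      pr <- tryCatch(pearson(pl[[eas[[lm]]]], pl[[tg]]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = 0L))
      data.frame(ea_at = lm, target = tg, r = pr$r, p = pr$p, n = pr$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  ea <- if (ea_landmark == "b_lock") pl$ea_b_single else
    pl[[paste0("ea_", ea_landmark)]]
  v0 <- if (v0_estimator == "fixed_slope") pl$v0_fixed else
    pl[[paste0("v0_", sub("^b", "b", v0_phase))]]
  ok <- is.finite(ea) & is.finite(v0)
  f <- ols_line(ea[ok], v0[ok])
  structure(list(correlations = cors,
                 line = list(slope = f$m, intercept = f$b, r2 = f$r2,
                             n = f$n),
                 pairs = data.frame(ea = ea[ok], v0 = v0[ok])),
            class = "pv_v0ea")
}

#' @export
print.pv_v0ea <- function(x, ...) {
  cat(sprintf("<pv_v0ea> pooled line: V0 = %.2f Ea + %.2f (r2 = %.3f, n = %d)\n",
              x$line$slope, x$line$intercept, x$line$r2, x$line$n))
  invisible(x)
}
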