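# Shared fixtures. Recordings are built once per test run and cached;
# everything is generated in code, nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

zero_noise <- c(lvp = 0, lvv_raw = 0, aop = 0, aoflow = 0, ecg = 0)

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# noiseless preload run, SDA off, known Ees/V0
rec_vload_clean <- function() {
  fixture("vload_clean", function() {
    cfg <- sim_config(Ees_true = 1.2, V0_base = 10, sda_enabled = FALSE,
                      noise_sd = zero_noise)
    simulate_run(cfg, make_protocol("vload_normal", cfg))
  })
}

# noiseless afterload run, SDA on
rec_pload_sda <- function() {
  fixture("pload_sda", function() {
    cfg <- sim_config(sda_enabled = TRUE, noise_sd = zero_noise)
    simulate_run(cfg, make_protocol("pload", cfg))
  })
}

# noisy preload run at default measurement noise
rec_vload_noisy <- function() {
  fixture("vload_noisy", function() {
    cfg <- sim_config(seed = 101L)
    distort_and_noise(simulate_run(cfg, make_protocol("vload_normal", cfg)))
  })
}

analysis_vload_clean <- function() {
  fixture("an_vload_clean", function() analyze_run(rec_vload_clean()))
}

analysis_pload_sda <- function() {
  fixture("an_pload_sda", function() analyze_run(rec_pload_sda()))
}

# independent OLS oracle via stats::lm
lm_line <- function(x, y) {
  f <- stats::lm(y ~ x)
  list(m = unname(coef(f)[2]), b = unname(coef(f)[1]),
       r2 = summary(f)$r.squared)
}

# brute-force bilinear split oracle: enumerate all admissible splits
# with lm fits, pick max geometric-mean r2, earliest on ties
bilinear_oracle <- function(ves, pes, min_seg = 3) {
  n <- length(ves)
  best_k <- NA_integer_
  best_gm <- -Inf
  for (k in min_seg:(n - min_seg)) {
    x1 <- ves[1:k]; x2 <- ves[(k + 1):n]
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) next
    f1 <- lm_line(x1, pes[1:k])
    f2 <- lm_line(x2, pes[(k + 1):n])
    gm <- sqrt(max(0, f1$r2) * max(0, f2$r2))
    if (gm > best_gm) {
      best_gm <- gm
      best_k <- k
    }
  }
  list(split = best_k, gm_r2 = best_gm)
}

# minimal synthetic beat for constructed-case tests
make_beat <- function(lvp, lvv, fs = 1000, idx = 1L, t0 = 0) {
  structure(list(beat_idx = idx, start = 1L, end = length(lvp) + 1L,
                 t0_s = t0, rr_s = length(lvp) / fs, fs = fs,
                 lvp = lvp, lvv_raw = lvv, aoflow = rep(0, length(lvp)),
                 lvv = lvv),
            class = "pv_beat")
}
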