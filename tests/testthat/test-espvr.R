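espoints <- function(ves, pes) data.frame(ves_ml = ves, pes_mmhg = pes)

test_that("linear ESPVR fit matches exact and oracle cases", {
  # exact line P = V - 50
  f <- fit_linear_espvr(espoints(c(60, 80, 100), c(10, 30, 50)))
  expect_equal(f$Ees, 1)
  expect_equal(f$V0, 50)
  expect_equal(f$r2, 1)

  # three collinear points, slope 2
  f2 <- fit_linear_espvr(espoints(c(10, 20, 30), c(5, 25, 45)))
  expect_equal(f2$Ees, 2)
  expect_equal(f2$r2, 1)

  # noisy points against the stats::lm oracle
  set.seed(31)
  v <- runif(50, 40, 120)
  p <- 1.5 * (v - 20) + rnorm(50, 0, 2)
  f3 <- fit_linear_espvr(espoints(v, p))
  o <- lm_line(v, p)
  expect_equal(f3$Ees, o$m, tolerance = 1e-10)
  expect_equal(-f3$V0 * f3$Ees, o$b, tolerance = 1e-10)
  expect_equal(f3$r2, o$r2, tolerance = 1e-10)

  expect_error(fit_linear_espvr(espoints(c(50, 50, 50), c(1, 2, 3))),
               "vertical")
  # non-positive slope: flagged, not raised
  f4 <- fit_linear_espvr(espoints(c(10, 20, 30), c(30, 20, 10)))
  expect_true(f4$nonphysiological)
})

test_that("bilinear fit recovers constructed two-line data exactly", {
  # two lines with slopes 3.3 and 1.5 crossing between the segments
  v1 <- seq(62, 70, length.out = 5)
  v2 <- seq(72, 88, length.out = 5)
  pts <- espoints(c(v1, v2), c(3.3 * (v1 - 60), 1.5 * (v2 - 46.8)))
  f <- fit_bilinear_espvr(pts)
  expect_equal(f$split_index, 5)
  expect_equal(f$phase1$Ees, 3.3)
  expect_equal(f$phase2$Ees, 1.5)
  expect_equal(f$phase1$r2, 1)
  expect_equal(f$phase2$r2, 1)
  expect_equal(f$gm_r2, 1)
  # breakpoint between the segments
  expect_gt(f$breakpoint$V, max(v1) - 1e-9)
  expect_lt(f$breakpoint$V, min(v2) + 1e-9)
})

test_that("one-line data ties resolve to the earliest split with equal slopes", {
  v <- seq(50, 95, length.out = 10)
  pts <- espoints(v, 2 * (v - 30))
  f <- fit_bilinear_espvr(pts)
  expect_equal(f$split_index, 3)  # earliest admissible with min_seg = 3
  expect_equal(f$gm_r2, 1)
  expect_equal(f$phase1$Ees, 2)
  expect_equal(f$phase2$Ees, 2)
  expect_error(fit_bilinear_espvr(pts[1:5, ]), "at least 6")
})

test_that("bilinear split equals the brute-force enumeration oracle", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    k_true <- sample(3:(n - 3), 1)
    v <- sort(runif(n, 40, 120))
    p <- numeric(n)
    p[1:k_true] <- 3 * (v[1:k_true] - 30) + rnorm(k_true, 0, 4)
    p[(k_true + 1):n] <- 1.2 * (v[(k_true + 1):n] - 5) +
      rnorm(n - k_true, 0, 4)
    f <- fit_bilinear_espvr(espoints(v, p))
    o <- bilinear_oracle(v, p)
    expect_equal(f$split_index, o$split)
    expect_equal(f$gm_r2, o$gm_r2, tolerance = 1e-10)
  }
})

test_that("line intersection algebra and parallel fallback", {
  bp <- intersection(c(2, -100), c(1, -20))
  expect_equal(bp$V, 80)
  expect_equal(bp$P, 60)
  expect_false(bp$parallel)

  same <- intersection(c(1.5, -10), c(1.5, -10))
  expect_true(same$parallel)

  # two parallel segments: fit falls back to the midpoint, flagged
  v <- seq(50, 95, length.out = 10)
  p <- 2 * (v - 30)
  p[6:10] <- p[6:10] + 15  # same slope, offset intercept
  f <- fit_bilinear_espvr(espoints(v, p))
  expect_true(f$breakpoint$parallel)
  expect_true(is.finite(f$breakpoint$V))
})

test_that("PRSW regression matches definitions and the lm oracle", {
  f <- fit_prsw(c(80, 100, 120), c(2000, 4000, 6000))
  expect_equal(f$Mw, 100)
  expect_equal(f$Vw, 60)
  expect_equal(f$r2, 1)
  expect_false(f$not_meaningful)

  set.seed(13)
  ved <- runif(30, 80, 130)
  sw <- 90 * (ved - 55) + rnorm(30, 0, 150)
  f2 <- fit_prsw(ved, sw)
  o <- lm_line(ved, sw)
  expect_equal(f2$Mw, o$m, tolerance = 1e-10)
  expect_equal(-f2$Vw * f2$Mw, o$b, tolerance = 1e-10)

  expect_error(fit_prsw(c(100, 100, 100), c(1, 2, 3)), "variation")
  # near-horizontal relation flagged, not raised
  flat <- fit_prsw(c(80, 100, 120), c(3000, 3010, 2990))
  expect_true(flat$not_meaningful)
})

test_that("afterload-run PRSW is flagged not meaningful", {
  an <- analysis_pload_sda()
  expect_false(is.null(an$prsw))
  expect_true(an$prsw$not_meaningful || an$prsw$Mw < 50)
})

test_that("phase landmarks index the window beats", {
  v1 <- seq(62, 70, length.out = 5)
  v2 <- seq(72, 88, length.out = 5)
  pts <- espoints(c(v1, v2), c(3.3 * (v1 - 60), 1.5 * (v2 - 46.8)))
  f <- fit_bilinear_espvr(pts)
  lm10 <- classify_phases(f, 10)
  expect_equal(unname(lm10), c(1L, 5L, 10L))
  lin_only <- classify_phases(NULL, 8)
  expect_equal(unname(lin_only[c("a", "c")]), c(1L, 8L))
  expect_true(is.na(lin_only[["b"]]))
})

test_that("expected r2 never rises with added noise", {
  v <- seq(40, 100, length.out = 20)
  mean_r2 <- vapply(c(0, 2, 6), function(sd) {
    mean(vapply(1:20, function(s) {
      set.seed(1000 + s)
      fit_linear_espvr(espoints(v, 1.5 * (v - 20) +
                                  rnorm(20, 0, sd)))$r2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) <= 0))
})

test_that("preload pipeline recovers Ees within 5% at default noise", {
  an <- analyze_run(rec_vload_noisy())
  expect_lt(abs(an$linear$Ees - 1.2) / 1.2, 0.05)
})
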