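# independent term-by-term evaluation of the population AIF, used as the
# oracle for frozen values
parker_oracle <- function(t_min) {
  g1 <- 0.809 / (0.0563 * sqrt(2 * pi)) * exp(-(t_min - 0.170)^2 / (2 * 0.0563^2))
  g2 <- 0.330 / (0.132 * sqrt(2 * pi)) * exp(-(t_min - 0.365)^2 / (2 * 0.132^2))
  g1 + g2 + 1.050 * exp(-0.1682 * t_min) / (1 + exp(-38.078 * (t_min - 0.483)))
}

test_that("population AIF matches term-by-term evaluation and its limits", {
  pa <- parker_aif(seq(0, 3600, by = 1))
  # bolus arrival value (frozen from the oracle: 0.08184992 mM)
  expect_equal(pa$curve$conc[1], 0.08184992, tolerance = 1e-7)
  expect_equal(pa$curve$conc[1], parker_oracle(0), tolerance = 1e-12)
  # washout tail at 10 min: alpha e^(-10 beta), Gaussians negligible
  expect_equal(pa$curve$conc[601], 1.050 * exp(-0.1682 * 10),
               tolerance = 1e-4)
  expect_equal(pa$curve$conc[601], parker_oracle(10), tolerance = 1e-12)
  # decayed below 1e-4 mM by 60 min
  expect_lt(pa$curve$conc[3601], 1e-4)
  # dense-grid argmax sits near the first Gaussian centre (0.170 min)
  expect_true(find_peak(pa$curve) >= 9 && find_peak(pa$curve) <= 13)
  expect_error(parker_aif(c(-5, 0, 5)), "non-negative")
})

test_that("the literal-exponent variant is exposed and differs mid-curve", {
  t <- seq(0, 300, 1)
  mult <- parker_aif(t)$curve$conc
  lit <- parker_aif(t, form = "literal")$curve$conc
  # before the sigmoid centre the two washout terms differ by ~alpha
  expect_gt(max(abs(mult - lit)), 0.5)
  # deep in washout the sigmoid saturates and the forms coincide
  deep_m <- parker_aif(c(0, 600), form = "multiplicative")$curve$conc[2]
  deep_l <- parker_aif(c(0, 600), form = "literal")$curve$conc[2]
  expect_equal(deep_m, deep_l, tolerance = 1e-6)
})

test_that("AIF evaluation is grid-refinement stable", {
  coarse <- parker_aif(seq(0, 300, by = 1))$curve
  fine <- parker_aif(seq(0, 300, by = 0.5))$curve
  shared <- match(coarse$times, fine$times)
  expect_lt(max(abs(coarse$conc - fine$conc[shared])), 1e-3)
})

test_that("peak finding honours the tie rule and smoothing window", {
  t <- seq(0, 45, 5)
  v <- c(0, 1, 2, 5, 5, 5, 2, 1, 0, 0)
  expect_equal(find_peak(concentration_curve(t, v, "blood")), 15)  # earliest
  v2 <- c(0, 0, 1, 8, 3, 1, 0, 0, 0, 0)
  expect_equal(find_peak(concentration_curve(t, v2, "blood")), 15)
  expect_error(find_peak(concentration_curve(t, rep(2, 10), "blood")),
               "constant")
  expect_error(find_peak(concentration_curve(t[1:4], v2[1:4], "blood")),
               "5 frames")
})

test_that("peak alignment recovers constructed shifts", {
  paif <- parker_aif(seq(0, 420, 1))
  # identity: aligning to an image-tagged copy leaves the curve unchanged
  copy <- aif(concentration_curve(paif$curve$times, paif$curve$conc,
                                  "blood"), source = "image")
  al0 <- align_paif_to_iaif(paif, copy, iaif_smooth_window = 1L)
  expect_equal(attr(al0, "shift_s"), 0)
  expect_equal(al0$curve$conc, paif$curve$conc)
  # pure 25-s delay on the acquisition grid
  t5 <- seq(0, 415, 5)
  del <- stats::approx(paif$curve$times + 25, paif$curve$conc, xout = t5,
                       rule = 2)$y
  del[t5 < 25] <- 0
  iaif <- aif(concentration_curve(t5, del, "blood"), source = "image")
  al <- align_paif_to_iaif(paif, iaif)
  expect_lte(abs(attr(al, "shift_s") - 25), 1)  # within one pAIF grid step
  # alignment never rescales: max is preserved exactly
  expect_identical(max(al$curve$conc), max(paif$curve$conc))
})

test_that("alignment survives 40% peak clipping plus noise", {
  paif <- parker_aif(seq(0, 420, 1))
  t5 <- seq(0, 415, 5)
  del <- stats::approx(paif$curve$times + 25, paif$curve$conc, xout = t5,
                       rule = 2)$y
  del[t5 < 25] <- 0
  set.seed(99)
  noisy <- pmax(0, pmin(del, 0.6 * max(del)) + rnorm(length(t5), 0, 0.05))
  iaif <- aif(concentration_curve(t5, noisy, "blood"), source = "image")
  al <- align_paif_to_iaif(paif, iaif)
  expect_lte(abs(attr(al, "shift_s") - 25), 5)  # within one iAIF frame
})

test_that("shift composition: delays add within one grid step", {
  paif <- parker_aif(seq(0, 420, 1))
  t5 <- seq(0, 415, 5)
  mkdel <- function(d) {
    y <- stats::approx(paif$curve$times + d, paif$curve$conc, xout = t5,
                       rule = 2)$y
    y[t5 < d] <- 0
    aif(concentration_curve(t5, y, "blood"), source = "image")
  }
  s1 <- attr(align_paif_to_iaif(paif, mkdel(15)), "shift_s")
  s2 <- attr(align_paif_to_iaif(paif, mkdel(15 + 20)), "shift_s")
  expect_lte(abs((s2 - s1) - 20), 1)
})
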