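test_that("impulse retention: R(0) = 1, vascular reduction, decay", {
  t <- seq(0, 600, 1)
  for (p in list(kidney_model_params(230, 0.15, 8, 120),
                 kidney_model_params(100, 0.4, 20, 50),
                 kidney_model_params(500, 0.05, 3, 300))) {
    r <- impulse_retention(t, p)
    expect_equal(r[1], 1)
    expect_true(all(r >= 0))
    expect_lt(r[length(r)], 0.05)
  }
  # FF -> 0 limit is the bare plasma exponential
  p0 <- kidney_model_params(230, 1e-12, 8, 120)
  expect_equal(impulse_retention(t, p0), exp(-t / 8), tolerance = 1e-9)
  expect_error(impulse_retention(-1:5, kidney_model_params(230, .15, 8, 120)),
               "non-negative")
})

test_that("tubular pathway equals adaptive quadrature of the convolution", {
  # R(t) - exp(-t/Tp) must equal FF * (1/Tp) e^(-u/Tp) (*) e^(-t/Tt)
  Tp <- 10; Tt <- 100; FF <- 0.2
  p <- kidney_model_params(230, FF, Tp, Tt)
  for (t in c(5, 30, 60, 200)) {
    quad <- stats::integrate(function(u) (1 / Tp) * exp(-u / Tp) *
                               exp(-(t - u) / Tt), 0, t,
                             rel.tol = 1e-12)$value
    closed <- impulse_retention(c(0, t), p)[2] - exp(-t / Tp)
    expect_equal(closed, FF * quad, tolerance = 1e-6)
  }
})

test_that("retention is continuous through the equal-transit-time limit", {
  t <- seq(0, 300, 1)
  base <- impulse_retention(t, kidney_model_params(230, 0.2, 50, 50))
  for (eps in c(1e-4, 1e-6)) {
    near <- impulse_retention(t, kidney_model_params(230, 0.2, 50,
                                                     50 * (1 + eps)))
    expect_lt(max(abs(near - base)), 10 * eps + 1e-9)
  }
})

test_that("forward model is linear and matches the zero-input case", {
  pa <- parker_aif(seq(0, 300, 1))
  p <- kidney_model_params(230, 0.2, 8, 120)
  geom <- kidney_geometry(150)
  st <- seq(0, 295, 5)
  ct <- forward_model(pa, p, geom, st)
  # zero AIF gives zero tissue concentration
  zero <- aif(concentration_curve(0:300, rep(0, 301), "blood"),
              source = "population")
  expect_equal(forward_model(zero, p, geom, st)$conc, rep(0, 60))
  # linearity in RPF
  p2 <- kidney_model_params(460, 0.2, 8, 120)
  expect_equal(forward_model(pa, p2, geom, st)$conc, 2 * ct$conc,
               tolerance = 1e-12)
  # linearity in the input concentration
  pa2 <- aif(concentration_curve(pa$curve$times, 3 * pa$curve$conc,
                                 "blood"), source = "population")
  expect_equal(forward_model(pa2, p, geom, st)$conc, 3 * ct$conc,
               tolerance = 1e-12)
  expect_error(forward_model(pa, p, geom, seq(0, 400, 5)), "span")
})

test_that("constant input with FF = 0 reaches the analytic steady state", {
  cst <- 2.0; Tp <- 8
  tt <- seq(0, 2000, 0.25)  # fine grid: quadrature error ~ h^2/(12 Tp^2)
  ca <- aif(concentration_curve(tt, rep(cst, length(tt)), "blood"),
            source = "population")
  p <- kidney_model_params(230, 1e-9, Tp, 120)
  geom <- kidney_geometry(150)
  got <- forward_model(ca, p, geom, 2000)$conc
  want <- (230 * Tp / 60) * cst / ((1 - 0.4) * 150)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("FFT convolution equals a brute-force double loop", {
  pa <- parker_aif(seq(0, 300, 1))
  p <- kidney_model_params(230, 0.2, 8, 120)
  geom <- kidney_geometry(150)
  st <- seq(0, 300, 5)
  got <- forward_model(pa, p, geom, st)$conc
  # oracle: explicit trapezoid over the convolution integral per time point
  ca <- pa$curve$conc; tt <- pa$curve$times
  r <- impulse_retention(tt, p)
  oracle <- sapply(st, function(t) {
    k <- which(tt == t)
    f <- ca[1:k] * r[k:1]
    s <- if (k == 1) 0 else sum(f) - 0.5 * (f[1] + f[k])
    230 / ((1 - 0.4) * 150) * s * (1 / 60)
  })
  expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 1e-3)
  expect_lt(max(abs(got - oracle)), 1e-9)  # same quadrature, tighter still
})

test_that("halving the convolution grid changes samples by < 0.5%", {
  p <- kidney_model_params(230, 0.2, 8, 120)
  geom <- kidney_geometry(150)
  st <- seq(5, 295, 5)
  c1 <- forward_model(parker_aif(seq(0, 300, 1)), p, geom, st)$conc
  c2 <- forward_model(parker_aif(seq(0, 300, 0.5)), p, geom, st)$conc
  expect_lt(max(abs(c1 - c2) / max(abs(c2))), 0.005)
})

test_that("tracer mass in the kidney is bounded by delivered tracer", {
  pa <- parker_aif(seq(0, 600, 1))
  geom <- kidney_geometry(150)
  st <- seq(0, 600, 5)
  set.seed(21)
  for (i in 1:5) {
    p <- random_truth()
    ct <- forward_model(pa, p, geom, st)$conc
    lhs <- sum(ct) * 5 * geom$Vt
    rhs <- p$RPF / (1 - geom$hematocrit) * sum(pa$curve$conc) * 1 *
      sum(impulse_retention(pa$curve$times, p)) * 1 / 60
    expect_lte(lhs, rhs * 1.001)
  }
})

test_that("eGFR arithmetic and BSA normalization", {
  expect_equal(egfr_from_params(kidney_model_params(230, 0.2, 8, 120)), 46)
  expect_equal(egfr_from_params(kidney_model_params(390.4, 0.1539, 8, 120)),
               60.08, tolerance = 1e-3)
  # cohort-mean habitus: BSA ~2.01 m^2, factor ~0.861
  body <- subject_body(1.72, 87.56)
  expect_equal(bsa_dubois(body), 2.007264, tolerance = 1e-5)
  expect_equal(normalize_egfr(100, body), 86.18699, tolerance = 1e-4)
  # BSA exactly 1.73 is the identity
  w173 <- (1.73 / (0.007184 * 170^0.725))^(1 / 0.425)
  expect_equal(normalize_egfr(50, subject_body(1.70, w173)), 50,
               tolerance = 1e-9)
  # heavier subject at fixed height normalizes lower
  expect_lt(normalize_egfr(100, subject_body(1.72, 2 * 87.56)),
            normalize_egfr(100, subject_body(1.72, 87.56)))
  expect_error(subject_body(-1, 80), "non-physiological")
})
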