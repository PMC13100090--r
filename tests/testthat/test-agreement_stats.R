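test_that("coefficient of variation from values and from summaries", {
  expect_equal(coefficient_of_variation(c(2, 2, 2, 2)), 0)
  x <- c(4, 8, 6, 2, 10)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  # published-summary mode reproduces cohort-table CV cells at 2 dp
  expect_equal(round(coefficient_of_variation(mean = 67.55, sd = 17.72), 2),
               0.26)
  expect_equal(round(coefficient_of_variation(mean = 390.4, sd = 255.9), 2),
               0.66)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("percentage Bland-Altman matches hand-computed arithmetic", {
  test <- c(10, 22, 28, 44, 52)
  ref <- c(12, 20, 30, 40, 50)
  pct <- 100 * (test - ref) / ref
  got <- bland_altman_percent(paired_measurements(test, ref))
  expect_equal(got$bias_pct, mean(pct))
  expect_equal(got$sd_pct, sd(pct))
  expect_equal(got$loa_low, mean(pct) - 1.96 * sd(pct))
  expect_equal(got$loa_high, mean(pct) + 1.96 * sd(pct))
  # identical methods agree perfectly
  same <- bland_altman_percent(paired_measurements(ref, ref))
  expect_equal(c(same$bias_pct, same$loa_low, same$loa_high), c(0, 0, 0))
  # proportional methods: bias 100(c-1), sd exactly 0
  prop <- bland_altman_percent(paired_measurements(1.2 * ref, ref))
  expect_equal(prop$bias_pct, 20, tolerance = 1e-12)
  expect_equal(prop$sd_pct, 0, tolerance = 1e-12)
  # pair-mean denominator variant
  pm <- bland_altman_percent(paired_measurements(test, ref), "pairmean")
  expect_equal(pm$diffs_pct, 100 * (test - ref) / ((test + ref) / 2))
  expect_error(bland_altman_percent(paired_measurements(test, c(0, ref[-1]))),
               "zero denominator")
})

test_that("limits of agreement identity reproduces bias +/- 1.96 SD", {
  got <- limits_of_agreement(-11.98, 21.63)
  expect_equal(got$loa_low, -54.3748)
  expect_equal(got$loa_high, 30.4148)
})

test_that("Pearson r, p and Fisher CI agree with cor.test", {
  x <- c(1, 2, 3, 4, 5, 6, 8, 9)
  expect_equal(pearson_with_ci(paired_measurements(2 * x + 1, x))$r, 1)
  expect_equal(pearson_with_ci(paired_measurements(-x, x))$r, -1)
  set.seed(31)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20, 0, 0.8)
  got <- pearson_with_ci(paired_measurements(a, b))
  oracle <- cor.test(a, b)
  expect_equal(got$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-10)
  expect_equal(got$ci95, as.numeric(oracle$conf.int), tolerance = 1e-3)
  expect_error(pearson_with_ci(paired_measurements(rep(1, 5), 1:5)),
               "variance")
})

test_that("Fisher CI covers the true correlation at ~95%", {
  set.seed(77)
  rho <- 0.6
  hits <- 0
  for (i in 1:100) {
    z <- rnorm(20)
    x <- z
    y <- rho * z + sqrt(1 - rho^2) * rnorm(20)
    ci <- pearson_with_ci(paired_measurements(x, y))$ci95
    if (rho >= ci[1] && rho <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("ICC(A,1) matches a from-scratch two-way ANOVA oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 10; k <- 2 + (rep %% 2)
    truth <- rnorm(n, 50, 15)
    ratings <- sapply(seq_len(k), function(j) truth + rnorm(n, j, 4))
    got <- icc_a1(ratings)
    # oracle: explicit sums of squares
    grand <- mean(ratings)
    rm_ <- rowMeans(ratings); cm_ <- colMeans(ratings)
    msr <- k * sum((rm_ - grand)^2) / (n - 1)
    msc <- n * sum((cm_ - grand)^2) / (k - 1)
    mse <- sum((ratings - outer(rm_, rep(1, k)) -
                  outer(rep(1, n), cm_) + grand)^2) / ((n - 1) * (k - 1))
    want <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    expect_lt(abs(got$icc - want), 1e-10)
    expect_true(got$ci95[1] <= got$icc && got$icc <= got$ci95[2])
  }
})

test_that("ICC is location invariant, scale invariant, and categorized", {
  set.seed(14)
  r <- sapply(1:2, function(j) rnorm(8, 40, 10) + rnorm(8, 0, 3))
  base <- icc_a1(r)$icc
  expect_equal(icc_a1(r + 100)$icc, base, tolerance = 1e-10)
  expect_equal(icc_a1(r * 3.7)$icc, base, tolerance = 1e-10)
  # identical columns: perfect absolute agreement
  ident <- cbind(1:6, 1:6)
  got <- icc_a1(ident)
  expect_equal(got$icc, 1)
  expect_equal(got$category, "excellent")
  expect_equal(icc_category(0.84), "good")
  expect_equal(icc_category(0.90), "good")
  expect_equal(icc_category(0.95), "excellent")
  expect_equal(icc_category(0.50), "moderate")
  expect_equal(icc_category(0.3), "poor")
  expect_error(icc_a1(matrix(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), ncol = 2)),
               "missing")
})

test_that("Mann-Whitney U: exact enumeration and identities", {
  # fully separated samples: U = 0, exact two-sided p = 2/choose(6,3)
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(got$U, 0)
  expect_equal(got$p_value, 0.1)
  # identical samples: U = n^2/2 by midranks, p ~ 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)
  expect_gte(same$p_value, 0.99)
  rev_sep <- mann_whitney_u(c(9, 10, 11), c(1, 2, 3), method = "exact")
  expect_equal(rev_sep$U, 9)  # n1 n2
})

test_that("Mann-Whitney normal approximation matches wilcox.test", {
  set.seed(17)
  x <- rnorm(15, 1); y <- rnorm(18)
  got <- mann_whitney_u(x, y, method = "normal")
  oracle <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$U, unname(oracle$statistic))
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-10)
  # with ties the midrank/tie-corrected path still matches
  xt <- round(x); yt <- round(y)
  got_t <- mann_whitney_u(xt, yt, method = "normal")
  oracle_t <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                           correct = TRUE))
  expect_equal(got_t$p_value, oracle_t$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney is invariant under monotone transforms", {
  set.seed(18)
  x <- rlnorm(8); y <- rlnorm(9, 0.5)
  base <- mann_whitney_u(x, y)
  for (f in list(log, sqrt, function(v) v^3)) {
    tr <- mann_whitney_u(f(x), f(y))
    expect_equal(tr$U, base$U)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("CKD-EPI 2021 reproduces reference arithmetic and monotonicity", {
  expect_equal(ckd_epi_2021(1.0, 60, "male"), 86.16262, tolerance = 1e-4)
  expect_equal(ckd_epi_2021(0.7, 40, "female"), 112.0543, tolerance = 1e-4)
  # at the knot Scr = kappa both power terms vanish
  expect_equal(ckd_epi_2021(0.9, 50, "male"), 142 * 0.9938^50)
  expect_equal(ckd_epi_2021(0.7, 50, "female"), 142 * 0.9938^50 * 1.012)
  # strictly decreasing in creatinine and age
  scr <- seq(0.4, 3, 0.1)
  expect_true(all(diff(ckd_epi_2021(scr, 60, "male")) < 0))
  expect_true(all(diff(sapply(30:80, function(a)
    ckd_epi_2021(1.1, a, "female"))) < 0))
  expect_error(ckd_epi_2021(-0.5, 60, "male"), "positive")
})
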