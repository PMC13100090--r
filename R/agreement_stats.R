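#' Coefficient of variation
#'
#' CV = sample SD (n - 1 denominator) / mean. Either pass the raw values,
#' or pass summary `mean` and `sd` directly (useful when only published
#' summary statistics are available).
#'
#' @param values Numeric vector (n >= 2), or `NULL` if summaries are given.
#' @param mean,sd Summary statistics, used when `values` is `NULL`.
#' @return The dimensionless CV.
#' @examples
#' coefficient_of_variation(mean = 67.55, sd = 17.72)  # 0.26 to 2 dp
#' @export
coefficient_of_variation <- function(values = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    if (length(values) < 2) stop("need n >= 2", call. = FALSE)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  } else if (is.null(mean) || is.null(sd)) {
    stop("give either values or both mean and sd", call. = FALSE)
  }
  if (mean == 0) stop("CV undefined for zero mean", call. = FALSE)
  sd / mean
}

#' Paired method measurements
#'
#' @param test,reference Equal-length numeric vectors (n >= 3), finite.
#' @param labels Character pair naming the two methods.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(test, reference,
                                labels = c("test", "reference")) {
  if (length(test) != length(reference) || length(test) < 3)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (!all(is.finite(test)) || !all(is.finite(reference)))
    stop("measurements must be finite", call. = FALSE)
  structure(list(test = as.numeric(test), reference = as.numeric(reference),
                 labels = labels),
            class = "paired_measurements")
}

#' Percentage Bland-Altman agreement
#'
#' Per-pair percentage difference 100 (test - ref) / denom, where the
#' denominator is the reference value (default) or the pair mean. Bias is
#' the mean percentage difference, and the 95% limits of agreement are
#' bias +/- 1.96 x sample SD.
#'
#' @param p A [paired_measurements()].
#' @param denom `"reference"` or `"pairmean"`.
#' @return List: `bias_pct`, `sd_pct`, `loa_low`, `loa_high`, `diffs_pct`.
#' @export
bland_altman_percent <- function(p, denom = c("reference", "pairmean")) {
  denom <- match.arg(denom)
  stopifnot(inherits(p, "paired_measurements"))
  d <- if (denom == "reference") p$reference else (p$test + p$reference) / 2
  if (any(d == 0))
    stop("zero denominator in pair(s): ",
         paste(which(d == 0), collapse = ", "), call. = FALSE)
  pct <- 100 * (p$test - p$reference) / d
  out <- limits_of_agreement(mean(pct), stats::sd(pct))
  out$diffs_pct <- pct
  out
}

#' Limits of agreement from a bias and SD
#'
#' @param bias_pct Mean percentage difference.
#' @param sd_pct Sample SD of the percentage differences.
#' @return List: `bias_pct`, `sd_pct`, `loa_low = bias - 1.96 sd`,
#'   `loa_high = bias + 1.96 sd`.
#' @export
limits_of_agreement <- function(bias_pct, sd_pct) {
  if (sd_pct < 0) stop("sd must be >= 0", call. = FALSE)
  list(bias_pct = bias_pct, sd_pct = sd_pct,
       loa_low = bias_pct - 1.96 * sd_pct,
       loa_high = bias_pct + 1.96 * sd_pct)
}

#' Pearson correlation with p-value and Fisher 95% CI
#'
#' r is the sample correlation; the two-sided p-value uses
#' t = r sqrt((n - 2)/(1 - r^2)) on n - 2 df; the confidence interval uses
#' the Fisher z transform with half-width 1.96/sqrt(n - 3).
#'
#' @param p A [paired_measurements()] with n >= 4.
#' @return List: `r`, `p_value`, `ci95` (length-2), `n`.
#' @export
pearson_with_ci <- function(p) {
  stopifnot(inherits(p, "paired_measurements"))
  n <- length(p$test)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(p$test) == 0 || stats::sd(p$reference) == 0)
    stop("zero variance on one side", call. = FALSE)
  r <- stats::cor(p$test, p$reference)
  if (abs(r) >= 1) {
    pv <- 0
    ci <- c(r, r)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  }
  list(r = r, p_value = pv, ci95 = ci, n = n)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, absolute agreement, single measurement:
#' ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k/n)(MSC - MSE)),
#' from the two-way ANOVA mean squares for rows/subjects (MSR),
#' columns/raters (MSC) and error (MSE). The p-value tests ICC = 0 via
#' F = MSR/MSE on (n - 1, (n - 1)(k - 1)) df; the CI uses the
#' McGraw-Wong F bounds with Satterthwaite df. Categories: poor < 0.50,
#' moderate 0.50-0.75, good 0.75-0.90, excellent > 0.90.
#'
#' @param ratings n_subjects x k_raters numeric matrix, no missing cells,
#'   n >= 5, k >= 2.
#' @param conf_level Confidence level, default 0.95.
#' @return List: `icc`, `p_value`, `ci95`, `category`, mean squares.
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("need n >= 5 subjects and k >= 2 raters",
                           call. = FALSE)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse == 0) # perfect agreement: the F bounds degenerate
    return(list(icc = 1, p_value = 0, ci95 = c(1, 1),
                category = "excellent", msr = msr, msc = msc, mse = mse))
  fstat <- msr / mse
  p_value <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc)); b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, p_value = p_value, ci95 = c(lower, upper),
       category = icc_category(icc), msr = msr, msc = msc, mse = mse)
}

#' @rdname icc_a1
#' @param icc An ICC value.
#' @export
icc_category <- function(icc) {
  if (icc > 0.90) "excellent"
  else if (icc >= 0.75) "good"
  else if (icc >= 0.50) "moderate"
  else "poor"
}

#' Mann-Whitney U test
#'
#' U from pooled midranks; the two-sided p-value uses the normal
#' approximation with tie correction and continuity correction
#' (`method = "normal"`), or full enumeration of all group assignments
#' (`method = "exact"`, available for min(n) <= 10 and no practical limit
#' on ties). `"auto"` picks exact when both groups have n <= 10.
#'
#' @param x,y Numeric samples, each n >= 3.
#' @param method `"auto"`, `"normal"` or `"exact"`.
#' @return List: `U` (for the first sample), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3 || n2 < 3) stop("each sample needs n >= 3", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") method <- if (max(n1, n2) <= 10) "exact" else "normal"
  if (method == "exact") {
    if (max(n1, n2) > 10)
      stop("exact enumeration limited to n <= 10 per group", call. = FALSE)
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= U + eps), mean(us >= U - eps))
    p <- min(1, p)
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) { # all values tied
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p_value = p, method = method)
}

#' Serum eGFR by the CKD-EPI 2021 creatinine equation
#'
#' eGFR = 142 min(Scr/kappa, 1)^a max(Scr/kappa, 1)^(-1.200)
#' 0.9938^age x 1.012 (if female), with kappa = 0.7 (female) / 0.9 (male)
#' and a = -0.241 (female) / -0.302 (male). No race term.
#'
#' @param serum_creatinine Serum creatinine, mg/dL, > 0. Vectorized.
#' @param age Age in years, > 0.
#' @param sex `"male"` or `"female"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckd_epi_2021(1.0, 60, "male")    # ~86.2
#' ckd_epi_2021(0.7, 40, "female")  # ~112.1
#' @export
ckd_epi_2021 <- function(serum_creatinine, age, sex) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  if (any(serum_creatinine <= 0)) stop("creatinine must be positive",
                                       call. = FALSE)
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  kappa <- if (sex == "female") 0.7 else 0.9
  a <- if (sex == "female") -0.241 else -0.302
  sexf <- if (sex == "female") 1.012 else 1
  142 * pmin(serum_creatinine / kappa, 1)^a *
    pmax(serum_creatinine / kappa, 1)^(-1.200) * 0.9938^age * sexf
}

#' Clinical record for serum eGFR
#'
#' @param serum_creatinine mg/dL, > 0.
#' @param age Years, > 0.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `subject_clinical`.
#' @export
subject_clinical <- function(serum_creatinine, age, sex) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  if (serum_creatinine <= 0 || age <= 0)
    stop("creatinine and age must be positive", call. = FALSE)
  structure(list(serum_creatinine = serum_creatinine, age = age, sex = sex),
            class = "subject_clinical")
}
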