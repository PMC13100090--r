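#' Parker population arterial input function parameters
#'
#' The ten printed parameters of the population AIF: two Gaussian
#' first-pass kernels plus a sigmoid-modulated exponential washout. All
#' times are in minutes; amplitudes in mM (Gaussian scales in mM min).
#' `alpha`, `beta`, `s` and `tau` are the exponential amplitude (mM), decay
#' constant (1/min), sigmoid width (1/min) and sigmoid centre (min) — these
#' are the AIF's own symbols, unrelated to the imaging flip angle.
#'
#' @param A1,A2 Gaussian scales, mM min.
#' @param sigma1,sigma2 Gaussian widths, min.
#' @param T1g,T2g Gaussian centres, min.
#' @param alpha Exponential amplitude, mM.
#' @param beta Exponential decay constant, 1/min.
#' @param s Sigmoid width, 1/min.
#' @param tau Sigmoid centre, min.
#' @return An object of class `parker_params`.
#' @export
parker_params <- function(A1 = 0.809, A2 = 0.330, sigma1 = 0.0563,
                          sigma2 = 0.132, T1g = 0.170, T2g = 0.365,
                          alpha = 1.050, beta = 0.1682, s = 38.078,
                          tau = 0.483) {
  p <- list(A1 = A1, A2 = A2, sigma1 = sigma1, sigma2 = sigma2,
            T1g = T1g, T2g = T2g, alpha = alpha, beta = beta, s = s,
            tau = tau)
  if (any(unlist(p) <= 0))
    stop("all Parker parameters must be strictly positive", call. = FALSE)
  structure(p, class = "parker_params")
}

#' Arterial input function container
#'
#' Wraps a blood concentration curve and records whether it is the
#' population functional form (on its own fine uniform grid, default 1 s)
#' or image-derived from an aortic ROI (on the acquisition grid).
#'
#' @param curve A blood [concentration_curve()].
#' @param source `"population"` or `"image"`.
#' @param grid_step Grid step in seconds (population AIFs must be on a
#'   uniform grid at this step).
#' @return An object of class `aif`.
#' @export
aif <- function(curve, source = c("population", "image"), grid_step = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(curve, "concentration_curve"))
  if (curve$tissue_class != "blood")
    stop("an AIF must be a blood concentration curve", call. = FALSE)
  if (source == "population") {
    steps <- diff(curve$times)
    if (is.null(grid_step)) grid_step <- steps[1]
    if (any(abs(steps - grid_step) > 1e-9))
      stop("population AIF must be on a uniform grid", call. = FALSE)
    if (any(curve$conc < 0))
      stop("population AIF concentrations must be >= 0", call. = FALSE)
  } else if (is.null(grid_step)) {
    grid_step <- stats::median(diff(curve$times))
  }
  structure(list(curve = curve, source = source,
                 grid_step = as.numeric(grid_step)),
            class = "aif")
}

#' Evaluate the Parker population AIF
#'
#' C_A(t) = sum_n A_n/(sigma_n sqrt(2 pi)) exp(-(t - T_n)^2 / (2 sigma_n^2))
#' + alpha exp(-beta t) / (1 + exp(-s (t - tau))), with t in minutes and
#' t = 0 the bolus arrival. The washout term is implemented in this
#' multiplicative form — an exponential modulated by a sigmoid;
#' `form = "literal"` evaluates the variant with the sigmoid denominator
#' inside the exponent instead, for comparison.
#'
#' @param t_grid Times in seconds, non-negative, strictly increasing and
#'   (for the default population use) uniformly spaced.
#' @param p A [parker_params()].
#' @param form `"multiplicative"` (default) or `"literal"`.
#' @return An [aif()] with `source = "population"`.
#' @examples
#' pa <- parker_aif(0:300)
#' max(pa$curve$conc)  # first-pass peak, ~6 mM
#' @export
parker_aif <- function(t_grid, p = parker_params(),
                       form = c("multiplicative", "literal")) {
  form <- match.arg(form)
  stopifnot(inherits(p, "parker_params"))
  if (any(t_grid < 0)) stop("AIF times must be non-negative", call. = FALSE)
  tm <- t_grid / 60
  g <- p$A1 / (p$sigma1 * sqrt(2 * pi)) * exp(-(tm - p$T1g)^2 / (2 * p$sigma1^2)) +
       p$A2 / (p$sigma2 * sqrt(2 * pi)) * exp(-(tm - p$T2g)^2 / (2 * p$sigma2^2))
  sig <- 1 + exp(-p$s * (tm - p$tau))
  wash <- if (form == "multiplicative") p$alpha * exp(-p$beta * tm) / sig
          else p$alpha * exp(-p$beta * tm / sig)
  aif(concentration_curve(t_grid, g + wash, "blood", "pAIF"),
      source = "population")
}

#' Locate the peak time of a concentration curve
#'
#' Argmax of the curve after optional centred moving-average smoothing;
#' ties break toward the earliest time. Clinical aortic curves at 5-s
#' resolution are noisy, so image-derived peaks are usually located with a
#' 3-frame window; `smooth_window = 1` disables smoothing.
#'
#' @param curve A [concentration_curve()] or [signal_curve()] with >= 5
#'   frames.
#' @param smooth_window Odd window length in frames.
#' @return Peak time in seconds.
#' @export
find_peak <- function(curve, smooth_window = 1L) {
  vals <- if (inherits(curve, "concentration_curve")) curve$conc else curve$values
  if (length(vals) < 5) stop("need at least 5 frames", call. = FALSE)
  w <- as.integer(smooth_window)
  if (w < 1 || w %% 2 == 0) stop("smooth_window must be odd and >= 1",
                                 call. = FALSE)
  if (w > 1) vals <- stats::filter(vals, rep(1 / w, w), sides = 2)
  if (max(vals, na.rm = TRUE) - min(vals, na.rm = TRUE) <= 0)
    stop("curve is constant; no peak", call. = FALSE)
  curve$times[which.max(vals)]
}

#' Align a population AIF to an image-derived AIF peak
#'
#' Shifts the population AIF rigidly in time by
#' delta = peak(iAIF) - peak(pAIF) so the two first-pass peaks coincide,
#' then re-expresses it on a uniform `grid_step` grid covering the
#' acquisition window, zero-padded before bolus arrival. Amplitudes are
#' never changed: the population form is trusted for shape and scale, the
#' individual's curve only for bolus-arrival timing.
#'
#' @param paif Population [aif()].
#' @param iaif Image-derived [aif()].
#' @param iaif_smooth_window Moving-average window for locating the iAIF
#'   peak (default 3 frames).
#' @param t_max End of the output grid in seconds; default the iAIF's last
#'   time point.
#' @return A population [aif()] on the new grid, with attribute `shift_s`
#'   (the applied shift, snapped to the grid step).
#' @export
align_paif_to_iaif <- function(paif, iaif, iaif_smooth_window = 3L,
                               t_max = NULL) {
  stopifnot(inherits(paif, "aif"), inherits(iaif, "aif"))
  if (paif$source != "population" || iaif$source != "image")
    stop("expected a population pAIF and an image-derived iAIF",
         call. = FALSE)
  delta <- find_peak(iaif$curve, iaif_smooth_window) - find_peak(paif$curve, 1L)
  h <- paif$grid_step
  delta <- round(delta / h) * h  # snap so grid nodes map onto grid nodes
  if (is.null(t_max)) t_max <- max(iaif$curve$times)
  out_t <- seq(0, t_max, by = h)
  y <- stats::approx(paif$curve$times + delta, paif$curve$conc, xout = out_t,
                     rule = c(1, 2))$y
  y[is.na(y)] <- 0  # before shifted bolus arrival
  out <- aif(concentration_curve(out_t, y, "blood", "pAIF (aligned)"),
             source = "population", grid_step = h)
  attr(out, "shift_s") <- delta
  out
}
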