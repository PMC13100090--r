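#' Whole-kidney two-pathway model parameters
#'
#' The model treats the whole parenchyma as one unit with two parallel
#' pathways: a vascular (plasma) pathway with mean transit time `Tp`, and a
#' tubular pathway receiving the filtered fraction `FF` of the plasma flow
#' with mean transit time `Tt`. Single-kidney eGFR is the product FF x RPF.
#'
#' @param RPF Renal plasma flow, mL/min, > 0.
#' @param FF Filtration fraction, in (0, 1).
#' @param Tp Plasma mean transit time, seconds, > 0.
#' @param Tt Tubular mean transit time, seconds, > 0.
#' @return An object of class `kidney_model_params`.
#' @export
kidney_model_params <- function(RPF, FF, Tp, Tt) {
  stopifnot(is.numeric(RPF), is.numeric(FF), is.numeric(Tp), is.numeric(Tt))
  if (RPF <= 0) stop("RPF must be positive", call. = FALSE)
  if (FF <= 0 || FF >= 1) stop("FF must lie in (0, 1)", call. = FALSE)
  if (Tp <= 0 || Tt <= 0) stop("transit times must be positive", call. = FALSE)
  structure(list(RPF = RPF, FF = FF, Tp = Tp, Tt = Tt),
            class = "kidney_model_params")
}

#' Kidney geometry and blood composition
#'
#' @param Vt Kidney parenchyma volume, mL, > 0.
#' @param hematocrit Hematocrit fraction in (0, 1); fixed at 0.4 in the
#'   model by default, overridable per subject.
#' @param side `"left"` or `"right"`.
#' @return An object of class `kidney_geometry`.
#' @export
kidney_geometry <- function(Vt, hematocrit = 0.4, side = c("left", "right")) {
  side <- match.arg(side)
  if (Vt <= 0) stop("Vt must be positive", call. = FALSE)
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  structure(list(Vt = Vt, hematocrit = hematocrit, side = side),
            class = "kidney_geometry")
}

#' Impulse retention function of the whole-kidney model
#'
#' Fraction of an instantaneous arterial tracer bolus still inside the
#' kidney at time t:
#' R(t) = exp(-t/Tp) + FF (Tt/(Tt - Tp)) (exp(-t/Tt) - exp(-t/Tp)).
#' The first term is tracer still in the plasma pathway; the second is the
#' filtered fraction in transit through the tubules — the convolution of
#' the plasma impulse response (1/Tp) exp(-t/Tp) with the tubular retention
#' exp(-t/Tt), scaled by FF. In the degenerate limit Tp = Tt it reduces to
#' FF (t/Tp) exp(-t/Tp). R(0) = 1 and R decays to 0.
#'
#' @param t_grid Times in seconds, >= 0, strictly increasing.
#' @param p A [kidney_model_params()].
#' @return Dimensionless retention values on `t_grid`.
#' @export
impulse_retention <- function(t_grid, p) {
  stopifnot(inherits(p, "kidney_model_params"))
  if (any(t_grid < 0)) stop("t_grid must be non-negative", call. = FALSE)
  ep <- exp(-t_grid / p$Tp)
  # relative spacing decides when the closed form is numerically safe
  if (abs(p$Tt - p$Tp) > 1e-9 * max(p$Tt, p$Tp)) {
    et <- exp(-t_grid / p$Tt)
    tub <- p$Tt / (p$Tt - p$Tp) * (et - ep)
  } else {
    tub <- (t_grid / p$Tp) * ep
  }
  ep + p$FF * tub
}

#' Forward whole-kidney model: tissue concentration from an AIF
#'
#' Ct(t) = RPF / ((1 - Hct) Vt) * (C_A (x) R)(t), where (x) is convolution
#' on the AIF's uniform fine grid with the grid step expressed in minutes
#' (RPF is per minute), evaluated by the trapezoidal rule and linearly
#' interpolated down to the requested sample times.
#'
#' @param input_aif An [aif()] on a uniform grid (image-derived AIFs should
#'   be interpolated to a fine grid first, see [interpolate_aif()]).
#' @param p A [kidney_model_params()].
#' @param geom A [kidney_geometry()].
#' @param sample_times Output times in seconds, within the AIF time span.
#' @return A parenchyma [concentration_curve()] at `sample_times`.
#' @export
forward_model <- function(input_aif, p, geom, sample_times) {
  stopifnot(inherits(input_aif, "aif"), inherits(p, "kidney_model_params"),
            inherits(geom, "kidney_geometry"))
  tt <- input_aif$curve$times
  h <- diff(tt)
  if (any(abs(h - h[1]) > 1e-9 * h[1]))
    stop("forward model needs the AIF on a uniform grid", call. = FALSE)
  h <- h[1]
  if (min(sample_times) < min(tt) || max(sample_times) > max(tt))
    stop("sample_times outside the AIF time span", call. = FALSE)
  ca <- input_aif$curve$conc
  r <- impulse_retention(tt - tt[1], p)
  n <- length(ca)
  # open convolution: full[k] = sum_{i+j=k+1} ca[i] r[j]; trapezoid ends
  full <- stats::convolve(ca, rev(r), type = "open")[seq_len(n)]
  conv <- (full - 0.5 * (ca[1] * r + ca * r[1])) * (h / 60)  # mM * min
  ct <- p$RPF / ((1 - geom$hematocrit) * geom$Vt) * conv
  yi <- stats::approx(tt, ct, xout = sample_times)$y
  concentration_curve(sample_times, yi, "parenchyma", "kidney (model)")
}

#' Interpolate an image-derived AIF to a uniform fine grid
#'
#' @param input_aif An [aif()].
#' @param grid_step Target grid step, seconds (default 1).
#' @return An [aif()] of the same source on the uniform grid.
#' @export
interpolate_aif <- function(input_aif, grid_step = 1) {
  stopifnot(inherits(input_aif, "aif"))
  tt <- input_aif$curve$times
  out_t <- seq(min(tt), max(tt), by = grid_step)
  y <- stats::approx(tt, input_aif$curve$conc, xout = out_t)$y
  structure(list(curve = concentration_curve(out_t, y, "blood",
                                             input_aif$curve$label),
                 source = input_aif$source, grid_step = grid_step),
            class = "aif")
}

#' Single-kidney eGFR from model parameters
#'
#' @param p A [kidney_model_params()].
#' @return eGFR in mL/min: filtration fraction times renal plasma flow.
#' @export
egfr_from_params <- function(p) {
  stopifnot(inherits(p, "kidney_model_params"))
  p$FF * p$RPF
}

#' Body habitus for BSA normalization
#'
#' @param height Height in metres, > 0.
#' @param weight Weight in kg, > 0.
#' @return An object of class `subject_body`.
#' @export
subject_body <- function(height, weight) {
  if (height <= 0 || height > 3 || weight <= 0 || weight > 700)
    stop("non-physiological height/weight", call. = FALSE)
  structure(list(height = height, weight = weight), class = "subject_body")
}

#' DuBois body surface area
#'
#' BSA = 0.007184 W^0.425 (100 H)^0.725 with W in kg and H in metres.
#'
#' @param body A [subject_body()].
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(body) {
  stopifnot(inherits(body, "subject_body"))
  0.007184 * body$weight^0.425 * (100 * body$height)^0.725
}

#' Normalize eGFR to 1.73 m^2 body surface area
#'
#' @param egfr_total Whole-subject eGFR, mL/min, >= 0.
#' @param body A [subject_body()].
#' @return eGFR in mL/min/1.73 m^2.
#' @export
normalize_egfr <- function(egfr_total, body) {
  if (egfr_total < 0) stop("eGFR must be non-negative", call. = FALSE)
  egfr_total * 1.73 / bsa_dubois(body)
}
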