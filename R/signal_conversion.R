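#' Acquisition parameters of the dynamic SPGR sequence
#'
#' Defaults follow a 1.5-T fat-suppressed 3D T1-weighted dynamic renal
#' protocol: TR 4.53 ms, flip angle 12 degrees, gadobutrol relaxivity
#' r1 = 5.2 L/mmol/s, pre-contrast T1 of 1.0 s for renal parenchyma and
#' 1.48 s for blood. `n_baseline_frames` is the number of pre-bolus frames
#' used to calibrate the equilibrium signal; the default of 5 corresponds
#' to a 25-s pre-injection baseline at 5-s temporal resolution.
#'
#' @param TR Repetition time, seconds.
#' @param flip_angle Flip angle, degrees, in (0, 90).
#' @param r1 Longitudinal relaxivity of the contrast agent, L/mmol/s.
#' @param T10_tissue Pre-contrast T1 of renal parenchyma, seconds.
#' @param T10_blood Pre-contrast T1 of blood, seconds.
#' @param n_baseline_frames Number of pre-bolus frames, >= 1.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(TR = 0.00453, flip_angle = 12, r1 = 5.2,
                               T10_tissue = 1.0, T10_blood = 1.48,
                               n_baseline_frames = 5L) {
  stopifnot(TR > 0, flip_angle > 0, flip_angle < 90, r1 > 0,
            T10_tissue > 0, T10_blood > 0, n_baseline_frames >= 1)
  structure(list(TR = TR, flip_angle = flip_angle, r1 = r1,
                 T10_tissue = T10_tissue, T10_blood = T10_blood,
                 n_baseline_frames = as.integer(n_baseline_frames)),
            class = "acquisition_params")
}

#' Steady-state spoiled gradient echo signal
#'
#' S = m0_eff (1 - E) / (1 - cos(alpha) E) with E = exp(-TR/T1), ignoring
#' T2* decay at short echo time. `m0_eff` is the single calibration scalar
#' absorbing the equilibrium magnetization and sin(alpha) (and receive-coil
#' gain), so it is calibrated per ROI, never globally.
#'
#' @param T1 Longitudinal relaxation time(s), seconds, > 0. Vectorized.
#' @param params An [acquisition_params()].
#' @param m0_eff Effective equilibrium signal, arbitrary units, > 0.
#' @return Signal in the same arbitrary units as `m0_eff`.
#' @export
spgr_signal <- function(T1, params, m0_eff = 1) {
  stopifnot(inherits(params, "acquisition_params"), m0_eff > 0)
  if (any(T1 <= 0)) stop("T1 must be positive", call. = FALSE)
  E <- exp(-params$TR / T1)
  ca <- cos(params$flip_angle * pi / 180)
  m0_eff * (1 - E) / (1 - ca * E)
}

#' Calibrate the effective equilibrium signal from baseline frames
#'
#' Divides the mean of the first `n_baseline_frames` signals by the SPGR
#' saturation factor at the pre-contrast T1, recovering `m0_eff`.
#'
#' @param curve A [signal_curve()] with at least `n_baseline_frames` frames.
#' @param T10 Pre-contrast T1 of the ROI tissue, seconds.
#' @param params An [acquisition_params()].
#' @return `m0_eff` in the curve's units.
#' @export
calibrate_m0 <- function(curve, T10, params) {
  stopifnot(inherits(curve, "signal_curve"),
            inherits(params, "acquisition_params"))
  nb <- params$n_baseline_frames
  if (length(curve$values) < nb)
    stop("curve shorter than the baseline window", call. = FALSE)
  s0 <- mean(curve$values[seq_len(nb)])
  if (!is.finite(s0) || s0 <= 0)
    stop("baseline mean signal must be positive to calibrate m0",
         call. = FALSE)
  s0 / (spgr_signal(T10, params, m0_eff = 1))
}

#' Convert an ROI signal curve to gadolinium concentration
#'
#' Inverts the SPGR signal equation frame by frame for E(t) =
#' (m0_eff - S)/(m0_eff - S cos(alpha)), recovers T1(t) = -TR/log E(t), and
#' applies the fast-exchange linear relaxivity relation
#' C(t) = (1/r1) (1/T1(t) - 1/T10).
#'
#' Frames where noise pushes E(t) outside (0, 1) cannot be inverted; such
#' frames are flagged, set to C = 0 when they fall inside the baseline
#' window, and linearly interpolated from their valid neighbours when
#' post-bolus. If more than 20% of frames are flagged the conversion
#' aborts.
#'
#' @inheritParams calibrate_m0
#' @param tissue_class `"blood"` or `"parenchyma"`, stored on the result.
#' @param m0_eff Optional pre-computed calibration; default recalibrates
#'   from this curve's baseline.
#' @return A [concentration_curve()] with attribute `qc_flag`, a logical
#'   vector marking repaired frames.
#' @export
signal_to_concentration <- function(curve, T10, params,
                                    tissue_class = c("parenchyma", "blood"),
                                    m0_eff = NULL) {
  tissue_class <- match.arg(tissue_class)
  if (is.null(m0_eff)) m0_eff <- calibrate_m0(curve, T10, params)
  S <- curve$values
  ca <- cos(params$flip_angle * pi / 180)
  E <- (m0_eff - S) / (m0_eff - S * ca)
  bad <- !is.finite(E) | E <= 0 | E >= 1
  if (mean(bad) > 0.2)
    stop(sprintf("%.0f%% of frames not invertible; conversion aborted",
                 100 * mean(bad)), call. = FALSE)
  T1 <- -params$TR / log(E)
  conc <- (1 / params$r1) * (1 / T1 - 1 / T10)
  if (any(bad)) {
    nb <- params$n_baseline_frames
    pre <- bad & seq_along(S) <= nb
    conc[pre] <- 0
    post <- which(bad & seq_along(S) > nb)
    if (length(post)) {
      ok <- which(!bad | seq_along(S) <= nb)
      conc[post] <- stats::approx(curve$times[ok], conc[ok],
                                  xout = curve$times[post], rule = 2)$y
    }
  }
  out <- concentration_curve(curve$times, conc, tissue_class, curve$label)
  attr(out, "qc_flag") <- bad
  out
}

#' Map a concentration curve to SPGR signal (forward direction)
#'
#' The exact inverse of [signal_to_concentration()]: C -> T1 via the
#' relaxivity relation, T1 -> signal via the SPGR equation. Used by the
#' synthetic module and by round-trip checks.
#'
#' @param curve A [concentration_curve()].
#' @param T10 Pre-contrast T1 for the curve's tissue, seconds.
#' @param params An [acquisition_params()].
#' @param m0_eff Effective equilibrium signal, arbitrary units.
#' @return A [signal_curve()].
#' @export
concentration_to_signal <- function(curve, T10, params, m0_eff) {
  stopifnot(inherits(curve, "concentration_curve"))
  R1 <- 1 / T10 + params$r1 * curve$conc
  if (any(R1 <= 0))
    stop("concentration implies non-positive relaxation rate", call. = FALSE)
  signal_curve(curve$times, spgr_signal(1 / R1, params, m0_eff), curve$label)
}
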