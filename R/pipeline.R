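#' Run the full per-subject DCE-MRI workflow
#'
#' Orchestrates the per-case chain: ROI curve extraction (when a 4D series
#' and masks are given), signal-to-concentration conversion, AIF
#' preparation (image-derived, and/or the population form aligned to the
#' individual's aortic peak time), per-kidney whole-kidney model fitting,
#' and eGFR aggregation. The population branch consults the aortic curve
#' only for its peak time, never its amplitude.
#'
#' @param series Optional [dynamic_series()]; with `masks`, curves and
#'   kidney volumes are extracted from it.
#' @param masks Named list of [roi_mask()] (`aorta` plus kidney masks);
#'   required with `series`.
#' @param aorta_curve,kidney_curves Alternative input: an aortic
#'   [signal_curve()] and a named list of kidney signal curves.
#' @param geom Named list of [kidney_geometry()] per kidney; derived from
#'   the masks when a series is given (override to supply hematocrit).
#' @param acq An [acquisition_params()].
#' @param clinical Optional [subject_clinical()] for serum eGFR.
#' @param body Optional [subject_body()]; if given, summed eGFR is also
#'   reported normalized to 1.73 m^2 BSA.
#' @param asl_rpf Optional named numeric of ASL-derived RPF (mL/min).
#' @param fit_cfg A [fit_config()].
#' @param aif_mode `"population"`, `"image"` or `"both"`.
#' @param iaif_smooth_window Peak-detection smoothing window (frames).
#' @return An object of class `case_report`: per-kidney `fit_result`s per
#'   AIF mode, summed (and BSA-normalized) eGFR per mode, serum eGFR, ASL
#'   RPF, QC flags and provenance.
#' @export
run_case <- function(series = NULL, masks = NULL, aorta_curve = NULL,
                     kidney_curves = NULL, geom = NULL,
                     acq = acquisition_params(), clinical = NULL,
                     body = NULL, asl_rpf = NULL, fit_cfg = fit_config(),
                     aif_mode = c("population", "image", "both"),
                     iaif_smooth_window = 3L) {
  aif_mode <- match.arg(aif_mode)
  qc <- list()

  if (!is.null(series)) {
    if (is.null(masks) || !"aorta" %in% names(masks))
      stop("[segmentation] series input requires masks including 'aorta'",
           call. = FALSE)
    kidney_names <- setdiff(names(masks), "aorta")
    if (!length(kidney_names))
      stop("[segmentation] no kidney mask provided", call. = FALSE)
    aorta_curve <- extract_mean_curve(series, masks$aorta)
    kidney_curves <- lapply(masks[kidney_names], extract_mean_curve,
                            series = series)
    if (is.null(geom)) {
      geom <- lapply(masks[kidney_names], function(m)
        kidney_geometry(kidney_volume(m),
                        side = if (grepl("left", m$label)) "left" else "right"))
    }
  }
  if (is.null(aorta_curve) || is.null(kidney_curves) || is.null(geom))
    stop("[input] need either series+masks or aorta_curve+kidney_curves+geom",
         call. = FALSE)

  iaif_conc <- signal_to_concentration(aorta_curve, acq$T10_blood, acq,
                                       "blood")
  qc$aorta_flagged_frames <- sum(attr(iaif_conc, "qc_flag"))
  iaif <- aif(iaif_conc, source = "image")

  kid_conc <- lapply(kidney_curves, function(sc) {
    cc <- signal_to_concentration(sc, acq$T10_tissue, acq, "parenchyma")
    qc[[paste0(sc$label, "_flagged_frames")]] <<- sum(attr(cc, "qc_flag"))
    cc
  })

  t_max <- max(aorta_curve$times)
  aifs <- list()
  if (aif_mode %in% c("population", "both")) {
    paif_raw <- parker_aif(seq(0, t_max + 120, by = 1))
    aifs$population <- align_paif_to_iaif(paif_raw, iaif,
                                          iaif_smooth_window, t_max = t_max)
    qc$paif_shift_s <- attr(aifs$population, "shift_s")
  }
  if (aif_mode %in% c("image", "both"))
    aifs$image <- interpolate_aif(iaif, grid_step = 1)

  fits <- lapply(names(aifs), function(mode) {
    lapply(names(kid_conc), function(side) {
      fit_whole_kidney(kid_conc[[side]], aifs[[mode]], geom[[side]], fit_cfg)
    }) |> stats::setNames(names(kid_conc))
  }) |> stats::setNames(names(aifs))

  summary_tab <- lapply(names(fits), function(mode) {
    egfr_sum <- sum(vapply(fits[[mode]], function(f) f$egfr, numeric(1)))
    rpf <- vapply(fits[[mode]], function(f) f$params$RPF, numeric(1))
    list(egfr_total = egfr_sum,
         egfr_total_bsa = if (!is.null(body)) normalize_egfr(egfr_sum, body)
                          else NULL,
         rpf = as.list(rpf))
  }) |> stats::setNames(names(fits))

  serum <- if (!is.null(clinical))
    ckd_epi_2021(clinical$serum_creatinine, clinical$age, clinical$sex)
  else NULL

  structure(list(fits = fits, summary = summary_tab, serum_egfr = serum,
                 asl_rpf = asl_rpf, qc = qc,
                 provenance = list(
                   software = paste0("renaldce ",
                     as.character(utils::packageVersion("renaldce"))),
                   seed = fit_cfg$rng_seed, aif_mode = aif_mode)),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>\n")
  for (mode in names(x$fits)) {
    s <- x$summary[[mode]]
    cat(sprintf("  %s AIF: total eGFR %.1f mL/min%s\n", mode, s$egfr_total,
                if (!is.null(s$egfr_total_bsa))
                  sprintf(" (%.1f mL/min/1.73m2)", s$egfr_total_bsa) else ""))
    for (side in names(x$fits[[mode]])) {
      f <- x$fits[[mode]][[side]]
      cat(sprintf("    %-14s RPF %6.1f mL/min  FF %.3f  eGFR %5.1f  R2 %.3f\n",
                  side, f$params$RPF, f$params$FF, f$egfr, f$r_squared))
    }
  }
  if (!is.null(x$serum_egfr))
    cat(sprintf("  serum eGFR: %.1f mL/min/1.73m2\n", x$serum_egfr))
  invisible(x)
}

#' Serialize a case report to JSON
#'
#' Stable, fully numeric serialization: identical inputs and seed yield a
#' byte-identical file.
#'
#' @param report A `case_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  stopifnot(inherits(report, "case_report"))
  out <- list(provenance = report$provenance, qc = report$qc,
              serum_egfr = report$serum_egfr, asl_rpf = report$asl_rpf)
  out$modes <- lapply(names(report$fits), function(mode) {
    kidneys <- lapply(report$fits[[mode]], function(f)
      list(rpf_ml_min = f$params$RPF, ff = f$params$FF, tp_s = f$params$Tp,
           tt_s = f$params$Tt, egfr_ml_min = f$egfr, rss = f$rss,
           r_squared = f$r_squared, converged = f$converged,
           start_index = f$start_index))
    c(list(aif = mode), report$summary[[mode]]["egfr_total"],
      report$summary[[mode]]["egfr_total_bsa"], list(kidneys = kidneys))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize model parameters to/from JSON
#'
#' @param p A [kidney_model_params()].
#' @param path JSON path.
#' @return `read_model_params_json()` returns a [kidney_model_params()].
#' @export
write_model_params_json <- function(p, path) {
  stopifnot(inherits(p, "kidney_model_params"))
  jsonlite::write_json(list(rpf_ml_min = p$RPF, ff = p$FF, tp_s = p$Tp,
                            tt_s = p$Tt),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params_json
#' @export
read_model_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kidney_model_params(RPF = x$rpf_ml_min, FF = x$ff, Tp = x$tp_s,
                      Tt = x$tt_s)
}
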