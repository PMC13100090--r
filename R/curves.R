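#' Time-stamped curve containers
#'
#' Signal and concentration curves are the exchange currency between every
#' stage of the pipeline: ROI extraction produces signal curves in arbitrary
#' units, signal-to-concentration conversion produces gadolinium
#' concentration curves in mM, and the kinetic model consumes and produces
#' concentration curves.
#'
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param values Numeric vector of signal intensities (arbitrary units),
#'   same length as `times`.
#' @param label Free-text label (e.g. `"aorta"`, `"left_kidney"`).
#' @return `signal_curve()` returns an object of class `signal_curve`;
#'   `concentration_curve()` an object of class `concentration_curve`.
#'   Both are lists with elements `times`, `values`/`conc` and `label`.
#' @examples
#' sc <- signal_curve(seq(0, 50, by = 5), rnorm(11, 100, 1), "aorta")
#' length(sc$times)
#' @export
signal_curve <- function(times, values, label = "") {
  check_time_series(times, values)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = as.character(label)[1]),
            class = "signal_curve")
}

#' @rdname signal_curve
#' @param conc Gadolinium concentration in mM, same length as `times`.
#' @param tissue_class `"blood"` or `"parenchyma"`; determines which
#'   pre-contrast T1 applies.
#' @export
concentration_curve <- function(times, conc, tissue_class = c("parenchyma", "blood"),
                                label = "") {
  tissue_class <- match.arg(tissue_class)
  check_time_series(times, conc)
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 tissue_class = tissue_class, label = as.character(label)[1]),
            class = "concentration_curve")
}

check_time_series <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("<signal_curve '%s'> %d frames, t = [%g, %g] s\n",
              x$label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve '%s' (%s)> %d frames, peak %.3g mM\n",
              x$label, x$tissue_class, length(x$times), max(x$conc)))
  invisible(x)
}

#' Read and write curves as CSV
#'
#' Curves travel between pipeline stages (and the command-line tool) as
#' two-column CSV: `time_s,value` for signal, `time_s,conc_mM` for
#' concentration. An optional logical `qc_flag` column records frames the
#' conversion step repaired. Values round-trip at full double precision.
#'
#' @param curve A `signal_curve` or `concentration_curve`.
#' @param path File path.
#' @return `write_curve_csv()` returns `path` invisibly. `read_curve_csv()`
#'   returns a curve of the class implied by the header.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "signal_curve")) {
    df <- data.frame(time_s = curve$times, value = curve$values)
  } else if (inherits(curve, "concentration_curve")) {
    df <- data.frame(time_s = curve$times, conc_mM = curve$conc)
    if (!is.null(attr(curve, "qc_flag")))
      df$qc_flag <- attr(curve, "qc_flag")
  } else stop("not a curve object", call. = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param label Label to attach to the curve read from `path`.
#' @param tissue_class Tissue class for concentration curves.
#' @export
read_curve_csv <- function(path, label = "", tissue_class = "parenchyma") {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("curve CSV must have a time_s column", call. = FALSE)
  if ("value" %in% names(df)) {
    signal_curve(df$time_s, df$value, label)
  } else if ("conc_mM" %in% names(df)) {
    cc <- concentration_curve(df$time_s, df$conc_mM, tissue_class, label)
    if ("qc_flag" %in% names(df)) attr(cc, "qc_flag") <- as.logical(df$qc_flag)
    cc
  } else stop("curve CSV must have a value or conc_mM column", call. = FALSE)
}
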