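#' Configuration for whole-kidney model fitting
#'
#' Physiological box bounds and starting values for the four model
#' parameters, plus the multistart policy. Bounds are enforced by fitting
#' on a smooth reparameterization (log for RPF/Tp/Tt, logit for FF) so a
#' classical Levenberg-Marquardt core can be used unmodified; the
#' optimizer additionally sees box bounds on the transformed coordinates.
#'
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param init Named list of starting values, inside the bounds.
#' @param max_iter Maximum LM iterations per start.
#' @param tolerance Relative convergence tolerance (ftol/ptol).
#' @param n_multistart Number of starts (>= 1); start 1 is `init`, the rest
#'   are deterministically jittered from `rng_seed`.
#' @param rng_seed Seed for the jitter; the fit is bit-reproducible for a
#'   given seed.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(RPF = c(1, 2000), FF = c(0.001, 0.6),
                                     Tp = c(1, 60), Tt = c(10, 600)),
                       init = list(RPF = 200, FF = 0.15, Tp = 8, Tt = 120),
                       max_iter = 200L, tolerance = 1e-10,
                       n_multistart = 5L, rng_seed = 1L) {
  for (nm in c("RPF", "FF", "Tp", "Tt")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] >= b[2])
      stop("bounds for ", nm, " must be an ordered pair", call. = FALSE)
    if (init[[nm]] <= b[1] || init[[nm]] >= b[2])
      stop("init for ", nm, " must lie strictly inside its bounds",
           call. = FALSE)
  }
  stopifnot(n_multistart >= 1, max_iter >= 1, tolerance > 0)
  structure(list(bounds = bounds, init = init, max_iter = as.integer(max_iter),
                 tolerance = tolerance, n_multistart = as.integer(n_multistart),
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

param_to_theta <- function(p, bounds) {
  c(log(p$RPF),
    stats::qlogis((p$FF - bounds$FF[1]) / diff(bounds$FF)),
    log(p$Tp), log(p$Tt))
}

theta_to_param <- function(theta, bounds) {
  kidney_model_params(RPF = exp(theta[1]),
                      FF = bounds$FF[1] + diff(bounds$FF) * stats::plogis(theta[2]),
                      Tp = exp(theta[3]), Tt = exp(theta[4]))
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the whole-kidney model to a measured concentration curve
#'
#' Bounded Levenberg-Marquardt least squares: minimizes the sum of squared
#' residuals between the measured parenchyma curve and
#' [forward_model()] over (RPF, FF, Tp, Tt), on the unconstrained
#' log/logit scale, taking the best of `n_multistart` deterministic starts.
#' Multistart guards against the well-known degeneracy of tracer-kinetic
#' fits, where several parameter combinations produce nearly identical
#' curves.
#'
#' @param ct Measured parenchyma [concentration_curve()].
#' @param input_aif An [aif()]; image-derived AIFs are interpolated to a
#'   1-s grid internally.
#' @param geom A [kidney_geometry()].
#' @param cfg A [fit_config()].
#' @param weights Optional per-frame residual weights (default ones).
#' @return An object of class `fit_result`: `params`
#'   ([kidney_model_params()]), `egfr` (mL/min), `rss`, `r_squared`,
#'   `converged`, `n_iter`, `start_index`.
#' @export
fit_whole_kidney <- function(ct, input_aif, geom, cfg = fit_config(),
                             weights = NULL) {
  stopifnot(inherits(ct, "concentration_curve"), inherits(input_aif, "aif"),
            inherits(geom, "kidney_geometry"), inherits(cfg, "fit_config"))
  if (length(ct$times) < 8)
    stop("need at least 8 frames to fit four parameters", call. = FALSE)
  if (stats::sd(ct$conc) == 0)
    stop("flat concentration curve; nothing to fit", call. = FALSE)
  steps <- diff(input_aif$curve$times)
  if (any(abs(steps - steps[1]) > 1e-9 * steps[1]) || steps[1] > 2)
    input_aif <- interpolate_aif(input_aif, grid_step = 1)
  if (is.null(weights)) weights <- rep(1, length(ct$conc))
  sw <- sqrt(weights)

  bounds <- cfg$bounds
  resid_fn <- function(theta) {
    p <- theta_to_param(theta, bounds)
    sw * (ct$conc - forward_model(input_aif, p, geom, ct$times)$conc)
  }
  lower <- c(log(bounds$RPF[1]), -36, log(bounds$Tp[1]), log(bounds$Tt[1]))
  upper <- c(log(bounds$RPF[2]),  36, log(bounds$Tp[2]), log(bounds$Tt[2]))

  theta0 <- param_to_theta(cfg$init, bounds)
  jitters <- if (cfg$n_multistart > 1) {
    with_local_seed(cfg$rng_seed,
      matrix(stats::runif(4 * (cfg$n_multistart - 1), -0.7, 0.7),
             ncol = 4))
  } else NULL

  best <- NULL
  for (k in seq_len(cfg$n_multistart)) {
    th <- if (k == 1) theta0 else pmin(pmax(theta0 + jitters[k - 1, ],
                                            lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$max_iter, ftol = cfg$tolerance,
                           ptol = cfg$tolerance)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% c(1, 2, 3, 4)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(theta = fit$par, rss = rss, converged = conv,
                   n_iter = fit$niter, start_index = k)
    }
  }
  if (is.null(best) || !best$converged)
    stop("no multistart run converged; check the curve and AIF",
         call. = FALSE)
  p <- theta_to_param(best$theta, bounds)
  fitted <- forward_model(input_aif, p, geom, ct$times)
  gof <- goodness_of_fit(ct, fitted)
  structure(list(params = p, egfr = egfr_from_params(p), rss = gof$rss,
                 r_squared = gof$r_squared, converged = best$converged,
                 n_iter = best$n_iter, start_index = best$start_index,
                 fitted = fitted),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> RPF %.1f mL/min, FF %.3f, Tp %.1f s, ",
                     "Tt %.1f s | eGFR %.1f mL/min | rss %.3g, R2 %.4f",
                     " (start %d)\n"),
              x$params$RPF, x$params$FF, x$params$Tp, x$params$Tt,
              x$egfr, x$rss, x$r_squared, x$start_index))
  invisible(x)
}

#' Residual sum of squares and R-squared of a fitted curve
#'
#' @param ct Measured [concentration_curve()].
#' @param fitted Model [concentration_curve()] at the same times.
#' @return List with `rss` (mM^2) and `r_squared`.
#' @export
goodness_of_fit <- function(ct, fitted) {
  if (length(ct$conc) != length(fitted$conc))
    stop("curves must share the same sampling", call. = FALSE)
  sst <- sum((ct$conc - mean(ct$conc))^2)
  if (sst == 0) stop("zero-variance curve; R-squared undefined", call. = FALSE)
  rss <- sum((ct$conc - fitted$conc)^2)
  list(rss = rss, r_squared = 1 - rss / sst)
}
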