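#' Configuration of a synthetic renal DCE exam
#'
#' Defines a fully specified digital case emulating a 5-s-resolution renal
#' DCE acquisition with a ~25-s pre-injection baseline: ground-truth
#' kinetic parameters per kidney, acquisition settings, signal-space noise
#' and the aortic peak-clipping artifact (inflow/saturation suppressing the
#' measured first-pass peak). Default truth values sit at the scale of an
#' adult cohort: RPF around 230 mL/min and kidney volume around 150 mL per
#' kidney.
#'
#' @param true_params Named list (`left`, `right`) of
#'   [kidney_model_params()]; a single entry simulates one kidney.
#' @param geom Named list of matching [kidney_geometry()].
#' @param acq An [acquisition_params()].
#' @param n_frames Number of frames (default 60).
#' @param frame_interval Temporal resolution, seconds (default 5).
#' @param baseline_s Pre-injection baseline, seconds (default 25).
#' @param delay_s Bolus arrival time, seconds (default = `baseline_s`).
#' @param noise_sigma_signal SD of signal-space noise, a.u. (default 0).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param aorta_clip_fraction Hard ceiling on the aortic concentration
#'   peak as a fraction of its maximum, in (0, 1]; 1 = no clipping.
#' @param m0_aorta,m0_kidney Effective equilibrium signals painted into
#'   the aorta and kidney ROIs, a.u.
#' @param rng_seed Seed; regeneration with the same config is
#'   bit-identical.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    true_params = list(
      left  = kidney_model_params(RPF = 230, FF = 0.15, Tp = 8,  Tt = 120),
      right = kidney_model_params(RPF = 215, FF = 0.14, Tp = 10, Tt = 100)),
    geom = list(left  = kidney_geometry(150, side = "left"),
                right = kidney_geometry(145, side = "right")),
    acq = acquisition_params(),
    n_frames = 60L, frame_interval = 5, baseline_s = 25,
    delay_s = baseline_s, noise_sigma_signal = 0,
    noise_model = c("gaussian", "rician"),
    aorta_clip_fraction = 1, m0_aorta = 1000, m0_kidney = 1000,
    rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(true_params) >= 1,
            identical(names(true_params), names(geom)),
            n_frames >= 10, frame_interval > 0, baseline_s >= 0,
            delay_s >= 0, noise_sigma_signal >= 0,
            m0_aorta > 0, m0_kidney > 0)
  if (aorta_clip_fraction <= 0 || aorta_clip_fraction > 1)
    stop("aorta_clip_fraction must lie in (0, 1]", call. = FALSE)
  for (p in true_params) stopifnot(inherits(p, "kidney_model_params"))
  for (g in geom) stopifnot(inherits(g, "kidney_geometry"))
  structure(list(true_params = true_params, geom = geom, acq = acq,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, baseline_s = baseline_s,
                 delay_s = delay_s, noise_sigma_signal = noise_sigma_signal,
                 noise_model = noise_model,
                 aorta_clip_fraction = aorta_clip_fraction,
                 m0_aorta = m0_aorta, m0_kidney = m0_kidney,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# Parker AIF delayed by delay_s on a uniform fine grid over [0, t_max]
delayed_parker_aif <- function(t_max, delay_s, grid_step = 1,
                               p = parker_params()) {
  tt <- seq(0, t_max, by = grid_step)
  conc <- numeric(length(tt))
  post <- tt >= delay_s
  if (any(post))
    conc[post] <- parker_aif(tt[post] - delay_s, p)$curve$conc
  aif(concentration_curve(tt, conc, "blood", "pAIF (delayed)"),
      source = "population", grid_step = grid_step)
}

add_signal_noise <- function(values, sigma, model) {
  if (sigma == 0) return(values)
  if (model == "gaussian") {
    values + stats::rnorm(length(values), 0, sigma)
  } else {
    sqrt((values + stats::rnorm(length(values), 0, sigma))^2 +
           stats::rnorm(length(values), 0, sigma)^2)
  }
}

#' Simulate a synthetic renal DCE case
#'
#' Forward-runs the whole generative chain: a Parker AIF delayed to the
#' bolus-arrival time on a 1-s grid; kidney concentration by the
#' whole-kidney forward model; aortic concentration sampled at the frame
#' times, optionally peak-clipped (hard ceiling at
#' `aorta_clip_fraction` x max, modelling inflow/saturation); both curves
#' mapped to SPGR signal with the respective pre-contrast T1; seeded noise
#' added in signal space, where MRI noise lives.
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `synthetic_case`: `config`, `truth` (data
#'   frame of per-kidney parameters and eGFR), `frame_times`, `aif_fine`
#'   (the delayed fine-grid AIF), `aorta_conc` (unclipped, frame-sampled),
#'   `aorta_signal`, `kidney_signal` (named list), and the noiseless
#'   signal curves under `noiseless`.
#' @export
simulate_case <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ft <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  aif_fine <- delayed_parker_aif(max(ft), cfg$delay_s)
  acq <- cfg$acq

  aorta_conc <- stats::approx(aif_fine$curve$times, aif_fine$curve$conc,
                              xout = ft)$y
  clipped <- pmin(aorta_conc, cfg$aorta_clip_fraction * max(aorta_conc))
  aorta_sig0 <- concentration_to_signal(
    concentration_curve(ft, clipped, "blood", "aorta"),
    acq$T10_blood, acq, cfg$m0_aorta)

  kidney_sig0 <- lapply(names(cfg$true_params), function(side) {
    ck <- forward_model(aif_fine, cfg$true_params[[side]],
                        cfg$geom[[side]], ft)
    ck$label <- paste0(side, "_kidney")
    concentration_to_signal(ck, acq$T10_tissue, acq, cfg$m0_kidney)
  })
  names(kidney_sig0) <- names(cfg$true_params)

  noisy <- with_local_seed(cfg$rng_seed, {
    a <- signal_curve(ft, add_signal_noise(aorta_sig0$values,
                                           cfg$noise_sigma_signal,
                                           cfg$noise_model), "aorta")
    k <- lapply(kidney_sig0, function(sc)
      signal_curve(ft, add_signal_noise(sc$values, cfg$noise_sigma_signal,
                                        cfg$noise_model), sc$label))
    list(aorta = a, kidneys = k)
  })

  truth <- do.call(rbind, lapply(names(cfg$true_params), function(side) {
    p <- cfg$true_params[[side]]
    data.frame(side = side, RPF = p$RPF, FF = p$FF, Tp = p$Tp, Tt = p$Tt,
               eGFR = egfr_from_params(p), Vt = cfg$geom[[side]]$Vt)
  }))
  structure(list(config = cfg, truth = truth, frame_times = ft,
                 aif_fine = aif_fine, aorta_conc = aorta_conc,
                 aorta_signal = noisy$aorta, kidney_signal = noisy$kidneys,
                 noiseless = list(aorta = aorta_sig0,
                                  kidneys = kidney_sig0)),
            class = "synthetic_case")
}

#' Build a 4D digital phantom from a synthetic case
#'
#' Paints a cylindrical aorta and two ellipsoidal kidneys onto a voxel
#' grid with the case's noiseless signal curves, adds independent
#' voxel-wise signal noise (SD = the config's `noise_sigma_signal`), and
#' returns masks that exactly match the painted regions. The ellipsoid
#' semi-axes are solved so each voxelized kidney mask volume is used as
#' that kidney's ground-truth volume, keeping the phantom self-consistent:
#' the kidney curves are generated with the realized mask volume, not the
#' nominal one.
#'
#' @param cfg A [synthetic_config()] with entries `left` and `right`.
#' @param shape Voxel grid `(nx, ny, nz)`, at least 16 x 16 x 4.
#' @param voxel_size Voxel edge lengths in mm.
#' @return List: `series` ([dynamic_series()]), `masks` (named list of
#'   [roi_mask()]), `case` (the [simulate_case()] output actually painted,
#'   with geometry updated to the mask volumes).
#' @export
make_phantom_volume <- function(cfg = synthetic_config(),
                                shape = c(48L, 48L, 16L),
                                voxel_size = c(3, 3, 4)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (any(shape < c(16, 16, 4)))
    stop("phantom grid must be at least 16 x 16 x 4", call. = FALSE)
  if (!all(c("left", "right") %in% names(cfg$true_params)))
    stop("phantom needs left and right kidney truth", call. = FALSE)
  ext <- shape * voxel_size
  cx <- (seq_len(shape[1]) - 0.5) * voxel_size[1]
  cy <- (seq_len(shape[2]) - 0.5) * voxel_size[2]
  cz <- (seq_len(shape[3]) - 0.5) * voxel_size[3]
  gx <- array(rep(cx, times = shape[2] * shape[3]), dim = shape)
  gy <- array(rep(rep(cy, each = shape[1]), times = shape[3]), dim = shape)
  gz <- array(rep(cz, each = shape[1] * shape[2]), dim = shape)
  vox_ml <- prod(voxel_size) / 1000

  # aorta: cylinder along z, anterior midline
  ao_c <- c(0.5 * ext[1], 0.18 * ext[2])
  ao_r <- 0.05 * min(ext[1], ext[2])
  aorta <- (gx - ao_c[1])^2 + (gy - ao_c[2])^2 <= ao_r^2

  kid_mask <- list()
  ell <- function(center, semi)
    ((gx - center[1]) / semi[1])^2 + ((gy - center[2]) / semi[2])^2 +
    ((gz - center[3]) / semi[3])^2 <= 1
  centers <- list(left = c(0.26 * ext[1], 0.62 * ext[2], 0.5 * ext[3]),
                  right = c(0.74 * ext[1], 0.62 * ext[2], 0.5 * ext[3]))
  for (side in c("left", "right")) {
    vt_mm3 <- cfg$geom[[side]]$Vt * 1000
    az <- min(0.45 * ext[3], 30)
    ax <- min(0.22 * ext[1], sqrt(3 * vt_mm3 / (4 * pi * az)))
    ay <- 3 * vt_mm3 / (4 * pi * az * ax)
    kid_mask[[side]] <- ell(centers[[side]], c(ax, ay, az))
  }

  # re-simulate with the realized (voxelized) volumes as ground truth
  geom2 <- cfg$geom
  for (side in c("left", "right"))
    geom2[[side]] <- kidney_geometry(sum(kid_mask[[side]]) * vox_ml,
                                     cfg$geom[[side]]$hematocrit, side)
  cfg2 <- cfg
  cfg2$geom <- geom2
  case <- simulate_case(cfg2)

  nf <- cfg$n_frames
  background <- 5
  vol <- with_local_seed(cfg$rng_seed + 1L, {
    v <- array(background, dim = c(shape, nf))
    for (f in seq_len(nf)) {
      fr <- array(background, dim = shape)
      fr[aorta] <- case$noiseless$aorta$values[f]
      fr[kid_mask$left] <- case$noiseless$kidneys$left$values[f]
      fr[kid_mask$right] <- case$noiseless$kidneys$right$values[f]
      if (cfg$noise_sigma_signal > 0)
        fr <- fr + stats::rnorm(length(fr), 0, cfg$noise_sigma_signal)
      v[, , , f] <- fr
    }
    pmax(v, 0)
  })
  series <- dynamic_series(vol, voxel_size, case$frame_times,
                           subject_id = "phantom")
  masks <- list(aorta = roi_mask(aorta, "aorta", vox_ml),
                left_kidney = roi_mask(kid_mask$left, "left_kidney", vox_ml),
                right_kidney = roi_mask(kid_mask$right, "right_kidney",
                                        vox_ml))
  list(series = series, masks = masks, case = case)
}
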