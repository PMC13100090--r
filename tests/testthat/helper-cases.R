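# shared fixtures: built in code, nothing on disk

default_acq <- acquisition_params()

# a fast fit configuration for unit tests (acceptance tests use defaults)
quick_fit_cfg <- function(seed = 1L) fit_config(n_multistart = 3L,
                                                rng_seed = seed)

# draw physiologically plausible ground-truth parameters
random_truth <- function() {
  kidney_model_params(RPF = stats::runif(1, 80, 500),
                      FF = stats::runif(1, 0.05, 0.30),
                      Tp = stats::runif(1, 3, 20),
                      Tt = stats::runif(1, 40, 300))
}

# single-kidney synthetic config wrapper
one_kidney_config <- function(p = kidney_model_params(230, 0.15, 8, 120),
                              Vt = 150, ...) {
  synthetic_config(true_params = list(left = p),
                   geom = list(left = kidney_geometry(Vt, side = "left")),
                   ...)
}

# kidney concentration curve + truth for a config (noise per config)
case_kidney_conc <- function(cfg) {
  case <- simulate_case(cfg)
  list(case = case,
       ct = signal_to_concentration(case$kidney_signal[[1]],
                                    default_acq$T10_tissue, default_acq),
       iaif = aif(signal_to_concentration(case$aorta_signal,
                                          default_acq$T10_blood,
                                          default_acq, "blood"),
                  source = "image"))
}
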