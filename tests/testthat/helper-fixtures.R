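# shared fixtures: the reference-scale device and a small seeded population
ref_geometry <- function(D_e = 30) device_geometry(D_e = D_e)
ref_acquisition <- function() acquisition_config()

# noise level giving amplitude SNR 20 for the mean 16-um cell
snr20_noise <- function(geom) blockade_fraction(16, geom$D_e, geom$L_total) / 20

small_population <- function(n = 20, seed = 11, noise_sd = 0, ...) {
  geom <- ref_geometry()
  cfg <- simulation_config(geom, ref_acquisition(), n_cells = n, seed = seed,
                           noise_sd = noise_sd,
                           recovery_mix = c(instant = 0.5, transient = 0.3,
                                            prolonged = 0.2), ...)
  sim <- simulate_trace(cfg)
  list(geom = geom, acq = cfg$acquisition, cfg = cfg,
       trace = sim$trace, truth = sim$truth)
}

# extraction results aligned with the ground-truth table
roundtrip_errors <- function(pop) {
  res <- extract_pulses(pop$trace, pop$geom, pop$acq)
  tr <- pop$truth
  stopifnot(length(res$records) <= nrow(tr))
  err <- lapply(seq_along(res$records), function(k) {
    r <- res$records[[k]]
    cls <- as.character(classify_recovery(
      ifelse(r$dT_r_censored, NA_real_, r$dT_r_ms), 40, r$dT_r_censored))
    data.frame(
      np_rel = abs(r$dI_np - tr$dI_np_true[k]) / tr$dI_np_true[k],
      c_rel = abs(r$dI_c - tr$dI_c_true[k]) / tr$dI_c_true[k],
      dT_cont_ms = abs(r$dT_cont_ms - tr$dT_cont_true[k]),
      diam_rel = abs(invert_cell_diameter(r$dI_np, pop$geom$D_e, pop$geom$L_total) -
                       tr$D_cell_true[k]) / tr$D_cell_true[k],
      class_ok = cls == tr$recovery_class_true[k])
  })
  list(res = res, errors = do.call(rbind, err))
}
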