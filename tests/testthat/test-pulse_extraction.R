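test_that("zero-phase low-pass: unit DC gain, strong stop-band, noise reduction", {
  fs <- 50000
  t <- (0:49999) / fs
  const <- raw_trace(t, rep(2.5, length(t)), meta = list(sampling_rate = fs))
  out <- lowpass_filter(const, 5000)
  expect_lt(max(abs(out$i - 2.5)) / 2.5, 1e-12)

  sine <- raw_trace(t, sin(2 * pi * 5000 * 10 * t), meta = list(sampling_rate = fs))
  att <- max(abs(lowpass_filter(sine, 5000)$i[1000:49000]))
  expect_lt(att, 10^(-20 / 20))  # >= 20 dB down at 10x cutoff

  set.seed(5)
  noisy <- raw_trace(t, 1 + rnorm(length(t), 0, 1e-3),
                     meta = list(sampling_rate = fs))
  expect_lt(sd(lowpass_filter(noisy, 5000)$i), sd(noisy$i))

  expect_error(lowpass_filter(const, 30000), "Nyquist")
})

test_that("event detection finds every simulated cell and nothing on flat traces", {
  pop <- small_population(n = 5, seed = 31)
  filt <- lowpass_filter(pop$trace, pop$acq$lowpass_cutoff)
  det <- detect_events(filt, pop$geom)
  expect_identical(nrow(det$windows), 5L)
  expect_true(all(det$windows$flag == "ok"))
  # window edges sit within the filter rise time (~1/cutoff) of the truth
  rise_s <- 1 / pop$acq$lowpass_cutoff
  expect_true(all(abs(det$windows$t_start - pop$truth$event_start_s) < rise_s))
  expect_true(all(abs(det$windows$t_end - pop$truth$event_end_s) < rise_s))
  # disjoint and sorted
  expect_true(all(diff(det$windows$t_start) > 0))
  expect_true(all(det$windows$t_end[-5] < det$windows$t_start[-1]))

  flat <- raw_trace((0:30000) / 5e4, rep(1, 30001),
                    meta = list(sampling_rate = 5e4))
  expect_identical(nrow(detect_events(lowpass_filter(flat, 5000),
                                      pop$geom)$windows), 0L)
})

test_that("overlapping events are flagged or rejected, never phenotyped", {
  pop <- small_population(n = 4, seed = 3, inject_coincidence = TRUE)
  res <- extract_pulses(pop$trace, pop$geom, pop$acq)
  expect_identical(res$n_accepted, 4L)
  expect_gte(res$n_rejected, 1L)
  expect_identical(res$n_detected, res$n_accepted + res$n_rejected)
  expect_match(paste(res$rejects$reason, collapse = " "), "coincidence")
})

test_that("segmentation reproduces the node-pore-contraction anatomy", {
  pop <- small_population(n = 3, seed = 8)
  filt <- lowpass_filter(pop$trace, pop$acq$lowpass_cutoff)
  det <- detect_events(filt, pop$geom)
  sp <- segment_event(det, 1, filt, pop$geom,
                      raw = pop$trace$i / det$baseline)
  expect_identical(sum(sp$segment_kind == "pore_pre"), pop$geom$n_pre_pairs)
  expect_identical(sum(sp$segment_kind == "contraction"), 1L)
  expect_identical(sum(sp$segment_kind == "pore_post"), pop$geom$n_post_pairs)
  pre <- sp$dI[sp$segment_kind == "pore_pre"]
  expect_lt(diff(range(pre)) / mean(pre), 1e-9)   # equal within (zero) noise
  expect_gt(sp$dI[sp$segment_kind == "contraction"], max(pre))
})

test_that("windows with too few plateaus raise a segmentation error", {
  fs <- 5e4
  t <- (0:39999) / fs
  i <- rep(1, length(t))
  i[10000:10500] <- 1 - 2e-3   # a single naked square drop
  tr <- raw_trace(t, i, meta = list(sampling_rate = fs))
  filt <- lowpass_filter(tr, 5000)
  geom <- ref_geometry()
  det <- detect_events(filt, geom)
  expect_identical(nrow(det$windows), 1L)
  expect_error(segment_event(det, 1, filt, geom), "segmentation error")
})

test_that("recovery time is measured by interpolated post-pore amplitudes", {
  sub <- function(kind, idx, t0, dur, dI)
    data.frame(segment_kind = kind, index = idx, t_start = t0,
               t_end = t0 + dur, dI = dI, dT_ms = dur * 1000)
  base <- rbind(
    sub("pore_pre", 1, 0.000, 0.003, 1e-3),
    sub("pore_pre", 2, 0.006, 0.003, 1e-3),
    sub("contraction", 1, 0.012, 0.030, 3e-3))
  post_t <- 0.042 + 0.006 * (0:4)
  # symmetric event: first post pore equals dI_np -> instant
  sym <- rbind(base, sub("pore_post", 1:5, post_t, 0.003, 1e-3))
  r <- measure_event(sym, window = 40)
  expect_equal(r$dT_r_ms, 0)
  expect_false(r$dT_r_censored)
  expect_equal(r$dI_np, 1e-3)
  expect_equal(r$dT_cont_ms, 30)

  # amplitudes rising through the 95% criterion between midpoints 2 and 3
  ramp <- rbind(base, sub("pore_post", 1:5, post_t, 0.003,
                          1e-3 * c(0.80, 0.90, 0.97, 0.99, 1.0)))
  r2 <- measure_event(ramp, window = 40, tolerance = 0.05)
  mid <- post_t + 0.0015 - 0.042
  expected <- (mid[2] + (0.95 - 0.90) / (0.97 - 0.90) * (mid[3] - mid[2])) * 1000
  expect_equal(r2$dT_r_ms, expected, tolerance = 1e-12)

  # never recovering -> censored at the window
  low <- rbind(base, sub("pore_post", 1:5, post_t, 0.003, 1e-3 * 0.7))
  r3 <- measure_event(low, window = 40)
  expect_true(r3$dT_r_censored)

  # contraction shallower than pores is physically inconsistent
  bad <- rbind(sub("pore_pre", 1, 0, 0.003, 5e-3),
               sub("contraction", 1, 0.012, 0.03, 3e-3),
               sub("pore_post", 1, 0.05, 0.003, 5e-3))
  expect_error(measure_event(bad), "inconsistent")
})

test_that("measured transient recovery lands within one post-pore spacing of truth", {
  geom <- ref_geometry()
  cfg <- simulation_config(geom, n_cells = 12, seed = 13,
                           recovery_mix = c(instant = 0, transient = 1,
                                            prolonged = 0))
  sim <- simulate_trace(cfg)
  res <- extract_pulses(sim$trace, geom, cfg$acquisition)
  expect_identical(res$n_accepted, 12L)
  spacing_ms <- (geom$node_length + geom$pore_length) / cfg$speed_node
  for (k in seq_len(12)) {
    r <- res$records[[k]]
    expect_false(r$dT_r_censored)
    expect_lt(abs(r$dT_r_ms - sim$truth$dT_r_true[k]), spacing_ms)
  }
})

test_that("baseline drift is tracked and amplitudes stay accurate under it", {
  pop <- small_population(n = 8, seed = 17, drift_slope = 0.01)
  rt <- roundtrip_errors(pop)
  expect_identical(rt$res$n_accepted, 8L)
  expect_lt(max(rt$errors$np_rel), 1e-3)
  expect_true(all(rt$errors$class_ok))
})
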