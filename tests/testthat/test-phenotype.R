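test_that("blockade relation: limits, pole, strict monotonicity", {
  expect_equal(blockade_fraction(0, 30, 5000), 0)
  expect_equal(blockade_fraction(15, 30, 5000), 8.3333e-4, tolerance = 1e-4)
  d <- seq(1, 30, by = 0.5)
  expect_true(all(diff(blockade_fraction(d, 30, 5000)) > 0))
  expect_error(blockade_fraction(30 * 0.8^(-1 / 3) * 1.001, 30, 5000), "pole")
})

test_that("diameter inversion round-trips the forward relation across the domain", {
  for (d in 5:25) {
    fr <- blockade_fraction(d, 30, 5000)
    expect_equal(invert_cell_diameter(fr, 30, 5000), d, tolerance = 1e-9)
  }
  expect_equal(invert_cell_diameter(8.3333e-4, 30, 5000), 15, tolerance = 1e-4)
  # continuity at 0+: d ~ (fraction * De^2 L)^(1/3)
  expect_equal(invert_cell_diameter(1e-9, 30, 5000), (1e-9 * 30^2 * 5000)^(1 / 3),
               tolerance = 1e-6)
  expect_error(invert_cell_diameter(1e6, 30, 5000), "attainable")
  expect_error(invert_cell_diameter(0, 30, 5000), "domain")
})

test_that("microsphere calibration recovers a planted effective diameter", {
  fr10 <- blockade_fraction(10, 30, 5000)
  cal <- calibrate_effective_diameter(fr10, 10, 5000)
  expect_equal(cal$D_e, 30, tolerance = 1e-6)
  expect_equal(cal$residual_rms, 0, tolerance = 1e-6)

  # spread of observed fractions: fitted D_e sits between the single-sphere
  # solutions (blockade is monotone in D_e)
  lo <- calibrate_effective_diameter(fr10 * 0.9, 10, 5000)$D_e
  hi <- calibrate_effective_diameter(fr10 * 1.1, 10, 5000)$D_e
  mid <- calibrate_effective_diameter(c(fr10 * 0.9, fr10 * 1.1), 10, 5000)$D_e
  expect_true(mid > min(lo, hi) && mid < max(lo, hi))
  expect_error(calibrate_effective_diameter(numeric(0), 10, 5000), "positive")
})

test_that("oblate-spheroid inversion reproduces the worked deformation example", {
  geom <- device_geometry(w_c = 12, h_channel = 30, L_c = 2055, D_e = 30)
  dg <- deformed_geometry(2.389e-3, geom)
  expect_equal(dg$V_deform_um3, 2.389e-3 * 2055 * 12 * 30, tolerance = 1e-12)
  expect_equal(dg$V_deform_um3, 1767.3, tolerance = 1e-3)
  expect_equal(dg$L_deform_um, sqrt(6 * dg$V_deform_um3 / (12 * pi)),
               tolerance = 1e-12)
  expect_equal(dg$L_deform_um, 16.77, tolerance = 1e-3)
  # a 15-um cell with conserved volume elongates to delta = sqrt(d / w_c)
  frac <- (pi * 15^3 / 6) / (2055 * 12 * 30)
  L <- deformed_geometry(frac, geom)$L_deform_um
  expect_equal(transverse_deformation(L, 15), sqrt(15 / 12), tolerance = 1e-9)
  expect_equal(transverse_deformation(L, 15), 1.118, tolerance = 1e-3)
  expect_error(deformed_geometry(1.2, geom), "implausible")
})

test_that("strain formula and flags behave at the reference regimes", {
  expect_equal(compressive_strain(15, 12), 0.2)
  expect_equal(compressive_strain(17.142857, 12), 0.3, tolerance = 1e-6)
  expect_equal(compressive_strain(12, 12), 0)
  expect_lt(compressive_strain(10, 12), 0)  # un-deformed cells allowed
})

test_that("wCDI matches the closed form, its pi-decomposition, and monotonicity", {
  geom <- device_geometry(L_c = 2055, h_channel = 30, w_c = 12, D_e = 30)
  flow <- flow_context(U_flow = 50)
  expect_equal(compute_wcdi(15, 30, flow, geom), (2055 / 1500) * 0.5,
               tolerance = 1e-12)
  expect_equal(compute_wcdi(15, 60, flow, geom),
               compute_wcdi(15, 30, flow, geom) / 2, tolerance = 1e-12)

  pt <- compute_pi_terms(15, 30, flow, geom)
  expect_equal(pt$pi3, 0.5)
  expect_equal(pt$pi4, 68.5)
  expect_equal(pt$pi2 * pt$pi3 * pt$pi4, compute_wcdi(15, 30, flow, geom),
               tolerance = 1e-12)
  expect_true(is.na(pt$pi1))
  pt2 <- compute_pi_terms(15, 30, flow_context(50, mu = 1e-3, E = 1000), geom)
  expect_gt(pt2$pi1, 0)

  # strictly decreasing in transit time, increasing in diameter
  dts <- seq(10, 60, by = 5)
  expect_true(all(diff(compute_wcdi(15, dts, flow, geom)) < 0))
  ds <- seq(10, 25, by = 1)
  expect_true(all(diff(compute_wcdi(ds, 30, flow, geom)) > 0))
})

test_that("wCDI is invariant under consistent unit rescaling", {
  geom_um <- device_geometry(L_c = 2055, h_channel = 30, w_c = 12, D_e = 30)
  # same device expressed in mm and s: lengths / 1000, times * 1000,
  # velocity in mm/s = um/ms numerically
  w_um <- compute_wcdi(15, 30, flow_context(50), geom_um)
  w_mm <- (2.055 / (50 * 0.030)) * (0.015 / 0.030)
  expect_equal(w_um, w_mm, tolerance = 1e-12)
})

test_that("flow velocity comes from the last pre-contraction pore", {
  pop <- small_population(n = 3, seed = 23)
  res <- extract_pulses(pop$trace, pop$geom, pop$acq)
  fl <- estimate_flow_velocity(res$records[[1]], pop$geom)
  expect_equal(fl$U_flow, pop$cfg$speed_node, tolerance = 1e-2)
  expect_equal(fl$U_c, pop$geom$L_c / res$records[[1]]$dT_cont_ms,
               tolerance = 1e-12)
  expect_equal(pop$geom$L_c / 30, 68.5)  # 30 ms transit -> 68.5 um/ms
})

test_that("recovery classes partition and respect the window boundary", {
  expect_identical(as.character(classify_recovery(0)), "instant")
  expect_identical(as.character(classify_recovery(25)), "transient")
  expect_identical(as.character(classify_recovery(40)), "transient")  # boundary
  expect_identical(as.character(classify_recovery(40.0001)), "prolonged")
  expect_identical(as.character(classify_recovery(NA, censored = TRUE)),
                   "prolonged")
  x <- classify_recovery(c(0, 1, 39, 40, 41, NA), 40,
                         c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(anyNA(x))
  expect_error(classify_recovery(-1), ">= 0")
})

test_that("cortical tension inverts the Laplace relation to machine precision", {
  expect_equal(cortical_tension(0.3, 4, 8), 1.2, tolerance = 1e-15)
  expect_equal(cortical_tension(0.3, 4, 1e9), 0.3 * 4 / 2, tolerance = 1e-6)
  expect_equal(cortical_tension(0.15, 4, 8), 0.6, tolerance = 1e-15)
  expect_error(cortical_tension(0.3, 8, 4), "R_c > R_p")
  # closed-form identity on random inputs
  set.seed(7)
  for (rep in 1:25) {
    Rp <- runif(1, 2, 6); Rc <- Rp + runif(1, 0.5, 10); dP <- runif(1, 0.03, 0.3)
    Teff <- cortical_tension(dP, Rp, Rc)
    expect_equal(2 * Teff * (1 / Rp - 1 / Rc), dP, tolerance = 1e-12)
  }
})

test_that("size-corrected wCDI overlaps for same-stiffness populations of different size", {
  geom <- ref_geometry()
  w_mean <- function(dmean, seed) {
    cfg <- simulation_config(geom, n_cells = 40, seed = seed,
                             diameter_mean = dmean, diameter_sd = 1)
    sim <- simulate_trace(cfg)
    res <- extract_pulses(sim$trace, geom, cfg$acquisition)
    ph <- phenotype_cells(res$records, geom)
    mean(ph$wCDI)
  }
  small <- w_mean(14, 101)
  large <- w_mean(19, 102)
  expect_lt(abs(small - large) / small, 0.1)  # within sampling error
})
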