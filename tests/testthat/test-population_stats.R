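test_that("population summary handles edge cases and removes 3-sd outliers", {
  mk <- function(w, cls = "instant", strain = 0.2)
    data.frame(wCDI = w, recovery_class = cls, strain = strain)
  s <- summarize_population(mk(c(1, 1, 1)))
  expect_equal(s$wcdi_mean, 1)
  expect_equal(s$wcdi_sd, 0)
  expect_identical(s$outlier_count, 0L)

  set.seed(41)
  w <- c(rnorm(99, 0.7, 0.02), 10)
  s2 <- summarize_population(mk(w), outlier_sd = 3)
  expect_identical(s2$n, 99L)
  expect_identical(s2$outlier_count, 1L)
  expect_error(summarize_population(mk(1)), "n >= 2")
})

test_that("recovery proportions of a simulated mixed population are recovered exactly", {
  pop <- small_population(n = 40, seed = 19)
  res <- extract_pulses(pop$trace, pop$geom, pop$acq)
  ph <- phenotype_cells(res$records, pop$geom)
  s <- summarize_population(ph, label = "sim")
  expect_equal(sum(s$recovery_proportions), 1, tolerance = 1e-12)
  truth_prop <- as.numeric(table(factor(pop$truth$recovery_class_true,
                                        levels = s$recovery_classes))) / 40
  expect_equal(s$recovery_proportions, truth_prop, tolerance = 1e-12)
})

test_that("normal overlap: limits, symmetry, scale equivariance", {
  expect_equal(overlap_coefficient(0.7, 0.1, 0.7, 0.1), 1)
  expect_lt(overlap_coefficient(0, 1, 100, 1), 1e-10)
  expect_equal(overlap_coefficient(0.7, 0.1, 1.2, 0.13),
               overlap_coefficient(1.2, 0.13, 0.7, 0.1), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:20) {
    m1 <- runif(1, -2, 2); m2 <- runif(1, -2, 2)
    s1 <- runif(1, 0.05, 2); s2 <- runif(1, 0.05, 2); c0 <- runif(1, 0.1, 10)
    expect_equal(overlap_coefficient(m1, s1, m2, s2),
                 overlap_coefficient(c0 * m1, c0 * s1, c0 * m2, c0 * s2),
                 tolerance = 1e-9)
  }
  expect_error(overlap_coefficient(0, -1, 1, 1), "standard deviations")
})

test_that("analytic overlap agrees with brute-force grid integration", {
  set.seed(17)
  grid_overlap <- function(m1, s1, m2, s2) {
    lo <- min(m1 - 10 * s1, m2 - 10 * s2); hi <- max(m1 + 10 * s1, m2 + 10 * s2)
    x <- seq(lo, hi, length.out = 200001)
    sum(pmin(dnorm(x, m1, s1), dnorm(x, m2, s2))) * (x[2] - x[1])
  }
  for (rep in 1:100) {
    m1 <- runif(1, -3, 3); m2 <- runif(1, -3, 3)
    s1 <- runif(1, 0.05, 3); s2 <- runif(1, 0.05, 3)
    expect_equal(overlap_coefficient(m1, s1, m2, s2),
                 grid_overlap(m1, s1, m2, s2), tolerance = 1e-6)
  }
})

test_that("EM: single-component data, monotone likelihood, identifiability flag", {
  set.seed(12)
  x <- rnorm(500, 0.865, 0.107)
  fit <- em_mixture_fraction(x, list(mean = 0.865, sd = 0.107),
                             list(mean = 1.133, sd = 0.144),
                             freeze_components = TRUE)
  expect_gte(fit$alpha, 0.95)
  expect_true(all(diff(fit$log_likelihood) > -1e-9))
  expect_true(fit$converged)
  free <- em_mixture_fraction(x, list(mean = 0.865, sd = 0.107),
                              list(mean = 1.133, sd = 0.144))
  expect_true(all(diff(free$log_likelihood) > -1e-9))

  same <- em_mixture_fraction(x, list(mean = 1, sd = 0.1),
                              list(mean = 1, sd = 0.1))
  expect_true("identifiability" %in% same$flags)
  expect_false(same$converged)
  expect_error(em_mixture_fraction(x[1:5], list(mean = 0, sd = 1),
                                   list(mean = 1, sd = 1)), "n >= 10")
})

test_that("EM matches an independent mixture fitter on the same data", {
  library(mclust)
  set.seed(2)
  x <- c(rnorm(150, 0.865, 0.107), rnorm(350, 1.133, 0.144))
  ours <- em_mixture_fraction(x, list(mean = 0.865, sd = 0.107),
                              list(mean = 1.133, sd = 0.144))
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # same (or better) optimum of the same likelihood
  expect_gte(tail(ours$log_likelihood, 1), ref$loglik - 0.1)
  expect_lt(abs(ours$alpha - ref$parameters$pro[order(ref$parameters$mean)][1]),
            0.05)
})

test_that("frozen-component EM recovers a planted 30/70 lineage fraction", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    n1 <- rbinom(1, 500, 0.30)
    x <- c(rnorm(n1, 0.865, 0.107), rnorm(500 - n1, 1.133, 0.144))
    fit <- em_mixture_fraction(x, list(mean = 0.865, sd = 0.107),
                               list(mean = 1.133, sd = 0.144),
                               freeze_components = TRUE)
    expect_true(all(diff(fit$log_likelihood) > -1e-9))
    fit$alpha - 0.30
  }, numeric(1))
  expect_lte(mean(abs(errs)), 0.05)
})

test_that("recovery-profile chi-square matches the hand-computed statistic", {
  mk_sum <- function(counts, label) structure(list(
    label = label, n = sum(counts),
    recovery_counts = counts,
    recovery_classes = c("instant", "transient", "prolonged")),
    class = "nps_population_summary")
  same <- compare_recovery_profiles(mk_sum(c(50, 30, 20), "A"),
                                    mk_sum(c(50, 30, 20), "B"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- compare_recovery_profiles(mk_sum(c(50, 30, 20), "A"),
                                   mk_sum(c(20, 30, 50), "B"))
  # expected counts 35/30/35 per row: chi2 = 4 * 15^2 / 35
  expect_equal(res$statistic, 4 * 225 / 35, tolerance = 1e-12)
  expect_identical(res$dof, 2L)
  expect_error(compare_recovery_profiles(mk_sum(c(0, 0, 0), "A"),
                                         mk_sum(c(1, 2, 3), "B")), "degenerate")
})

test_that("wCDI comparison: identical, shifted, and degenerate samples", {
  x <- rnorm(50, 0.7, 0.1)
  same <- compare_wcdi(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$method, "paired")

  shift <- compare_wcdi(x, x + 10 * sd(x))
  expect_lt(shift$p_value, 1e-6)

  welch <- compare_wcdi(x, rnorm(30, 1.2, 0.1))
  expect_identical(welch$method, "welch_unpaired_dialect")
  expect_error(compare_wcdi(1, c(1, 2)), "n >= 2")
  expect_error(compare_wcdi(rep(1, 5), rep(2, 5)), "degenerate")
})
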