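#' Summarize a phenotyped cell population
#'
#' Removes wCDI outliers beyond `outlier_sd` standard deviations of the mean
#' (single pass), then reports wCDI mean/sd, mean strain, and the proportions
#' of the three recovery classes over the accepted cells.
#'
#' @param phenotypes data.frame from [phenotype_cells()] (or
#'   [read_phenotypes()]).
#' @param outlier_sd outlier cut in sd units (3 by convention).
#' @param label population label carried into the summary.
#' @return Object of class `nps_population_summary`: `label`, `n`,
#'   `wcdi_mean`, `wcdi_sd`, `strain_mean`, `recovery_proportions` (named
#'   fractions summing to 1), `recovery_counts`, `outlier_count`.
#' @export
summarize_population <- function(phenotypes, outlier_sd = 3, label = "population") {
  df <- as.data.frame(phenotypes)
  if (nrow(df) < 2L)
    stop("insufficient data: population summary needs n >= 2", call. = FALSE)
  w <- df$wCDI
  m <- mean(w); s <- stats::sd(w)
  keep <- if (s > 0) abs(w - m) <= outlier_sd * s else rep(TRUE, length(w))
  acc <- df[keep, ]
  cls <- factor(acc$recovery_class, levels = c("instant", "transient", "prolonged"))
  counts <- table(cls)
  structure(list(
    label = label, n = nrow(acc),
    wcdi_mean = mean(acc$wCDI), wcdi_sd = stats::sd(acc$wCDI),
    strain_mean = mean(acc$strain),
    recovery_proportions = as.numeric(counts) / nrow(acc),
    recovery_counts = as.integer(counts),
    recovery_classes = names(counts),
    outlier_count = sum(!keep)), class = "nps_population_summary")
}

#' @export
print.nps_population_summary <- function(x, ...) {
  cat(sprintf("%s: n=%d, wCDI %.3f +/- %.3f, mean strain %.3f, %d outlier(s) removed\n",
              x$label, x$n, x$wcdi_mean, x$wcdi_sd, x$strain_mean, x$outlier_count))
  cat(sprintf("  recovery: %s\n",
              paste(sprintf("%s %.1f%%", x$recovery_classes,
                            100 * x$recovery_proportions), collapse = ", ")))
  invisible(x)
}

#' Overlap coefficient of two normal distributions
#'
#' The integral of the pointwise minimum of two normal densities,
#' \eqn{\int \min(f_1, f_2)\,dx}, computed analytically: the densities cross
#' where the log-density difference — a quadratic in x — vanishes (at most two
#' roots), and within each interval the pointwise minimum is a single
#' density, so the integral is a sum of normal CDF increments. Symmetric in
#' its arguments, invariant under common location/scale changes, and in
#' `[0, 1]` (1 iff the distributions coincide).
#'
#' @param m1,s1 mean and sd of the first normal (`s1 > 0`).
#' @param m2,s2 mean and sd of the second normal.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' overlap_coefficient(0.699, 0.106, 1.230, 0.13) # ~0.024
#' @export
overlap_coefficient <- function(m1, s1, m2, s2) {
  if (s1 <= 0 || s2 <= 0)
    stop("parameter error: standard deviations must be > 0", call. = FALSE)
  if (m1 == m2 && s1 == s2) return(1)
  # log f1 - log f2 = a x^2 + b x + c
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  roots <- if (abs(a) < .Machine$double.eps * (1 / s1^2 + 1 / s2^2)) {
    if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) numeric(0) else sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  cuts <- c(-Inf, roots, Inf)
  total <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k]; hi <- cuts[k + 1L]
    probe <- if (is.infinite(lo) && is.infinite(hi)) (m1 + m2) / 2
             else if (is.infinite(lo)) hi - max(s1, s2)
             else if (is.infinite(hi)) lo + max(s1, s2)
             else (lo + hi) / 2
    use1 <- stats::dnorm(probe, m1, s1, log = TRUE) <=
            stats::dnorm(probe, m2, s2, log = TRUE)
    m <- if (use1) m1 else m2; s <- if (use1) s1 else s2
    total <- total + (stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s))
  }
  min(max(total, 0), 1)
}

#' Two-component Gaussian mixture decomposition by EM
#'
#' Estimates the fraction `alpha` of component 1 in a univariate sample
#' (e.g. the myoepithelial fraction of a mixed mammary-epithelial wCDI
#' distribution) by expectation-maximization, initialized from reference
#' component parameters (e.g. the fitted distributions of FACS-sorted
#' lineages). The E-step computes responsibilities; the M-step updates the
#' weights and — unless `freeze_components` — the component means and sds.
#' The log-likelihood is non-decreasing across iterations; convergence is
#' declared when its improvement falls below `tol`.
#'
#' @param values numeric sample, `n >= 10`.
#' @param init1,init2 lists `list(mean=, sd=)` initializing the two
#'   components; `init1` defines which component `alpha` refers to.
#' @param freeze_components if `TRUE`, only the mixing weights are updated
#'   (reference-component variant).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param weight1 initial weight of component 1.
#' @return Object of class `nps_mixture`: `alpha`, `comp1`, `comp2`,
#'   `log_likelihood` (trajectory), `n_iter`, `converged`, `flags`
#'   (e.g. `identifiability` when `init1 == init2`, `sd_floor` when a
#'   component collapsed and was restarted on the floor).
#' @export
em_mixture_fraction <- function(values, init1, init2, freeze_components = FALSE,
                                tol = 1e-8, max_iter = 500, weight1 = 0.5) {
  x <- as.numeric(values)
  if (length(x) < 10L) stop("EM requires n >= 10", call. = FALSE)
  if (init1$sd <= 0 || init2$sd <= 0)
    stop("initial sds must be > 0", call. = FALSE)
  flags <- character(0)
  if (identical(init1$mean, init2$mean) && identical(init1$sd, init2$sd))
    flags <- c(flags, "identifiability")
  m <- c(init1$mean, init2$mean); s <- c(init1$sd, init2$sd)
  w <- c(weight1, 1 - weight1)
  sd_floor <- 1e-6 * stats::sd(x)
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step in log space for stability
    l1 <- log(w[1]) + stats::dnorm(x, m[1], s[1], log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, m[2], s[2], log = TRUE)
    mx <- pmax(l1, l2)
    lse <- mx + log(exp(l1 - mx) + exp(l2 - mx))
    ll <- c(ll, sum(lse))
    r1 <- exp(l1 - lse)
    # M-step
    n1 <- sum(r1); n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    if (!freeze_components) {
      m <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
      s_new <- sqrt(c(sum(r1 * (x - m[1])^2) / n1,
                      sum((1 - r1) * (x - m[2])^2) / n2))
      if (any(s_new < sd_floor)) {
        s_new <- pmax(s_new, sd_floor)
        flags <- union(flags, "sd_floor")
      }
      s <- s_new
    }
    if (it > 1 && ll[it] - ll[it - 1] < tol) { converged <- TRUE; break }
  }
  if ("identifiability" %in% flags) converged <- FALSE
  structure(list(alpha = w[1],
                 comp1 = list(mean = m[1], sd = s[1]),
                 comp2 = list(mean = m[2], sd = s[2]),
                 log_likelihood = ll, n_iter = length(ll),
                 converged = converged, flags = flags,
                 init = list(init1 = init1, init2 = init2,
                             freeze_components = freeze_components)),
            class = "nps_mixture")
}

#' @export
print.nps_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: alpha = %.3f (comp1 N(%.3f, %.3f^2), comp2 N(%.3f, %.3f^2))\n",
              x$alpha, x$comp1$mean, x$comp1$sd, x$comp2$mean, x$comp2$sd))
  cat(sprintf("  %d iteration(s), converged: %s%s\n", x$n_iter, x$converged,
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Chi-square comparison of recovery-type profiles
#'
#' Tests whether two populations share the same distribution over the three
#' recovery classes (instant/transient/prolonged) with a chi-square test on
#' the 2 x 3 contingency table of counts.
#'
#' @param summaryA,summaryB `nps_population_summary` objects (their
#'   `recovery_counts` are used).
#' @return list: `statistic`, `dof` (2), `p_value`, `table`.
#' @export
compare_recovery_profiles <- function(summaryA, summaryB) {
  stopifnot(inherits(summaryA, "nps_population_summary"),
            inherits(summaryB, "nps_population_summary"))
  tab <- rbind(summaryA$recovery_counts, summaryB$recovery_counts)
  rownames(tab) <- c(summaryA$label, summaryB$label)
  if (any(rowSums(tab) == 0))
    stop("degenerate table: a population has zero total count", call. = FALSE)
  if (all(tab[1, ] == tab[2, ])) {
    return(list(statistic = 0, dof = ncol(tab) - 1L, p_value = 1, table = tab))
  }
  if (any(colSums(tab) == 0))
    stop("degenerate table: a recovery class has expected count zero",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}

#' Compare wCDI between two populations by t-test
#'
#' Paired t-test when the samples have equal length (the screening protocol
#' pairs populations of equal n); Welch's two-sample t-test otherwise,
#' flagged as a dialect in the result.
#'
#' @param valuesA,valuesB numeric wCDI samples, `n >= 2` each.
#' @return list: `statistic`, `dof`, `p_value`, `method`.
#' @export
compare_wcdi <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("t-test requires n >= 2 in each population", call. = FALSE)
  if (stats::sd(valuesA) == 0 && stats::sd(valuesB) == 0)
    stop("degenerate comparison: zero variance in both samples", call. = FALSE)
  paired <- length(valuesA) == length(valuesB)
  if (paired && stats::sd(valuesA - valuesB) == 0) {
    # constant pairwise difference: t is 0 (identical samples) or infinite
    # (exact shift), by continuity
    d <- mean(valuesA - valuesB)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                dof = length(valuesA) - 1L,
                p_value = if (d == 0) 1 else 0, method = "paired"))
  }
  tt <- if (paired) stats::t.test(valuesA, valuesB, paired = TRUE)
        else stats::t.test(valuesA, valuesB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
       p_value = tt$p.value,
       method = if (paired) "paired" else "welch_unpaired_dialect")
}
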