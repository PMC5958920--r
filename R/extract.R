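#' Zero-phase low-pass filter
#'
#' Filters the trace in the frequency domain with the squared-magnitude
#' response of an order-`order` Butterworth low-pass,
#' \eqn{H(f) = 1 / (1 + (f/f_c)^{2n})}, applied with zero phase. The DC gain
#' is exactly 1 (a constant trace is returned unchanged) and the impulse
#' response is symmetric, so step edges keep their half-amplitude crossing at
#' the true edge time — the property the sub-pulse boundary refinement in
#' [segment_event()] relies on. The trace is edge-padded before the FFT to
#' suppress wrap-around.
#'
#' @param trace an `nps_trace`.
#' @param cutoff cutoff frequency (Hz), must be below Nyquist.
#' @param order Butterworth order of the magnitude prototype.
#' @return A filtered `nps_trace` on the same time base.
#' @export
lowpass_filter <- function(trace, cutoff, order = 4) {
  stopifnot(inherits(trace, "nps_trace"))
  fs <- trace$meta$sampling_rate
  if (cutoff >= fs / 2)
    stop("filter parameter error: cutoff must be below the Nyquist frequency",
         call. = FALSE)
  n <- length(trace$i)
  pad <- min(n, ceiling(fs / cutoff) * 4L)
  x <- c(rep(trace$i[1], pad), trace$i, rep(trace$i[n], pad))
  m <- stats::nextn(length(x), c(2, 3, 5))
  x <- c(x, rep(trace$i[n], m - length(x)))
  f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) * fs / m
  H <- 1 / (1 + (f / cutoff)^(2 * order))
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / m
  trace$i <- y[pad + seq_len(n)]
  trace$meta$lowpass_cutoff <- cutoff
  trace
}

#' Estimate the slowly varying baseline of a trace
#'
#' Median of non-overlapping blocks (`block_ms`) followed by a running median
#' across blocks spanning `span_ms`, linearly interpolated back to the sample
#' grid. Samples marked in `exclude` (detected events, in the second pass of
#' [detect_events()]) are left out of the block medians; blocks with too few
#' clean samples are filled by linear interpolation from their neighbours, so
#' the baseline is bridged under events rather than dragged down by them.
#'
#' @param trace an `nps_trace`.
#' @param block_ms block width in ms.
#' @param span_ms running-median span in ms; must be much longer than one
#'   event (default 500 ms).
#' @param exclude optional logical vector (same length as the trace) marking
#'   samples to leave out of the estimate.
#' @return numeric vector of per-sample baseline estimates.
#' @export
estimate_baseline <- function(trace, block_ms = 20, span_ms = 500,
                              exclude = NULL) {
  fs <- trace$meta$sampling_rate
  n <- length(trace$i)
  bl <- max(2L, round(block_ms / 1000 * fs))
  nb <- n %/% bl
  if (nb < 5L)
    stop("baseline error: trace too short for baseline estimation", call. = FALSE)
  idx <- seq_len(nb * bl)
  grp <- rep(seq_len(nb), each = bl)
  x <- trace$i[idx]
  if (!is.null(exclude)) {
    # partially masked blocks are dropped entirely: the median of one-sided
    # clean samples is biased under drift, and interpolation across events
    # from fully clean blocks is exact for slow (locally linear) drift
    keep <- !exclude[idx]
    n_clean <- tapply(keep, grp, sum)
    bmed <- rep(NA_real_, nb)
    ok <- n_clean >= 0.9 * bl
    bmed[ok] <- tapply(x[keep], grp[keep], stats::median)[as.character(which(ok))]
  } else {
    bmed <- as.numeric(tapply(x, grp, stats::median))
  }
  centers <- (seq_len(nb) - 0.5) * bl
  if (anyNA(bmed)) {
    if (all(is.na(bmed)))
      stop("baseline error: no clean baseline blocks found", call. = FALSE)
    bmed <- stats::approx(centers[!is.na(bmed)], bmed[!is.na(bmed)],
                          xout = centers, rule = 2)$y
  }
  k <- max(3L, round(span_ms / block_ms))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (nb %% 2 == 1) nb else nb - 1L)
  smooth <- stats::runmed(bmed, k, endrule = "median")
  out <- stats::approx(centers, smooth, xout = seq_len(n), rule = 2)$y
  # linear extrapolation beyond the first/last block centers, so a drifting
  # baseline is not flattened at the trace edges
  xs <- seq_len(n)
  head_i <- xs < centers[1]
  if (any(head_i))
    out[head_i] <- smooth[1] + (xs[head_i] - centers[1]) *
      (smooth[2] - smooth[1]) / (centers[2] - centers[1])
  tail_i <- xs > centers[nb]
  if (any(tail_i))
    out[tail_i] <- smooth[nb] + (xs[tail_i] - centers[nb]) *
      (smooth[nb] - smooth[nb - 1]) / (centers[nb] - centers[nb - 1])
  out
}

#' Detect candidate cell-transit events in a trace
#'
#' Normalizes the (already filtered) trace by its estimated baseline, then
#' finds excursions below `baseline - k * sigma` (sigma is a robust noise
#' estimate from first differences). Excursions separated by less than
#' `merge_gap_ms` — node passages, where the current returns to baseline
#' mid-event — are merged into one candidate window. Windows are then vetted
#' against the geometry: a window whose number of low plateaus exceeds what
#' one cell can produce is flagged `coincidence`; a window shorter than the
#' minimal plausible transit is flagged `truncated`. Flagged windows are
#' excluded from phenotype output but counted.
#'
#' @param trace a filtered `nps_trace`.
#' @param geometry an `nps_geometry`.
#' @param k detection threshold in robust noise sd units.
#' @param merge_gap_ms maximum in-event gap (node transit) to merge, ms.
#' @param min_run_ms below-threshold runs shorter than this are ignored;
#'   rejects filter-edge undershoot (~1/cutoff long) while every real
#'   sub-pulse (pore transit and longer) passes.
#' @param min_baseline_samples minimum number of near-baseline samples
#'   required to estimate the baseline.
#' @param min_duration_ms windows shorter than this are flagged truncated.
#' @param block_ms,span_ms passed to [estimate_baseline()].
#' @return list with `windows` (data.frame: `t_start`, `t_end` \[s\],
#'   `i_start`, `i_end` \[sample\], `flag` in `ok|coincidence|truncated`),
#'   `baseline` (per-sample estimate), `sigma` (robust noise sd), and
#'   `normalized` (baseline-normalized current vector).
#' @export
detect_events <- function(trace, geometry, k = 5, merge_gap_ms = 10,
                          min_run_ms = 1, min_baseline_samples = 100,
                          min_duration_ms = 5, block_ms = 20, span_ms = 500) {
  stopifnot(inherits(trace, "nps_trace"), inherits(geometry, "nps_geometry"))
  fs <- trace$meta$sampling_rate
  # pass 1: rough baseline, rough windows
  base <- estimate_baseline(trace, block_ms = block_ms, span_ms = span_ms)
  x <- trace$i / base
  sigma <- stats::mad(diff(x)) / sqrt(2)  # robust to steps and drift
  rough <- group_excursions(x, fs, k * sigma, merge_gap_ms, min_run_ms)
  # pass 2: re-estimate the baseline with event samples masked, so pulses do
  # not drag it down, then detect on the cleaned normalization
  if (length(rough$w_start)) {
    pad <- round(2 * merge_gap_ms / 1000 * fs)
    excl <- rep(FALSE, length(x))
    for (j in seq_along(rough$w_start)) {
      excl[max(1L, rough$w_start[j] - pad):
             min(length(x), rough$w_end[j] + pad)] <- TRUE
    }
    base <- estimate_baseline(trace, block_ms = block_ms, span_ms = span_ms,
                              exclude = excl)
    x <- trace$i / base
    sigma <- stats::mad(diff(x)) / sqrt(2)
  }
  thr <- max(k * sigma, 1e-5)
  if (sum(abs(x - 1) <= thr) < min_baseline_samples)
    stop("baseline error: fewer than ", min_baseline_samples,
         " baseline samples found", call. = FALSE)
  ev <- group_excursions(x, fs, thr, merge_gap_ms, min_run_ms)
  if (length(ev$w_start) == 0L) {
    return(list(windows = data.frame(t_start = numeric(0), t_end = numeric(0),
                                     i_start = integer(0), i_end = integer(0),
                                     n_low = integer(0), flag = character(0)),
                baseline = base, sigma = sigma, normalized = x))
  }
  ss <- geometry$segment_sequence
  max_low <- sum(ss$kind != "node")  # pores + contraction for a single cell
  dur_ms <- (ev$w_end - ev$w_start + 1) / fs * 1000
  flag <- rep("ok", length(ev$w_start))
  flag[ev$n_low > max_low] <- "coincidence"
  flag[dur_ms < min_duration_ms] <- "truncated"
  list(windows = data.frame(t_start = trace$t[ev$w_start],
                            t_end = trace$t[ev$w_end],
                            i_start = as.integer(ev$w_start),
                            i_end = as.integer(ev$w_end),
                            n_low = as.integer(ev$n_low),
                            flag = flag, row.names = NULL),
       baseline = base, sigma = sigma, normalized = x)
}

# below-threshold runs of x (normalized), merged across gaps shorter than
# merge_gap_ms; returns window sample bounds and the low-run count per window
group_excursions <- function(x, fs, thr, merge_gap_ms, min_run_ms) {
  thr <- max(thr, 1e-5)
  below <- x < 1 - thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lo_s <- starts[r$values]; lo_e <- ends[r$values]
  keep <- (lo_e - lo_s + 1L) >= round(min_run_ms / 1000 * fs)
  lo_s <- lo_s[keep]; lo_e <- lo_e[keep]
  if (length(lo_s) == 0L)
    return(list(w_start = integer(0), w_end = integer(0), n_low = integer(0)))
  gap <- (lo_s[-1] - lo_e[-length(lo_e)]) / fs * 1000
  grp <- cumsum(c(TRUE, gap > merge_gap_ms))
  list(w_start = as.integer(tapply(lo_s, grp, min)),
       w_end = as.integer(tapply(lo_e, grp, max)),
       n_low = tabulate(grp))
}

# Refine a plateau edge to the half-amplitude crossing, linearly
# interpolated between samples. x is baseline-normalized (filtered), the
# plateau sits at 1 - drop, the crossing level at 1 - drop/2. For a
# zero-phase filter the half-amplitude crossing of a step sits at the true
# edge time. `rising = FALSE`: edge entering the plateau (signal falling);
# `rising = TRUE`: edge leaving it.
half_crossing <- function(x, t, i_edge, drop, rising) {
  level <- 1 - drop / 2
  n <- length(x)
  j <- i_edge
  if (!rising) {
    # locate adjacent pair with x[j0] >= level > x[j0 + 1]
    if (x[j] < level) {
      while (j > 1L && x[j - 1L] < level) j <- j - 1L
      j0 <- j - 1L
    } else {
      while (j < n && x[j + 1L] >= level) j <- j + 1L
      j0 <- j
    }
  } else {
    # locate adjacent pair with x[j0] <= level < x[j0 + 1]
    if (x[j] <= level) {
      while (j < n && x[j + 1L] <= level) j <- j + 1L
      j0 <- j
    } else {
      while (j > 1L && x[j - 1L] > level) j <- j - 1L
      j0 <- j - 1L
    }
  }
  if (j0 < 1L || j0 >= n) return(t[i_edge])
  x0 <- x[j0]; x1 <- x[j0 + 1L]
  if (x1 == x0) return(t[j0])
  t[j0] + (level - x0) / (x1 - x0) * (t[j0 + 1L] - t[j0])
}

#' Segment a detected event window into sub-pulses
#'
#' Binarizes the window at `baseline - k_seg * sigma`, labels the resulting
#' low plateaus against the geometry's segment sequence (the deepest/longest
#' plateau is the contraction; plateaus before it are pre-contraction pores,
#' after it post-contraction pores), measures each amplitude as
#' `baseline - median(plateau core)`, and refines every boundary to the
#' half-amplitude crossing (exact for zero-phase-filtered step edges).
#'
#' @param detection result of [detect_events()].
#' @param window_index row of `detection$windows` to segment.
#' @param trace the same filtered `nps_trace` passed to [detect_events()].
#' @param geometry an `nps_geometry`.
#' @param k_seg binarization threshold in noise-sd units (lower than the
#'   detection threshold so shallow pore drops of small cells still split).
#' @param core_fraction central fraction of each plateau used for the
#'   amplitude median (excludes filter-smoothed edges).
#' @param min_run_ms ignore below-threshold runs shorter than this
#'   (filter-edge undershoot), as in [detect_events()].
#' @param raw optional baseline-normalized *unfiltered* current vector (same
#'   length as the trace). When given, plateau amplitudes are measured on it,
#'   free of residual filter ripple; boundaries always come from the
#'   filtered trace.
#' @return data.frame of sub-pulses: `segment_kind`
#'   (`pore_pre|contraction|pore_post`), `index` within kind, `t_start`,
#'   `t_end` \[s\], `dI` (normalized amplitude), `dT_ms`.
#' @export
segment_event <- function(detection, window_index, trace, geometry,
                          k_seg = 3.5, core_fraction = 0.5, min_run_ms = 1,
                          raw = NULL) {
  w <- detection$windows[window_index, ]
  if (w$flag != "ok")
    stop("segmentation error: window flagged '", w$flag, "'", call. = FALSE)
  fs <- trace$meta$sampling_rate
  margin <- max(2L, round(0.002 * fs))
  i0 <- max(1L, w$i_start - margin)
  i1 <- min(length(trace$t), w$i_end + margin)
  x <- detection$normalized[i0:i1]
  t <- trace$t[i0:i1]
  thr <- pmax(k_seg * detection$sigma, 1e-5)
  below <- x < 1 - thr
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  lo_s <- starts[r$values]; lo_e <- ends[r$values]
  keep_run <- (lo_e - lo_s + 1L) >= round(min_run_ms / 1000 * fs)
  lo_s <- lo_s[keep_run]; lo_e <- lo_e[keep_run]
  ss <- geometry$segment_sequence
  ci <- which(ss$kind == "contraction")
  n_pre <- sum(ss$kind == "pore" & seq_along(ss$kind) < ci)
  n_post <- sum(ss$kind == "pore" & seq_along(ss$kind) > ci)
  n_expected <- n_pre + n_post + 1L
  if (length(lo_s) != n_expected)
    stop(sprintf(paste0("segmentation error: %d low plateau(s) found, geometry",
                        " predicts %d"), length(lo_s), n_expected), call. = FALSE)

  amp_src <- if (is.null(raw)) x else raw[i0:i1]
  plateau_stat <- function(s, e) {
    len <- e - s + 1L
    trim <- floor(len * (1 - core_fraction) / 2)
    stats::median(amp_src[(s + trim):(e - trim)])
  }
  dI <- 1 - mapply(plateau_stat, lo_s, lo_e)
  if (any(dI <= 0))
    stop("segmentation error: non-positive plateau amplitude", call. = FALSE)
  # contraction = position n_pre + 1 by geometry; sanity: must be the deepest
  k_c <- n_pre + 1L
  if (which.max(dI) != k_c)
    stop("segmentation error: deepest plateau is not at the contraction position",
         call. = FALSE)
  kind <- c(rep("pore_pre", n_pre), "contraction", rep("pore_post", n_post))
  t_start <- mapply(function(s, e, d) half_crossing(x, t, s, d, rising = FALSE),
                    lo_s, lo_e, dI)
  t_end <- mapply(function(s, e, d) half_crossing(x, t, e, d, rising = TRUE),
                  lo_s, lo_e, dI)
  data.frame(segment_kind = kind,
             index = c(seq_len(n_pre), 1L, seq_len(n_post)),
             t_start = t_start, t_end = t_end, dI = dI,
             dT_ms = (t_end - t_start) * 1000, row.names = NULL)
}

#' Measure a segmented event into a pulse record
#'
#' Summarizes sub-pulses into the per-cell measurement: `dI_np` (mean
#' pre-contraction pore amplitude), `dI_c`, `dT_cont`, and the recovery time
#' `dT_r` — the elapsed time from contraction exit to the midpoint of the
#' first post-contraction pore whose amplitude is within `tolerance` of
#' `dI_np`, linearly interpolated between successive post-pore midpoints when
#' the crossing falls between them. If the first post-contraction pore
#' already satisfies the criterion the cell recovered instantly
#' (`dT_r = 0`); if the criterion is never met the record is censored at
#' `window` (prolonged recovery).
#'
#' @param subpulses data.frame from [segment_event()].
#' @param cell_id identifier for the record.
#' @param window recovery measurement window (ms).
#' @param tolerance relative tolerance defining amplitude equality.
#' @return Object of class `nps_pulse_record`.
#' @export
measure_event <- function(subpulses, cell_id = "cell", window = 40,
                          tolerance = 0.05) {
  pre <- subpulses[subpulses$segment_kind == "pore_pre", ]
  con <- subpulses[subpulses$segment_kind == "contraction", ]
  post <- subpulses[subpulses$segment_kind == "pore_post", ]
  if (nrow(pre) < 1L || nrow(con) != 1L || nrow(post) < 1L)
    stop("measurement requires >= 1 pre pore, 1 contraction, >= 1 post pore",
         call. = FALSE)
  dI_np <- mean(pre$dI)
  dI_c <- con$dI
  if (dI_c <= dI_np)
    stop("inconsistent event: contraction amplitude does not exceed the pore amplitude",
         call. = FALSE)
  # a recovering cell approaches its free-size amplitude from below; a post
  # pore well above dI_np means a second cell shares the channel
  if (any(post$dI > (1 + 3 * tolerance) * dI_np))
    stop("inconsistent event: post-contraction amplitude exceeds the ",
         "pre-contraction level (likely coincidence)", call. = FALSE)
  t_exit <- con$t_end
  t_mid <- (post$t_start + post$t_end) / 2 - t_exit  # s since exit
  amp <- post$dI
  target <- (1 - tolerance) * dI_np
  ok <- amp >= target
  if (ok[1]) {
    dT_r <- 0; censored <- FALSE
  } else if (!any(ok)) {
    dT_r <- NA_real_; censored <- TRUE
  } else {
    j <- which(ok)[1]
    # linear interpolation of the amplitude trajectory between midpoints
    t_cross <- t_mid[j - 1] +
      (target - amp[j - 1]) / (amp[j] - amp[j - 1]) * (t_mid[j] - t_mid[j - 1])
    dT_r <- max(0, t_cross * 1000)
    censored <- FALSE
  }
  structure(list(cell_id = cell_id, baseline_I = 1,
                 dI_np = dI_np, dI_c = dI_c,
                 dT_cont_ms = con$dT_ms,
                 dT_r_ms = dT_r, dT_r_censored = censored,
                 window_ms = window, tolerance = tolerance,
                 subpulses = subpulses),
            class = "nps_pulse_record")
}

#' @export
print.nps_pulse_record <- function(x, ...) {
  cat(sprintf("pulse record %s: dI_np=%.4g dI_c=%.4g dT_cont=%.3f ms dT_r=%s\n",
              x$cell_id, x$dI_np, x$dI_c, x$dT_cont_ms,
              if (x$dT_r_censored) sprintf("censored(>%g ms)", x$window_ms)
              else sprintf("%.3f ms", x$dT_r_ms)))
  invisible(x)
}

#' Extract all pulse records from a raw trace
#'
#' End-to-end pipeline: low-pass filter, baseline estimation, event
#' detection, sub-pulse segmentation and measurement. Coincidence and
#' truncated windows, and windows failing segmentation, are excluded and
#' counted (`n_detected = n_accepted + n_rejected`).
#'
#' @param trace a raw `nps_trace`.
#' @param geometry an `nps_geometry`.
#' @param acquisition an `nps_acquisition` (supplies the filter cutoff).
#' @param window,tolerance see [measure_event()].
#' @param k,k_seg,merge_gap_ms see [detect_events()] and [segment_event()].
#' @return list with `records` (accepted `nps_pulse_record`s), `rejects`
#'   (data.frame of window times + reason), and counts
#'   `n_detected`, `n_accepted`, `n_rejected`.
#' @export
extract_pulses <- function(trace, geometry, acquisition, window = 40,
                           tolerance = 0.05, k = 5, k_seg = 3.5,
                           merge_gap_ms = 10) {
  filt <- lowpass_filter(trace, acquisition$lowpass_cutoff)
  det <- detect_events(filt, geometry, k = k, merge_gap_ms = merge_gap_ms)
  raw_norm <- trace$i / det$baseline
  wins <- det$windows
  records <- list()
  rejects <- data.frame(t_start = numeric(0), t_end = numeric(0),
                        reason = character(0))
  id <- 0L
  for (w in seq_len(nrow(wins))) {
    if (wins$flag[w] != "ok") {
      rejects <- rbind(rejects, data.frame(t_start = wins$t_start[w],
                                           t_end = wins$t_end[w],
                                           reason = wins$flag[w]))
      next
    }
    rec <- tryCatch({
      sp <- segment_event(det, w, filt, geometry, k_seg = k_seg,
                          raw = raw_norm)
      id <- id + 1L
      measure_event(sp, cell_id = sprintf("event_%04d", id),
                    window = window, tolerance = tolerance)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      rejects <- rbind(rejects, data.frame(t_start = wins$t_start[w],
                                           t_end = wins$t_end[w],
                                           reason = conditionMessage(rec)))
    } else {
      records <- c(records, list(rec))
    }
  }
  list(records = records, rejects = rejects,
       n_detected = nrow(wins), n_accepted = length(records),
       n_rejected = nrow(rejects))
}
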