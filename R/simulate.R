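#' Configuration of a synthetic mechano-NPS population
#'
#' The forward model that generates traces with known per-cell ground truth.
#' A cell transits the segment sequence at constant speed `speed_node` in
#' node/pore sections and at `L_c / dT_cont` inside the contraction channel,
#' where the transit time is
#' `dT_cont = stiffness_ms_per_um * multiplier * D_cell`: proportional to
#' cell size at fixed stiffness, so that the size-corrected wCDI depends only
#' on the stiffness multiplier. Pore drops follow the blockade relation for
#' the true diameter; the contraction drop is the occluded-volume fraction of
#' a volume-conserving oblate spheroid. Post-contraction pore amplitudes
#' follow the recovery model: equal to the pre-contraction amplitude
#' (instant), a single-exponential approach to it (transient), or a constant
#' deficit (prolonged).
#'
#' @param geometry an `nps_geometry` with `D_e` set.
#' @param acquisition an `nps_acquisition`.
#' @param n_cells number of cells.
#' @param diameter_mean,diameter_sd normal diameter distribution (um),
#'   truncated below `D_e`.
#' @param diameters optional explicit diameters overriding the distribution.
#' @param speed_node cell speed in node/pore sections (um/ms), the proxy for
#'   the node-section fluid velocity `U_flow`.
#' @param stiffness_ms_per_um contraction slowdown per um of cell diameter
#'   (ms/um); 1.875 gives the reference-scale ~30 ms transit for a 16 um cell.
#' @param slowdown_sdlog log-sd of the lognormal per-cell stiffness
#'   multiplier (median 1).
#' @param recovery_mix named probabilities over
#'   `c(instant, transient, prolonged)`; must sum to 1.
#' @param transient_range range (ms) of uniformly drawn transient recovery
#'   times.
#' @param transient_deficit initial fractional amplitude deficit of the
#'   first post-contraction pore for transient cells.
#' @param prolonged_deficit constant fractional deficit for prolonged cells
#'   (must exceed `recovery_tol` so they never pass the equality criterion).
#' @param recovery_tol relative tolerance defining "recovered": the post-pore
#'   amplitude is within `recovery_tol` of the pre-contraction amplitude.
#'   `dT_r_true` for transient cells is the first time the continuous
#'   exponential trajectory meets this criterion.
#' @param noise_sd additive white Gaussian noise sd (normalized units).
#' @param drift_slope linear baseline drift (normalized units per second).
#' @param gap_mean_s,gap_min_s inter-event gap: `gap_min_s` plus an
#'   exponential with mean `gap_mean_s`.
#' @param lead_in_s baseline padding before the first and after the last
#'   event (needed by the baseline estimator).
#' @param duration_s optional fixed trace duration; events that overflow it
#'   raise an error suggesting a longer trace.
#' @param inject_coincidence if `TRUE`, appends one pair of overlapping
#'   events (two cells in the channel at once) for rejection tests.
#' @param seed integer seed; the same seed reproduces the trace bit for bit.
#' @return Object of class `nps_sim_config`.
#' @export
simulation_config <- function(geometry, acquisition = acquisition_config(),
                              n_cells = 100,
                              diameter_mean = 16, diameter_sd = 2,
                              diameters = NULL,
                              speed_node = 32,
                              stiffness_ms_per_um = 1.875,
                              slowdown_sdlog = 0.15,
                              recovery_mix = c(instant = 0.5, transient = 0.3,
                                               prolonged = 0.2),
                              transient_range = c(5, 35),
                              transient_deficit = 0.4,
                              prolonged_deficit = 0.3,
                              recovery_tol = 0.05,
                              noise_sd = 0, drift_slope = 0,
                              gap_mean_s = 0.15, gap_min_s = 0.05,
                              lead_in_s = 0.2, duration_s = NULL,
                              inject_coincidence = FALSE, seed = 1L) {
  stopifnot(inherits(geometry, "nps_geometry"), inherits(acquisition, "nps_acquisition"))
  if (is.na(geometry$D_e))
    stop("simulation requires a geometry with D_e set", call. = FALSE)
  if (abs(sum(recovery_mix) - 1) > 1e-12)
    stop("recovery_mix probabilities must sum to 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  if (prolonged_deficit <= recovery_tol)
    stop("prolonged_deficit must exceed recovery_tol", call. = FALSE)
  if (transient_deficit <= recovery_tol)
    stop("transient_deficit must exceed recovery_tol", call. = FALSE)
  structure(as.list(environment()), class = "nps_sim_config")
}

# piecewise-constant drop profile of one cell: data.frame(kind, dT_ms, drop)
event_profile <- function(D_cell, speed_node, dT_cont, recovery, geometry,
                          recovery_tol) {
  ss <- geometry$segment_sequence
  ci <- which(ss$kind == "contraction")
  dI_np <- blockade_fraction(D_cell, geometry$D_e, geometry$L_total)
  V_cell <- pi * D_cell^3 / 6
  V_cont <- geometry$L_c * geometry$w_c * geometry$h_channel
  dI_c <- V_cell / V_cont
  if (dI_c <= dI_np)
    stop("infeasible cell: contraction drop does not exceed the pore drop ",
         "(cell too large for this geometry/D_e)", call. = FALSE)
  dT <- ifelse(ss$kind == "contraction", dT_cont, ss$length / speed_node)
  drop <- numeric(nrow(ss))
  drop[ss$kind == "pore" & seq_len(nrow(ss)) < ci] <- dI_np
  drop[ci] <- dI_c
  # post pores: recovery trajectory evaluated at the pore's midpoint time
  # measured from contraction exit
  t_end <- cumsum(dT)
  t_exit <- t_end[ci]
  post_idx <- which(ss$kind == "pore" & seq_len(nrow(ss)) > ci)
  t_mid <- t_end[post_idx] - dT[post_idx] / 2 - t_exit
  drop[post_idx] <- dI_np * (1 - recovery$deficit_fun(t_mid))
  kind <- ifelse(ss$kind == "pore",
                 ifelse(seq_len(nrow(ss)) < ci, "pore_pre", "pore_post"),
                 ss$kind)
  list(profile = data.frame(kind = kind, dT_ms = dT, drop = drop),
       dI_np = dI_np, dI_c = dI_c)
}

recovery_model <- function(class, dT_r = NA, transient_deficit, prolonged_deficit,
                           recovery_tol) {
  switch(class,
    instant = list(class = "instant", dT_r_true = 0, censored = FALSE,
                   deficit_fun = function(t) rep(0, length(t))),
    transient = {
      tau <- dT_r / log(transient_deficit / recovery_tol)
      list(class = "transient", dT_r_true = dT_r, censored = FALSE,
           deficit_fun = function(t) transient_deficit * exp(-t / tau))
    },
    prolonged = list(class = "prolonged", dT_r_true = NA_real_, censored = TRUE,
                     deficit_fun = function(t) rep(prolonged_deficit, length(t))))
}

#' Simulate the current pulse of a single transiting cell
#'
#' Renders the piecewise-constant (pre low-pass) pulse anatomy of one cell:
#' a blockade drop in every pore, return to baseline in every node, the much
#' deeper contraction drop, and post-contraction pore amplitudes following
#' the chosen recovery trajectory.
#'
#' @param D_cell free cell diameter (um), must be below `geometry$D_e`.
#' @param geometry an `nps_geometry` with `D_e` set.
#' @param acquisition an `nps_acquisition` (sets the sampling rate).
#' @param speed_node node/pore transit speed (um/ms).
#' @param dT_cont contraction transit time (ms).
#' @param recovery_class `"instant"`, `"transient"` or `"prolonged"`.
#' @param dT_r_true transient recovery time (ms); required for transient cells.
#' @param transient_deficit,prolonged_deficit,recovery_tol recovery-model
#'   parameters, see [simulation_config()].
#' @return list with `drop` (sampled drop values, normalized units, starting
#'   at the cell's channel entry), `truth` (one-row data.frame of ground
#'   truth) and `subpulses` (per-segment boundary times in ms and drops).
#' @export
simulate_event_pulse <- function(D_cell, geometry, acquisition,
                                 speed_node = 32, dT_cont = 30,
                                 recovery_class = "instant", dT_r_true = NA,
                                 transient_deficit = 0.4,
                                 prolonged_deficit = 0.3, recovery_tol = 0.05) {
  stopifnot(inherits(geometry, "nps_geometry"))
  if (is.na(geometry$D_e)) stop("geometry D_e must be set", call. = FALSE)
  if (D_cell >= geometry$D_e)
    stop("infeasible cell: D_cell must be below the effective diameter D_e",
         call. = FALSE)
  rec <- recovery_model(recovery_class, dT_r_true, transient_deficit,
                        prolonged_deficit, recovery_tol)
  ep <- event_profile(D_cell, speed_node, dT_cont, rec, geometry, recovery_tol)
  prof <- ep$profile
  t_end <- cumsum(prof$dT_ms)
  t_start <- c(0, t_end[-length(t_end)])
  fs_ms <- acquisition$sampling_rate / 1000   # samples per ms
  n <- ceiling(t_end[length(t_end)] * fs_ms) + 1L
  drop <- numeric(n)
  # each sample integrates the drop over its sampling interval, so segment
  # edges land at their continuous-time positions (the boundary sample takes
  # the fractional coverage); the zero-phase analysis filter then recovers
  # edge times to sub-sample accuracy
  for (k in seq_len(nrow(prof))) {
    if (prof$drop[k] == 0) next
    u0 <- t_start[k] * fs_ms; u1 <- t_end[k] * fs_ms
    ks <- (floor(u0) + 1L):min(ceiling(u1), n)
    w <- pmin(ks, u1) - pmax(ks - 1, u0)
    drop[ks] <- drop[ks] + prof$drop[k] * pmax(w, 0)
  }
  truth <- data.frame(
    D_cell_true = D_cell, dI_np_true = ep$dI_np, dI_c_true = ep$dI_c,
    dT_cont_true = dT_cont, speed_node = speed_node,
    recovery_class_true = rec$class, dT_r_true = rec$dT_r_true,
    dT_r_censored_true = rec$censored,
    duration_ms = t_end[length(t_end)])
  list(drop = drop, truth = truth,
       subpulses = cbind(prof, t_start_ms = t_start, t_end_ms = t_end))
}

#' Simulate a full current trace with per-cell ground truth
#'
#' Concatenates baseline, the sampled pulses of `n_cells` cells at random
#' start times, additive white Gaussian noise and linear drift. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config an `nps_sim_config` from [simulation_config()].
#' @return list with `trace` (an `nps_trace`, normalized units) and `truth`
#'   (data.frame, one row per cell: true diameter, amplitudes, transit and
#'   recovery times, class, `event_start_s`/`event_end_s`, and a
#'   `coincident` flag for injected overlapping events).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "nps_sim_config"))
  geom <- config$geometry; acq <- config$acquisition
  set.seed(config$seed)
  n <- config$n_cells
  d_max <- min(geom$D_e * 0.999, d_pole(geom$D_e) * 0.99)
  if (is.null(config$diameters)) {
    D <- numeric(0)
    while (length(D) < n) {
      cand <- stats::rnorm(n, config$diameter_mean, config$diameter_sd)
      D <- c(D, cand[cand > 0 & cand < d_max])
    }
    D <- D[seq_len(n)]
  } else {
    D <- rep_len(config$diameters, n)
    if (any(D >= d_max)) stop("explicit diameter >= D_e is infeasible", call. = FALSE)
  }
  mult <- stats::rlnorm(n, 0, config$slowdown_sdlog)
  classes <- if (n > 0) sample(names(config$recovery_mix), n, replace = TRUE,
                               prob = config$recovery_mix) else character(0)
  dT_r <- stats::runif(n, config$transient_range[1], config$transient_range[2])
  gaps <- config$gap_min_s + stats::rexp(n, 1 / config$gap_mean_s)

  pulses <- vector("list", n)
  truth <- vector("list", n)
  t_cursor <- config$lead_in_s
  for (k in seq_len(n)) {
    p <- simulate_event_pulse(
      D[k], geom, acq, speed_node = config$speed_node,
      dT_cont = config$stiffness_ms_per_um * mult[k] * D[k],
      recovery_class = classes[k], dT_r_true = dT_r[k],
      transient_deficit = config$transient_deficit,
      prolonged_deficit = config$prolonged_deficit,
      recovery_tol = config$recovery_tol)
    tr <- p$truth
    tr$cell_id <- sprintf("cell_%04d", k)
    tr$event_start_s <- t_cursor
    tr$event_end_s <- t_cursor + tr$duration_ms / 1000
    tr$coincident <- FALSE
    pulses[[k]] <- p
    truth[[k]] <- tr
    t_cursor <- tr$event_end_s + gaps[k]
  }

  if (config$inject_coincidence && n >= 1) {
    # two median-sized cells, the second entering while the first is still in
    # the channel
    for (j in 1:2) {
      p <- simulate_event_pulse(
        stats::median(D), geom, acq, speed_node = config$speed_node,
        dT_cont = config$stiffness_ms_per_um * stats::median(D),
        recovery_class = "instant",
        transient_deficit = config$transient_deficit,
        prolonged_deficit = config$prolonged_deficit,
        recovery_tol = config$recovery_tol)
      tr <- p$truth
      tr$cell_id <- sprintf("coinc_%d", j)
      tr$event_start_s <- t_cursor + (j - 1) * 0.4 * tr$duration_ms / 1000
      tr$event_end_s <- tr$event_start_s + tr$duration_ms / 1000
      tr$coincident <- TRUE
      pulses <- c(pulses, list(p))
      truth <- c(truth, list(tr))
    }
    t_cursor <- truth[[length(truth)]]$event_end_s + config$gap_min_s
  }

  total_s <- t_cursor + config$lead_in_s
  if (!is.null(config$duration_s)) {
    if (total_s > config$duration_s)
      stop(sprintf(paste0("events overflow the requested trace duration ",
                          "(need %.3f s > %.3f s): increase duration_s"),
                   total_s, config$duration_s), call. = FALSE)
    total_s <- config$duration_s
  }
  fs <- acq$sampling_rate
  n_samp <- ceiling(total_s * fs) + 1L
  i <- rep(1.0, n_samp)
  for (k in seq_along(pulses)) {
    i0 <- floor(truth[[k]]$event_start_s * fs) + 1L
    dr <- pulses[[k]]$drop
    idx <- i0:min(i0 + length(dr) - 1L, n_samp)
    i[idx] <- i[idx] - dr[seq_along(idx)]
  }
  tvec <- (seq_len(n_samp) - 1L) / fs
  # drift is multiplicative: the blockade is a resistance ratio, so a
  # drifting baseline current scales the absolute drop with it
  if (config$drift_slope != 0) i <- i * (1 + config$drift_slope * tvec)
  if (config$noise_sd > 0) i <- i + stats::rnorm(n_samp, 0, config$noise_sd)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(D_cell_true = numeric(0), dI_np_true = numeric(0),
               dI_c_true = numeric(0), dT_cont_true = numeric(0),
               speed_node = numeric(0), recovery_class_true = character(0),
               dT_r_true = numeric(0), dT_r_censored_true = logical(0),
               duration_ms = numeric(0), cell_id = character(0),
               event_start_s = numeric(0), event_end_s = numeric(0),
               coincident = logical(0))
  list(trace = raw_trace(tvec, i, meta = list(sampling_rate = fs,
                                              normalized = TRUE,
                                              seed = config$seed)),
       truth = truth_df)
}
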