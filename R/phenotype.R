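#' Fractional current blockade of a particle in a sensing channel
#'
#' The Coulter (resistive-pulse) blockade relation for a spherical particle of
#' diameter `d` in a channel of effective electrical diameter `D_e` and sensed
#' length `L_total`:
#' \deqn{\Delta I / I = \frac{d^3}{D_e^2 L}\,\frac{1}{1 - 0.8 (d/D_e)^3}}
#' The correction factor has a pole at \eqn{d = D_e \cdot 0.8^{-1/3}}; the
#' function is defined (and strictly increasing in `d`) only below it.
#'
#' @param d particle diameter (um), `d >= 0`; vectorized.
#' @param D_e effective channel diameter (um).
#' @param L_total sensed channel length (um).
#' @return Fractional blockade \eqn{\Delta I / I} (dimensionless).
#' @examples
#' blockade_fraction(15, D_e = 30, L_total = 5000) # 8.333e-4
#' @export
blockade_fraction <- function(d, D_e, L_total) {
  stopifnot(D_e > 0, L_total > 0, all(d >= 0))
  r3 <- (d / D_e)^3
  denom <- 1 - 0.8 * r3
  if (any(denom <= 0))
    stop("blockade domain error: d/D_e beyond the pole at 0.8^(-1/3)", call. = FALSE)
  d^3 / (D_e^2 * L_total) / denom
}

d_pole <- function(D_e) D_e * 0.8^(-1 / 3)

#' Calibrate the channel's effective diameter from microsphere blockades
#'
#' Polystyrene microspheres of known diameter `d_sphere` are run through the
#' device; the mean observed fractional blockade is inverted for `D_e` in the
#' blockade relation by bracketed root-finding (the blockade is strictly
#' decreasing in `D_e`, so the root is unique).
#'
#' @param observed_fractions observed \eqn{\Delta I / I} values, all positive.
#' @param d_sphere microsphere diameter (um).
#' @param L_total sensed channel length (um).
#' @param tol relative root-finding tolerance.
#' @return Object of class `nps_calibration`: `D_e`, per-sphere relative
#'   residuals against the fitted `D_e`, their RMS, `n_spheres`, `d_sphere`,
#'   `L_total`.
#' @export
calibrate_effective_diameter <- function(observed_fractions, d_sphere, L_total,
                                         tol = 1e-9) {
  if (length(observed_fractions) < 1L || any(observed_fractions <= 0))
    stop("calibration requires >= 1 positive observed fraction", call. = FALSE)
  target <- mean(observed_fractions)
  # blockade -> Inf as D_e -> d_sphere * 0.8^(1/3) from above, -> 0 as D_e -> Inf
  lo <- d_sphere * 0.8^(1 / 3) * (1 + 1e-9)
  hi <- d_sphere * 1e6
  f <- function(De) blockade_fraction(d_sphere, De, L_total) - target
  if (f(hi) > 0)
    stop("calibration error: observed fraction too small for any plausible D_e",
         call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = tol * d_sphere)$root
  fitted <- blockade_fraction(d_sphere, root, L_total)
  resid <- (observed_fractions - fitted) / fitted
  structure(list(D_e = root, residuals = resid,
                 residual_rms = sqrt(mean(resid^2)),
                 n_spheres = length(observed_fractions),
                 d_sphere = d_sphere, L_total = L_total),
            class = "nps_calibration")
}

#' @export
print.nps_calibration <- function(x, ...) {
  cat(sprintf("effective diameter D_e = %.4f um (%d sphere(s) of %g um, residual RMS %.3g)\n",
              x$D_e, x$n_spheres, x$d_sphere, x$residual_rms))
  invisible(x)
}

#' Invert the blockade relation for free cell diameter
#'
#' Solves \eqn{\Delta I_{np}/I} for the unique particle diameter `d` in
#' `(0, D_e * 0.8^(-1/3))` by bracketed root-finding.
#'
#' @param fraction observed fractional blockade in a pore (vectorized).
#' @param D_e calibrated effective diameter (um).
#' @param L_total sensed channel length (um).
#' @param tol relative tolerance on the recovered diameter.
#' @return Cell diameter(s) in um.
#' @export
invert_cell_diameter <- function(fraction, D_e, L_total, tol = 1e-9) {
  stopifnot(D_e > 0, L_total > 0)
  if (any(fraction <= 0))
    stop("blockade domain error: fraction must be > 0", call. = FALSE)
  hi <- d_pole(D_e) * (1 - 1e-12)
  fmax <- blockade_fraction(hi * (1 - 1e-6), D_e, L_total)
  vapply(fraction, function(fr) {
    if (fr >= fmax)
      stop("blockade domain error: fraction exceeds the attainable range",
           call. = FALSE)
    stats::uniroot(function(d) blockade_fraction(d, D_e, L_total) - fr,
                   c(0, hi * (1 - 1e-6)), tol = tol * D_e)$root
  }, numeric(1))
}

#' Deformed-cell geometry from the contraction-channel blockade
#'
#' In the contraction channel the cell blocks a volume fraction of the
#' channel: \eqn{\Delta I_c / I \approx V_{deform} / V_{contraction}} with
#' \eqn{V_{contraction} = L_c w_c h_{channel}}. Assuming isometric compression
#' into an oblate spheroid, \eqn{V_{deform} = \pi w_c L_{deform}^2 / 6}, which
#' is inverted for the elongation length \eqn{L_{deform}}.
#'
#' @param fraction_c contraction-channel fractional blockade
#'   \eqn{\Delta I_c / I}, in `(0, 1)`; vectorized.
#' @param geometry an `nps_geometry`.
#' @param proportionality calibration scalar for the volume-blockade
#'   proportionality (default 1).
#' @return data.frame with `V_deform_um3` and `L_deform_um`.
#' @export
deformed_geometry <- function(fraction_c, geometry, proportionality = 1) {
  stopifnot(inherits(geometry, "nps_geometry"))
  if (any(fraction_c <= 0))
    stop("contraction blockade must be > 0", call. = FALSE)
  if (any(fraction_c >= 1))
    stop("physically implausible occlusion: fraction_c >= 1", call. = FALSE)
  V_cont <- geometry$L_c * geometry$w_c * geometry$h_channel
  V_deform <- proportionality * fraction_c * V_cont
  data.frame(V_deform_um3 = V_deform,
             L_deform_um = sqrt(6 * V_deform / (pi * geometry$w_c)))
}

#' Transverse deformation of a compressed cell
#'
#' \eqn{\delta_{deform} = L_{deform} / D_{cell}}: how far the cell elongates
#' in the channel plane relative to its free diameter (> 1 once it spreads
#' beyond its free size).
#'
#' @param L_deform elongation length in the contraction channel (um).
#' @param D_cell free cell diameter (um).
#' @return Dimensionless ratio.
#' @export
transverse_deformation <- function(L_deform, D_cell) {
  stopifnot(all(L_deform > 0), all(D_cell > 0))
  L_deform / D_cell
}

#' Compressive strain imposed by the contraction channel
#'
#' \eqn{\varepsilon = (D_{cell} - w_c) / D_{cell}}. Negative values (cell
#' smaller than the channel) are allowed and mean the cell transits
#' un-deformed.
#'
#' @param D_cell free cell diameter (um).
#' @param w_c contraction channel width (um).
#' @return Dimensionless strain.
#' @export
compressive_strain <- function(D_cell, w_c) {
  stopifnot(all(D_cell > 0), w_c > 0)
  (D_cell - w_c) / D_cell
}

#' Flow context (node-section and contraction-transit velocities)
#'
#' `U_flow` is taken from the last pre-contraction pore: the cell's transit
#' speed there (pore length / sub-pulse duration) proxies the fluid velocity
#' feeding the contraction channel. `U_c = L_c / dT_cont` is the transit
#' velocity inside the contraction.
#'
#' @param record an `nps_pulse_record` from [measure_event()].
#' @param geometry an `nps_geometry`.
#' @param mu fluid viscosity (Pa s), metadata for the pi-term with the
#'   elastic modulus.
#' @param E elastic modulus (Pa) or `NA`; metadata only.
#' @return Object of class `nps_flow`: `U_flow`, `U_c` (um/ms), `mu`, `E`.
#' @export
estimate_flow_velocity <- function(record, geometry, mu = 1e-3, E = NA_real_) {
  stopifnot(inherits(record, "nps_pulse_record"), inherits(geometry, "nps_geometry"))
  pre <- record$subpulses[record$subpulses$segment_kind == "pore_pre", ]
  if (nrow(pre) < 1L)
    stop("flow estimate requires at least one pre-contraction pore sub-pulse",
         call. = FALSE)
  dT <- pre$dT_ms[nrow(pre)]
  if (dT <= 0) stop("degenerate event: zero-duration pore sub-pulse", call. = FALSE)
  flow_context(U_flow = geometry$pore_length / dT,
               U_c = geometry$L_c / record$dT_cont_ms, mu = mu, E = E)
}

#' @rdname estimate_flow_velocity
#' @param U_flow,U_c velocities in um/ms, for constructing a flow context
#'   directly (e.g. a per-run override).
#' @export
flow_context <- function(U_flow, U_c = NA_real_, mu = 1e-3, E = NA_real_) {
  stopifnot(U_flow > 0, is.na(U_c) || U_c > 0)
  structure(list(U_flow = U_flow, U_c = U_c, mu = mu, E = E),
            class = "nps_flow")
}

#' Whole-cell deformability index (wCDI)
#'
#' \deqn{wCDI = \frac{L_c}{U_{flow} h_{channel}} \cdot \frac{D_{cell}}{\Delta T_{cont}}}
#' A dimensionless index of whole-cell deformability: more deformable cells
#' transit the contraction channel faster for their size and score higher.
#' Because `D_cell` enters the numerator while larger cells transit more
#' slowly, the index corrects for cell size. It equals the product of the
#' Buckingham-pi terms `pi2 * pi3 * pi4` from [compute_pi_terms()] and is
#' empirically inverse to cortical tension and elastic modulus.
#'
#' @param D_cell free cell diameter (um); vectorized.
#' @param dT_cont contraction transit time (ms); vectorized.
#' @param flow an `nps_flow` (only `U_flow` is used).
#' @param geometry an `nps_geometry`.
#' @return Dimensionless wCDI.
#' @examples
#' geom <- device_geometry(w_c = 12)
#' compute_wcdi(15, 30, flow_context(U_flow = 50), geom)
#' @export
compute_wcdi <- function(D_cell, dT_cont, flow, geometry) {
  stopifnot(inherits(flow, "nps_flow"), inherits(geometry, "nps_geometry"),
            all(D_cell > 0), all(dT_cont > 0))
  (geometry$L_c / (flow$U_flow * geometry$h_channel)) * D_cell / dT_cont
}

#' Buckingham-pi decomposition of the deformability problem
#'
#' The dimensional analysis of a cell (elastic modulus `E`, diameter
#' `D_cell`) compressed in a channel (height `h_channel`, contraction length
#' `L_c`) under flow (`U_flow`, viscosity `mu`) yields four dimensionless
#' groups:
#' \deqn{\pi_1 = \frac{h_{channel} E}{U_{flow}\,\mu},\quad
#'       \pi_2 = \frac{h_{channel}}{\Delta T_{cont} U_{flow}},\quad
#'       \pi_3 = \frac{D_{cell}}{h_{channel}},\quad
#'       \pi_4 = \frac{L_c}{h_{channel}}}
#' with \eqn{\pi_2 \pi_3 \pi_4 = wCDI} exactly. `pi1` (the only group
#' containing the modulus) is returned only when `E` and `mu` are available;
#' its units are reconciled internally (um, ms, Pa, Pa s).
#'
#' @inheritParams compute_wcdi
#' @return Object of class `nps_pi_terms`: `pi1` (or `NA`), `pi2`, `pi3`,
#'   `pi4`, and `wCDI` (their product).
#' @export
compute_pi_terms <- function(D_cell, dT_cont, flow, geometry) {
  stopifnot(inherits(flow, "nps_flow"), inherits(geometry, "nps_geometry"),
            all(D_cell > 0), all(dT_cont > 0))
  h <- geometry$h_channel
  pi2 <- h / (dT_cont * flow$U_flow)
  pi3 <- D_cell / h
  pi4 <- geometry$L_c / h
  pi1 <- if (!is.na(flow$E) && !is.na(flow$mu)) {
    # h [um -> m], E [Pa], U [um/ms -> m/s], mu [Pa s]
    (h * 1e-6 * flow$E) / (flow$U_flow * 1e-3 * flow$mu)
  } else NA_real_
  structure(list(pi1 = pi1, pi2 = pi2, pi3 = pi3, pi4 = pi4,
                 wCDI = pi2 * pi3 * pi4),
            class = "nps_pi_terms")
}

#' Classify recovery from compressive deformation
#'
#' Cells are classed by the time `dT_r` needed for post-contraction pore
#' amplitudes to return to the pre-contraction level: `instant`
#' (`dT_r = 0`; the first post-contraction pore already matches), `transient`
#' (`0 < dT_r <= window`), `prolonged` (`dT_r > window`, or censored — the
#' cell never recovered inside the device's measurement window).
#'
#' @param dT_r recovery time(s) in ms; `NA` allowed when `censored` is `TRUE`.
#' @param window measurement window (ms); 40 ms for the reference device.
#' @param censored logical vector: recovery not observed within the window.
#' @return factor with levels `instant`, `transient`, `prolonged`.
#' @export
classify_recovery <- function(dT_r, window = 40, censored = FALSE) {
  stopifnot(window > 0)
  n <- max(length(dT_r), length(censored))
  dT_r <- rep_len(dT_r, n); censored <- rep_len(censored, n)
  if (any(!censored & (is.na(dT_r) | dT_r < 0)))
    stop("recovery time must be >= 0 (or censored)", call. = FALSE)
  cls <- ifelse(censored | (!is.na(dT_r) & dT_r > window), "prolonged",
                ifelse(dT_r == 0, "instant", "transient"))
  factor(cls, levels = c("instant", "transient", "prolonged"))
}

#' Cortical tension from micropipette aspiration
#'
#' At the critical suction pressure the aspirated cap is hemispherical
#' (aspirated length equals the pipette radius) and the law of Laplace gives
#' \deqn{\Delta P_{crit} = 2 T_{eff} (1/R_p - 1/R_c)}
#' which is inverted for the effective cortical tension.
#'
#' @param dP_crit critical pressure (kPa); vectorized.
#' @param R_p pipette radius (um).
#' @param R_c cell radius (um); must exceed `R_p`.
#' @return Cortical tension in mN/m.
#' @examples
#' cortical_tension(0.3, R_p = 4, R_c = 8) # 1.2 mN/m
#' @export
cortical_tension <- function(dP_crit, R_p, R_c) {
  if (any(R_p <= 0) || any(R_c <= R_p))
    stop("aspiration geometry error: need R_c > R_p > 0", call. = FALSE)
  if (any(dP_crit <= 0))
    stop("critical pressure must be > 0", call. = FALSE)
  # kPa / um^-1 : 1e3 Pa / 1e6 m^-1 = 1e-3 N/m = 1 mN/m
  dP_crit / (2 * (1 / R_p - 1 / R_c))
}

#' Convert extracted pulse records into per-cell biophysical phenotypes
#'
#' For each accepted pulse record: invert the pore blockade for the free
#' diameter `D_cell`, convert the contraction blockade into `V_deform` and
#' `L_deform` (oblate-spheroid model), form the transverse deformation
#' `delta_deform`, the imposed strain, the wCDI, and the recovery class.
#'
#' @param records list of `nps_pulse_record` objects ([extract_pulses()]).
#' @param geometry an `nps_geometry` with calibrated `D_e` (or pass `D_e`).
#' @param D_e optional override of `geometry$D_e` (um).
#' @param window recovery window in ms for classification.
#' @param U_flow optional per-run flow velocity (um/ms); when `NULL` the
#'   velocity is estimated per cell from the last pre-contraction pore.
#' @param mu fluid viscosity (Pa s), carried into the flow context.
#' @return data.frame with columns `cell_id`, `D_cell_um`, `L_deform_um`,
#'   `delta_deform`, `strain`, `dT_cont_ms`, `dT_r_ms`, `dT_r_censored`,
#'   `wCDI`, `recovery_class`, plus `V_deform_um3`, `U_flow_um_ms`,
#'   `U_c_um_ms`, `deformed` (FALSE when the cell is smaller than the
#'   contraction width, where delta and wCDI lose their meaning).
#' @export
phenotype_cells <- function(records, geometry, D_e = geometry$D_e, window = 40,
                            U_flow = NULL, mu = 1e-3) {
  stopifnot(inherits(geometry, "nps_geometry"))
  if (is.na(D_e))
    stop("D_e is unset: run calibrate_effective_diameter() first", call. = FALSE)
  if (inherits(records, "nps_pulse_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    D_cell <- invert_cell_diameter(rec$dI_np, D_e, geometry$L_total)
    geo <- deformed_geometry(rec$dI_c, geometry)
    flow <- if (is.null(U_flow)) {
      estimate_flow_velocity(rec, geometry, mu = mu)
    } else flow_context(U_flow, U_c = geometry$L_c / rec$dT_cont_ms, mu = mu)
    cls <- classify_recovery(ifelse(rec$dT_r_censored, NA_real_, rec$dT_r_ms),
                             window = window, censored = rec$dT_r_censored)
    data.frame(
      cell_id = rec$cell_id,
      D_cell_um = D_cell,
      L_deform_um = geo$L_deform_um,
      delta_deform = transverse_deformation(geo$L_deform_um, D_cell),
      strain = compressive_strain(D_cell, geometry$w_c),
      dT_cont_ms = rec$dT_cont_ms,
      dT_r_ms = if (rec$dT_r_censored) NA_real_ else rec$dT_r_ms,
      dT_r_censored = rec$dT_r_censored,
      wCDI = compute_wcdi(D_cell, rec$dT_cont_ms, flow, geometry),
      recovery_class = as.character(cls),
      V_deform_um3 = geo$V_deform_um3,
      U_flow_um_ms = flow$U_flow,
      U_c_um_ms = flow$U_c,
      deformed = D_cell > geometry$w_c,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
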