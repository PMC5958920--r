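#' Device geometry for a mechano-NPS channel
#'
#' Describes the physical sensing channel: an ordered sequence of segments
#' (pre-contraction pore/node pairs, one long narrow contraction segment,
#' post-contraction node/pore pairs). All lengths and widths are in
#' micrometres. The effective electrical diameter `D_e` is unknown until
#' microsphere calibration ([calibrate_effective_diameter()]) and may be left
#' `NA`.
#'
#' When `segment_sequence` is not supplied it is built as
#' `n_pre_pairs` x (pore, node), contraction, `n_post_pairs` x (node, pore),
#' so a transiting cell produces a pore drop immediately on entry and the
#' symmetric post-contraction pore train used to monitor shape recovery.
#'
#' @param w_c contraction channel width (um); must satisfy `w_c < w_pore < w_node`.
#' @param w_pore,w_node pore and node widths (um).
#' @param h_channel channel height (um).
#' @param L_c contraction channel length (um).
#' @param pore_length,node_length lengths of each pore / node segment (um).
#' @param n_pre_pairs,n_post_pairs number of pore-node pairs before / after
#'   the contraction segment.
#' @param D_e effective electrical diameter (um) from calibration, or `NA`.
#' @param segment_sequence optional data.frame with columns `kind`
#'   (`"pore"|"node"|"contraction"`), `length`, `width` overriding the default
#'   layout. Exactly one contraction segment is required.
#' @return An object of class `nps_geometry`: a list with the fields above
#'   plus `L_total`, the summed (sensed) channel length used in the blockade
#'   equation.
#' @examples
#' geom <- device_geometry(w_c = 12)
#' geom$L_total
#' @export
device_geometry <- function(w_c = 12, w_pore = 25, w_node = 85, h_channel = 30,
                            L_c = 2055, pore_length = 100, node_length = 85,
                            n_pre_pairs = 3, n_post_pairs = 7, D_e = NA_real_,
                            segment_sequence = NULL) {
  if (is.null(segment_sequence)) {
    pre  <- do.call(rbind, replicate(n_pre_pairs, data.frame(
      kind = c("pore", "node"), length = c(pore_length, node_length),
      width = c(w_pore, w_node)), simplify = FALSE))
    post <- do.call(rbind, replicate(n_post_pairs, data.frame(
      kind = c("node", "pore"), length = c(node_length, pore_length),
      width = c(w_node, w_pore)), simplify = FALSE))
    segment_sequence <- rbind(
      pre,
      data.frame(kind = "contraction", length = L_c, width = w_c),
      post)
  }
  segment_sequence <- as.data.frame(segment_sequence)
  geom <- structure(list(
    segment_sequence = segment_sequence,
    w_pore = w_pore, w_node = w_node, w_c = w_c,
    h_channel = h_channel, L_c = L_c,
    L_total = sum(segment_sequence$length),
    D_e = D_e,
    n_pre_pairs = sum(segment_sequence$kind == "pore" &
                        seq_len(nrow(segment_sequence)) <
                          which(segment_sequence$kind == "contraction")[1]),
    n_post_pairs = sum(segment_sequence$kind == "pore" &
                         seq_len(nrow(segment_sequence)) >
                           which(segment_sequence$kind == "contraction")[1]),
    pore_length = pore_length, node_length = node_length
  ), class = "nps_geometry")
  validate_geometry(geom)
}

validate_geometry <- function(geom) {
  ss <- geom$segment_sequence
  if (!all(c("kind", "length", "width") %in% names(ss)))
    stop("segment_sequence must have columns kind, length, width", call. = FALSE)
  if (any(!is.finite(ss$length)) || any(ss$length <= 0) || any(ss$width <= 0))
    stop("geometry invariant violated: all segment lengths and widths must be > 0",
         call. = FALSE)
  for (f in c("w_pore", "w_node", "w_c", "h_channel", "L_c"))
    if (!is.finite(geom[[f]]) || geom[[f]] <= 0)
      stop("geometry invariant violated: ", f, " must be > 0", call. = FALSE)
  if (!(geom$w_c < geom$w_pore && geom$w_pore < geom$w_node))
    stop("geometry invariant violated: w_c < w_pore < w_node required", call. = FALSE)
  if (sum(ss$kind == "contraction") != 1L)
    stop("geometry invariant violated: exactly one contraction segment required",
         call. = FALSE)
  if (abs(sum(ss$length) - geom$L_total) > 1e-9 * geom$L_total)
    stop("geometry invariant violated: segment lengths must sum to L_total",
         call. = FALSE)
  if (!is.na(geom$D_e) && geom$D_e <= geom$w_c)
    stop("geometry invariant violated: D_e must exceed the contraction width w_c",
         call. = FALSE)
  geom
}

#' @export
print.nps_geometry <- function(x, ...) {
  cat("mechano-NPS device geometry\n")
  cat(sprintf("  contraction: %g um long x %g um wide, channel height %g um\n",
              x$L_c, x$w_c, x$h_channel))
  cat(sprintf("  node/pore widths: %g / %g um; %d pre + %d post pore(s)\n",
              x$w_node, x$w_pore, x$n_pre_pairs, x$n_post_pairs))
  cat(sprintf("  sensed length L_total = %g um; D_e = %s um\n", x$L_total,
              if (is.na(x$D_e)) "uncalibrated" else format(x$D_e)))
  invisible(x)
}

#' Acquisition settings for a mechano-NPS run
#'
#' @param sampling_rate sampling rate of the current trace (Hz).
#' @param applied_voltage applied DC voltage (V); the reference device uses 1 V.
#' @param inlet_pressure driving pressure (kPa); ~21 kPa in the reference device.
#' @param lowpass_cutoff low-pass filter cutoff applied before extraction (Hz);
#'   must be below the Nyquist frequency.
#' @param baseline_current_hint optional expected baseline current (normalized
#'   traces use 1).
#' @return An object of class `nps_acquisition`.
#' @export
acquisition_config <- function(sampling_rate = 50000, applied_voltage = 1,
                               inlet_pressure = 21, lowpass_cutoff = 5000,
                               baseline_current_hint = NA_real_) {
  acq <- structure(list(
    sampling_rate = sampling_rate, applied_voltage = applied_voltage,
    inlet_pressure = inlet_pressure, lowpass_cutoff = lowpass_cutoff,
    baseline_current_hint = baseline_current_hint), class = "nps_acquisition")
  if (!is.finite(acq$sampling_rate) || acq$sampling_rate <= 0)
    stop("acquisition invariant violated: sampling_rate must be > 0", call. = FALSE)
  if (acq$sampling_rate <= 2 * acq$lowpass_cutoff)
    stop("acquisition invariant violated: sampling_rate must exceed 2 x lowpass_cutoff",
         call. = FALSE)
  if (acq$applied_voltage <= 0)
    stop("acquisition invariant violated: applied_voltage must be > 0", call. = FALSE)
  acq
}

#' Load device geometry and acquisition settings from a config file
#'
#' Reads a JSON or YAML file with two top-level sections, `geometry` and
#' `acquisition`, whose keys match the arguments of [device_geometry()] and
#' [acquisition_config()]. Missing optional keys take the documented
#' defaults; unknown keys are an error so typos do not silently vanish.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `geometry` (class `nps_geometry`) and
#'   `acquisition` (class `nps_acquisition`).
#' @export
load_device_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || is.null(cfg$geometry))
    stop("config error: mandatory section 'geometry' missing", call. = FALSE)
  geo_keys <- names(formals(device_geometry))
  acq_keys <- names(formals(acquisition_config))
  bad <- setdiff(names(cfg$geometry), geo_keys)
  if (length(bad)) stop("config error: unknown geometry key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  acq <- if (is.null(cfg$acquisition)) list() else cfg$acquisition
  bad <- setdiff(names(acq), acq_keys)
  if (length(bad)) stop("config error: unknown acquisition key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  list(geometry = do.call(device_geometry, cfg$geometry),
       acquisition = do.call(acquisition_config, acq))
}

# cumulative segment boundaries (um from channel entrance)
segment_boundaries <- function(geom) {
  c(0, cumsum(geom$segment_sequence$length))
}
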