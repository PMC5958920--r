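#' Construct a raw current trace
#'
#' A trace is a uniformly sampled current-versus-time record. Internally all
#' traces are kept in normalized units (baseline current = 1); [read_trace()]
#' records in `meta$normalized` whether the file declared normalized units.
#'
#' @param t time stamps in seconds, strictly increasing and uniform
#'   (relative jitter below 1e-6).
#' @param i current samples, same length as `t`, all finite.
#' @param meta named list of acquisition metadata (e.g. `sampling_rate`).
#' @return Object of class `nps_trace` with fields `t`, `i`, `meta`.
#' @export
raw_trace <- function(t, i, meta = list()) {
  if (length(t) < 2L) stop("trace must contain at least 2 samples", call. = FALSE)
  if (length(t) != length(i)) stop("t and i must have equal length", call. = FALSE)
  if (any(!is.finite(i))) {
    stop("trace format error: non-finite current sample at row ",
         which(!is.finite(i))[1], call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0))
    stop("trace format error: time stamps must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("trace format error: non-uniform time base (relative jitter > 1e-6)",
         call. = FALSE)
  if (is.null(meta$sampling_rate)) meta$sampling_rate <- 1 / mean(dt)
  structure(list(t = as.numeric(t), i = as.numeric(i), meta = meta),
            class = "nps_trace")
}

#' @export
print.nps_trace <- function(x, ...) {
  cat(sprintf("mechano-NPS trace: %d samples, %.4g s at %.4g Hz\n",
              length(x$t), x$t[length(x$t)] - x$t[1], x$meta$sampling_rate))
  invisible(x)
}

#' Read a current trace from delimited text
#'
#' Expects two numeric columns (time in seconds, current) separated by
#' whitespace or commas. Lines starting with `#` are metadata of the form
#' `# key: value`; recognised keys include `sampling_rate` and `units`
#' (`units: normalized` marks a baseline-1 trace).
#'
#' @param path file path.
#' @return An `nps_trace`; `meta$normalized` is `TRUE` when the header
#'   declared normalized units.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) m[3] else v
    }
  }
  meta$normalized <- identical(meta$units, "normalized")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  con <- textConnection(body)
  on.exit(close(con))
  dat <- utils::read.table(con, sep = "", col.names = c("t", "i"),
                           colClasses = "numeric")
  raw_trace(dat$t, dat$i, meta = meta)
}

#' Write a current trace as delimited text
#'
#' Writes `# key: value` metadata lines followed by two whitespace-separated
#' columns (time \[s\], current). Full double precision is kept so a
#' write/read cycle reproduces the trace bit-identically.
#'
#' @param trace an `nps_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nps_trace"))
  meta <- trace$meta
  meta$units <- if (isTRUE(meta$normalized)) "normalized" else meta$units
  meta$normalized <- NULL
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k, if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
  body <- paste(format(trace$t, digits = 17, scientific = TRUE, trim = TRUE),
                format(trace$i, digits = 17, scientific = TRUE, trim = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

phenotype_columns <- c("cell_id", "D_cell_um", "L_deform_um", "delta_deform",
                       "strain", "dT_cont_ms", "dT_r_ms", "dT_r_censored",
                       "wCDI", "recovery_class")

#' Write a per-cell phenotype table
#'
#' One row per cell, fixed column order: `cell_id`, `D_cell_um`,
#' `L_deform_um`, `delta_deform`, `strain`, `dT_cont_ms`, `dT_r_ms`,
#' `dT_r_censored`, `wCDI`, `recovery_class`. Censored recovery times
#' (cells that did not regain their free shape inside the measurement
#' window) are written as an empty `dT_r_ms` field with
#' `dT_r_censored = TRUE`. Floats are written at full precision so the
#' table round-trips exactly through [read_phenotypes()].
#'
#' @param phenotypes data.frame of phenotypes (e.g. from [phenotype_cells()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  if (NROW(phenotypes) == 0L) stop("no phenotype records to write", call. = FALSE)
  df <- as.data.frame(phenotypes)[, phenotype_columns]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    col <- format(df[[j]], digits = 17, trim = TRUE)
    col[is.na(df[[j]])] <- ""
    df[[j]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell phenotype table written by [write_phenotypes()]
#'
#' @param path CSV path.
#' @return data.frame with the standard phenotype columns; `dT_r_ms` is `NA`
#'   for censored cells.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character"))
  missing <- setdiff(phenotype_columns, names(df))
  if (length(missing))
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$dT_r_ms <- suppressWarnings(as.numeric(df$dT_r_ms))
  df$dT_r_censored <- as.logical(df$dT_r_censored)
  df[, phenotype_columns]
}
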