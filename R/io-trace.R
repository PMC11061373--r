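# Voltage traces: in-memory container and raw f32 + JSON sidecar storage.

#' Construct a voltage trace
#'
#' A single neuron's extracellular voltage signal in millivolts with its
#' sampling rate. All samples must be finite and the sampling rate positive.
#'
#' @param samples numeric vector of voltages (mV).
#' @param fs_hz sampling rate in Hz.
#' @param cell_id character identifier.
#' @return An object of class `voltage_trace` with fields `samples`, `fs_hz`,
#'   `cell_id`.
#' @export
voltage_trace <- function(samples, fs_hz, cell_id = "cell") {
  samples <- as.numeric(samples)
  if (length(fs_hz) != 1 || !is.finite(fs_hz) || fs_hz <= 0)
    bl_error("bad_fs", "fs_hz must be a single positive number, got %s", fs_hz[1])
  if (length(samples) && !all(is.finite(samples)))
    bl_error("non_finite_samples", "trace '%s' contains non-finite samples", cell_id)
  structure(list(samples = samples, fs_hz = as.numeric(fs_hz),
                 cell_id = as.character(cell_id)),
            class = "voltage_trace")
}

as_voltage_trace <- function(x) {
  if (inherits(x, "voltage_trace")) return(x)
  bl_error("not_a_trace", "expected a voltage_trace object")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace %s: %d samples @ %g Hz (%.1f s), range [%.3g, %.3g] mV>\n",
              x$cell_id, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz,
              if (length(x$samples)) min(x$samples) else NA,
              if (length(x$samples)) max(x$samples) else NA))
  invisible(x)
}

trace_duration <- function(trace) length(trace$samples) / trace$fs_hz

#' Write a voltage trace as raw float32 plus JSON sidecar
#'
#' Samples are stored as little-endian 32-bit floats at `<path>`; metadata
#' (`fs_hz`, `units`, `cell_id`, `n_samples`) goes to the sibling
#' `<path stripped of .f32>.json`.
#'
#' @param trace a [voltage_trace()].
#' @param path output path, conventionally ending in `.f32`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  trace <- as_voltage_trace(trace)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(trace$samples, con, size = 4L, endian = "little")
  side <- sub("\\.f32$", "", path)
  jsonlite::write_json(
    list(fs_hz = trace$fs_hz, units = "mV", cell_id = trace$cell_id,
         n_samples = length(trace$samples)),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voltage trace
#'
#' Accepts either a raw little-endian float32 file (`.f32`) with a JSON
#' sidecar holding `fs_hz`, `units` and `cell_id`, or a single-column CSV
#' whose leading `# key: value` comment lines carry the same metadata.
#'
#' @param path path to a `.f32` or `.csv` trace file.
#' @return A [voltage_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) bl_error("file_missing", "trace file not found: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(read_trace_csv(path))
  side <- paste0(sub("\\.f32$", "", path), ".json")
  if (!file.exists(side))
    bl_error("sidecar_missing", "JSON sidecar not found for %s (expected %s)", path, side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs_hz) || !is.finite(meta$fs_hz) || meta$fs_hz <= 0)
    bl_error("bad_fs", "sidecar %s: fs_hz must be positive", side)
  n <- file.info(path)$size / 4
  samples <- readBin(path, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(samples) && !all(is.finite(samples)))
    bl_error("non_finite_samples", "trace %s contains non-finite samples", path)
  voltage_trace(samples, meta$fs_hz, meta$cell_id %||% basename(path))
}

read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\\s*[:=]\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  if (is.null(meta$fs_hz)) bl_error("sidecar_missing", "CSV %s lacks a '# fs_hz:' header line", path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) && grepl("[A-Za-z]", body[1])) body <- body[-1]  # column header
  samples <- as.numeric(body[nzchar(body)])
  if (anyNA(samples) || (length(samples) && !all(is.finite(samples))))
    bl_error("non_finite_samples", "CSV trace %s contains non-numeric or non-finite samples", path)
  voltage_trace(samples, as.numeric(meta$fs_hz), meta$cell_id %||% basename(path))
}
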