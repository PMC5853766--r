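# Minimal RIFF/WAVE reader and writer (16-bit PCM and 32-bit IEEE float,
# mono or first-channel extraction) plus the JSON annotation sidecar.

#' Read a WAV file into a recording
#'
#' Supports 16-bit PCM and 32-bit float encodings; stereo files are
#' reduced to the first channel with a warning. Samples are scaled to
#' `[-1, 1]`. If `<path>.json` exists it is loaded as the annotation
#' sidecar.
#'
#' @param path Path to a `.wav` file.
#' @return A [pcg_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort_data(sprintf("file not found: %s", path), "pcgdx_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_data(sprintf("not a RIFF/WAVE file: %s", path),
               "pcgdx_format_error")
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        channels = readBin(con, "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, signed = FALSE,
                              endian = "little"),
        bits = readBin(con, "integer", 1, 2, signed = FALSE,
                       endian = "little"))
      extra <- size - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort_data(sprintf("missing fmt/data chunk: %s", path),
               "pcgdx_format_error")
  }
  x <- if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2,
            endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "numeric", length(data_raw) / 4, 4,
            endian = "little")
  } else {
    abort_data(sprintf("unsupported encoding (format %d, %d bit): %s",
                       fmt$audio_format, fmt$bits, path),
               "pcgdx_format_error")
  }
  if (fmt$channels > 1) {
    warning(sprintf("%s: %d channels; using the first", path,
                    fmt$channels), call. = FALSE)
    x <- x[seq(1, length(x), by = fmt$channels)]
  }
  x <- pmin(1, pmax(-1, x))
  ann <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) ann <- read_annotation(sidecar)
  pcg_recording(x, fmt$sample_rate, annotation = ann,
                source_id = basename(path))
}

#' Write a recording to a WAV file (plus optional annotation sidecar)
#'
#' @param rec A [pcg_recording()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @param sidecar Also write `<path>.json` with the annotation, if the
#'   recording has one (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16, sidecar = TRUE) {
  if (!bits %in% c(16, 32)) abort_config("bits must be 16 or 32", "bits")
  x <- pmin(1, pmax(-1, rec$samples))
  n <- length(x)
  bytes_per <- bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes_per), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2,
           endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(rec$sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate_hz * bytes_per), con, 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes_per), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmin(32767, round(x * 32768))), con, 2,
             endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  if (sidecar && !is.null(rec$annotation)) {
    write_annotation(rec$annotation, paste0(path, ".json"))
  }
  invisible(path)
}

#' Read / write the JSON annotation sidecar
#'
#' The sidecar schema is `{s1_times_s, s2_times_s, cycle_bounds_s,
#' label}`, shared between the simulator's ground truth and the
#' segmenter's output, so detections can be compared to annotations
#' directly.
#'
#' @param ann A [pcg_annotation()].
#' @param path JSON file path.
#' @return `read_annotation` returns a [pcg_annotation()].
#' @export
write_annotation <- function(ann, path) {
  jsonlite::write_json(list(s1_times_s = ann$s1_times_s,
                            s2_times_s = ann$s2_times_s,
                            cycle_bounds_s = unname(ann$cycle_bounds_s),
                            label = ann$label),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pcg_annotation(obj$s1_times_s, obj$s2_times_s,
                 matrix(obj$cycle_bounds_s, ncol = 2), obj$label)
}
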