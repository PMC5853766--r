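#' Diagnostic heart sound classes
#'
#' The five categories the classifier distinguishes: normal heart sounds,
#' third heart sound (S3), fourth heart sound (S4), systolic murmur, and
#' diastolic murmur.
#'
#' @format Character vector of length 5.
#' @export
PCG_CLASSES <- c("NORMAL", "S3", "S4", "SYSTOLIC_MURMUR", "DIASTOLIC_MURMUR")

abort_config <- function(msg, field = NULL) {
  stop(structure(
    class = c("pcgdx_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

abort_data <- function(msg, class = "pcgdx_data_error") {
  stop(structure(
    class = c(class, "pcgdx_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Construct a phonocardiogram recording
#'
#' Bundles a mono waveform with its sample rate, an optional ground-truth
#' [pcg_annotation()], and a free-text source identifier.
#'
#' @param samples Numeric vector of amplitudes; must lie in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param annotation Optional `pcg_annotation` with S1/S2 timing and label.
#' @param source_id Free-text provenance string.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, sample_rate_hz, annotation = NULL,
                          source_id = "") {
  if (!is.numeric(samples)) abort_config("samples must be numeric")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    abort_config("sample_rate_hz must be a positive number", "sample_rate_hz")
  }
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    abort_config("samples must lie within [-1, 1]", "samples")
  }
  if (!is.null(annotation) && !inherits(annotation, "pcg_annotation")) {
    abort_config("annotation must be a pcg_annotation or NULL", "annotation")
  }
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.numeric(sample_rate_hz),
         annotation = annotation,
         source_id = as.character(source_id)[1]),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf("<pcg_recording> %.2f s @ %g Hz (%d samples)\n",
              dur, x$sample_rate_hz, length(x$samples)))
  if (!is.null(x$annotation)) {
    cat(sprintf("  label: %s; %d cycles annotated\n",
                x$annotation$label, nrow(x$annotation$cycle_bounds_s)))
  }
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Ground-truth timing annotation for a recording
#'
#' Event times mark the acoustic centre of each sound (the peak of its
#' amplitude envelope), the quantity an envelogram detector localizes.
#' S1 and S2 events strictly interleave (S1 first) and each annotated cycle
#' contains exactly one S1 followed by one S2.
#'
#' @param s1_times_s Increasing numeric vector of S1 centre times (s).
#' @param s2_times_s Increasing numeric vector of S2 centre times (s), one
#'   per S1, each inside its cycle.
#' @param cycle_bounds_s Two-column matrix `(start, end)` per cardiac cycle.
#' @param label One of [PCG_CLASSES].
#' @return An object of class `pcg_annotation`.
#' @export
pcg_annotation <- function(s1_times_s, s2_times_s, cycle_bounds_s, label) {
  label <- match.arg(label, PCG_CLASSES)
  s1 <- as.numeric(s1_times_s); s2 <- as.numeric(s2_times_s)
  cb <- matrix(as.numeric(cycle_bounds_s), ncol = 2)
  colnames(cb) <- c("start", "end")
  if (length(s1) != length(s2) || length(s1) != nrow(cb)) {
    abort_config("one S1, one S2 and one cycle bound per cycle required")
  }
  if (is.unsorted(s1, strictly = TRUE) || is.unsorted(s2, strictly = TRUE)) {
    abort_config("event times must be strictly increasing")
  }
  inter <- as.vector(rbind(s1, s2))
  if (is.unsorted(inter, strictly = TRUE)) {
    abort_config("S1 and S2 events must strictly interleave")
  }
  structure(list(s1_times_s = s1, s2_times_s = s2, cycle_bounds_s = cb,
                 label = label),
            class = "pcg_annotation")
}

duration_s <- function(rec) length(rec$samples) / rec$sample_rate_hz

rms <- function(x) sqrt(mean(x^2))

db <- function(ratio) 10 * log10(ratio)
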