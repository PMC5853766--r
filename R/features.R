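# Per-cycle 40x40 spectrogram features. Each cardiac cycle (S1 onset to
# next S1 onset) is time-warped to a canonical 800 ms at a 1 kHz working
# rate, transformed with a short-time FFT, log-compressed, cropped to the
# heart-sound band with margin, and bilinearly resized to exactly 40x40.

#' Spectrogram feature configuration
#'
#' @param canonical_s Canonical cycle duration after time-warping, s.
#' @param working_rate_hz Analysis sample rate, Hz.
#' @param window_ms STFT window (Hann), ms.
#' @param overlap Fractional window overlap.
#' @param nfft FFT length (zero-padded).
#' @param freq_range_hz Two-element crop of the frequency axis, Hz; covers
#'   the 20-100 Hz heart-sound band with margin.
#' @param size Output grid side (time x frequency), fixed at 40 for the
#'   classifier input.
#' @return List of class `spectrogram_config`.
#' @export
spectrogram_config <- function(canonical_s = 0.8, working_rate_hz = 1000,
                               window_ms = 64, overlap = 0.75, nfft = 256,
                               freq_range_hz = c(10, 200), size = 40) {
  if (length(freq_range_hz) != 2 || freq_range_hz[1] >= freq_range_hz[2]) {
    abort_config("freq_range_hz must be an ascending pair", "freq_range_hz")
  }
  if (freq_range_hz[2] > working_rate_hz / 2) {
    abort_config("freq_range_hz exceeds the working Nyquist",
                 "freq_range_hz")
  }
  structure(list(canonical_s = canonical_s,
                 working_rate_hz = working_rate_hz,
                 window_ms = window_ms, overlap = overlap, nfft = nfft,
                 freq_range_hz = freq_range_hz, size = as.integer(size)),
            class = "spectrogram_config")
}

# linear-interpolation weight matrix mapping n_in regular grid points to
# n_out points spanning the same interval
interp_weights <- function(n_in, n_out) {
  if (n_in == 1) return(matrix(1, n_out, 1))
  x <- seq(1, n_in, length.out = n_out)
  i0 <- pmin(floor(x), n_in - 1)
  f <- x - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0)] <- 1 - f
  W[cbind(seq_len(n_out), i0 + 1)] <- f
  W
}

#' Extract the 40x40 spectrogram feature of one cardiac cycle
#'
#' The cycle waveform is peak-normalized (device gain cancels exactly),
#' linearly time-warped to the canonical duration, analyzed with a Hann
#' STFT, compressed as `log(1 + |X|)`, cropped in frequency, bilinearly
#' interpolated to a `size x size` grid (rows = time, columns =
#' frequency), and min-max normalized to `[0, 1]` (an all-zero cycle maps
#' to an all-zero matrix).
#'
#' @param rec A [pcg_recording()].
#' @param cycle Two-element `(start, end)` in seconds, within the
#'   recording, at least 200 ms long.
#' @param config A [spectrogram_config()].
#' @return List of class `spectrogram_feature` with fields `matrix`,
#'   `cycle_index`, `time_span_s`, `freq_range_hz`.
#' @export
extract_cycle_spectrogram <- function(rec, cycle,
                                      config = spectrogram_config()) {
  start <- cycle[1]; end <- cycle[2]
  if (!is.finite(start) || !is.finite(end) || end - start < 0.2) {
    abort_data("degenerate cycle: shorter than 200 ms",
               "pcgdx_feature_error")
  }
  if (start < 0 || end > duration_s(rec) + 1e-9) {
    abort_data("cycle extends beyond the recording",
               "pcgdx_feature_error")
  }
  fs <- rec$sample_rate_hz
  i0 <- max(1L, floor(start * fs) + 1L)
  i1 <- min(length(rec$samples), ceiling(end * fs))
  x <- rec$samples[i0:i1]
  if (max(abs(x)) > 0) x <- x / max(abs(x))

  # time-warp to the canonical duration at the working rate
  n_out <- round(config$canonical_s * config$working_rate_hz)
  x <- stats::approx(seq(0, 1, length.out = length(x)), x,
                     xout = seq(0, 1, length.out = n_out))$y

  wlen <- round(config$window_ms / 1000 * config$working_rate_hz)
  hop <- max(1L, round(wlen * (1 - config$overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / wlen)
  starts <- seq(1L, n_out - wlen + 1L, by = hop)
  frames <- vapply(starts, function(s) {
    fr <- x[s:(s + wlen - 1)] * w
    c(fr, numeric(config$nfft - wlen))
  }, numeric(config$nfft))
  S <- Mod(stats::mvfft(frames))               # nfft x nframes
  freqs <- (seq_len(config$nfft) - 1) / config$nfft * config$working_rate_hz
  keep <- which(freqs >= config$freq_range_hz[1] &
                  freqs <= config$freq_range_hz[2])
  S <- log1p(S[keep, , drop = FALSE])          # freq x time

  # separable bilinear resize to size x size, rows = time, columns =
  # frequency (two small interpolation-weight matrix products)
  M <- interp_weights(ncol(S), config$size) %*% t(S) %*%
    t(interp_weights(nrow(S), config$size))

  rng <- range(M)
  M <- if (diff(rng) > 0) (M - rng[1]) / diff(rng) else matrix(0, config$size,
                                                               config$size)
  structure(list(matrix = M, cycle_index = NA_integer_,
                 time_span_s = c(start, end),
                 freq_range_hz = config$freq_range_hz),
            class = "spectrogram_feature")
}

#' Extract features for every complete cycle of a recording
#'
#' One feature per cycle, in order; cycles that fail extraction (too
#' short, out of bounds) are skipped with a warning.
#'
#' @param rec A [pcg_recording()].
#' @param seg A `cycle_segmentation` from [segment()], or a
#'   [pcg_annotation()] (its `cycle_bounds_s` are used).
#' @param config A [spectrogram_config()].
#' @return List of `spectrogram_feature` objects.
#' @export
featurize_recording <- function(rec, seg, config = spectrogram_config()) {
  cycles <- if (inherits(seg, "pcg_annotation")) {
    seg$cycle_bounds_s
  } else if (inherits(seg, "cycle_segmentation")) {
    cbind(seg$cycles[, "s1"], seg$cycles[, "next_s1"])
  } else {
    abort_config("seg must be a cycle_segmentation or pcg_annotation", "seg")
  }
  if (!nrow(cycles)) abort_data("no complete cycles to featurize",
                                "pcgdx_feature_error")
  # a detected last-cycle bound may overhang the recording end slightly
  cycles[, 2] <- pmin(cycles[, 2], duration_s(rec))
  out <- list()
  for (k in seq_len(nrow(cycles))) {
    ft <- tryCatch(extract_cycle_spectrogram(rec, cycles[k, ], config),
                   pcgdx_data_error = function(e) {
                     warning(sprintf("cycle %d skipped: %s", k,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (!is.null(ft)) {
      ft$cycle_index <- k
      out[[length(out) + 1]] <- ft
    }
  }
  if (!length(out)) abort_data("no cycle could be featurized",
                               "pcgdx_feature_error")
  out
}
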