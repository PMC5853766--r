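# Denoising front end: zero-phase Butterworth band-pass restricted to the
# 20-100 Hz heart-sound band, magnitude spectral subtraction with
# overlap-add resynthesis, and a heuristic interpretability gate mirroring
# the two signal-domain failure modes of bedside recordings (low amplitude,
# high background noise).

#' Zero-phase Butterworth band-pass filter
#'
#' Heart sound energy concentrates in 20-100 Hz, so a simple band-pass
#' attenuates lung sounds and rumble without touching S1/S2 timing
#' (forward-backward filtering is zero phase). Length, sample rate and
#' annotation are preserved.
#'
#' @param rec A [pcg_recording()].
#' @param low_cut_hz,high_cut_hz Band edges in Hz.
#' @param order Butterworth design order (default 4).
#' @param zero_phase Apply forward-backward (`filtfilt`)? Default `TRUE`.
#' @return The filtered [pcg_recording()].
#' @export
bandpass <- function(rec, low_cut_hz = 20, high_cut_hz = 100, order = 4,
                     zero_phase = TRUE) {
  nyq <- rec$sample_rate_hz / 2
  if (!(low_cut_hz > 0 && low_cut_hz < high_cut_hz && high_cut_hz < nyq)) {
    abort_config("need 0 < low_cut_hz < high_cut_hz < Nyquist",
                 "high_cut_hz")
  }
  bf <- signal::butter(order, c(low_cut_hz, high_cut_hz) / nyq, type = "pass")
  x <- rec$samples
  # reflect-pad so filter edge transients decay inside the padding
  np <- min(length(x) - 1L, round(0.5 * rec$sample_rate_hz))
  xp <- c(rev(x[seq_len(np)]), x, rev(x[(length(x) - np + 1):length(x)]))
  y <- if (zero_phase) signal::filtfilt(bf, xp)
       else as.numeric(signal::filter(bf, xp))
  y <- y[(np + 1):(np + length(x))]
  y <- pmin(1, pmax(-1, y))
  pcg_recording(y, rec$sample_rate_hz, annotation = rec$annotation,
                source_id = rec$source_id)
}

#' Spectral-subtraction denoising parameters
#'
#' @param frame_ms Analysis frame length, ms (default 256 ms).
#' @param hop_frac Hop as a fraction of the frame (default 0.5).
#' @param noise_percentile Fraction of lowest-energy frames averaged into
#'   the noise magnitude estimate, in `(0, 0.5]`.
#' @param over_subtraction Multiplier on the noise magnitude (default 1.5:
#'   the quietest-frames estimate is biased low, so modest
#'   over-subtraction is needed to remove stationary noise fully).
#' @param spectral_floor Minimum retained fraction of each magnitude bin,
#'   in `[0, 0.5]`.
#' @return A validated list of class `denoise_params`.
#' @export
denoise_params <- function(frame_ms = 256, hop_frac = 0.5,
                           noise_percentile = 0.1, over_subtraction = 1.5,
                           spectral_floor = 0.05) {
  if (!(hop_frac > 0 && hop_frac <= 1)) {
    abort_config("hop_frac must lie in (0, 1]", "hop_frac")
  }
  if (!(noise_percentile > 0 && noise_percentile <= 0.5)) {
    abort_config("noise_percentile must lie in (0, 0.5]", "noise_percentile")
  }
  if (!(spectral_floor >= 0 && spectral_floor <= 0.5)) {
    abort_config("spectral_floor must lie in [0, 0.5]", "spectral_floor")
  }
  structure(list(frame_ms = frame_ms, hop_frac = hop_frac,
                 noise_percentile = noise_percentile,
                 over_subtraction = over_subtraction,
                 spectral_floor = spectral_floor),
            class = "denoise_params")
}

#' FFT-based spectral subtraction
#'
#' Classic magnitude spectral subtraction: short-time FFT with a Hann
#' window, noise magnitude estimated as the mean spectrum of the
#' lowest-energy frames, per-bin magnitude
#' `max(|X| - over_subtraction * |N|, spectral_floor * |X|)`, and
#' weighted overlap-add resynthesis with the original phase. Output length
#' equals input length; the annotation is unchanged.
#'
#' @param rec A [pcg_recording()].
#' @param params A [denoise_params()].
#' @return The denoised [pcg_recording()].
#' @export
spectral_subtract <- function(rec, params = denoise_params()) {
  x <- rec$samples
  fs <- rec$sample_rate_hz
  flen <- round(params$frame_ms / 1000 * fs)
  if (length(x) < flen) {
    abort_data("recording shorter than one analysis frame")
  }
  hop <- max(1L, round(flen * params$hop_frac))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / flen)   # Hann
  nfr <- max(1L, floor((length(x) - flen) / hop) + 1L)
  pad <- max(length(x), (nfr - 1L) * hop + flen)
  xp <- c(x, numeric(pad - length(x)))

  starts <- (seq_len(nfr) - 1L) * hop
  frames <- vapply(starts, function(s) xp[(s + 1):(s + flen)] * w,
                   numeric(flen))
  X <- stats::mvfft(frames)
  mag <- Mod(X)

  energy <- colSums(frames^2)
  k <- max(1L, ceiling(params$noise_percentile * nfr))
  quiet <- order(energy)[seq_len(k)]
  nhat <- rowMeans(mag[, quiet, drop = FALSE])

  newmag <- pmax(mag - params$over_subtraction * nhat,
                 params$spectral_floor * mag)
  scale <- ifelse(mag > 0, newmag / mag, 0)
  Y <- X * scale

  yfr <- Re(stats::mvfft(Y, inverse = TRUE)) / flen
  y <- numeric(pad); den <- numeric(pad)
  for (j in seq_len(nfr)) {
    idx <- (starts[j] + 1):(starts[j] + flen)
    y[idx] <- y[idx] + yfr[, j] * w
    den[idx] <- den[idx] + w^2
  }
  y <- ifelse(den > 1e-8, y / pmax(den, 1e-8), 0)
  y <- pmin(1, pmax(-1, y[seq_along(x)]))
  pcg_recording(y, fs, annotation = rec$annotation, source_id = rec$source_id)
}

#' Interpretability gate for acquired recordings
#'
#' Mechanizes the two signal-domain reasons a bedside phone recording fails
#' review: too small an amplitude, and background noise drowning the heart
#' sounds. The SNR estimate is the ratio of envelope-peak power (top decile
#' of a 200 ms power envelope) to envelope-trough power (bottom
#' quintile). The gate is advisory: it flags, it does not drop.
#'
#' @param rec A [pcg_recording()].
#' @param min_snr_db Minimum acceptable estimated SNR (default 5 dB).
#' @param min_peak Minimum acceptable peak amplitude, full scale
#'   (default 0.01).
#' @return A list of class `interpretability_report` with fields
#'   `interpretable`, `estimated_snr_db`, `peak_amplitude`, `reasons`.
#' @export
assess_interpretability <- function(rec, min_snr_db = 5, min_peak = 0.01) {
  x <- rec$samples
  if (!length(x)) abort_data("empty recording")
  peak <- max(abs(x))
  # a 200 ms power envelope: long enough that stationary in-band noise
  # shows almost no peak/trough contrast, while pulsatile heart sounds
  # keep a large one (diastolic troughs stay near the noise floor)
  win <- max(3L, round(0.2 * rec$sample_rate_hz))
  env2 <- stats::filter(x^2, rep(1 / win, win), sides = 2)
  env2 <- env2[!is.na(env2)]
  qs <- stats::quantile(env2, c(0.2, 0.9), names = FALSE)
  sig_p <- mean(env2[env2 >= qs[2]])
  noi_p <- mean(env2[env2 <= qs[1]])
  est_snr <- if (noi_p <= 0) Inf else db(max(sig_p - noi_p, 0) / noi_p)

  reasons <- character()
  if (peak < min_peak) reasons <- c(reasons, "LOW_AMPLITUDE")
  if (est_snr < min_snr_db) reasons <- c(reasons, "HIGH_NOISE")
  structure(list(interpretable = length(reasons) == 0,
                 estimated_snr_db = est_snr,
                 peak_amplitude = peak,
                 reasons = reasons),
            class = "interpretability_report")
}
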