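# Synthetic phonocardiogram generator.
#
# Timbre model: S1 and S2 are Gaussian-windowed tone bursts inside the
# 20-100 Hz band where heart sound energy concentrates; murmurs are
# band-limited (40-100 Hz) Gaussian noise shaped by the canonical
# phonocardiographic envelopes (diamond for systolic, decrescendo for
# diastolic); S3/S4 are fainter low-frequency bursts at their physiologic
# offsets from S2/S1.

#' Simulation configuration for a synthetic phonocardiogram
#'
#' Defaults reflect the recording protocol the package targets: roughly 10 s
#' recordings in a quiet room (30 dB SNR), resting heart rate, and a sample
#' rate comfortably above the heart-sound band.
#'
#' @param sound_class One of [PCG_CLASSES].
#' @param heart_rate_bpm Mean heart rate, beats/minute, in `[30, 200]`.
#' @param duration_s Recording length in seconds (> 0).
#' @param sample_rate_hz Sampling rate, Hz (>= 2000).
#' @param af_mode If `TRUE`, RR intervals are irregular (atrial
#'   fibrillation); incompatible with `sound_class = "S4"` since AF
#'   abolishes the atrial kick that produces S4.
#' @param rr_cv Coefficient of variation of RR intervals when `af_mode`.
#' @param murmur_intensity Murmur amplitude relative to S1, `>= 0`.
#' @param snr_db Signal-to-noise ratio of added environmental noise, dB;
#'   `Inf` for a clean recording.
#' @param noise_profile Named mix weights for `white`, `pink` and `hum`
#'   noise components (non-negative, not all zero).
#' @param seed Integer RNG seed; the simulator is deterministic given
#'   `(config, seed)`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(sound_class = "NORMAL",
                       heart_rate_bpm = 70,
                       duration_s = 10,
                       sample_rate_hz = 2000,
                       af_mode = FALSE,
                       rr_cv = 0.2,
                       murmur_intensity = 0.5,
                       snr_db = 30,
                       noise_profile = c(white = 1, pink = 0, hum = 0),
                       seed = 1L) {
  sound_class <- match.arg(sound_class, PCG_CLASSES)
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm < 30 ||
      heart_rate_bpm > 200) {
    abort_config("heart_rate_bpm must lie in [30, 200]", "heart_rate_bpm")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz < 2000) {
    abort_config("sample_rate_hz must be >= 2000", "sample_rate_hz")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort_config("duration_s must be positive", "duration_s")
  }
  if (!is.numeric(murmur_intensity) || murmur_intensity < 0) {
    abort_config("murmur_intensity must be >= 0", "murmur_intensity")
  }
  if (isTRUE(af_mode) && sound_class == "S4") {
    abort_config("af_mode cannot be combined with sound_class 'S4'",
                 "af_mode")
  }
  if (isTRUE(af_mode) && (!is.numeric(rr_cv) || rr_cv <= 0 || rr_cv >= 1)) {
    abort_config("rr_cv must lie in (0, 1)", "rr_cv")
  }
  np <- noise_profile[c("white", "pink", "hum")]
  np[is.na(np)] <- 0
  if (any(np < 0) || sum(np) <= 0) {
    abort_config("noise_profile weights must be non-negative, not all zero",
                 "noise_profile")
  }
  structure(list(sound_class = sound_class,
                 heart_rate_bpm = heart_rate_bpm,
                 duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz,
                 af_mode = isTRUE(af_mode),
                 rr_cv = rr_cv,
                 murmur_intensity = murmur_intensity,
                 snr_db = snr_db,
                 noise_profile = np / sum(np),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gaussian-windowed tone burst added in place. centre_s is the acoustic
# centre; sigma = duration/6 so the burst is essentially contained.
add_burst <- function(x, fs, centre_s, freq_hz, dur_s, amp, phase = 0) {
  half <- dur_s / 2
  i0 <- max(1L, floor((centre_s - half) * fs) + 1L)
  i1 <- min(length(x), ceiling((centre_s + half) * fs) + 1L)
  if (i1 < i0) return(x)
  t <- (seq(i0, i1) - 1) / fs
  g <- exp(-0.5 * ((t - centre_s) / (dur_s / 6))^2)
  x[i0:i1] <- x[i0:i1] + amp * g * sin(2 * pi * freq_hz * (t - centre_s) + phase)
  x
}

# Zero-phase band-limited Gaussian noise (unit variance), 4th-order
# Butterworth applied forward-backward.
bandlimited_noise <- function(n, fs, low_hz, high_hz) {
  raw <- stats::rnorm(n + 2000)           # pad against filter edge transients
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, raw)[1001:(1000 + n)]
  y / stats::sd(y)
}

#' Generate one annotated synthetic phonocardiogram
#'
#' Lays down S1 bursts at (regular or gamma-distributed) RR intervals with
#' S2 at 35% of each RR interval, adds the class-specific extra sound or
#' murmur, peak-normalizes to 0.9, and adds environmental noise at the
#' configured SNR. Fully deterministic given the config (which includes the
#' seed). Annotated times mark the acoustic centre of each sound.
#'
#' @param config A [sim_config()].
#' @return A [pcg_recording()] carrying a complete [pcg_annotation()].
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  mean_rr <- 60 / config$heart_rate_bpm

  set.seed(config$seed)

  # --- cycle timing ------------------------------------------------------
  # First S1 leaves room for a possible S4 burst; cycles must end inside
  # the recording (with margin for the S2/diastolic content of the last).
  t1 <- vector("numeric"); rr <- vector("numeric")
  t <- 0.35
  repeat {
    this_rr <- if (config$af_mode) {
      shape <- 1 / config$rr_cv^2
      stats::rgamma(1, shape = shape, scale = mean_rr / shape)
    } else mean_rr
    this_rr <- max(this_rr, 0.3)   # refractory floor
    if (t + this_rr > config$duration_s - 0.05) break
    t1 <- c(t1, t); rr <- c(rr, this_rr)
    t <- t + this_rr
  }
  if (!length(t1)) abort_config("duration_s too short for one cardiac cycle",
                                "duration_s")
  t2 <- t1 + 0.35 * rr

  # --- deterministic heart sounds ---------------------------------------
  x <- numeric(n)
  for (k in seq_along(t1)) {
    x <- add_burst(x, fs, t1[k], freq_hz = 35, dur_s = 0.110, amp = 1.0)
    x <- add_burst(x, fs, t2[k], freq_hz = 60, dur_s = 0.090, amp = 0.8)
  }

  cls <- config$sound_class
  if (cls == "S3") {
    off <- stats::runif(length(t1), 0.120, 0.180)
    for (k in seq_along(t1)) {
      x <- add_burst(x, fs, t2[k] + off[k], freq_hz = 30, dur_s = 0.060,
                     amp = 0.4)
    }
  } else if (cls == "S4") {
    off <- stats::runif(length(t1), 0.070, 0.100)
    for (k in seq_along(t1)) {
      x <- add_burst(x, fs, t1[k] - off[k], freq_hz = 30, dur_s = 0.060,
                     amp = 0.4)
    }
  } else if (cls %in% c("SYSTOLIC_MURMUR", "DIASTOLIC_MURMUR")) {
    noi <- bandlimited_noise(n, fs, 40, 100) / 3   # ~unit peak amplitude
    env <- numeric(n)
    tt <- (seq_len(n) - 1) / fs
    for (k in seq_along(t1)) {
      if (cls == "SYSTOLIC_MURMUR") {
        # diamond (crescendo-decrescendo) between end of S1 and start of S2
        a <- t1[k] + 0.055; b <- t2[k] - 0.045
        if (b <= a) next
        sel <- tt >= a & tt <= b
        f <- (tt[sel] - a) / (b - a)
        env[sel] <- pmax(env[sel], 1 - abs(2 * f - 1))
      } else {
        # decrescendo from just after S2 across early-mid diastole
        a <- t2[k] + 0.060; b <- t2[k] + 0.060 + 0.55 * (rr[k] - 0.35 * rr[k])
        b <- min(b, t1[k] + rr[k] - 0.080)
        if (b <= a) next
        sel <- tt >= a & tt <= b
        f <- (tt[sel] - a) / (b - a)
        env[sel] <- pmax(env[sel], (1 - f)^1.5)
      }
    }
    x <- x + config$murmur_intensity * env * noi
  }

  x <- x / max(abs(x)) * 0.9

  ann <- pcg_annotation(s1_times_s = t1, s2_times_s = t2,
                        cycle_bounds_s = cbind(t1, t1 + rr),
                        label = cls)
  rec <- pcg_recording(x, fs, annotation = ann,
                       source_id = sprintf("synth:%s:seed=%d", cls,
                                           config$seed))
  if (is.finite(config$snr_db)) {
    rec <- add_noise(rec, config$snr_db, config$noise_profile,
                     seed = config$seed + 104729L)
  }
  rec
}

noise_realization <- function(n, fs, profile, seed) {
  set.seed(seed)
  comp <- matrix(0, n, 3)
  if (profile[["white"]] > 0) comp[, 1] <- stats::rnorm(n)
  if (profile[["pink"]] > 0) {
    # shape white noise to a 1/f power spectrum in the frequency domain
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1))                       # guard DC
    f <- pmin(f, n - f + 1)                          # two-sided symmetry
    W <- W / sqrt(f)
    p <- Re(stats::fft(W, inverse = TRUE)) / n
    comp[, 2] <- p / stats::sd(p)
  }
  if (profile[["hum"]] > 0) {
    t <- (seq_len(n) - 1) / fs
    h <- sin(2 * pi * 60 * t) + 0.3 * sin(2 * pi * 180 * t)
    comp[, 3] <- h / stats::sd(h)
  }
  mix <- comp %*% sqrt(profile)    # weights apportion noise *power*
  as.vector(mix) / stats::sd(mix)
}

#' Add environmental noise at an exact signal-to-noise ratio
#'
#' The noise realization is scaled so the requested global SNR (relative to
#' the clean input) is met exactly; the annotation is carried through
#' unchanged. If the sum would clip, signal and noise are scaled down
#' together (SNR preserved).
#'
#' @param rec A [pcg_recording()].
#' @param snr_db Target SNR in dB (finite).
#' @param noise_profile Named weights for `white`, `pink`, `hum` components.
#' @param seed RNG seed for the noise realization.
#' @return A [pcg_recording()] with the same annotation.
#' @export
add_noise <- function(rec, snr_db, noise_profile = c(white = 1, pink = 0,
                                                     hum = 0),
                      seed = 1L) {
  if (!length(rec$samples)) abort_data("cannot add noise to an empty recording")
  if (!is.finite(snr_db)) abort_config("snr_db must be finite", "snr_db")
  np <- noise_profile[c("white", "pink", "hum")]
  np[is.na(np)] <- 0
  if (any(np < 0) || sum(np) <= 0) {
    abort_config("noise_profile weights must be non-negative, not all zero",
                 "noise_profile")
  }
  np <- np / sum(np)
  n <- length(rec$samples)
  noi <- noise_realization(n, rec$sample_rate_hz, np, seed)
  target_rms <- rms(rec$samples) / 10^(snr_db / 20)
  noi <- noi / rms(noi) * target_rms     # make the realized SNR exact
  # hard-clip the (rare) excursions beyond full scale; rescaling instead
  # would silently change the signal level and so the realized SNR
  y <- pmin(1, pmax(-1, rec$samples + noi))
  pcg_recording(y, rec$sample_rate_hz, annotation = rec$annotation,
                source_id = rec$source_id)
}

#' Generate a balanced labeled dataset of synthetic recordings
#'
#' Draws per-recording heart rates, murmur intensities and SNRs uniformly
#' from the configured ranges, balanced across the five classes, with
#' per-recording seeds derived reproducibly from `seed`.
#'
#' @param per_class_count Recordings per class (>= 1).
#' @param config_ranges List with two-element ranges `heart_rate_bpm`,
#'   `murmur_intensity`, `snr_db`, optional scalar `af_frac` (fraction of
#'   eligible recordings simulated in AF) and scalars `duration_s`,
#'   `sample_rate_hz`.
#' @param seed Master RNG seed.
#' @return List with elements `recordings` (list of [pcg_recording()]) and
#'   `labels` (character vector).
#' @export
generate_dataset <- function(per_class_count,
                             config_ranges = list(),
                             seed = 1L) {
  if (!is.numeric(per_class_count) || per_class_count < 1) {
    abort_config("per_class_count must be >= 1", "per_class_count")
  }
  defaults <- list(heart_rate_bpm = c(50, 110),
                   murmur_intensity = c(0.3, 0.8),
                   snr_db = c(15, 30),
                   af_frac = 0,
                   duration_s = 10,
                   sample_rate_hz = 2000)
  cr <- utils::modifyList(defaults, config_ranges)
  for (f in c("heart_rate_bpm", "murmur_intensity", "snr_db")) {
    if (length(cr[[f]]) != 2 || any(!is.finite(cr[[f]])) ||
        cr[[f]][1] > cr[[f]][2]) {
      abort_config(sprintf("range '%s' must be two finite ascending values",
                           f), f)
    }
  }
  m <- as.integer(per_class_count)
  labels <- rep(PCG_CLASSES, each = m)
  ntot <- length(labels)
  set.seed(seed)
  hr <- stats::runif(ntot, cr$heart_rate_bpm[1], cr$heart_rate_bpm[2])
  mi <- stats::runif(ntot, cr$murmur_intensity[1], cr$murmur_intensity[2])
  sn <- stats::runif(ntot, cr$snr_db[1], cr$snr_db[2])
  af <- stats::runif(ntot) < cr$af_frac & labels != "S4"
  seeds <- sample.int(2^30, ntot)
  recs <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    cfg <- sim_config(sound_class = labels[i], heart_rate_bpm = hr[i],
                      duration_s = cr$duration_s,
                      sample_rate_hz = cr$sample_rate_hz,
                      af_mode = af[i], murmur_intensity = mi[i],
                      snr_db = sn[i], seed = seeds[i])
    recs[[i]] <- generate_recording(cfg)
  }
  list(recordings = recs, labels = labels)
}
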