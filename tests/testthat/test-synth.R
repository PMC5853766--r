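test_that("regular rhythm lays S1 beats at exactly 60/HR spacing", {
  rec <- quiet_rec(sound_class = "NORMAL", heart_rate_bpm = 60,
                   duration_s = 10, snr_db = Inf)
  s1 <- rec$annotation$s1_times_s
  expect_true(abs(length(s1) - 10) <= 1)      # one boundary cycle of slack
  expect_lt(max(abs(diff(s1) - 1.0)), 1e-3)   # RR sd < 1 ms
  expect_equal(length(rec$samples), 10 * rec$sample_rate_hz)
  expect_lte(max(abs(rec$samples)), 1)
})

test_that("annotation invariants hold across classes and rhythms", {
  for (cls in PCG_CLASSES) {
    af <- cls == "S3"   # exercise AF on one eligible class
    rec <- quiet_rec(sound_class = cls, heart_rate_bpm = 75, af_mode = af,
                     seed = 7)
    ann <- rec$annotation
    expect_identical(ann$label, cls)
    expect_equal(length(ann$s1_times_s), nrow(ann$cycle_bounds_s))
    expect_equal(length(ann$s1_times_s), length(ann$s2_times_s))
    inter <- as.vector(rbind(ann$s1_times_s, ann$s2_times_s))
    expect_false(is.unsorted(inter, strictly = TRUE))
    # each S2 inside its own cycle
    expect_true(all(ann$s2_times_s > ann$cycle_bounds_s[, 1] &
                      ann$s2_times_s < ann$cycle_bounds_s[, 2]))
  }
})

test_that("AF mode recovers the configured RR coefficient of variation", {
  rec <- quiet_rec(heart_rate_bpm = 70, duration_s = 200, af_mode = TRUE,
                   rr_cv = 0.2, snr_db = Inf, seed = 2)
  rr <- diff(rec$annotation$s1_times_s)
  expect_gte(length(rr), 199)
  cv <- sd(rr) / mean(rr)
  expect_lt(abs(cv - 0.2), 0.05)
})

test_that("systolic murmur puts band-limited energy in systole", {
  rec <- quiet_rec(sound_class = "SYSTOLIC_MURMUR", murmur_intensity = 0.5,
                   heart_rate_bpm = 60, snr_db = Inf, seed = 4)
  ann <- rec$annotation
  fs <- rec$sample_rate_hz
  band_energy <- function(centres) {
    vapply(centres, function(centre) {
      idx <- round((centre - 0.05) * fs):round((centre + 0.05) * fs)
      mean(rec$samples[idx]^2)
    }, numeric(1))
  }
  # mid-systole vs mid-diastole windows, away from S1/S2/S3 positions
  mid_sys <- mean(band_energy((ann$s1_times_s + ann$s2_times_s) / 2))
  rr <- diff(ann$cycle_bounds_s[1, ])
  mid_dia <- mean(band_energy(ann$s2_times_s + 0.45 * rr))
  expect_gte(10 * log10(mid_sys / mid_dia), 6)
})

test_that("diastolic murmur energy sits in diastole instead", {
  rec <- quiet_rec(sound_class = "DIASTOLIC_MURMUR", murmur_intensity = 0.5,
                   heart_rate_bpm = 60, snr_db = Inf, seed = 4)
  ann <- rec$annotation
  fs <- rec$sample_rate_hz
  win <- function(centres) {
    vapply(centres, function(centre) {
      idx <- round((centre - 0.05) * fs):round((centre + 0.05) * fs)
      mean(rec$samples[idx]^2)
    }, numeric(1))
  }
  early_dia <- mean(win(ann$s2_times_s + 0.15))
  mid_sys <- mean(win((ann$s1_times_s + ann$s2_times_s) / 2))
  expect_gt(10 * log10(early_dia / mid_sys), 3)
})

test_that("most synthesized energy lies below 150 Hz", {
  for (cls in PCG_CLASSES) {
    rec <- quiet_rec(sound_class = cls, seed = 5)
    sp <- Mod(stats::fft(rec$samples))^2
    f <- (seq_along(sp) - 1) / length(sp) * rec$sample_rate_hz
    half <- f <= rec$sample_rate_hz / 2
    frac <- sum(sp[half & f < 150]) / sum(sp[half])
    expect_gte(frac, 0.9)
  }
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- sim_config(sound_class = "S3", seed = 42)
  expect_identical(generate_recording(cfg)$samples,
                   generate_recording(cfg)$samples)
  other <- generate_recording(sim_config(sound_class = "S3", seed = 43))
  expect_false(identical(generate_recording(cfg)$samples, other$samples))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(heart_rate_bpm = 20), "heart_rate_bpm",
               class = "pcgdx_config_error")
  expect_error(sim_config(sample_rate_hz = 500), "sample_rate_hz",
               class = "pcgdx_config_error")
  expect_error(sim_config(murmur_intensity = -0.1), "murmur_intensity",
               class = "pcgdx_config_error")
  expect_error(sim_config(sound_class = "S4", af_mode = TRUE), "af_mode",
               class = "pcgdx_config_error")
})

test_that("add_noise hits the requested SNR and leaves annotation alone", {
  rec <- quiet_rec(snr_db = Inf, seed = 3)
  noisy0 <- add_noise(rec, 0, seed = 9)
  resid <- noisy0$samples - rec$samples
  achieved <- 20 * log10(sqrt(mean(rec$samples^2)) / sqrt(mean(resid^2)))
  expect_lt(abs(achieved - 0), 0.5)
  expect_identical(noisy0$annotation, rec$annotation)

  hi <- add_noise(rec, 60, seed = 9)
  expect_lt(sqrt(mean((hi$samples - rec$samples)^2)) /
              sqrt(mean(rec$samples^2)), 0.01)
  expect_error(add_noise(rec, NaN), class = "pcgdx_config_error")
})

test_that("pink noise falls off with frequency (~ -3 dB/octave)", {
  n <- 2^17
  x <- pcgdx:::noise_realization(n, 2000, c(white = 0, pink = 1, hum = 0),
                                 seed = 5)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / n * 2000
  sel <- f >= 20 & f <= 500
  fit <- stats::lm(log10(sp[sel]) ~ log10(f[sel]))
  slope_db_oct <- 10 * coef(fit)[2] * log10(2)
  expect_lt(abs(slope_db_oct - (-3)), 1)
})

test_that("generate_dataset is balanced, reproducible, seed-sensitive", {
  ds <- generate_dataset(3, seed = 5)
  expect_length(ds$recordings, 15)
  expect_equal(unname(table(ds$labels)), rep(3L, 5), ignore_attr = TRUE)
  ds2 <- generate_dataset(3, seed = 5)
  expect_identical(ds$recordings[[7]]$samples, ds2$recordings[[7]]$samples)
  ds3 <- generate_dataset(3, seed = 6)
  expect_identical(table(ds3$labels), table(ds$labels))
  expect_false(identical(ds$recordings[[1]]$samples,
                         ds3$recordings[[1]]$samples))
  expect_error(generate_dataset(0), class = "pcgdx_config_error")
  expect_error(generate_dataset(2, list(snr_db = numeric())),
               class = "pcgdx_config_error")
})
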