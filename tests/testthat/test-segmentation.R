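test_that("Shannon energy of constant signals matches the closed form", {
  # 0 * ln 0 := 0; |x| = 1 gives exactly 0; |x| = e^{-1/2} attains the
  # transform's maximum e^{-1}
  zero <- shannon_envelope(numeric(1000), normalize = FALSE,
                           standardize = FALSE)
  expect_true(all(zero$values == 0))

  ones <- shannon_envelope(rep(1, 1000), normalize = FALSE,
                           standardize = FALSE)
  expect_equal(max(abs(ones$values)), 0, tolerance = 1e-12)

  opt <- shannon_envelope(rep(exp(-0.5), 1000), normalize = FALSE,
                          standardize = FALSE)
  expect_equal(unique(round(opt$values, 10)), round(exp(-1), 10))
  expect_equal(exp(-1), shannon_of_const(exp(-0.5)))
  # e^{-1/2} is the argmax of -x^2 ln x^2 on (0, 1]
  grid <- seq(0.01, 1, by = 0.01)
  expect_equal(grid[which.max(vapply(grid, shannon_of_const, 1))],
               exp(-0.5), tolerance = 0.01)
})

test_that("envelope is gain-invariant and finite on silence", {
  rec <- quiet_rec(seed = 3)
  e1 <- shannon_envelope(rec)
  half <- pcg_recording(rec$samples / 2, rec$sample_rate_hz)
  e2 <- shannon_envelope(half)
  expect_equal(e1$values, e2$values, tolerance = 1e-9)
  expect_true(all(is.finite(e1$values)))
})

test_that("detect_events finds constructed bumps and honors min_gap", {
  t <- seq(0, 2, by = 0.005)
  env_vals <- 2 * exp(-((t - 0.8) / 0.02)^2) + 3 * exp(-((t - 1.1) / 0.02)^2)
  env <- structure(list(values = as.numeric(scale(env_vals)), times_s = t,
                        hop_s = 0.005), class = "pcg_envelope")
  ev <- detect_events(env, envelope_params(peak_threshold = 0.5))
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$time_s), c(0.8, 1.1), tolerance = 0.01)

  ev1 <- detect_events(env, envelope_params(peak_threshold = 0.5,
                                            min_gap_ms = 400))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$time_s, 1.1, tolerance = 0.01)   # taller bump wins
})

test_that("a normal recording yields about two events per cycle", {
  rec <- quiet_rec(heart_rate_bpm = 60, duration_s = 10, snr_db = 30,
                   seed = 3)
  env <- shannon_envelope(rec)
  ev <- detect_events(env)
  n_s1 <- length(rec$annotation$s1_times_s)
  expect_true(abs(nrow(ev) - 2 * n_s1) <= 2)
})

test_that("assign_s1_s2 reproduces the alternating-interval worked cases", {
  seg <- assign_s1_s2(c(0.0, 0.3, 1.0, 1.3, 2.0), mean_rr_s = 1.0)
  expect_equal(seg$s1_times_s, c(0.0, 1.0, 2.0))
  expect_equal(seg$s2_times_s, c(0.3, 1.3))

  ev <- as.vector(rbind(0:9, 0:9 + 0.35))
  seg2 <- assign_s1_s2(ev, mean_rr_s = 1.0)
  expect_equal(seg2$s1_times_s, as.numeric(0:9))
  expect_equal(nrow(seg2$cycles), 10)
  expect_equal(seg2$quality, 1.0)
  # systole < diastole inside every cycle
  expect_true(all(seg2$cycles[, "s2"] - seg2$cycles[, "s1"] <
                    seg2$cycles[, "next_s1"] - seg2$cycles[, "s2"]))

  expect_error(assign_s1_s2(c(0, 0.3, 1.0), 1.0),
               class = "pcgdx_segmentation_error")
})

test_that("segmentation matches simulator ground truth on clean classes", {
  for (cls in c("NORMAL", "SYSTOLIC_MURMUR")) {
    for (hr in c(60, 100)) {
      rec <- quiet_rec(sound_class = cls, heart_rate_bpm = hr,
                       murmur_intensity = 0.6, snr_db = 30, seed = hr)
      seg <- segment(rec)
      ann <- rec$annotation
      m1 <- match_events(seg$s1_times_s, ann$s1_times_s)
      m2 <- match_events(seg$s2_times_s, ann$s2_times_s)
      expect_gte(m1$recall, 0.95)
      expect_gte(m2$recall, 0.95)
    }
  }
})

test_that("segmentation tracks an irregular (AF) rhythm", {
  rec <- quiet_rec(heart_rate_bpm = 80, af_mode = TRUE, rr_cv = 0.2,
                   snr_db = 20, seed = 1)
  seg <- segment(rec)
  m1 <- match_events(seg$s1_times_s, rec$annotation$s1_times_s)
  expect_gte(m1$recall, 0.9)
})

test_that("event times shift with the input (up to hop quantization)", {
  rec <- quiet_rec(heart_rate_bpm = 70, snr_db = Inf, seed = 9)
  shift_s <- 0.1
  fs <- rec$sample_rate_hz
  shifted <- pcg_recording(c(numeric(shift_s * fs), rec$samples),
                           fs, annotation = NULL)
  ev0 <- detect_events(shannon_envelope(rec))
  ev1 <- detect_events(shannon_envelope(shifted))
  n <- min(nrow(ev0), nrow(ev1))
  deltas <- ev1$time_s[seq_len(n)] - ev0$time_s[seq_len(n)]
  expect_lt(max(abs(deltas - shift_s)), 0.015)
})

test_that("degenerate inputs raise typed segmentation failures", {
  expect_error(segment(pcg_recording(numeric(0), 2000)),
               class = "pcgdx_segmentation_error")
  expect_error(segment(pcg_recording(numeric(5000), 2000)),
               class = "pcgdx_segmentation_error")
  expect_error(envelope_params(hop_ms = 30, window_ms = 20),
               class = "pcgdx_config_error")
})

test_that("cycle segmentation invariants hold on a clean recording", {
  rec <- quiet_rec(heart_rate_bpm = 72, snr_db = 25, seed = 21)
  seg <- segment(rec)
  expect_false(is.unsorted(seg$s1_times_s, strictly = TRUE))
  expect_false(is.unsorted(seg$s2_times_s, strictly = TRUE))
  expect_true(all(seg$cycles[, "s1"] < seg$cycles[, "s2"]))
  expect_true(all(seg$cycles[, "s2"] < seg$cycles[, "next_s1"]))
  expect_true(all(seg$cycles[, "s2"] - seg$cycles[, "s1"] <
                    seg$cycles[, "next_s1"] - seg$cycles[, "s2"]))
  expect_equal(seg$mean_rr_s, 60 / 72, tolerance = 0.02)
})
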