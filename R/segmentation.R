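# ECG-free S1/S2 detection from the normalized average Shannon energy
# envelogram. Candidate peaks are picked liberally from the envelope;
# labelling then selects a near-periodic S1 chain (dynamic programming
# around the estimated RR interval) and locates S2 inside the systolic
# window of each cycle, so extra envelope humps from S3/S4 or murmurs do
# not corrupt the cycle structure.

#' Envelogram parameters
#'
#' @param window_ms Shannon-energy averaging window, ms.
#' @param hop_ms Envelope step, ms (must not exceed `window_ms`).
#' @param peak_threshold Peak threshold on the standardized envelope
#'   (standard-deviation units).
#' @param min_gap_ms Minimum distance between retained peaks, ms; shorter
#'   than any physiologic systole, so S1 and S2 are never merged.
#' @param recovery Re-scan suspiciously long inter-event gaps at half
#'   threshold? Default `TRUE`.
#' @return A validated list of class `envelope_params`.
#' @export
envelope_params <- function(window_ms = 20, hop_ms = 5, peak_threshold = 0.5,
                            min_gap_ms = 120, recovery = TRUE) {
  if (!(hop_ms > 0 && hop_ms <= window_ms)) {
    abort_config("need 0 < hop_ms <= window_ms", "hop_ms")
  }
  if (!is.finite(peak_threshold)) {
    abort_config("peak_threshold must be finite", "peak_threshold")
  }
  if (!(min_gap_ms > 0)) abort_config("min_gap_ms must be > 0", "min_gap_ms")
  structure(list(window_ms = window_ms, hop_ms = hop_ms,
                 peak_threshold = peak_threshold, min_gap_ms = min_gap_ms,
                 recovery = isTRUE(recovery)),
            class = "envelope_params")
}

# Anti-aliased reduction to the 1 kHz working rate used for envelope
# analysis (heart-sound content sits far below 400 Hz).
to_working_rate <- function(x, fs, target = 1000) {
  if (fs <= target) return(list(x = x, fs = fs))
  lp <- signal::butter(4, (0.4 * target) / (fs / 2), type = "low")
  xf <- signal::filtfilt(lp, x)
  t_new <- seq(0, (length(x) - 1) / fs, by = 1 / target)
  list(x = stats::approx((seq_along(x) - 1) / fs, xf, xout = t_new)$y,
       fs = target)
}

#' Normalized average Shannon energy envelope
#'
#' Per-sample Shannon energy `-x^2 * ln(x^2)` (with `0 * ln 0 := 0`) is
#' averaged over sliding windows and, by default, standardized to zero
#' mean and unit variance. The transform accentuates mid-amplitude
#' transients such as S1/S2 against both the noise floor and sharp spikes.
#'
#' @param rec A [pcg_recording()] (or bare numeric vector at 1 kHz).
#' @param params An [envelope_params()].
#' @param normalize Peak-normalize the input to `[-1, 1]` first (default
#'   `TRUE`; disable only when feeding already-calibrated amplitudes).
#' @param standardize Standardize the envelope (default `TRUE`).
#' @return List of class `pcg_envelope` with `values`, `times_s`, `hop_s`.
#' @export
shannon_envelope <- function(rec, params = envelope_params(),
                             normalize = TRUE, standardize = TRUE) {
  if (inherits(rec, "pcg_recording")) {
    wr <- to_working_rate(rec$samples, rec$sample_rate_hz)
  } else {
    wr <- list(x = as.numeric(rec), fs = 1000)
  }
  x <- wr$x; fs <- wr$fs
  if (!length(x)) abort_data("empty signal", "pcgdx_segmentation_error")
  if (normalize && max(abs(x)) > 0) x <- x / max(abs(x))

  s <- x^2
  e <- ifelse(s > 0, -s * log(s), 0)
  win <- max(1L, min(round(params$window_ms / 1000 * fs), length(e)))
  hop <- max(1L, round(params$hop_ms / 1000 * fs))
  cs <- c(0, cumsum(e))
  starts <- seq(1L, max(1L, length(e) - win + 1L), by = hop)
  vals <- (cs[starts + win] - cs[starts]) / win
  centres <- (starts - 1 + (win - 1) / 2) / fs
  if (standardize) {
    sdv <- stats::sd(vals)
    vals <- if (is.na(sdv) || sdv == 0) rep(0, length(vals))
            else (vals - mean(vals)) / sdv
  }
  structure(list(values = vals, times_s = centres, hop_s = hop / fs),
            class = "pcg_envelope")
}

# quadratic (three-point) interpolation of a local maximum
refine_peak <- function(v, t, i, hop) {
  if (i <= 1 || i >= length(v)) return(t[i])
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(t[i])
  delta <- (v[i - 1] - v[i + 1]) / (2 * denom)
  t[i] + max(-0.5, min(0.5, delta)) * hop
}

#' Detect candidate heart sound events on an envelope
#'
#' Local maxima above `peak_threshold`, separated by at least `min_gap_ms`
#' (taller peak wins a conflict). With `recovery` on, inter-event gaps
#' longer than 1.5x the median are re-scanned at half threshold to pick up
#' beats missed by the global threshold. Peak times are refined by
#' quadratic interpolation.
#'
#' @param env A `pcg_envelope` from [shannon_envelope()].
#' @param params An [envelope_params()].
#' @return `data.frame` with columns `time_s` and `height` (may be empty).
#' @export
detect_events <- function(env, params = envelope_params()) {
  v <- env$values; t <- env$times_s
  if (length(v) >= 5) {
    # light Gaussian smoothing (sd = one hop) removes the residual
    # carrier ripple of low-frequency bursts before peak picking
    g <- stats::dnorm(-2:2); g <- g / sum(g)
    v <- as.numeric(stats::filter(v, g, sides = 2))
    v[is.na(v)] <- env$values[is.na(v)]
  }
  find_peaks <- function(thr, lo = -Inf, hi = Inf) {
    n <- length(v)
    if (n < 3) return(integer())
    cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
    cand[v[cand] > thr & t[cand] > lo & t[cand] < hi]
  }
  gap_s <- params$min_gap_ms / 1000
  keep_spaced <- function(idx, kept_t = numeric()) {
    kept <- integer()
    for (i in idx[order(-v[idx])]) {
      if (!any(abs(c(t[kept], kept_t) - t[i]) < gap_s)) kept <- c(kept, i)
    }
    sort(kept)
  }
  kept <- keep_spaced(find_peaks(params$peak_threshold))
  if (params$recovery && length(kept) >= 3) {
    gaps <- diff(t[kept])
    medg <- stats::median(gaps)
    long <- which(gaps > 1.5 * medg)
    extra <- integer()
    for (g in long) {
      lo <- t[kept[g]] + gap_s; hi <- t[kept[g + 1]] - gap_s
      extra <- c(extra, find_peaks(params$peak_threshold / 2, lo, hi))
    }
    if (length(extra)) {
      extra <- keep_spaced(unique(extra), kept_t = t[kept])
      kept <- sort(c(kept, extra))
    }
  }
  times <- vapply(kept, function(i) refine_peak(v, t, i, env$hop_s),
                  numeric(1))
  data.frame(time_s = times, height = v[kept])
}

# Dominant periodicity of the envelope, by autocorrelation over
# physiologic RR lags (0.3-2.0 s <=> 30-200 bpm).
estimate_rr <- function(env) {
  v <- env$values - mean(env$values)
  n <- length(v)
  max_lag <- min(n - 2L, round(2.0 / env$hop_s))
  min_lag <- round(0.3 / env$hop_s)
  if (max_lag <= min_lag) return(NA_real_)
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[-1]
  lags <- seq_along(ac)
  ok <- lags >= min_lag
  # restrict to local maxima of the acf so shoulders are not picked
  locmax <- c(FALSE, diff(sign(diff(ac))) < 0, FALSE)
  cand <- which(ok & locmax)
  if (!length(cand)) cand <- which(ok)
  # comb score: the true period also shows correlation at twice the lag,
  # which sub-harmonic intervals (e.g. the diastolic spacing) do not
  comb <- vapply(cand, function(l) {
    ac[l] + if (2 * l <= length(ac)) 0.5 * ac[2 * l] else 0
  }, numeric(1))
  cand[which.max(comb)] * env$hop_s
}

#' Label detected events as S1/S2 and build cardiac cycles
#'
#' Selects the strongest near-periodic chain of events at the heart-rate
#' period as one sound train, identifies the train as S1 or S2 by the rule
#' that systole (S1 to S2) is shorter than diastole (the fraction of the
#' cycle at which the partner sound falls is below one half), and then
#' locates S2 within each cycle's systolic window using a timing prior
#' centred at 35% of the RR interval. At high heart rates (mean RR below
#' 0.6 s) where the interval rule degenerates, the taller train is taken
#' as S2 (in the Shannon envelope the higher-pitched S2 burst runs closer
#' to the transform's maximum than the taller-amplitude S1).
#'
#' @param events `data.frame` from [detect_events()] (or numeric times).
#' @param mean_rr_s Estimated mean RR interval, s.
#' @return List of class `cycle_segmentation`: `s1_times_s`, `s2_times_s`,
#'   `cycles` (matrix `s1, s2, next_s1`), `mean_rr_s`, `quality`.
#' @export
assign_s1_s2 <- function(events, mean_rr_s) {
  if (is.numeric(events)) {
    events <- data.frame(time_s = as.numeric(events),
                         height = rep(1, length(events)))
  }
  if (nrow(events) < 4) {
    abort_data("fewer than 4 events: recording unsegmentable",
               "pcgdx_segmentation_error")
  }
  if (!is.finite(mean_rr_s) || mean_rr_s <= 0) {
    abort_data("invalid RR estimate", "pcgdx_segmentation_error")
  }
  t <- events$time_s; h <- events$height
  o <- order(t); t <- t[o]; h <- h[o]
  n <- length(t)
  hbar <- stats::median(h)

  # --- strongest near-periodic chain (dynamic programming) --------------
  # steps of ~one RR are cheap, strongly off-period steps are penalized,
  # and a step of ~two RR (one missed beat) costs a modest flat penalty
  val <- h; parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    lo <- t[i] - 2.4 * mean_rr_s; hi <- t[i] - 0.55 * mean_rr_s
    js <- which(t >= lo & t <= hi)
    if (length(js)) {
      g <- (t[i] - t[js]) / mean_rr_s
      dev <- pmin(abs(g - 1), abs(g - 2) + 0.25)
      pen <- 4 * hbar * dev^2
      sc <- val[js] - pen
      j <- js[which.max(sc)]
      if (max(sc) > 0) { val[i] <- h[i] + max(sc); parent[i] <- j }
    }
  }
  end <- which.max(val)
  chain <- end
  while (!is.na(parent[chain[1]])) chain <- c(parent[chain[1]], chain)

  if (length(chain) < 2) {
    abort_data("no periodic sound train found",
               "pcgdx_segmentation_error")
  }

  # --- which train is it? -----------------------------------------------
  # S2 of each cycle: the best-scoring event in the systolic window,
  # with a timing prior centred at 35% of the cycle
  pick_s2 <- function(s1_idx, med_rr) {
    ts1 <- t[s1_idx]; K <- length(ts1)
    s2i <- rep(NA_integer_, K)
    for (k in seq_len(K)) {
      a <- ts1[k]
      rrk <- if (k < K) ts1[k + 1] - a else med_rr
      lo <- a + max(0.12, 0.15 * rrk); hi <- a + 0.60 * rrk
      cand <- setdiff(which(t > lo & t < hi), s1_idx)
      if (length(cand)) {
        f <- (t[cand] - a) / rrk
        sc <- h[cand] * exp(-0.5 * ((f - 0.35) / 0.12)^2)
        s2i[k] <- cand[which.max(sc)]
      }
    }
    s2i
  }

  # Build a full labelling from an initial S1 train: extend it outward by
  # one period at a time, correct residual errors against the typical
  # envelope heights of the two trains, and locate S2 per cycle.
  complete_labeling <- function(s1_idx, other_train = integer()) {
    s1_idx <- sort(unique(s1_idx))
    if (length(s1_idx) < 2) return(NULL)
    med_rr <- stats::median(diff(t[s1_idx]))
    excluded <- sort(unique(c(other_train, s1_idx)))
    grab <- function(centre_t) {
      cand <- setdiff(which(abs(t - centre_t) < 0.45 * med_rr), excluded)
      if (!length(cand)) return(NA_integer_)
      sc <- h[cand] * exp(-0.5 * ((t[cand] - centre_t) / (0.15 * med_rr))^2)
      if (max(sc) < 0.3 * hbar) return(NA_integer_)
      cand[which.max(sc)]
    }
    repeat {
      i <- grab(t[s1_idx[1]] - med_rr)
      if (is.na(i) || i %in% s1_idx) break
      s1_idx <- c(i, s1_idx); excluded <- sort(unique(c(excluded, i)))
    }
    repeat {
      i <- grab(t[s1_idx[length(s1_idx)]] + med_rr)
      if (is.na(i) || i %in% s1_idx) break
      s1_idx <- c(s1_idx, i); excluded <- sort(unique(c(excluded, i)))
    }

    # height-model corrections: an "S1" that sits a systolic interval
    # after an unassigned event and fits the S2 height model better is
    # swapped for that event; long RR gaps are filled with the unassigned
    # event that best fits the S1 height model
    s2i <- pick_s2(s1_idx, med_rr)
    mh1 <- mean(h[s1_idx])
    mh2 <- mean(h[s2i], na.rm = TRUE)
    if (is.finite(mh1) && is.finite(mh2) && abs(mh1 - mh2) > 0.05) {
      s1_like <- function(i) {
        abs(h[i] - mh1) < abs(h[i] - mh2) &
          abs(h[i] - mh1) < 0.75 * abs(mh2 - mh1)
      }
      for (k in seq_along(s1_idx)) {
        i <- s1_idx[k]
        e <- setdiff(which(t[i] - t >= 0.12 & t[i] - t <= 0.45 * med_rr),
                     s1_idx)
        if (!length(e)) next
        e <- e[which.max(h[e])]
        if (s1_like(e) && abs(h[e] - mh1) < abs(h[i] - mh1)) s1_idx[k] <- e
      }
      s1_idx <- sort(unique(s1_idx))
      repeat {
        gaps <- diff(t[s1_idx])
        k <- which(gaps > 1.4 * med_rr)
        ins <- NA_integer_
        for (g in k) {
          a <- t[s1_idx[g]]; b <- t[s1_idx[g + 1]]
          cand <- setdiff(which(t > a + 0.4 * med_rr &
                                  t < b - 0.4 * med_rr), s1_idx)
          cand <- cand[s1_like(cand)]
          if (length(cand)) {
            ins <- cand[which.min(abs(h[cand] - mh1))]
            break
          }
        }
        if (is.na(ins)) break
        s1_idx <- sort(c(s1_idx, ins))
      }
    }
    ts1 <- t[s1_idx]
    med_rr <- stats::median(diff(ts1))
    s2i <- pick_s2(s1_idx, med_rr)
    K <- length(ts1)
    s2 <- ifelse(is.na(s2i), NA_real_, t[s2i])
    has_s2 <- !is.na(s2)
    cyc_end <- c(ts1[-1], ts1[K] + med_rr)
    cycles <- cbind(s1 = ts1[has_s2], s2 = s2[has_s2],
                    next_s1 = cyc_end[has_s2])
    valid <- cycles[, "s1"] < cycles[, "s2"] &
      cycles[, "s2"] < cycles[, "next_s1"]
    if (med_rr >= 0.6) {
      valid <- valid & (cycles[, "s2"] - cycles[, "s1"]) <
        (cycles[, "next_s1"] - cycles[, "s2"])
    }
    structure(list(s1_times_s = ts1,
                   s2_times_s = s2[has_s2],
                   cycles = cycles,
                   mean_rr_s = med_rr,
                   quality = sum(valid) / K),
              class = "cycle_segmentation")
  }

  # Two hypotheses about the periodic chain: it is the S1 train, or it is
  # the S2 train (then S1 is the event a systolic interval before each
  # chain beat). Each is completed into a full labelling and scored by
  # physiologic plausibility: many valid cycles, with the systolic
  # fraction tight around 35% of the cycle. This subsumes the classic
  # "systole is the shorter interval" rule and stays robust when a
  # murmur's envelope hump forms a periodic train of its own.
  h2_idx <- integer()
  for (k in seq_len(length(chain) - 1)) {
    a <- t[chain[k]]; b <- t[chain[k + 1]]; rrk <- b - a
    cand <- setdiff(which(t > a & t < b), chain)
    if (!length(cand)) next
    f_sys <- (b - t[cand]) / rrk
    sc <- h[cand] * exp(-0.5 * ((f_sys - 0.35) / 0.12)^2)
    if (max(sc) > 0.05 * hbar) h2_idx <- c(h2_idx, cand[which.max(sc)])
  }
  labelings <- list(complete_labeling(chain),
                    complete_labeling(h2_idx, other_train = chain))
  labelings <- Filter(Negate(is.null), labelings)
  if (!length(labelings)) {
    abort_data("could not establish an S1 train",
               "pcgdx_segmentation_error")
  }
  scores <- vapply(labelings, labeling_score, numeric(1))
  labelings[[which.max(scores)]]
}

# physiologic-plausibility score of a labelling: valid cycles, damped by
# how far the median systolic fraction sits from 35% of the cycle and by
# its spread (a true labelling is tight around it, even in AF)
labeling_score <- function(seg) {
  if (is.null(seg) || !nrow(seg$cycles)) return(-Inf)
  sf <- (seg$cycles[, "s2"] - seg$cycles[, "s1"]) /
    (seg$cycles[, "next_s1"] - seg$cycles[, "s1"])
  med <- stats::median(sf)
  spread <- if (length(sf) > 2) stats::sd(sf) else 0
  seg$quality * nrow(seg$cycles) *
    exp(-((med - 0.35) / 0.10)^2) * exp(-(spread / 0.05)^2)
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cycle_segmentation> %d S1, %d S2, %d cycles; mean RR %.3f s (%.0f bpm); quality %.2f\n",
    length(x$s1_times_s), length(x$s2_times_s), nrow(x$cycles),
    x$mean_rr_s, 60 / x$mean_rr_s, x$quality))
  invisible(x)
}

#' Segment a recording into cardiac cycles
#'
#' Composition of [shannon_envelope()], [detect_events()] (with the RR
#' interval estimated from the envelope's autocorrelation) and
#' [assign_s1_s2()].
#'
#' @param rec A [pcg_recording()].
#' @param params An [envelope_params()].
#' @return A `cycle_segmentation`.
#' @export
segment <- function(rec, params = envelope_params()) {
  if (!length(rec$samples) || max(abs(rec$samples)) == 0) {
    abort_data("empty or silent recording: unsegmentable",
               "pcgdx_segmentation_error")
  }
  env <- shannon_envelope(rec, params)
  ev <- detect_events(env, params)
  if (nrow(ev) < 4) {
    abort_data("fewer than 4 events: recording unsegmentable",
               "pcgdx_segmentation_error")
  }
  rr <- estimate_rr(env)
  # the autocorrelation period can lock onto a harmonic (especially under
  # an irregular rhythm), so compete the halved and doubled period too and
  # keep whichever labelling explains the most plausible cycles
  cands <- unique(round(pmin(pmax(
    c(rr, rr / 2, 2 * rr, 2 * rr / 3, 3 * rr / 2), 0.3), 2.2), 4))
  seg <- NULL; best <- -Inf
  for (r in cands) {
    s <- try(assign_s1_s2(ev, r), silent = TRUE)
    if (inherits(s, "try-error")) next
    sc <- labeling_score(s)
    if (sc > best) { best <- sc; seg <- s }
  }
  if (is.null(seg)) {
    abort_data("no labelling explains the detected events",
               "pcgdx_segmentation_error")
  }
  # refinement pass with the RR recovered from the first-pass S1 train
  if (is.finite(seg$mean_rr_s) && abs(seg$mean_rr_s - rr) / rr > 0.02) {
    seg2 <- try(assign_s1_s2(ev, seg$mean_rr_s), silent = TRUE)
    if (!inherits(seg2, "try-error") && labeling_score(seg2) >= best) {
      seg <- seg2
    }
  }
  seg
}

#' Match detected event times against reference times
#'
#' Greedy one-to-one matching within a tolerance, the standard way to
#' score a heart sound detector against annotations.
#'
#' @param detected,reference Numeric vectors of event times, s.
#' @param tol_s Matching tolerance (default 0.03 s).
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
match_events <- function(detected, reference, tol_s = 0.03) {
  used <- rep(FALSE, length(detected))
  matched <- 0L
  for (r in reference) {
    d <- which(!used & abs(detected - r) <= tol_s)
    if (length(d)) {
      used[d[which.min(abs(detected[d] - r))]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_matched = matched,
       recall = if (length(reference)) matched / length(reference) else NA,
       precision = if (length(detected)) matched / length(detected) else NA)
}
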