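# shared fixtures, built in code

quiet_rec <- function(..., seed = 1) {
  generate_recording(sim_config(..., seed = seed))
}

# brute-force inversion of the binomial CDF by bisection: the independent
# oracle for the exact binomial interval
cp_bisect <- function(k, n, level = 0.95, tol = 1e-9) {
  a <- (1 - level) / 2
  bis <- function(f) {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bis(function(p) stats::pbinom(k - 1, n, p) > 1 - a)   # P(X >= k) < a
  upper <- if (k == n) 1 else
    bis(function(p) stats::pbinom(k, n, p) >= a)           # P(X <= k) >= a
  c(lower = lower, upper = upper)
}

# mean per-sample Shannon energy of a constant-amplitude signal
shannon_of_const <- function(a) {
  s <- a^2
  if (s == 0) 0 else -s * log(s)
}
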