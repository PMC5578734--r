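# Independent oracles used across the suite.

# closed-form simple-OLS via the normal equations (no lm)
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# brute-force top-3 unique-peptide quantification
top3_oracle <- function(peptides) {
  u <- peptides[peptides$is_unique, , drop = FALSE]
  sapply(split(u$intensity, u$protein_id), function(v) {
    v <- sort(v, decreasing = TRUE)
    sum(v[seq_len(min(3, length(v)))])
  })
}

# exhaustive hinge-breakpoint search by explicit normal equations
hinge_oracle <- function(time, value) {
  lv <- log2(value)
  n <- length(time)
  cands <- time[seq_len(n - 3L)]
  best <- NULL
  for (b in cands) {
    h <- pmax(time - b, 0)
    cf <- ols_oracle(h, lv)
    rss <- sum((lv - cf["intercept"] - cf["slope"] * h)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(lag = b, rate = unname(cf["slope"]) * 60, rss = rss)
  }
  best
}

# quantify a simulated trace end to end with its matching blank
rho_roundtrip <- function(rho, seed, ...) {
  tr <- simulate_polysome_trace(rho = rho, seed = seed, ...)
  bl <- simulate_blank_trace(tr, seed = seed + 100000L)
  inactive_fraction(quantify_trace(tr, blank = bl))
}
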