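# Independent brute-force oracles: direct loops over pairs, no shared code
# with the implementation under test.

oracle_agreement <- function(ref, cand) {
  n <- length(ref)
  d <- numeric(n); m <- numeric(n); pct <- numeric(n)
  acc <- 0L; under <- 0L; over <- 0L; abs_sum <- 0
  for (i in seq_len(n)) {
    d[i] <- cand[i] - ref[i]
    m[i] <- (cand[i] + ref[i]) / 2
    pct[i] <- 100 * d[i] / ref[i]
    abs_sum <- abs_sum + abs(d[i])
    r <- cand[i] / ref[i]
    if (r < 0.95) under <- under + 1L
    else if (r > 1.05) over <- over + 1L
    else acc <- acc + 1L
  }
  mu <- sum(d) / n
  sdd <- sqrt(sum((d - mu)^2) / (n - 1))
  pmu <- sum(pct) / n
  mm <- sum(m) / n
  sxx <- sum((m - mm)^2)
  slope <- sum((m - mm) * (d - mu)) / sxx
  list(bias_mean = mu, bias_sd = sdd,
       bias_pct_mean = pmu,
       bias_pct_sd = sqrt(sum((pct - pmu)^2) / (n - 1)),
       mae = abs_sum / n,
       pct_accurate = 100 * acc / n, pct_under = 100 * under / n,
       pct_over = 100 * over / n,
       loa_low = mu - 1.96 * sdd, loa_high = mu + 1.96 * sdd,
       slope = slope, intercept = mu - slope * mm)
}

oracle_confusion <- function(ref, cand, cutoff) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(ref)) {
    ref_low <- ref[i] < cutoff
    cand_low <- cand[i] < cutoff
    if (ref_low && cand_low) tp <- tp + 1L
    else if (ref_low) fn <- fn + 1L
    else if (cand_low) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# 20th percentile by hand interpolation at h = 0.2 * (n - 1).
oracle_quintile <- function(x) {
  sx <- sort(x)
  h <- 0.2 * (length(x) - 1)
  lo <- floor(h)
  if (lo + 1 == length(sx)) return(sx[lo + 1])
  sx[lo + 1] + (h - lo) * (sx[lo + 2] - sx[lo + 1])
}
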