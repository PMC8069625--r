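# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

oracle_features <- function(v) {
  n <- length(v)
  mu <- 0
  for (x in v) mu <- mu + x
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (x in v) {
    d <- x - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  energy <- 0
  for (x in v) energy <- energy + x * x
  change <- 0
  if (n > 1) for (i in 1:(n - 1)) change <- change + abs(v[i + 1] - v[i])
  s <- sort(v)
  h <- (n - 1) * 0.95 + 1            # type-7 quantile by hand
  lo <- floor(h)
  q95 <- s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  c(mean = mu, variance = m2, maximum = max(v), q95 = q95,
    absolute_energy = energy, absolute_change = change,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0)
}

oracle_confusion <- function(f, o, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(f)) {
    pos <- f[i] >= threshold
    if (pos && o[i] == 1) tp <- tp + 1
    else if (pos && o[i] == 0) fp <- fp + 1
    else if (!pos && o[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Truncated-power restricted cubic term evaluated longhand for 3 knots.
oracle_rcs3 <- function(x, t1, t2, t3) {
  pp <- function(u) ifelse(u > 0, u^3, 0)
  (pp(x - t1) - pp(x - t2) * (t3 - t1) / (t3 - t2) +
      pp(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
}
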