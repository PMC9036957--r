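# Independent oracles and shared fixtures.  Each oracle re-derives the
# quantity from first principles, separately from the package code paths it
# checks.

protocol <- cervicalProtocol() # b = 0...2000, delta 20 ms, Delta 40 ms

# The four published per-group parameter rows (D, beta, mu in map units)
# and their ADC values, used as round-trip truths.
publishedGroupRows <- list(
  scc  = list(adc = 0.92, d = 0.77, beta = 0.67, mu = 8.19),
  aca  = list(adc = 1.00, d = 0.80, beta = 0.71, mu = 8.40),
  low  = list(adc = 0.98, d = 0.82, beta = 0.73, mu = 8.27),
  high = list(adc = 0.90, d = 0.74, beta = 0.68, mu = 8.26)
)

# Direct transliteration of the FROC decay formula, written independently of
# frocSignal: gradient factor via the Stejskal-Tanner relation, all unit
# conversions inline.
oracleFrocSignal <- function(s0, d, beta, mu, b, deltaMs, DeltaMs) {
  dlt <- deltaMs * 1e-3
  Dlt <- DeltaMs * 1e-3
  D <- d * 1e-3
  m <- mu * 1e-3
  sapply(b, function(bi) {
    if (bi == 0) return(s0)
    gGd2b <- (bi / (Dlt - dlt / 3))^beta
    s0 * exp(-D * m^(2 * (beta - 1)) * gGd2b *
               (Dlt - (2 * beta - 1) / (2 * beta + 1) * dlt))
  })
}

# Exhaustive-enumeration two-sided Mann-Whitney p-value (no ties).
oracleMannWhitneyP <- function(a, b) {
  nA <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  uStat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  uObs <- uStat(seq_len(nA))
  combs <- utils::combn(length(pooled), nA)
  us <- apply(combs, 2, uStat)
  nTot <- ncol(combs)
  uMid <- nA * (length(b)) / 2
  # two-sided: double the smaller tail of the symmetric null, capped at 1
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# Brute-force AUC as the concordant-pair fraction (ties get half credit).
oracleAuc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

# Exhaustive Youden scan over observed thresholds, rule score >= cutoff.
oracleYouden <- function(scores, pos) {
  best <- NULL
  for (ct in sort(unique(scores))) {
    sens <- mean(scores[pos] >= ct)
    spec <- mean(scores[!pos] < ct)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cutoff = ct, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Exhaustive grid search over (D, beta, mu) at the stated resolution; S0
# taken from the fit under test.  RSS is minimized over the achievable decay
# scales, grouping grid points that share D * mu^(2 beta - 2).
oracleGridRss <- function(signal, s0, scheme,
                          dGrid = seq(0.01, 3.0, by = 0.01),
                          betaGrid = seq(0.30, 1.00, by = 0.01),
                          muGrid = seq(1, 20, by = 0.1)) {
  b <- bValues(scheme)
  tm <- gradientTiming(scheme)
  dS <- tm[["deltaSmall"]] * 1e-3
  dB <- tm[["deltaBig"]] * 1e-3
  best <- Inf
  for (beta in betaGrid) {
    tau <- dB - (2 * beta - 1) / (2 * beta + 1) * dS
    k <- (dB - dS / 3)^(-beta) * tau
    bPow <- ifelse(b == 0, 0, b^beta)
    # decay scale C = D[mm^2/s] * mu[mm]^(2 beta - 2) * k for every grid pair
    cVals <- as.vector(outer(dGrid * 1e-3, (muGrid * 1e-3)^(2 * (beta - 1))) * k)
    model <- exp(-outer(cVals, bPow))
    rss <- rowSums((s0 * model - rep(signal, each = length(cVals)))^2)
    best <- min(best, rss)
  }
  best
}
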