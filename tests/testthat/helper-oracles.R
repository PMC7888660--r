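# Independent oracles used to cross-check package statistics. These are
# deliberately written as direct transcriptions of the published formulas /
# brute-force enumerations, not calls into the code paths they check.

# D'Agostino-Pearson omnibus statistic, formula-level transcription.
# Skewness z: D'Agostino (1970) Johnson SU approximation, log form.
# Kurtosis z: Anscombe & Glynn (1983).
oracle_k2 <- function(x) {
  n <- length(x)
  xc <- x - sum(x) / n
  s2 <- sum(xc^2) / n
  g1 <- (sum(xc^3) / n) / s2^(3 / 2)
  g2 <- (sum(xc^4) / n) / s2^2

  Y <- g1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  b2g1 <- (3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3)) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  Wsq <- sqrt(2 * (b2g1 - 1)) - 1
  dlt <- 1 / sqrt(0.5 * log(Wsq))
  alph <- sqrt(2 / (Wsq - 1))
  Z1 <- dlt * log(Y / alph + sqrt((Y / alph)^2 + 1))

  mu <- 3 * (n - 1) / (n + 1)
  sig2 <- (24 * n * (n - 2) * (n - 3)) / ((n + 1)^2 * (n + 3) * (n + 5))
  stdg2 <- (g2 - mu) / sqrt(sig2)
  rootb1 <- (6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9))) *
    sqrt((6 * (n + 3) * (n + 5)) / (n * (n - 2) * (n - 3)))
  Acap <- 6 + (8 / rootb1) * (2 / rootb1 + sqrt(1 + 4 / rootb1^2))
  u <- 1 + stdg2 * sqrt(2 / (Acap - 4))
  cuberoot <- function(v) sign(v) * abs(v)^(1 / 3)
  Z2 <- ((1 - 2 / (9 * Acap)) - cuberoot((1 - 2 / Acap) / u)) /
    sqrt(2 / (9 * Acap))

  Z1^2 + Z2^2
}

# Exhaustive upper-tail hypergeometric sum: P(overlap >= k) when drawing
# `draw` genes from a universe of `total` containing `marked` marked genes.
oracle_hyper_tail <- function(k, marked, total, draw) {
  ks <- seq(k, min(marked, draw))
  if (!length(ks) || k > min(marked, draw)) return(if (k <= 0) 1 else 0)
  sum(exp(lchoose(marked, ks) + lchoose(total - marked, draw - ks) -
            lchoose(total, draw)))
}

# Plain least-squares solve via normal equations, as an independent check
# on pseudoinverse projections (full-column-rank systems only).
oracle_lstsq <- function(A, b) {
  solve(crossprod(A), crossprod(A, b))
}
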