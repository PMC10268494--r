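# Independent oracles: brute-force or closed-form recomputations kept
# deliberately separate from the package's own code paths.

# Hand-derived closed form of the balanced fermentation family
# (C6H12O6 -> b butyrate + (2-2b) acetate + (4-2b) H2 + 2 CO2 ...),
# derived by solving the C/H/O/charge system by hand.
oracle_family <- function(b) {
  c(glucose = -1, butyrate = b, acetate = 2 - 2 * b, H2 = 4 - 2 * b,
    CO2 = 2, H2O = 2 * b - 2, `H+` = 2 - b)
}

# Independently typed elemental data (C, H, O, charge) for residual checks.
ORACLE_ELEMENTS <- list(
  glucose = c(6, 12, 6, 0), butyrate = c(4, 7, 2, -1),
  acetate = c(2, 3, 2, -1), lactate = c(3, 5, 3, -1),
  formate = c(1, 1, 2, -1), CO2 = c(1, 0, 2, 0), H2 = c(0, 2, 0, 0),
  CH4 = c(1, 4, 0, 0), H2O = c(0, 2, 1, 0), `H+` = c(0, 1, 0, 1)
)

oracle_residuals <- function(coefs) {
  tot <- c(C = 0, H = 0, O = 0, charge = 0)
  for (nm in names(coefs)) {
    tot <- tot + coefs[[nm]] * ORACLE_ELEMENTS[[nm]]
  }
  # degree of reduction residual follows as 4C + H - 2O - charge
  c(tot, electron = unname(4 * tot[1] + tot[2] - 2 * tot[3] - tot[4]))
}

# Brute-force type-7 quantile (linear interpolation of order statistics).
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_tukey_mask <- function(x, k = 3) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  x < q1 - k * iqr | x > q3 + k * iqr
}

# Textbook pooled-variance two-sample t statistic and two-sided p.
oracle_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
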