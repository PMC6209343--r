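# Independent brute-force oracles for the precision statistics, kept
# deliberately naive and separate from the package implementations.

oracle_ape <- function(m) {
  vals <- c()
  for (j in seq_len(nrow(m))) {
    mj <- mean(m[j, ])
    if (mj == 0) next
    dev <- 0
    for (i in seq_len(ncol(m))) dev <- dev + abs(m[j, i] - mj) / mj
    vals <- c(vals, dev / ncol(m))
  }
  100 * mean(vals)
}

oracle_cv <- function(m) {
  vals <- c()
  for (j in seq_len(nrow(m))) {
    mj <- mean(m[j, ])
    if (mj == 0) next
    vals <- c(vals, sd(m[j, ]) / mj)
  }
  100 * mean(vals)
}

oracle_pa <- function(m, tol) {
  hits <- 0
  for (j in seq_len(nrow(m)))
    if (abs(m[j, 1] - m[j, 2]) <= tol) hits <- hits + 1
  100 * hits / nrow(m)
}

# symmetry statistic summed over all ordered off-diagonal cells, each
# unordered pair therefore counted twice and halved
oracle_bowker <- function(tab) {
  k <- nrow(tab)
  chi2 <- 0
  npairs <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      tot <- tab[i, j] + tab[j, i]
      if (tot > 0) {
        chi2 <- chi2 + (tab[i, j] - tab[j, i])^2 / (2 * tot)
        npairs <- npairs + 0.5
      }
    }
  }
  list(chi2 = chi2, df = as.integer(round(npairs)))
}

# noise-free length-at-age data from a known curve
curve_data <- function(family, L0, Linf, coeff, ages = seq(0.25, 4.5, 0.25)) {
  p <- growth_params(family, L0, Linf, coeff)
  data.frame(age = ages, length = predict_length(p, ages))
}
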