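# Independent reference computations used to cross-check the package
# implementations. Each is coded from the textbook definition, not by
# calling the implementation under test.

# two-sided Fisher p by explicit hypergeometric enumeration with
# log-binomial coefficients
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  p <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(r1 + r2, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank <- function(x, mu0 = 0) {
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  masks <- 0:(2^n - 1)
  w_all <- vapply(masks, function(m)
    sum(r[bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0]), numeric(1))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# element-wise log2(CPM + 1) with endogenous-only denominator, looped
oracle_log2_cpm <- function(counts, flags) {
  endo <- flags == "endogenous"
  keep <- flags %in% c("endogenous", "mito")
  out <- matrix(NA_real_, sum(keep), ncol(counts))
  for (j in seq_len(ncol(counts))) {
    denom <- sum(counts[endo, j])
    out[, j] <- log2(counts[keep, j] * 1e6 / denom + 1)
  }
  out
}

# textbook Pearson correlation from the sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# median/MAD outlier mask recomputed from first principles
oracle_mad_mask <- function(values, n_mads, side, log_scale = FALSE) {
  x <- if (log_scale) log10(values + 1) else values
  med <- stats::median(x)
  m <- 1.4826 * stats::median(abs(x - med))
  if (m == 0) return(rep(FALSE, length(x)))
  if (side == "lower") x < med - n_mads * m else x > med + n_mads * m
}

# small synthetic configuration for fast unit tests
small_config <- function(...) {
  synth_config(n_genes = 400, genes_per_class_marker = 20,
               n_mito = 10, n_ercc = 10, ...)
}
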