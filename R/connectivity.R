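# Directed connectivity tallies, out-of-class bias and exact tests.

#' Tally directed connectivity by progenitor-pool category
#'
#' Counts tested and connected pairs for every directed pre -> post pool
#' category, the overall connection probability, and per pre-pool the
#' out-of-class bias (probability of connecting out of class divided by
#' the sum of out- and in-class probabilities) together with a Fisher
#' exact test of out-of-class vs in-class connection counts.
#'
#' @param t a `PairTestTable` data.frame with columns `pre_pool`,
#'   `post_pool`, `connected` (logical).
#' @param pools allowed pool labels; any other label is an error.
#' @return A list of class `ConnectivitySummary` with elements
#'   `categories` (data.frame `pre_pool`, `post_pool`, `n_tested`,
#'   `n_connected`, `probability`; probability is `NA` for untested
#'   categories), `overall` (list `n_tested`, `n_connected`,
#'   `probability`), and `bias` (data.frame `pre_pool`, `p_out`, `p_in`,
#'   `out_of_class_bias`, `fisher_p`).
#' @export
tally_connectivity <- function(t, pools = c("aIP", "OP")) {
  stopifnot(is.data.frame(t))
  if (!nrow(t)) stop("pair-test table is empty")
  bad <- which(!(t$pre_pool %in% pools) | !(t$post_pool %in% pools))
  if (length(bad))
    stop("unknown pool label in row(s): ",
         paste(utils::head(bad), collapse = ", "))
  grid <- expand.grid(pre_pool = pools, post_pool = pools,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cats <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- t$pre_pool == grid$pre_pool[i] & t$post_pool == grid$post_pool[i]
    n <- sum(sel)
    k <- sum(t$connected[sel])
    data.frame(pre_pool = grid$pre_pool[i], post_pool = grid$post_pool[i],
               n_tested = n, n_connected = k,
               probability = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  overall <- list(n_tested = nrow(t), n_connected = sum(t$connected),
                  probability = sum(t$connected) / nrow(t))
  bias <- do.call(rbind, lapply(pools, function(p) {
    inr <- cats[cats$pre_pool == p & cats$post_pool == p, ]
    outr <- cats[cats$pre_pool == p & cats$post_pool != p, ]
    p_in <- inr$probability
    p_out <- if (nrow(outr) == 1) outr$probability else
      sum(outr$n_connected) / sum(outr$n_tested)
    b <- if (is.na(p_in) || is.na(p_out)) NA_real_ else
      suppressWarnings(out_of_class_bias(p_out, p_in))
    fp <- if (inr$n_tested > 0 && sum(outr$n_tested) > 0)
      fisher_exact_2x2(sum(outr$n_connected),
                       sum(outr$n_tested) - sum(outr$n_connected),
                       inr$n_connected,
                       inr$n_tested - inr$n_connected)
    else NA_real_
    data.frame(pre_pool = p, p_out = p_out, p_in = p_in,
               out_of_class_bias = b, fisher_p = fp,
               stringsAsFactors = FALSE)
  }))
  structure(list(categories = cats, overall = overall, bias = bias),
            class = "ConnectivitySummary")
}

#' @export
print.ConnectivitySummary <- function(x, ...) {
  cat(sprintf("Connectivity: %d/%d tested pairs connected (%.1f%%)\n",
              x$overall$n_connected, x$overall$n_tested,
              100 * x$overall$probability))
  print(x$categories, row.names = FALSE)
  print(x$bias, row.names = FALSE)
  invisible(x)
}

#' Out-of-class connectivity bias
#'
#' The probability of connecting to neurons derived from the other
#' progenitor pool divided by the sum of the out-of-class and in-class
#' connection probabilities. 0.5 indicates no preference; 1.0 indicates
#' exclusively out-of-class connections.
#'
#' @param p_out out-of-class connection probability, in [0, 1].
#' @param p_in in-class connection probability, in [0, 1].
#' @return The bias `p_out / (p_out + p_in)`; `NA` with a warning when
#'   both probabilities are zero.
#' @export
out_of_class_bias <- function(p_out, p_in) {
  if (any(c(p_out, p_in) < 0) || any(c(p_out, p_in) > 1))
    stop("probabilities must lie in [0, 1]")
  if (p_out + p_in == 0) {
    warning("both probabilities zero; bias undefined")
    return(NA_real_)
  }
  p_out / (p_out + p_in)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `rbind(c(a, b), c(c, d))`,
#' computed by summing the hypergeometric probabilities of every table
#' with the same margins whose probability does not exceed that of the
#' observed table (within a relative slack of 1e-12, guarding floating
#' point ties). When any margin is zero the table carries no
#' information and `p = 1` is returned with a warning.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    warning("a margin is zero; p = 1 by convention")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Per-pair output bias toward L5a
#'
#' For each simultaneously recorded L5a/L5b pair the bias is the L5a
#' amplitude as a fraction of the summed pair amplitudes; 0.5 means
#' equal drive. Pairs with both amplitudes zero are dropped with a
#' warning.
#'
#' @param t a `PairedResponseTable` data.frame with columns
#'   `amp_L5a_mV`, `amp_L5b_mV` (both >= 0).
#' @return A list with `per_pair` (numeric vector of biases), `mean`,
#'   `sem` (sample SD / sqrt(n)) and `n`.
#' @export
output_bias <- function(t) {
  stopifnot(is.data.frame(t))
  a <- t$amp_L5a_mV; b <- t$amp_L5b_mV
  if (any(a < 0) || any(b < 0)) stop("amplitudes must be >= 0")
  zero <- a + b == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with both amplitudes zero dropped")
    a <- a[!zero]; b <- b[!zero]
  }
  bias <- a / (a + b)
  n <- length(bias)
  list(per_pair = bias, mean = mean(bias),
       sem = if (n > 1) stats::sd(bias) / sqrt(n) else NA_real_, n = n)
}

# exact null distribution of the positive-rank sum W+ for given absolute
# ranks, by subset-sum convolution over 2*ranks (integers for midranks)
.signed_rank_dist <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)  # counts over W2 = 0..total
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Wilcoxon signed-rank test against a location
#'
#' Two-sided one-sample test of symmetry about `mu0`. Zero differences
#' are dropped (Wilcoxon's convention; `zero_policy = "pratt"` instead
#' ranks them with the rest and then discards their contribution). Ties
#' receive midranks. For `n <= exact_max_n` nonzero differences the
#' p-value is exact, from the full enumeration of all `2^n` sign
#' assignments (computed by convolution); for larger `n` a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param values numeric vector.
#' @param mu0 hypothesized center.
#' @param zero_policy `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @param exact_max_n largest n for the exact null distribution.
#' @return A list with `statistic` (W+, the positive-rank sum),
#'   `p_value`, `n` (nonzero differences) and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0,
                                 zero_policy = c("wilcoxon", "pratt"),
                                 exact_max_n = 25) {
  zero_policy <- match.arg(zero_policy)
  d <- values - mu0
  d <- d[!is.na(d)]
  if (!length(d)) stop("no non-missing differences")
  if (all(d == 0)) {
    warning("all differences zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE))
  }
  if (zero_policy == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    ranks2 <- round(2 * r)
    dist <- .signed_rank_dist(ranks2)
    w2 <- round(2 * w)
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w, p_value = p, n = n, exact = TRUE)
  } else {
    mu <- sum(r) / 2
    ties <- table(r)
    sigma2 <- sum(r^2) / 4
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    list(statistic = w, p_value = 2 * stats::pnorm(-abs(z)), n = n,
         exact = FALSE)
  }
}
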