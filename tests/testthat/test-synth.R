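test_that("generators are bit-identical for a fixed seed", {
  sc <- small_config(seed = 42)
  r1 <- generate_reference_counts(sc, n_per_class = 20)
  r2 <- generate_reference_counts(sc, n_per_class = 20)
  expect_identical(r1, r2)
  q1 <- generate_query_cells(sc, n_per_pool = 30)
  q2 <- generate_query_cells(sc, n_per_pool = 30)
  expect_identical(q1, q2)
  p1 <- generate_pair_tests(seed = 7)
  p2 <- generate_pair_tests(seed = 7)
  expect_identical(p1, p2)
  t1 <- generate_epsp_trace(seed = 3)
  t2 <- generate_epsp_trace(seed = 3)
  expect_identical(t1, t2)
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_reference_counts(sc, 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated counts are non-negative integers with consistent totals", {
  sc <- small_config(seed = 1)
  r <- generate_reference_counts(sc, n_per_class = 15)
  expect_true(all(r$counts$counts >= 0))
  expect_true(all(r$counts$counts == round(r$counts$counts)))
  expect_equal(unname(colSums(r$counts$counts)),
               unname(compute_qc_metrics(r$counts)$library_size))
  expect_length(r$labels, ncol(r$counts$counts))
})

test_that("zero marker fold-change leaves no class signal", {
  sc <- small_config(marker_log2fc = 0, seed = 5)
  r <- generate_reference_counts(sc, n_per_class = 200)
  endo <- r$counts$gene_flags == "endogenous"
  denom <- colSums(r$counts$counts[endo, ])
  # per-cell count share of each class's marker block: own vs other
  # classes should differ by no more than sampling error (|t| < 4)
  for (k in seq_along(sc$class_names)) {
    idx <- (k - 1) * 20 + seq_len(20)
    frac <- colSums(r$counts$counts[idx, ]) / denom
    own <- frac[r$labels == sc$class_names[k]]
    other <- frac[r$labels != sc$class_names[k]]
    t_stat <- (mean(own) - mean(other)) /
      sqrt(var(own) / length(own) + var(other) / length(other))
    expect_lt(abs(t_stat), 4)
  }
})

test_that("planted markers separate class medians by more than 1 log2 unit", {
  sc <- synth_config(seed = 2)  # 3 classes, 50 markers each, log2fc 3
  r <- generate_reference_counts(sc, n_per_class = 200)
  norm <- log2_cpm(r$counts)
  for (k in seq_along(sc$class_names)) {
    idx <- (k - 1) * 50 + seq_len(50)
    own <- apply(norm[idx, r$labels == sc$class_names[k], drop = FALSE],
                 1, median)
    other <- apply(norm[idx, r$labels != sc$class_names[k], drop = FALSE],
                   1, median)
    expect_true(all(own - other > 1))
  }
})

test_that("query cells follow their pool mixtures", {
  sc <- synth_config(lowq_fraction = 0, seed = 3)
  q <- generate_query_cells(sc, n_per_pool = 1000)
  # degenerate mixture: every cell from class 1
  sc1 <- small_config(pool_mixtures = list(aIP = c(1, 0, 0)), seed = 4)
  q1 <- generate_query_cells(sc1, n_per_pool = 100)
  expect_true(all(q1$truth$true_class == "Agmat"))
  # empirical proportions within the binomial 99% CI of the mixture
  for (p in names(sc$pool_mixtures)) {
    cls <- q$truth$true_class[q$truth$pool == p]
    for (k in seq_along(sc$class_names)) {
      prob <- sc$pool_mixtures[[p]][k]
      phat <- mean(cls == sc$class_names[k])
      half <- 2.576 * sqrt(prob * (1 - prob) / 1000) + 0.5 / 1000
      expect_lt(abs(phat - prob), half + 1e-12)
    }
  }
})

test_that("low-quality injection depresses libraries and inflates mito", {
  sc <- synth_config(lowq_fraction = 0.1, seed = 8)
  q <- generate_query_cells(sc, n_per_pool = 100)  # 200 cells
  n_lowq <- sum(q$truth$is_lowq)
  expect_gt(n_lowq, 8)   # binomial(200, 0.1) 99.9% range
  expect_lt(n_lowq, 40)
  m <- compute_qc_metrics(q$counts)
  clean_med_mito <- median(m$mito_prop[!q$truth$is_lowq])
  clean_med_lib <- median(m$library_size[!q$truth$is_lowq])
  expect_true(all(m$mito_prop[q$truth$is_lowq] > clean_med_mito))
  expect_true(all(m$library_size[q$truth$is_lowq] < clean_med_lib / 2))
})

test_that("pair-test outcomes are Bernoulli with the category probability", {
  t0 <- generate_pair_tests(c("aIP->aIP" = 0), c("aIP->aIP" = 50), seed = 1)
  expect_equal(sum(t0$connected), 0)
  t1 <- generate_pair_tests(c("OP->OP" = 1), c("OP->OP" = 10), seed = 1)
  expect_equal(sum(t1$connected), 10)
  expect_true(all(!is.na(t1$delay_ms) & t1$delay_ms > 0))
  expect_true(all(is.na(t0$delay_ms)))
  probs <- c("aIP->aIP" = 0.031, "aIP->OP" = 0.122,
             "OP->OP" = 0.146, "OP->aIP" = 0.147)
  tt <- generate_pair_tests(probs, setNames(rep(5000, 4), names(probs)),
                            seed = 9)
  emp <- with(tt, tapply(connected, paste0(pre_pool, "->", post_pool), mean))
  expect_true(all(abs(emp[names(probs)] - probs) < 0.01))
})

test_that("paired responses honor the configured bias", {
  r0 <- generate_paired_responses(0.5, 20, noise_cv = 0, seed = 1)
  expect_equal(r0$amp_L5a_mV, r0$amp_L5b_mV)
  r1 <- generate_paired_responses(0.67, 20, noise_cv = 0, seed = 1)
  expect_equal(r1$amp_L5a_mV / (r1$amp_L5a_mV + r1$amp_L5b_mV),
               rep(0.67, 20))
  expect_true(all(r1$amp_L5a_mV > 0 & r1$amp_L5b_mV > 0))
  ob <- output_bias(generate_paired_responses(0.67, 500, 0.3, seed = 5))
  expect_lt(abs(ob$mean - 0.67), 0.02)
})

test_that("epsp traces match the analytic kernel", {
  # zero amplitude: pure noise around 0
  t0 <- generate_epsp_trace(amplitude_mV = 0, noise_sd_mV = 0.1, seed = 2)
  expect_lt(abs(mean(t0$sweeps)), 0.02)
  expect_lt(abs(sd(as.vector(t0$sweeps)) - 0.1), 0.02)
  # noiseless: sampled peak equals the closed-form kernel peak
  t1 <- generate_epsp_trace(amplitude_mV = 2, noise_sd_mV = 0,
                            sampling_khz = 100)
  expect_equal(max(t1$sweeps), 2, tolerance = 1e-4)
  expect_equal(min(t1$sweeps), 0)
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_config(nb_dispersion = 0), "dispersion")
  expect_error(synth_config(nb_mean_baseline = -1), "baseline")
  expect_error(synth_config(pool_mixtures = list(aIP = c(0.5, 0.4, 0.2))),
               "sum to 1")
  expect_error(synth_config(n_genes = 10), "n_genes")
  expect_error(generate_pair_tests(c("aIP->aIP" = 0.5),
                                   c("aIP->OP" = 10)), "unknown category")
  expect_error(generate_paired_responses(1.2, 10), "true_bias")
  expect_error(generate_epsp_trace(rise_tau_ms = 5, decay_tau_ms = 2),
               "decay_tau_ms")
})
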