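# Synthetic-data generators. Every generator is a pure function of its
# arguments plus an explicit integer seed: the RNG state of the caller is
# never touched (withr::with_seed) and identical inputs give bit-identical
# outputs.

#' Configuration for the synthetic single-cell generators
#'
#' Defines the generative model used by [generate_reference_counts()] and
#' [generate_query_cells()]: negative-binomial counts with class-specific
#' marker blocks, log-normal library-size variation, mitochondrial / ERCC
#' spike-in fractions, and an injected low-quality cell population.
#' Defaults emulate a plate of upper-layer cortical neurons spanning three
#' transcriptomic classes (Agmat, Adamts2, Rrad) sampled from two
#' progenitor pools (aIP, OP), at roughly 10k counts per cell.
#'
#' @param n_classes number of transcriptomic classes.
#' @param genes_per_class_marker planted marker genes per class.
#' @param n_genes total endogenous genes (markers included).
#' @param nb_mean_baseline expected counts per non-marker gene.
#' @param nb_dispersion shared NB dispersion; `var = mu + disp * mu^2`.
#' @param marker_log2fc log2 fold-change of a class's markers in cells of
#'   that class.
#' @param library_size_sigma sd (natural-log scale) of the log-normal
#'   per-cell library factor.
#' @param mito_fraction_mean expected mitochondrial fraction of total
#'   counts in a clean cell.
#' @param ercc_fraction_mean expected ERCC spike-in fraction.
#' @param lowq_fraction fraction of query cells injected as low quality
#'   (library x 0.1, mito and ERCC fractions tripled).
#' @param pool_mixtures named list, one numeric vector of class
#'   proportions (summing to 1) per pool.
#' @param class_names class labels; defaults to the three upper-layer
#'   classes when `n_classes == 3`.
#' @param n_mito,n_ercc number of mitochondrial genes and ERCC species.
#' @param seed integer seed used by the generators.
#'
#' @return An object of class `SynthConfig` (a validated list).
#' @export
synth_config <- function(n_classes = 3,
                         genes_per_class_marker = 50,
                         n_genes = 2000,
                         nb_mean_baseline = 1.5,
                         nb_dispersion = 0.4,
                         marker_log2fc = 3,
                         library_size_sigma = 0.35,
                         mito_fraction_mean = 0.05,
                         ercc_fraction_mean = 0.03,
                         lowq_fraction = 0.1,
                         pool_mixtures = list(
                           aIP = c(0.94, 0.06, 0),
                           OP  = c(0.65, 0.32, 0.03)),
                         class_names = NULL,
                         n_mito = 20,
                         n_ercc = 30,
                         seed = 1L) {
  if (nb_mean_baseline <= 0) stop("nb_mean_baseline must be positive")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (library_size_sigma <= 0) stop("library_size_sigma must be positive")
  for (p in c(mito_fraction_mean, ercc_fraction_mean, lowq_fraction))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  if (3 * (mito_fraction_mean + ercc_fraction_mean) >= 1)
    stop("tripled mito + ERCC fractions must stay below 1")
  if (n_genes < n_classes * genes_per_class_marker)
    stop("n_genes must be >= n_classes * genes_per_class_marker")
  if (is.null(class_names)) {
    class_names <- if (n_classes == 3)
      c("Agmat", "Adamts2", "Rrad") else paste0("class", seq_len(n_classes))
  }
  if (length(class_names) != n_classes)
    stop("class_names must have length n_classes")
  for (nm in names(pool_mixtures)) {
    mx <- pool_mixtures[[nm]]
    if (length(mx) != n_classes)
      stop("pool mixture '", nm, "' must have length n_classes")
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-9)
      stop("pool mixture '", nm, "' must be non-negative and sum to 1")
  }
  structure(
    list(n_classes = n_classes,
         genes_per_class_marker = genes_per_class_marker,
         n_genes = n_genes, nb_mean_baseline = nb_mean_baseline,
         nb_dispersion = nb_dispersion, marker_log2fc = marker_log2fc,
         library_size_sigma = library_size_sigma,
         mito_fraction_mean = mito_fraction_mean,
         ercc_fraction_mean = ercc_fraction_mean,
         lowq_fraction = lowq_fraction, pool_mixtures = pool_mixtures,
         class_names = class_names, n_mito = n_mito, n_ercc = n_ercc,
         seed = as.integer(seed)),
    class = "SynthConfig")
}

# gene universe: endogenous (markers first, in class blocks), mito, ercc,
# one reporter gene
.synth_genes <- function(config) {
  gene_ids <- c(sprintf("gene%04d", seq_len(config$n_genes)),
                sprintf("mt-gene%02d", seq_len(config$n_mito)),
                sprintf("ERCC-%05d", seq_len(config$n_ercc)),
                "reporter-GFP")
  gene_flags <- c(rep("endogenous", config$n_genes),
                  rep("mito", config$n_mito),
                  rep("ercc", config$n_ercc),
                  "reporter")
  marker_class <- rep(NA_character_, length(gene_ids))
  idx <- seq_len(config$n_classes * config$genes_per_class_marker)
  marker_class[idx] <- rep(config$class_names,
                           each = config$genes_per_class_marker)
  list(gene_ids = gene_ids, gene_flags = gene_flags,
       marker_class = marker_class)
}

# endogenous mean vector for one class
.endo_means <- function(config, class_name, genes) {
  mu <- rep(config$nb_mean_baseline, config$n_genes)
  own <- which(genes$marker_class[seq_len(config$n_genes)] == class_name)
  mu[own] <- mu[own] * 2^config$marker_log2fc
  mu
}

# full mean vector for one cell; lowq scales the library down 10x and
# triples the mito / ERCC fractions
.cell_means <- function(config, class_name, genes, lowq = FALSE) {
  endo <- .endo_means(config, class_name, genes)
  f_m <- config$mito_fraction_mean
  f_e <- config$ercc_fraction_mean
  if (lowq) {
    endo <- endo * 0.1
    f_m <- 3 * f_m
    f_e <- 3 * f_e
  }
  e_tot <- sum(endo)
  mito_tot <- e_tot * f_m / (1 - f_m - f_e)
  ercc_tot <- e_tot * f_e / (1 - f_m - f_e)
  c(endo,
    rep(mito_tot / config$n_mito, config$n_mito),
    rep(ercc_tot / config$n_ercc, config$n_ercc),
    2)  # reporter
}

# NB draw for a block of cells sharing a mean vector, each scaled by its
# own log-normal library factor
.draw_counts <- function(config, mu, lib_factors) {
  size <- 1 / config$nb_dispersion
  n_g <- length(mu)
  vapply(lib_factors, function(f)
    stats::rnbinom(n_g, mu = mu * f, size = size), numeric(n_g))
}

#' Generate a labeled reference count matrix
#'
#' Synthetic stand-in for a labeled reference dataset: `n_per_class` cells
#' per class, counts drawn from the class's negative-binomial model with
#' per-cell log-normal library factors. No low-quality cells are injected.
#'
#' @param config a [synth_config()].
#' @param n_per_class cells per class.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list with `counts` (a `CountMatrix`) and `labels`
#'   (character vector, one class label per cell).
#' @export
generate_reference_counts <- function(config, n_per_class = 200,
                                      seed = config$seed) {
  stopifnot(inherits(config, "SynthConfig"))
  genes <- .synth_genes(config)
  withr::with_seed(as.integer(seed), {
    blocks <- lapply(seq_len(config$n_classes), function(k) {
      mu <- .cell_means(config, config$class_names[k], genes)
      lf <- stats::rlnorm(n_per_class, 0, config$library_size_sigma)
      .draw_counts(config, mu, lf)
    })
    counts <- do.call(cbind, blocks)
  })
  labels <- rep(config$class_names, each = n_per_class)
  cell_ids <- sprintf("ref_%s_%03d", rep(config$class_names,
                                         each = n_per_class),
                      rep(seq_len(n_per_class), config$n_classes))
  list(counts = count_matrix(counts, genes$gene_ids, genes$gene_flags,
                             cell_ids),
       labels = labels)
}

#' Generate Patch-seq query cells from pool-specific class mixtures
#'
#' Each query cell's class is drawn from its pool's mixture
#' (`config$pool_mixtures`); counts come from that class's generative
#' model. A fraction `config$lowq_fraction` of cells is injected as low
#' quality: library size scaled by 0.1 and mitochondrial / ERCC fractions
#' tripled, so that they fall past the default MAD cutoffs.
#'
#' @param config a [synth_config()].
#' @param n_per_pool cells per pool.
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @return A list with `counts` (a `CountMatrix`), `annotation`
#'   (data.frame `cell_id`, `pool`) and `truth` (data.frame `cell_id`,
#'   `true_class`, `pool`, `is_lowq`).
#' @export
generate_query_cells <- function(config, n_per_pool = 100,
                                 seed = config$seed + 1L) {
  stopifnot(inherits(config, "SynthConfig"))
  pools <- names(config$pool_mixtures)
  if (is.null(pools) || !length(pools))
    stop("config$pool_mixtures must be a named list")
  genes <- .synth_genes(config)
  withr::with_seed(as.integer(seed), {
    truth <- do.call(rbind, lapply(pools, function(p) {
      cls <- sample(config$class_names, n_per_pool, replace = TRUE,
                    prob = config$pool_mixtures[[p]])
      lowq <- stats::runif(n_per_pool) < config$lowq_fraction
      data.frame(cell_id = sprintf("%s_%04d", p, seq_len(n_per_pool)),
                 true_class = cls, pool = p, is_lowq = lowq,
                 stringsAsFactors = FALSE)
    }))
    counts <- vapply(seq_len(nrow(truth)), function(i) {
      mu <- .cell_means(config, truth$true_class[i], genes,
                        lowq = truth$is_lowq[i])
      lf <- stats::rlnorm(1, 0, config$library_size_sigma)
      stats::rnbinom(length(mu), mu = mu * lf,
                     size = 1 / config$nb_dispersion)
    }, numeric(length(genes$gene_ids)))
  })
  list(counts = count_matrix(counts, genes$gene_ids, genes$gene_flags,
                             truth$cell_id),
       annotation = truth[, c("cell_id", "pool")],
       truth = truth)
}

#' Generate a Bernoulli pair-test table
#'
#' One row per tested directed putative connection. The `connected` flag
#' is Bernoulli with the probability of the pair's directed category
#' (`"aIP->OP"` etc.); connected pairs receive a log-normal synaptic
#' delay and amplitude, all pairs an intersomatic distance.
#'
#' @param prob_by_category named numeric vector of connection
#'   probabilities; names are `"pre->post"` pool labels.
#' @param n_by_category named integer vector of tested pair counts, same
#'   names as `prob_by_category`.
#' @param seed integer seed.
#' @param delay_median_ms,delay_sdlog log-normal delay parameters.
#' @param amp_median_mV,amp_sdlog log-normal amplitude parameters.
#' @param distance_range_um uniform range for intersomatic distance.
#' @return A data.frame (class `PairTestTable`) with columns `pair_id`,
#'   `pre_pool`, `post_pool`, `connected`, `delay_ms`, `amplitude_mV`,
#'   `distance_um`.
#' @export
generate_pair_tests <- function(prob_by_category = c("aIP->aIP" = 0.031,
                                                     "aIP->OP"  = 0.122,
                                                     "OP->OP"   = 0.146,
                                                     "OP->aIP"  = 0.147),
                                n_by_category = c("aIP->aIP" = 100,
                                                  "aIP->OP"  = 100,
                                                  "OP->OP"   = 100,
                                                  "OP->aIP"  = 100),
                                seed = 1L,
                                delay_median_ms = 1.8, delay_sdlog = 0.3,
                                amp_median_mV = 0.5, amp_sdlog = 0.6,
                                distance_range_um = c(20, 150)) {
  if (any(prob_by_category < 0 | prob_by_category > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(n_by_category < 0)) stop("counts must be >= 0")
  unknown <- setdiff(names(n_by_category), names(prob_by_category))
  if (length(unknown))
    stop("unknown category key: ", paste(unknown, collapse = ", "))
  cats <- names(n_by_category)
  pre <- sub("->.*$", "", cats)
  post <- sub("^.*->", "", cats)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_along(cats), function(i) {
      n <- n_by_category[[i]]
      if (n == 0) return(NULL)
      conn <- stats::runif(n) < prob_by_category[[cats[i]]]
      delay <- ifelse(conn,
                      stats::rlnorm(n, log(delay_median_ms), delay_sdlog),
                      NA_real_)
      amp <- ifelse(conn,
                    stats::rlnorm(n, log(amp_median_mV), amp_sdlog),
                    NA_real_)
      data.frame(pre_pool = pre[i], post_pool = post[i], connected = conn,
                 delay_ms = delay, amplitude_mV = amp,
                 distance_um = stats::runif(n, distance_range_um[1],
                                            distance_range_um[2]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  })
  out <- cbind(pair_id = sprintf("pair%05d", seq_len(nrow(out))), out)
  class(out) <- c("PairTestTable", "data.frame")
  out
}

#' Generate simultaneously recorded L5a/L5b paired response amplitudes
#'
#' Per pair, a total drive is split `true_bias : (1 - true_bias)` between
#' the L5a and L5b amplitudes, each then multiplied by independent
#' log-normal noise with unit mean and coefficient of variation
#' `noise_cv`. Amplitudes are strictly positive; with `noise_cv = 0`
#' every per-pair bias equals `true_bias` exactly.
#'
#' @param true_bias expected L5a share of the summed pair amplitude,
#'   in (0, 1).
#' @param n_pairs number of pairs.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param total_median_mV median of the log-normal per-pair total drive.
#' @param total_sdlog sd (log scale) of the total drive.
#' @return A data.frame (class `PairedResponseTable`) with columns
#'   `pair_id`, `amp_L5a_mV`, `amp_L5b_mV`.
#' @export
generate_paired_responses <- function(true_bias = 0.67, n_pairs = 21,
                                      noise_cv = 0.3, seed = 1L,
                                      total_median_mV = 2,
                                      total_sdlog = 0.4) {
  if (true_bias <= 0 || true_bias >= 1)
    stop("true_bias must lie strictly inside (0, 1)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  withr::with_seed(as.integer(seed), {
    total <- stats::rlnorm(n_pairs, log(total_median_mV), total_sdlog)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      eps_a <- stats::rlnorm(n_pairs, -sdlog^2 / 2, sdlog)
      eps_b <- stats::rlnorm(n_pairs, -sdlog^2 / 2, sdlog)
    } else {
      eps_a <- eps_b <- rep(1, n_pairs)
    }
  })
  out <- data.frame(pair_id = sprintf("pair%04d", seq_len(n_pairs)),
                    amp_L5a_mV = total * true_bias * eps_a,
                    amp_L5b_mV = total * (1 - true_bias) * eps_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("PairedResponseTable", "data.frame")
  out
}

# double-exponential EPSP kernel, normalized so its peak is 1
.epsp_kernel <- function(t, onset, rise_tau, decay_tau) {
  k <- numeric(length(t))
  on <- t >= onset
  dt <- t[on] - onset
  raw <- exp(-dt / decay_tau) - exp(-dt / rise_tau)
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  k[on] <- raw / peak
  k
}

#' Generate synthetic membrane-potential sweeps containing an EPSP
#'
#' Baseline-zero traces carrying a double-exponential EPSP
#' (`exp(-t/decay) - exp(-t/rise)`, peak-normalized to `amplitude_mV`)
#' starting at `onset_ms`, plus i.i.d. Gaussian noise. The presynaptic
#' action-potential time is recorded as `onset_ms` so that the synaptic
#' delay of the noiseless trace equals the kernel's 20%-of-peak rise
#' time.
#'
#' @param onset_ms EPSP onset (and presynaptic AP time).
#' @param amplitude_mV true peak amplitude; 0 gives pure noise.
#' @param rise_tau_ms,decay_tau_ms kernel time constants,
#'   `decay > rise > 0`.
#' @param noise_sd_mV Gaussian noise sd per sample.
#' @param sampling_khz sampling rate.
#' @param duration_ms trace length.
#' @param n_sweeps number of sweeps.
#' @param seed integer seed.
#' @return A [trace_set()] whose `meta` records the true onset,
#'   amplitude, taus and seed.
#' @export
generate_epsp_trace <- function(onset_ms = 10, amplitude_mV = 2,
                                rise_tau_ms = 2, decay_tau_ms = 20,
                                noise_sd_mV = 0.1, sampling_khz = 20,
                                duration_ms = 100, n_sweeps = 1,
                                seed = 1L) {
  if (rise_tau_ms <= 0 || decay_tau_ms <= 0)
    stop("time constants must be positive")
  if (decay_tau_ms <= rise_tau_ms)
    stop("decay_tau_ms must exceed rise_tau_ms")
  if (sampling_khz <= 0) stop("sampling rate must be positive")
  time_ms <- seq(0, duration_ms, by = 1 / sampling_khz)
  clean <- amplitude_mV * .epsp_kernel(time_ms, onset_ms, rise_tau_ms,
                                       decay_tau_ms)
  withr::with_seed(as.integer(seed), {
    sweeps <- t(vapply(seq_len(n_sweeps), function(i)
      clean + stats::rnorm(length(time_ms), 0, noise_sd_mV),
      numeric(length(time_ms))))
  })
  trace_set(time_ms, sweeps, stim_onset_ms = onset_ms,
            presyn_ap_time_ms = onset_ms,
            meta = list(true_onset_ms = onset_ms,
                        true_amplitude_mV = amplitude_mV,
                        rise_tau_ms = rise_tau_ms,
                        decay_tau_ms = decay_tau_ms,
                        noise_sd_mV = noise_sd_mV, seed = as.integer(seed)))
}

#' Generate a hyperpolarizing current-step trace
#'
#' Membrane potential settling exponentially toward
#' `baseline + delta_mV` during the step and back afterwards, plus
#' optional Gaussian noise; the fixture for input-resistance estimation.
#'
#' @param delta_mV steady-state voltage deflection of the step.
#' @param tau_ms membrane time constant.
#' @param step_onset_ms,step_end_ms step window.
#' @param duration_ms trace length.
#' @param sampling_khz sampling rate.
#' @param baseline_mV resting potential.
#' @param noise_sd_mV Gaussian noise sd (0 for a clean trace).
#' @param injected_current_pA recorded in `meta`.
#' @param seed integer seed.
#' @return A [trace_set()] with one sweep.
#' @export
generate_step_trace <- function(delta_mV = -45, tau_ms = 20,
                                step_onset_ms = 100, step_end_ms = 600,
                                duration_ms = 700, sampling_khz = 10,
                                baseline_mV = -70, noise_sd_mV = 0,
                                injected_current_pA = -300, seed = 1L) {
  if (tau_ms <= 0) stop("tau_ms must be positive")
  time_ms <- seq(0, duration_ms, by = 1 / sampling_khz)
  v <- rep(baseline_mV, length(time_ms))
  during <- time_ms >= step_onset_ms & time_ms < step_end_ms
  v[during] <- baseline_mV +
    delta_mV * (1 - exp(-(time_ms[during] - step_onset_ms) / tau_ms))
  after <- time_ms >= step_end_ms
  v_end <- baseline_mV +
    delta_mV * (1 - exp(-(step_end_ms - step_onset_ms) / tau_ms))
  v[after] <- baseline_mV +
    (v_end - baseline_mV) * exp(-(time_ms[after] - step_end_ms) / tau_ms)
  if (noise_sd_mV > 0)
    withr::with_seed(as.integer(seed),
      v <- v + stats::rnorm(length(v), 0, noise_sd_mV))
  trace_set(time_ms, matrix(v, nrow = 1), stim_onset_ms = step_onset_ms,
            meta = list(delta_mV = delta_mV, tau_ms = tau_ms,
                        step_onset_ms = step_onset_ms,
                        step_end_ms = step_end_ms,
                        injected_current_pA = injected_current_pA,
                        seed = as.integer(seed)))
}
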