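# lineagecircuits

Does the embryonic progenitor a cortical neuron comes from leave a
trace in its adult transcriptomic identity and synaptic wiring?
`lineagecircuits` implements the statistical chain used to answer that
question for two lineage pools of mouse neocortical excitatory neurons
— **aIP**-derived (apical intermediate progenitors, Tα1-labelled) and
**OP**-derived (all other concurrently dividing progenitors):

* **Single-cell QC and normalization** — per-cell library size,
  detected genes, mitochondrial and ERCC fractions; robust outlier
  removal at >3 MADs below the log-median (library, genes), >5 MADs
  above the median (mito) and >4 MADs (ERCC); `log2(CPM + 1)` over
  endogenous genes.
* **Reference-atlas classification of Patch-seq cells** — per-class
  median log2-CPM profiles with pairwise marker selection; each query
  cell is mapped to the class with the highest Pearson correlation over
  a random 80% of markers, across 100 bootstrap iterations; the modal
  vote fraction is the *certainty*, and cells are classified only above
  50% certainty and outside low-quality classes.
* **Connectivity statistics** — directed connection probabilities by
  progenitor-pool category; the *out-of-class bias*
  `p_out / (p_out + p_in)` (0.5 = no preference); exact two-sided
  Fisher 2×2 tests by hypergeometric enumeration; the L5a/L5b *output
  bias* `a / (a + b)` with exact Wilcoxon signed-rank tests
  (full 2^n enumeration for n ≤ 25, midranks for ties).
* **EPSP features** — sweep averaging, detection of responses >2 SD
  above baseline, synaptic delay at the interpolated 20%-of-peak
  crossing, input resistance from a −300 pA step.
* **Synthetic data** — negative-binomial count plates with planted
  marker blocks and injected low-quality cells, Bernoulli pair-test
  tables, biased paired-response amplitudes, and double-exponential
  EPSP traces; every generator is a pure function of its parameters and
  seed.

## Worked example

```r
library(lineagecircuits)

sc    <- synth_config(seed = 7)                      # study-condition defaults
ref   <- generate_reference_counts(sc, n_per_class = 200)
atlas <- build_reference(ref$counts, ref$labels)
#> ReferenceAtlas: 3 classes, 2020 profile genes, 150 markers

qry     <- generate_query_cells(sc, n_per_pool = 300)
metrics <- filter_cells(compute_qc_metrics(qry$counts))
#> filter_cells: removing 61 / 600 cells (10.2%)
norm <- log2_cpm(subset_counts(qry$counts, cells = metrics$cell_id[metrics$pass_all]))
res  <- classify_cells(norm, atlas, classifier_params(seed = 8))
composition_table(res, qry$annotation)$composition
#>   pool   class   n       prop
#> 1  aIP Adamts2  20 0.07272727
#> 2  aIP   Agmat 255 0.92727273
#> 3  aIP    Rrad   0 0.00000000
#> 4   OP Adamts2  88 0.33333333
#> 5   OP   Agmat 168 0.63636364
#> 6   OP    Rrad   8 0.03030303
```

About 10% of cells are removed as low quality (matching the injected
fraction), and the recovered compositions sit within sampling error of
the generating mixtures — aIP cells are nearly all *Agmat*, OP cells a
*Agmat*/*Adamts2*/*Rrad* blend.

```r
pairs <- generate_pair_tests(n_by_category = setNames(rep(250, 4),
           c("aIP->aIP", "aIP->OP", "OP->OP", "OP->aIP")), seed = 9)
tally_connectivity(pairs)
#> Connectivity: 121/1000 tested pairs connected (12.1%)
#>  pre_pool post_pool n_tested n_connected probability
#>       aIP       aIP      250           8       0.032
#>        OP       aIP      250          41       0.164
#>       aIP        OP      250          37       0.148
#>        OP        OP      250          35       0.140
#>  pre_pool p_out  p_in out_of_class_bias     fisher_p
#>       aIP 0.148 0.032         0.8222222 6.214268e-06
#>        OP 0.164 0.140         0.5394737 5.336068e-01
```

aIP-derived neurons connect preferentially *out of class* (bias 0.82,
Fisher p ≈ 6e-6) while OP-derived neurons show no preference (0.54,
p ≈ 0.53) — the synthetic table was generated under exactly that
asymmetry.

```r
ob <- output_bias(generate_paired_responses(0.67, 21, 0.3, seed = 10))
wt <- wilcoxon_signed_rank(ob$per_pair, 0.5)
#> output bias toward L5a: 0.62 +/- 0.01 (n = 21)
#> Wilcoxon signed-rank vs 0.5: W = 231, p = 9.537e-07

tr  <- generate_epsp_trace(amplitude_mV = 1.2, noise_sd_mV = 0.15,
                           n_sweeps = 15, seed = 11)
avg <- average_sweeps(tr)
f   <- detect_epsp(tr$time_ms, avg, tr$stim_onset_ms)
#> EPSP detected: TRUE, amplitude 1.19 mV (baseline SD 0.041 mV)
synaptic_delay(tr$time_ms, avg, tr$presyn_ap_time_ms,
               f$baseline_mean_mV, f$amplitude_mV)
#> [1] 0.37
```

The whole chain can also be driven from one config via
`run_pipeline(list(seed = 1), out_dir = "run1")`, which persists every
intermediate artifact (Matrix Market counts, CSV tables, a JSON
report); `validate_config()` checks a config file first.

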