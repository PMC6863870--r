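# End-to-end orchestration: simulate -> qc -> classify -> connectivity
# -> ephys, from a single validated config, with a machine-readable
# JSON report.

.known_stages <- c("simulate", "qc", "classify", "connectivity", "ephys")

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    synth = list(),           # overrides for synth_config()
    stages = list(
      simulate = list(enabled = TRUE, n_per_class = 100, n_per_pool = 100,
                      pairs = list(), responses = list(), trace = list()),
      qc = list(enabled = TRUE, k_library = 3, k_genes = 3, k_mito = 5,
                k_ercc = 4),
      classify = list(enabled = TRUE, n_boot = 100, marker_fraction = 0.8,
                      certainty_threshold = 0.5, top_k = 50),
      connectivity = list(enabled = TRUE),
      ephys = list(enabled = TRUE)))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config
}

#' Validate a pipeline configuration
#'
#' Checks the config (a list, or a path to a YAML/JSON file) against the
#' pipeline schema and returns explicit messages for every violation.
#'
#' @param config list or file path.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  config <- .load_config(config)
  v <- character()
  extra <- setdiff(names(config), c("seed", "out_dir", "synth", "stages"))
  if (length(extra))
    v <- c(v, paste0("unknown top-level key(s): ",
                     paste(extra, collapse = ", "),
                     "; allowed: seed, out_dir, synth, stages"))
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    v <- c(v, "seed must be an integer")
  st <- config$stages
  if (!is.null(st)) {
    bad <- setdiff(names(st), .known_stages)
    if (length(bad))
      v <- c(v, paste0("unknown stage key(s): ",
                       paste(bad, collapse = ", "), "; allowed: ",
                       paste(.known_stages, collapse = ", ")))
    mf <- st$classify$marker_fraction
    if (!is.null(mf) && (mf <= 0 || mf > 1))
      v <- c(v, sprintf("classify.marker_fraction = %g outside (0, 1]", mf))
    ct <- st$classify$certainty_threshold
    if (!is.null(ct) && (ct < 0 || ct >= 1))
      v <- c(v, sprintf("classify.certainty_threshold = %g outside [0, 1)",
                        ct))
    for (k in c("k_library", "k_genes", "k_mito", "k_ercc")) {
      kk <- st$qc[[k]]
      if (!is.null(kk) && kk <= 0)
        v <- c(v, sprintf("qc.%s = %g must be positive", k, kk))
    }
    for (s in intersect(names(st), .known_stages)) {
      en <- st[[s]]$enabled
      if (!is.null(en) && !is.logical(en))
        v <- c(v, sprintf("%s.enabled must be logical", s))
    }
    deps <- setdiff(.known_stages, "simulate")
    sim_on <- isTRUE(st$simulate$enabled) || is.null(st$simulate$enabled)
    for (s in deps) {
      if (isTRUE(st[[s]]$enabled) && !sim_on)
        v <- c(v, sprintf("stage '%s' enabled but 'simulate' disabled: no input", s))
    }
  }
  if (!is.null(config$synth)) {
    lf <- config$synth$lowq_fraction
    if (!is.null(lf) && (lf < 0 || lf > 1))
      v <- c(v, sprintf("synth.lowq_fraction = %g outside [0, 1]", lf))
  }
  v
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order (simulate, qc,
#' classify, connectivity, ephys), persists every intermediate artifact
#' under `out_dir`, and writes `report.json`. Identical config and seed
#' reproduce identical report bodies (the `timestamps` entry aside).
#'
#' @param config list or YAML/JSON path; see [validate_config()].
#' @param out_dir output directory; overrides `config$out_dir`; a
#'   temporary directory is used when neither is set.
#' @return The report, invisibly a list (class `RunReport`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  user <- .load_config(config)
  cfg <- .merge_config(.default_config(), user)
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("lineagecircuits_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- cfg$stages
  seed <- as.integer(cfg$seed)
  report <- list(package = "lineagecircuits",
                 version = as.character(utils::packageVersion("lineagecircuits")),
                 seed = seed, config = cfg, stages = list())

  sim <- NULL
  if (isTRUE(st$simulate$enabled)) {
    sc <- do.call(synth_config, c(cfg$synth, list(seed = seed)))
    ref <- generate_reference_counts(sc, st$simulate$n_per_class,
                                     seed = seed)
    qry <- generate_query_cells(sc, st$simulate$n_per_pool,
                                seed = seed + 1L)
    pairs <- do.call(generate_pair_tests,
                     c(st$simulate$pairs, list(seed = seed + 2L)))
    resp <- do.call(generate_paired_responses,
                    c(st$simulate$responses, list(seed = seed + 3L)))
    trace <- do.call(generate_epsp_trace,
                     c(st$simulate$trace,
                       list(n_sweeps = 20, seed = seed + 4L)))
    write_count_matrix(ref$counts, file.path(out_dir, "reference"))
    writeLines(ref$labels, file.path(out_dir, "reference", "labels.txt"))
    write_count_matrix(qry$counts, file.path(out_dir, "query"))
    utils::write.csv(qry$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "pair_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(resp, file.path(out_dir, "paired_responses.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(time_ms = trace$time_ms,
                                t(trace$sweeps)),
                     file.path(out_dir, "trace.csv"), row.names = FALSE)
    sim <- list(ref = ref, qry = qry, pairs = pairs, resp = resp,
                trace = trace, sc = sc)
    report$stages$simulate <- list(
      n_reference_cells = ncol(ref$counts$counts),
      n_query_cells = ncol(qry$counts$counts),
      n_pair_tests = nrow(pairs), n_response_pairs = nrow(resp),
      files = c("reference", "query", "ground_truth.csv",
                "pair_tests.csv", "paired_responses.csv", "trace.csv"))
  }

  passed <- NULL
  if (isTRUE(st$qc$enabled)) {
    metrics <- compute_qc_metrics(sim$qry$counts)
    metrics <- filter_cells(metrics, st$qc$k_library, st$qc$k_genes,
                            st$qc$k_mito, st$qc$k_ercc, verbose = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "qc_metrics.csv"),
                     row.names = FALSE)
    passed <- metrics$cell_id[metrics$pass_all]
    writeLines(passed, file.path(out_dir, "qc_pass_cells.tsv"))
    report$stages$qc <- list(
      n_cells_in = nrow(metrics), n_cells_pass = length(passed),
      removal_fraction = 1 - length(passed) / nrow(metrics))
  }

  if (isTRUE(st$classify$enabled)) {
    atlas <- build_reference(sim$ref$counts, sim$ref$labels,
                             top_k = st$classify$top_k)
    write_atlas(atlas, file.path(out_dir, "atlas"))
    keep <- passed %||% sim$qry$counts$cell_ids
    norm <- log2_cpm(subset_counts(sim$qry$counts, cells = keep))
    params <- classifier_params(
      n_boot = st$classify$n_boot,
      marker_fraction = st$classify$marker_fraction,
      certainty_threshold = st$classify$certainty_threshold,
      seed = seed + 5L)
    res <- classify_cells(norm, atlas, params)
    utils::write.csv(res, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    comp <- composition_table(res, sim$qry$annotation)
    utils::write.csv(comp$composition,
                     file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
    report$stages$classify <- list(
      n_markers = length(atlas$markers),
      n_classified = sum(res$classified),
      n_unclassified = sum(!res$classified),
      composition = comp$composition, totals = comp$totals)
  }

  if (isTRUE(st$connectivity$enabled)) {
    tal <- tally_connectivity(sim$pairs)
    ob <- output_bias(sim$resp)
    wt <- wilcoxon_signed_rank(ob$per_pair, 0.5)
    utils::write.csv(tal$categories,
                     file.path(out_dir, "connectivity_categories.csv"),
                     row.names = FALSE)
    report$stages$connectivity <- list(
      overall = tal$overall, categories = tal$categories,
      bias = tal$bias,
      output_bias = list(mean = ob$mean, sem = ob$sem, n = ob$n,
                         wilcoxon_p = wt$p_value))
  }

  if (isTRUE(st$ephys$enabled)) {
    avg <- average_sweeps(sim$trace)
    feat <- detect_epsp(sim$trace$time_ms, avg, sim$trace$stim_onset_ms)
    delay <- if (feat$detected)
      synaptic_delay(sim$trace$time_ms, avg, sim$trace$presyn_ap_time_ms,
                     feat$baseline_mean_mV, feat$amplitude_mV)
    else NA_real_
    report$stages$ephys <- list(
      detected = feat$detected, amplitude_mV = feat$amplitude_mV,
      baseline_sd_mV = feat$baseline_sd_mV, synaptic_delay_ms = delay)
  }

  report$timestamps <- list(finished = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report$out_dir <- out_dir
  class(report) <- "RunReport"
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.RunReport <- function(x, ...) {
  cat("lineagecircuits run, seed", x$seed, "\n")
  cat("stages:", paste(names(x$stages), collapse = ", "), "\n")
  cat("artifacts in:", x$out_dir, "\n")
  invisible(x)
}
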