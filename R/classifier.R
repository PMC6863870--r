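# Reference-atlas construction and bootstrap correlation classification.
#
# The procedure: each query cell is correlated against the per-class
# median log2-CPM profile over a random 80% subset of the marker genes;
# over 100 such bootstrap iterations the fraction of votes for the modal
# class is the cell's certainty, and cells are classified only when the
# certainty strictly exceeds 0.5 and the winning class is not flagged
# low quality.

#' Bootstrap classifier parameters
#'
#' @param n_boot bootstrap iterations.
#' @param marker_fraction fraction of marker genes drawn (without
#'   replacement) per iteration, in (0, 1].
#' @param certainty_threshold strict lower bound on the modal vote
#'   fraction required to classify, in [0, 1).
#' @param correlation `"pearson"` or `"spearman"`.
#' @param seed integer seed for the bootstrap draws.
#' @return An object of class `ClassifierParams`.
#' @export
classifier_params <- function(n_boot = 100, marker_fraction = 0.8,
                              certainty_threshold = 0.5,
                              correlation = c("pearson", "spearman"),
                              seed = 1L) {
  correlation <- match.arg(correlation)
  if (marker_fraction <= 0 || marker_fraction > 1)
    stop("marker_fraction must lie in (0, 1]")
  if (certainty_threshold < 0 || certainty_threshold >= 1)
    stop("certainty_threshold must lie in [0, 1)")
  if (n_boot < 1) stop("n_boot must be >= 1")
  structure(list(n_boot = as.integer(n_boot),
                 marker_fraction = marker_fraction,
                 certainty_threshold = certainty_threshold,
                 correlation = correlation, seed = as.integer(seed)),
            class = "ClassifierParams")
}

#' Build a reference atlas from labeled counts
#'
#' Normalizes the labeled reference counts to log2-CPM, computes each
#' class's median profile per gene, and selects marker genes: for every
#' ordered pair of classes (i, j), genes are ranked by the difference of
#' class median log2-CPM (`median_i - median_j`, descending); a gene is
#' eligible only if the difference is positive and class i (the higher
#' class) detects it (count > 0) in at least `min_detect_frac` of its
#' cells; the top `top_k` eligible genes per ordered pair are kept and
#' the union over all pairs is the atlas marker set.
#'
#' @param counts labeled reference [count_matrix()].
#' @param labels class label per cell.
#' @param top_k markers retained per ordered class pair.
#' @param min_detect_frac detection-fraction filter in the higher class.
#' @param lowq_classes class names flagged low quality; query cells
#'   mapping to them are left unclassified.
#' @return An object of class `ReferenceAtlas`: list with `class_names`,
#'   `profiles` (gene x class median log2-CPM matrix), `markers`,
#'   `lowq_classes`.
#' @export
build_reference <- function(counts, labels, top_k = 50,
                            min_detect_frac = 0.3,
                            lowq_classes = character()) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (length(labels) != ncol(counts$counts))
    stop("labels length must equal number of cells")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("class with fewer than 2 cells: ", paste(small, collapse = ", "))
  norm <- log2_cpm(counts)
  detected <- counts$counts[rownames(norm), , drop = FALSE] > 0
  profiles <- vapply(classes, function(cl)
    apply(norm[, labels == cl, drop = FALSE], 1, stats::median),
    numeric(nrow(norm)))
  detect_frac <- vapply(classes, function(cl)
    rowMeans(detected[, labels == cl, drop = FALSE]),
    numeric(nrow(norm)))
  markers <- character()
  for (i in classes) for (j in classes) {
    if (i == j) next
    d <- profiles[, i] - profiles[, j]
    ok <- d > 0 & detect_frac[, i] >= min_detect_frac
    ord <- order(d, decreasing = TRUE)
    ord <- ord[ok[ord]]
    markers <- union(markers, rownames(norm)[utils::head(ord, top_k)])
  }
  bad <- setdiff(lowq_classes, classes)
  if (length(bad))
    stop("lowq_classes not in labels: ", paste(bad, collapse = ", "))
  structure(list(class_names = classes, profiles = profiles,
                 markers = sort(markers),
                 lowq_classes = as.character(lowq_classes)),
            class = "ReferenceAtlas")
}

#' @export
print.ReferenceAtlas <- function(x, ...) {
  cat(sprintf("ReferenceAtlas: %d classes, %d profile genes, %d markers\n",
              length(x$class_names), nrow(x$profiles), length(x$markers)))
  if (length(x$lowq_classes))
    cat("low-quality classes:", paste(x$lowq_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Correlate one cell profile against every atlas class
#'
#' Correlation is computed over `gene_subset` between the cell's
#' log2-CPM values and each class's median profile. A correlation that
#' is undefined because either vector has zero variance over the subset
#' is returned as `-Inf` so that it can never win the argmax.
#'
#' @param cell_profile named numeric vector of log2-CPM values; names
#'   must cover `gene_subset`.
#' @param atlas a [build_reference()] atlas.
#' @param gene_subset genes to use; defaults to all atlas markers. Must
#'   contain at least 3 genes.
#' @param method `"pearson"` or `"spearman"`.
#' @return Named numeric vector, one correlation per class.
#' @export
correlate_to_classes <- function(cell_profile, atlas,
                                 gene_subset = atlas$markers,
                                 method = "pearson") {
  stopifnot(inherits(atlas, "ReferenceAtlas"))
  if (length(gene_subset) < 3)
    stop("gene_subset must contain at least 3 genes")
  if (!all(gene_subset %in% rownames(atlas$profiles)))
    stop("gene_subset must be a subset of atlas profile genes")
  x <- cell_profile[gene_subset]
  if (anyNA(x)) stop("cell_profile missing values for gene_subset")
  p <- atlas$profiles[gene_subset, , drop = FALSE]
  r <- suppressWarnings(stats::cor(x, p, method = method))[1, ]
  r[!is.finite(r)] <- -Inf
  r
}

#' Classify query cells by bootstrap correlation mapping
#'
#' For each of `params$n_boot` iterations a random
#' `floor(marker_fraction * n_markers)` subset of the atlas markers is
#' drawn without replacement; every cell is assigned to the class with
#' the highest correlation over that subset (ties broken toward the
#' lexicographically smallest class name). The certainty is the vote
#' fraction of the modal class; a cell is classified iff its certainty
#' strictly exceeds `certainty_threshold` and the modal class is not
#' flagged low quality. Deterministic given `params$seed`.
#'
#' Markers absent from `norm` are dropped with a warning when they make
#' up less than 20% of the marker set, otherwise an error is raised.
#'
#' @param norm log2-CPM matrix (genes x cells) from [log2_cpm()].
#' @param atlas a [build_reference()] atlas.
#' @param params a [classifier_params()].
#' @param missing_marker_tol maximum tolerated fraction of atlas markers
#'   absent from `norm`.
#' @return A data.frame (class `ClassificationResult`) with columns
#'   `cell_id`, `best_class`, `certainty`, `classified`, `n_boot`;
#'   attribute `mean_correlations` holds the cell x class matrix of
#'   bootstrap-averaged correlations and attribute `n_ties` the number
#'   of argmax ties encountered.
#' @export
classify_cells <- function(norm, atlas, params = classifier_params(),
                           missing_marker_tol = 0.2) {
  stopifnot(inherits(atlas, "ReferenceAtlas"),
            inherits(params, "ClassifierParams"))
  markers <- atlas$markers
  missing <- setdiff(markers, rownames(norm))
  if (length(missing)) {
    frac <- length(missing) / length(markers)
    if (frac >= missing_marker_tol)
      stop(sprintf("%.0f%% of atlas markers missing from input", 100 * frac))
    warning(length(missing), " atlas marker(s) missing from input; dropped")
    markers <- setdiff(markers, missing)
  }
  n_sub <- floor(params$marker_fraction * length(markers))
  if (n_sub < 3)
    stop("fewer than 3 markers per bootstrap subsample")
  classes <- sort(atlas$class_names)
  prof <- atlas$profiles[markers, classes, drop = FALSE]
  x <- norm[markers, , drop = FALSE]
  n_cells <- ncol(x)
  votes <- matrix(0L, n_cells, length(classes),
                  dimnames = list(colnames(x), classes))
  corr_sum <- matrix(0, n_cells, length(classes),
                     dimnames = dimnames(votes))
  n_ties <- 0L
  withr::with_seed(params$seed, {
    for (b in seq_len(params$n_boot)) {
      sub <- sample(length(markers), n_sub)
      xs <- x[sub, , drop = FALSE]
      ps <- prof[sub, , drop = FALSE]
      if (params$correlation == "spearman") {
        xs <- apply(xs, 2, rank)
        ps <- apply(ps, 2, rank)
      }
      r <- suppressWarnings(stats::cor(xs, ps))
      r[!is.finite(r)] <- -Inf
      best <- max.col(r, ties.method = "first")  # columns sorted by name
      n_ties <- n_ties +
        sum(rowSums(r == r[cbind(seq_len(n_cells), best)]) > 1)
      votes[cbind(seq_len(n_cells), best)] <-
        votes[cbind(seq_len(n_cells), best)] + 1L
      corr_sum <- corr_sum + r
    }
  })
  modal <- max.col(votes, ties.method = "first")
  certainty <- votes[cbind(seq_len(n_cells), modal)] / params$n_boot
  best_class <- classes[modal]
  classified <- certainty > params$certainty_threshold &
    !(best_class %in% atlas$lowq_classes)
  out <- data.frame(cell_id = colnames(x), best_class = best_class,
                    certainty = certainty, classified = classified,
                    n_boot = params$n_boot,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ClassificationResult", "data.frame")
  attr(out, "mean_correlations") <- corr_sum / params$n_boot
  attr(out, "n_ties") <- n_ties
  out
}

#' Per-pool composition of classified cells
#'
#' @param results a [classify_cells()] table.
#' @param annotations data.frame with columns `cell_id`, `pool` covering
#'   every cell in `results`.
#' @return A list with `composition` (data.frame `pool`, `class`, `n`,
#'   `prop`; proportions among classified cells of the pool) and
#'   `totals` (data.frame `pool`, `n_classified`, `n_unclassified`).
#' @export
composition_table <- function(results, annotations) {
  stopifnot(is.data.frame(results), is.data.frame(annotations))
  idx <- match(results$cell_id, annotations$cell_id)
  if (anyNA(idx))
    stop("annotation missing for cell: ",
         paste(utils::head(results$cell_id[is.na(idx)]), collapse = ", "))
  pool <- annotations$pool[idx]
  pools <- sort(unique(pool))
  classes <- sort(unique(results$best_class[results$classified]))
  comp <- do.call(rbind, lapply(pools, function(p) {
    cl <- results$best_class[results$classified & pool == p]
    n <- vapply(classes, function(k) sum(cl == k), integer(1))
    data.frame(pool = p, class = classes, n = n,
               prop = if (length(cl)) n / length(cl) else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  totals <- data.frame(
    pool = pools,
    n_classified = vapply(pools, function(p)
      sum(results$classified & pool == p), integer(1)),
    n_unclassified = vapply(pools, function(p)
      sum(!results$classified & pool == p), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(composition = comp, totals = totals)
}

#' Chi-square test of a class composition
#'
#' Either a goodness-of-fit test of observed per-class counts against
#' reference proportions, or a Pearson contingency test (without
#' continuity correction) of two count vectors.
#'
#' @param observed per-class counts.
#' @param reference per-class reference proportions (`mode = "gof"`) or
#'   counts (`mode = "contingency"`).
#' @param mode test construction.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
chi_square_composition <- function(observed, reference,
                                   mode = c("gof", "contingency")) {
  mode <- match.arg(mode)
  if (sum(observed) == 0) stop("total observed count is zero")
  if (length(observed) < 2) stop("need at least 2 categories")
  if (mode == "gof") {
    if (any(reference <= 0))
      stop("reference proportions must be positive")
    ht <- suppressWarnings(
      stats::chisq.test(observed, p = reference / sum(reference)))
  } else {
    ht <- suppressWarnings(
      stats::chisq.test(rbind(observed, reference), correct = FALSE))
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Serialize a ReferenceAtlas to a directory
#'
#' Writes `atlas.json` (class names, markers, low-quality flags) and
#' `profiles.csv` (gene x class median log2-CPM).
#'
#' @param atlas a `ReferenceAtlas`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "ReferenceAtlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(class_names = atlas$class_names, markers = atlas$markers,
         lowq_classes = atlas$lowq_classes),
    file.path(dir, "atlas.json"))
  utils::write.csv(data.frame(gene_id = rownames(atlas$profiles),
                              atlas$profiles, check.names = FALSE),
                   file.path(dir, "profiles.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a ReferenceAtlas written by [write_atlas()]
#'
#' @param dir directory with `atlas.json` and `profiles.csv`.
#' @return A `ReferenceAtlas`.
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  prof <- utils::read.csv(file.path(dir, "profiles.csv"),
                          check.names = FALSE)
  m <- as.matrix(prof[, -1, drop = FALSE])
  rownames(m) <- prof$gene_id
  structure(list(class_names = meta$class_names, profiles = m,
                 markers = as.character(meta$markers),
                 lowq_classes = as.character(meta$lowq_classes)),
            class = "ReferenceAtlas")
}
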