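# Per-cell QC, MAD outlier filtering and log2-CPM normalization.

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the library size (total counts over all
#' genes), the number of detected genes (count > 0), and the proportions
#' of counts assigned to mitochondrial genes and ERCC spike-ins. Cells
#' with zero total counts get proportions of 0 and a warning.
#'
#' @param m a [count_matrix()].
#' @return A data.frame (class `QCMetrics`) with columns `cell_id`,
#'   `library_size`, `n_genes`, `mito_prop`, `ercc_prop`.
#' @export
compute_qc_metrics <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  if (ncol(m$counts) == 0) stop("count matrix has no cells")
  lib <- colSums(m$counts)
  ngene <- colSums(m$counts > 0)
  mito <- colSums(m$counts[m$gene_flags == "mito", , drop = FALSE])
  ercc <- colSums(m$counts[m$gene_flags == "ercc", , drop = FALSE])
  zero <- lib == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero total counts; ",
            "proportions set to 0")
  denom <- ifelse(zero, 1, lib)
  out <- data.frame(cell_id = m$cell_ids, library_size = lib,
                    n_genes = ngene, mito_prop = mito / denom,
                    ercc_prop = ercc / denom,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("QCMetrics", "data.frame")
  out
}

#' Flag outliers beyond a multiple of the MAD from the median
#'
#' The MAD is scaled by 1.4826 (the normal consistency constant, as in
#' [stats::mad()]). With `log_scale = TRUE` the median and MAD are taken
#' on `log10(x + pseudocount)`. If the MAD is zero (all values identical)
#' no point can be judged an outlier: an all-`FALSE` mask is returned
#' with a warning.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param n_mads positive multiplier.
#' @param side `"lower"` flags values below `median - n_mads * MAD`,
#'   `"upper"` above `median + n_mads * MAD`.
#' @param log_scale compute on log10 scale.
#' @param pseudocount added before the log transform.
#' @return Logical mask, `TRUE` for outliers.
#' @export
mad_outlier <- function(values, n_mads, side = c("lower", "upper"),
                        log_scale = FALSE, pseudocount = 1) {
  side <- match.arg(side)
  if (sum(is.finite(values)) < 2)
    stop("need at least 2 finite values")
  if (n_mads <= 0) stop("n_mads must be positive")
  x <- values
  if (log_scale) {
    if (any(x + pseudocount <= 0))
      stop("log scale requires values + pseudocount > 0")
    x <- log10(x + pseudocount)
  }
  med <- stats::median(x)
  m <- stats::mad(x)  # 1.4826-scaled
  if (m == 0) {
    warning("MAD is zero; no outliers can be flagged")
    return(rep(FALSE, length(x)))
  }
  if (side == "lower") x < med - n_mads * m else x > med + n_mads * m
}

#' Filter low-quality cells by MAD cutoffs
#'
#' Applies the four standard robust filters jointly across the plate:
#' library size and detected genes more than `k_library` / `k_genes` MADs
#' below the log10-transformed median, mitochondrial proportion more than
#' `k_mito` MADs above the median, and ERCC proportion more than `k_ercc`
#' MADs above the median. A cell passes only if it passes all four.
#'
#' @param metrics a `QCMetrics` table from [compute_qc_metrics()].
#' @param k_library,k_genes,k_mito,k_ercc MAD multipliers.
#' @param verbose report the removal fraction via `message()`.
#' @return The metrics data.frame augmented with logical columns
#'   `pass_library`, `pass_genes`, `pass_mito`, `pass_ercc`, `pass_all`.
#' @export
filter_cells <- function(metrics, k_library = 3, k_genes = 3,
                         k_mito = 5, k_ercc = 4, verbose = TRUE) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) < 3)
    stop("fewer than 3 cells: MAD thresholds are meaningless")
  metrics$pass_library <- !mad_outlier(metrics$library_size, k_library,
                                       "lower", log_scale = TRUE)
  metrics$pass_genes <- !mad_outlier(metrics$n_genes, k_genes,
                                     "lower", log_scale = TRUE)
  metrics$pass_mito <- !mad_outlier(metrics$mito_prop, k_mito, "upper")
  metrics$pass_ercc <- !mad_outlier(metrics$ercc_prop, k_ercc, "upper")
  metrics$pass_all <- metrics$pass_library & metrics$pass_genes &
    metrics$pass_mito & metrics$pass_ercc
  if (verbose)
    message(sprintf("filter_cells: removing %d / %d cells (%.1f%%)",
                    sum(!metrics$pass_all), nrow(metrics),
                    100 * mean(!metrics$pass_all)))
  metrics
}

#' log2 counts-per-million normalization
#'
#' Per cell, CPM is computed as `counts * 1e6 / (endogenous total)`,
#' where the denominator sums endogenous-flagged genes only (ERCC
#' spike-ins, the reporter, and mitochondrial genes are excluded from
#' the denominator). ERCC and reporter rows are dropped from the output;
#' endogenous and mitochondrial rows are retained. Values are
#' `log2(CPM + 1)`. Cells without any endogenous count are dropped with
#' a warning.
#'
#' @param m a [count_matrix()].
#' @return A numeric matrix (genes x cells) of `log2(CPM + 1)` values
#'   with gene ids as rownames and cell ids as colnames.
#' @export
log2_cpm <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  endo <- m$gene_flags == "endogenous"
  if (!any(endo)) stop("no endogenous genes in matrix")
  denom <- colSums(m$counts[endo, , drop = FALSE])
  keep_cells <- denom > 0
  if (!all(keep_cells))
    warning(sum(!keep_cells),
            " cell(s) with zero endogenous counts dropped")
  keep_genes <- m$gene_flags %in% c("endogenous", "mito")
  cpm <- sweep(m$counts[keep_genes, keep_cells, drop = FALSE], 2,
               1e6 / denom[keep_cells], "*")
  log2(cpm + 1)
}
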