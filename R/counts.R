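#' Gene-by-cell count matrix with gene category flags
#'
#' Container for raw single-cell RNA-seq counts. Genes are rows, cells are
#' columns. Every gene carries exactly one category flag: `"endogenous"`
#' (genomic, non-mitochondrial), `"mito"` (mitochondrial), `"ercc"`
#' (spike-in) or `"reporter"` (electroporated fluorophore sequence). The
#' flags drive QC proportions ([compute_qc_metrics()]) and the
#' normalization denominator ([log2_cpm()]).
#'
#' @param counts integer matrix (genes x cells) of non-negative counts.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param gene_flags character vector, one of `"endogenous"`, `"mito"`,
#'   `"ercc"`, `"reporter"` per gene.
#' @param cell_ids character vector of unique cell identifiers (columns).
#'
#' @return An object of class `CountMatrix`: a list with elements
#'   `counts`, `gene_ids`, `gene_flags`, `cell_ids`.
#' @export
count_matrix <- function(counts, gene_ids, gene_flags, cell_ids) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length must equal nrow(counts)")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length must equal ncol(counts)")
  if (length(gene_flags) != nrow(counts))
    stop("gene_flags length must equal nrow(counts)")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  bad <- setdiff(unique(gene_flags), c("endogenous", "mito", "ercc", "reporter"))
  if (length(bad))
    stop("unknown gene_flags: ", paste(bad, collapse = ", "))
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         gene_flags = as.character(gene_flags),
         cell_ids = as.character(cell_ids)),
    class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$gene_flags))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by gene and/or cell index
#'
#' @param x a `CountMatrix`.
#' @param genes,cells index vectors (logical, integer or character);
#'   missing means keep all.
#' @return A `CountMatrix`.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(gi)) gi <- match(gi, x$gene_ids)
  if (is.character(ci)) ci <- match(ci, x$cell_ids)
  count_matrix(x$counts[gi, ci, drop = FALSE],
               x$gene_ids[gi], x$gene_flags[gi], x$cell_ids[ci])
}

#' Write a CountMatrix as Matrix Market plus annotation TSVs
#'
#' Writes `matrix.mtx` (sparse, genes x cells), `genes.tsv`
#' (gene_id, flag; no header) and `barcodes.tsv` (cell ids) into `dir`.
#'
#' @param x a `CountMatrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(x$gene_ids, x$gene_flags),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a CountMatrix written by [write_count_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return A `CountMatrix`.
#' @export
read_count_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  g <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                         colClasses = "character")
  b <- readLines(file.path(dir, "barcodes.tsv"))
  count_matrix(m, g[[1]], g[[2]], b)
}

#' Write a CountMatrix as one dense CSV
#'
#' First column `gene_id`, second `flag`, then one column per cell.
#'
#' @param x a `CountMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  df <- data.frame(gene_id = x$gene_ids, flag = x$gene_flags,
                   x$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CountMatrix from the dense CSV layout of [write_counts_csv()]
#'
#' @param path CSV file.
#' @return A `CountMatrix`.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  count_matrix(as.matrix(df[, -(1:2), drop = FALSE]),
               df$gene_id, df$flag, colnames(df)[-(1:2)])
}
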