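#' @importFrom methods as is
#' @importFrom stats pchisq pf phyper pnorm prcomp pt rlnorm rnbinom rnorm rpois
#'   cor lm coef var cmdscale dist sd setNames aggregate
#' @importFrom utils combn head read.csv read.delim write.csv write.table
NULL

# Canonical subpopulation order used throughout: most to least abundant in
# healthy liver immune tissue.
SUBPOPS <- c("NKT", "Myeloid", "Plasma", "B")
SUBPOP_LEVELS <- c(SUBPOPS, "Unassigned")

#' UMI count matrix container
#'
#' A genes x cells matrix of non-negative integer UMI counts with gene
#' symbols as rownames, cell barcodes as colnames and a dataset identifier.
#' Counts are stored sparse (`dgCMatrix`).
#'
#' @param counts genes x cells matrix or sparse Matrix of non-negative
#'   integers with unique rownames (gene symbols) and colnames (barcodes).
#' @param dataset_id single string naming the dataset of origin.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, dataset_id) {
  if (!is(counts, "CsparseMatrix")) {
    counts <- as(as(as(Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
                    "generalMatrix"), "CsparseMatrix")
  }
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene symbols (rownames) and barcodes (colnames)")
  if (any(counts@x < 0))
    stop("negative entries are not valid UMI counts")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicate gene symbols: ", paste(dup_g, collapse = ", "))
  dup_b <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_b))
    stop("duplicate barcodes: ", paste(head(dup_b, 5L), collapse = ", "))
  structure(list(counts = counts, dataset_id = dataset_id),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> dataset '%s': %d genes x %d cells, %d nonzero\n",
              x$dataset_id, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

genes.count_matrix <- function(x) rownames(x$counts)
barcodes.count_matrix <- function(x) colnames(x$counts)

#' Per-cell metadata table
#'
#' One row per retained cell: barcode, dataset id, optional tissue tag,
#' optional cluster id, optional subpopulation label.
#'
#' @param barcode,dataset_id character vectors (recycled dataset_id allowed).
#' @param tissue_tag,cluster_id,subpop optional per-cell annotations.
#' @return A `data.frame` with class `cell_table` prepended.
#' @export
cell_table <- function(barcode, dataset_id, tissue_tag = NA_character_,
                       cluster_id = NA_integer_, subpop = NA_character_) {
  df <- data.frame(barcode = as.character(barcode),
                   dataset_id = as.character(dataset_id),
                   tissue_tag = as.character(tissue_tag),
                   cluster_id = as.integer(cluster_id),
                   subpop = as.character(subpop),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$dataset_id, df$barcode)))
    stop("duplicate (dataset, barcode) rows in cell table")
  bad <- !is.na(df$subpop) & !df$subpop %in% SUBPOP_LEVELS
  if (any(bad))
    stop("unknown subpopulation labels: ",
         paste(unique(df$subpop[bad]), collapse = ", "))
  class(df) <- c("cell_table", "data.frame")
  df
}

# subset a cell_table to the cells of one count_matrix, in matrix order
.align_cells <- function(table, cm) {
  idx <- match(colnames(cm$counts), table$barcode)
  if (anyNA(idx))
    stop("cell table is missing barcodes present in the count matrix")
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-normalized expression container
#'
#' Natural-log normalized expression: entry for raw count `x` in a cell with
#' library size `L` is `log(1 + scale_factor * x / L)`; zeros stay zero so
#' sparsity is preserved.
#'
#' @param values sparse genes x cells matrix of normalized values.
#' @param scale_factor the scale factor used (default convention 10,000).
#' @param dataset_id dataset identifier string.
#' @param library_sizes named per-cell library sizes (total UMIs).
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, scale_factor, dataset_id,
                              library_sizes = NULL) {
  structure(list(values = values, scale_factor = scale_factor,
                 dataset_id = dataset_id, library_sizes = library_sizes),
            class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> dataset '%s': %d genes x %d cells (ln(1 + %g x/L))\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

.as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else m
}
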