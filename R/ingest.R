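#' Read a UMI count matrix
#'
#' Supports the Matrix Market triplet layout (`matrix.mtx` + `barcodes.tsv` +
#' `features.tsv` in one directory, genes x cells) and a dense CSV encoding
#' (gene symbols as rownames, barcodes as header). Integer counts are
#' preserved exactly.
#'
#' @param path directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @param dataset_id dataset identifier; defaults to the directory/file name.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "csv"), dataset_id = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    files <- file.path(path, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("incomplete MTX triplet, missing: ", paste(missing, collapse = ", "))
    m <- as(Matrix::readMM(files[1L]), "CsparseMatrix")
    barcodes <- readLines(files[2L])
    features <- readLines(files[3L])
    if (length(features) != nrow(m))
      stop(sprintf("features.tsv has %d entries but matrix has %d rows",
                   length(features), nrow(m)))
    if (length(barcodes) != ncol(m))
      stop(sprintf("barcodes.tsv has %d entries but matrix has %d columns",
                   length(barcodes), ncol(m)))
    # allow 10x-style multi-column features files; symbol is the first field
    features <- vapply(strsplit(features, "\t"), `[[`, character(1), 1L)
    dimnames(m) <- list(features, barcodes)
    if (is.null(dataset_id)) dataset_id <- basename(normalizePath(path))
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (is.null(dataset_id))
      dataset_id <- sub("\\.csv$", "", basename(path))
  }
  count_matrix(m, dataset_id)
}

#' Write a count matrix (dense CSV encoding)
#'
#' @param cm a [count_matrix()].
#' @param path output CSV file.
#' @export
write_counts_csv <- function(cm, path) {
  write.csv(as.matrix(cm$counts), path, quote = FALSE)
  invisible(path)
}

#' Filter cells by tissue tag or barcode pattern
#'
#' The barcode-level extraction applied when a deposited dataset mixes
#' compartments (e.g. retaining only liver-origin cells when spleen and
#' peripheral blood barcodes are present).
#'
#' @param cm a [count_matrix()].
#' @param table matching [cell_table()].
#' @param keep_tags tissue tags to retain, and/or
#' @param pattern regular expression matched against barcodes.
#' @return list with filtered `cm` and `table`; the gene axis and counts are
#'   untouched.
#' @export
filter_cells_by_tag <- function(cm, table, keep_tags = NULL, pattern = NULL) {
  if (is.null(keep_tags) && is.null(pattern))
    stop("provide keep_tags and/or pattern")
  tab <- .align_cells(table, cm)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(keep_tags)) keep <- keep & tab$tissue_tag %in% keep_tags
  if (!is.null(pattern)) keep <- keep & grepl(pattern, tab$barcode)
  if (!any(keep)) stop("filter matches zero cells")
  list(cm = count_matrix(cm$counts[, keep, drop = FALSE], cm$dataset_id),
       table = tab[keep, , drop = FALSE])
}

#' Filter cells positive for a gene
#'
#' CD45+ selection: keep cells whose UMI count for `gene` (e.g. PTPRC) is at
#' least `min_count`.
#'
#' @param cm a [count_matrix()].
#' @param table matching [cell_table()].
#' @param gene gene symbol; must be present.
#' @param min_count minimum UMI count (default 1).
#' @return list with filtered `cm` and `table`.
#' @export
filter_cells_by_gene_positive <- function(cm, table, gene, min_count = 1L) {
  if (!gene %in% rownames(cm$counts))
    stop("gene not present: ", gene)
  tab <- .align_cells(table, cm)
  keep <- as.vector(cm$counts[gene, ] >= min_count)
  if (!any(keep))
    stop(sprintf("no cell has %s count >= %d", gene, min_count))
  list(cm = count_matrix(cm$counts[, keep, drop = FALSE], cm$dataset_id),
       table = tab[keep, , drop = FALSE])
}

#' Align gene universes across datasets
#'
#' Intersection (default) keeps the shared genes only, matching the
#' convention that cross-dataset comparisons are computed on shared genes;
#' union zero-fills missing genes and flags them per dataset in the
#' `"zero_filled"` attribute (a list of symbol vectors).
#'
#' @param cms list of >= 2 [count_matrix()] objects.
#' @param mode `"intersection"` or `"union"`.
#' @return list of `count_matrix` objects on an identical, sorted gene axis.
#' @export
harmonize_genes <- function(cms, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (length(cms) < 2L) stop("need at least two datasets")
  sets <- lapply(cms, function(cm) rownames(cm$counts))
  genes <- if (mode == "intersection") Reduce(intersect, sets)
           else Reduce(union, sets)
  if (!length(genes)) stop("empty gene intersection")
  genes <- sort(genes)
  out <- lapply(cms, function(cm) {
    present <- intersect(genes, rownames(cm$counts))
    m <- cm$counts[present, , drop = FALSE]
    if (length(present) < length(genes)) {
      fill <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0),
                                   dims = c(length(genes) - length(present),
                                            ncol(m)),
                                   dimnames = list(setdiff(genes, present),
                                                   colnames(m)))
      m <- rbind(m, fill)
    }
    res <- count_matrix(m[genes, , drop = FALSE], cm$dataset_id)
    attr(res, "zero_filled") <- setdiff(genes, present)
    res
  })
  names(out) <- vapply(cms, function(cm) cm$dataset_id, character(1))
  out
}
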