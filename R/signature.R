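#' Build an integrated meta-atlas
#'
#' Concatenates annotated, gene-harmonized datasets into one
#' [normalized_matrix()] plus combined cell table; dataset provenance is
#' retained per cell so every atlas cell maps back to (dataset, barcode).
#' Expression values are never altered by integration (corrections live in
#' PC space), so the atlas carries the original normalized values.
#'
#' @param nm_list list of [normalized_matrix()] objects on an identical gene
#'   axis.
#' @param tables list of matching annotated [cell_table()]s (subpop set).
#' @return list with `nm` (combined matrix, dataset_id `"atlas"`) and
#'   `cells` (combined annotated table).
#' @export
build_meta_atlas <- function(nm_list, tables) {
  genes <- rownames(nm_list[[1L]]$values)
  for (nm in nm_list[-1L])
    if (!identical(rownames(nm$values), genes))
      stop("gene axes differ; harmonize first")
  tabs <- mapply(function(nm, tab) .align_cells(tab, list(counts = nm$values)),
                 nm_list, tables, SIMPLIFY = FALSE)
  for (tab in tabs)
    if (all(is.na(tab$subpop)))
      stop("annotation missing: subpop not set for dataset ",
           tab$dataset_id[1L])
  cells <- do.call(rbind, tabs)
  rownames(cells) <- NULL
  class(cells) <- c("cell_table", "data.frame")
  values <- do.call(cbind, lapply(nm_list, function(nm) nm$values))
  list(nm = normalized_matrix(values, nm_list[[1L]]$scale_factor, "atlas"),
       cells = cells)
}

#' DE of an atlas subpopulation against a reference compartment
#'
#' Group 1 is the subpopulation in the atlas (cells pooled across datasets),
#' group 2 the same subpopulation in the reference compartment (e.g. PBMC).
#' Positive `logfc` means higher in the atlas.
#'
#' @param atlas output of [build_meta_atlas()].
#' @param ref_nm reference [normalized_matrix()] on the same gene axis.
#' @param ref_table annotated reference [cell_table()].
#' @param subpop subpopulation compared.
#' @param min_cells minimum cells per group.
#' @return a DE table.
#' @export
de_vs_reference <- function(atlas, ref_nm, ref_table, subpop,
                            min_cells = 3L) {
  de_between_datasets(atlas$nm, ref_nm, atlas$cells, ref_table, subpop,
                      min_cells = min_cells)
}

#' Extract per-subpopulation meta-signatures
#'
#' Runs [de_vs_reference()] for each subpopulation present in both
#' compartments and keeps the flagged genes with their direction
#' (`sign(logfc)`).
#'
#' @param atlas output of [build_meta_atlas()].
#' @param ref_nm,ref_table reference compartment.
#' @param subpops subpopulations to process (default: the four canonical
#'   ones present in both compartments).
#' @return object of class `signature_set`: named list per subpopulation of
#'   data.frames (gene, logfc, ratio, p_adj, direction).
#' @export
extract_signatures <- function(atlas, ref_nm, ref_table,
                               subpops = NULL) {
  if (is.null(subpops)) {
    subpops <- intersect(SUBPOPS,
                         intersect(unique(atlas$cells$subpop),
                                   unique(ref_table$subpop)))
  }
  sigs <- lapply(subpops, function(s) {
    de <- de_vs_reference(atlas, ref_nm, ref_table, s)
    de <- de[de$de_flag, c("gene", "logfc", "ratio", "p", "p_adj"),
             drop = FALSE]
    de$direction <- ifelse(de$logfc > 0, "up", "down")
    rownames(de) <- NULL
    de
  })
  names(sigs) <- subpops
  structure(sigs, class = "signature_set")
}

#' @exportS3Method base::print
print.signature_set <- function(x, ...) {
  cat("<signature_set>\n")
  for (s in names(x))
    cat(sprintf("  %-8s %4d genes (%d up / %d down)\n", s, nrow(x[[s]]),
                sum(x[[s]]$direction == "up"),
                sum(x[[s]]$direction == "down")))
  invisible(x)
}

#' Read a gene -> function map
#'
#' TSV with two columns (gene, function), one pair per line, header
#' optional. Genes may map to multiple functions via repeated rows.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene`, `func`.
#' @export
read_function_map <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene", "func"))
  if (nrow(df) && identical(tolower(df$gene[1L]), "gene"))
    df <- df[-1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Link flagged DE genes to cell functions (chord-plot edges)
#'
#' Emits one edge per (function, gene) pair for flagged genes with mapped
#' functions; excluded function labels (e.g. redundant or disease-state
#' categories) are dropped, and flagged genes with no mapping are reported
#' in the `"unmapped"` attribute.
#'
#' @param de a classified DE table (or one signature of a
#'   [extract_signatures()] set, which is already flagged-only).
#' @param fmap function map data.frame (`gene`, `func`).
#' @param exclude function labels to drop.
#' @return data.frame of edges (func, gene, direction, logfc) with an
#'   `unmapped` attribute listing flagged genes without functions.
#' @export
link_functions <- function(de, fmap, exclude = character(0)) {
  flagged <- if ("de_flag" %in% names(de)) de[de$de_flag, , drop = FALSE]
             else de
  fmap <- fmap[!fmap$func %in% exclude, , drop = FALSE]
  hit <- fmap[fmap$gene %in% flagged$gene, , drop = FALSE]
  idx <- match(hit$gene, flagged$gene)
  edges <- data.frame(func = hit$func, gene = hit$gene,
                      direction = ifelse(flagged$logfc[idx] > 0, "up",
                                         "down"),
                      logfc = flagged$logfc[idx], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  attr(edges, "unmapped") <- setdiff(flagged$gene, fmap$gene)
  edges
}
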