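#' Default immune marker panel
#'
#' T lymphocytes are identified by CD3D; NK cells by KLRF1 and FCGR3A; the
#' myeloid lineage by CD14 and FCGR3A; B cells by CD19; plasma cells by SDC1
#' (CD138). FCGR3A appears in two panels on purpose; disambiguation relies on
#' the co-markers, which panel-mean scoring handles. NK and T are merged to
#' NKT after assignment.
#'
#' @return named list mapping panel name to marker symbols.
#' @export
default_marker_panel <- function() {
  list(T = "CD3D",
       NK = c("KLRF1", "FCGR3A"),
       Myeloid = c("CD14", "FCGR3A"),
       B = "CD19",
       Plasma = "SDC1")
}

# panel name -> final subpopulation
.panel_to_subpop <- c(T = "NKT", NK = "NKT", Myeloid = "Myeloid",
                      B = "B", Plasma = "Plasma")

#' Read a marker panel from YAML or JSON
#'
#' Format: a mapping `panel_name: [symbols]`.
#'
#' @param path file path (.yaml/.yml needs the yaml package, else JSON).
#' @return named list of symbol vectors.
#' @export
read_marker_panel <- function(path) {
  panel <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML panels")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lapply(panel, as.character)
}

#' Score clusters against a marker panel
#'
#' For each cluster and each panel entry, the score is the mean over the
#' cluster's cells of the mean scaled (z-scored) expression of the panel's
#' markers.
#'
#' @param nm a [normalized_matrix()] (single dataset or atlas).
#' @param labels per-cell cluster labels.
#' @param panel marker panel, default [default_marker_panel()].
#' @return clusters x panel-entries score matrix.
#' @export
score_clusters <- function(nm, labels, panel = default_marker_panel()) {
  markers <- unique(unlist(panel))
  missing <- setdiff(markers, rownames(nm$values))
  if (length(missing))
    stop("markers absent from gene universe: ",
         paste(missing, collapse = ", "))
  z <- scale_genes(nm, genes = markers)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  scores <- matrix(NA_real_, length(lv), length(panel),
                   dimnames = list(lv, names(panel)))
  for (cl in lv) {
    cells <- labels == cl
    for (p in names(panel)) {
      scores[cl, p] <- mean(z[panel[[p]], cells, drop = FALSE])
    }
  }
  scores
}

#' Assign clusters to subpopulations
#'
#' Each cluster takes the argmax panel entry if its margin over the runner-up
#' is at least `min_margin` (inclusive); exact ties and sub-margin calls
#' become `Unassigned`. NK and T assignments are merged into NKT. A manual
#' override map (cluster label -> subpopulation) takes precedence.
#'
#' @param scores cluster x panel score matrix from [score_clusters()].
#' @param labels per-cell cluster labels.
#' @param table a [cell_table()] for the same cells (in label order).
#' @param min_margin required scaled-expression margin (default 0.25).
#' @param overrides optional named vector/list, cluster label -> subpop.
#' @return the `cell_table` with `cluster_id` and `subpop` filled in.
#' @export
assign_subpopulations <- function(scores, labels, table, min_margin = 0.25,
                                  overrides = NULL) {
  labels <- as.character(labels)
  if (nrow(table) != length(labels))
    stop("cell table and label vector differ in length")
  # collapse panel entries to subpopulation level first (T and NK both map
  # to NKT), taking the best panel score per subpopulation; the margin rule
  # then compares competing subpopulations, not competing co-markers
  subs <- unique(.panel_to_subpop[colnames(scores)])
  sub_scores <- vapply(subs, function(s) {
    cols <- colnames(scores)[.panel_to_subpop[colnames(scores)] == s]
    apply(scores[, cols, drop = FALSE], 1L, max)
  }, numeric(nrow(scores)))
  if (nrow(scores) == 1L)
    sub_scores <- matrix(sub_scores, 1L, dimnames = list(rownames(scores),
                                                          subs))
  cl_sub <- apply(sub_scores, 1L, function(s) {
    o <- order(s, decreasing = TRUE)
    if (s[o[1L]] == s[o[2L]]) return("Unassigned")          # exact tie
    if (s[o[1L]] - s[o[2L]] < min_margin) return("Unassigned")
    colnames(sub_scores)[o[1L]]
  })
  names(cl_sub) <- rownames(scores)
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    bad <- setdiff(ov, SUBPOP_LEVELS)
    if (length(bad)) stop("override to unknown subpop: ",
                          paste(bad, collapse = ", "))
    cl_sub[names(ov)] <- ov
  }
  out <- table
  out$cluster_id <- match(labels, rownames(scores)) - 1L
  out$subpop <- unname(cl_sub[labels])
  out
}

#' Subpopulation proportion table
#'
#' Per-dataset counts and percentages of each subpopulation; `Unassigned`
#' cells are tallied separately and excluded from the percentages.
#'
#' @param table a [cell_table()] with `subpop` set.
#' @return object of class `proportion_table`: list with `counts` (dataset x
#'   subpop matrix), `percent`, and `unassigned` (per-dataset count).
#' @export
proportions_table <- function(table) {
  if (all(is.na(table$subpop))) stop("subpop not set; annotate first")
  assigned <- table[!is.na(table$subpop) & table$subpop != "Unassigned", ]
  ds <- sort(unique(table$dataset_id))
  counts <- matrix(0L, length(ds), length(SUBPOPS),
                   dimnames = list(ds, SUBPOPS))
  tab <- base::table(assigned$dataset_id, factor(assigned$subpop, SUBPOPS))
  counts[rownames(tab), ] <- tab
  pct <- 100 * counts / pmax(rowSums(counts), 1L)
  un <- vapply(ds, function(d)
    sum(table$dataset_id == d & table$subpop == "Unassigned", na.rm = TRUE),
    integer(1))
  structure(list(counts = counts, percent = pct, unassigned = un),
            class = "proportion_table")
}

#' @exportS3Method base::print
print.proportion_table <- function(x, ...) {
  cat("<proportion_table> percentages:\n")
  print(round(x$percent, 2))
  if (any(x$unassigned > 0)) {
    cat("unassigned cells:\n")
    print(x$unassigned)
  }
  invisible(x)
}

#' Annotate a processed dataset end to end
#'
#' @param processed output of [process_dataset()].
#' @param table the dataset's [cell_table()].
#' @param panel marker panel.
#' @param min_margin assignment margin.
#' @return annotated `cell_table`.
#' @export
annotate_dataset <- function(processed, table, panel = default_marker_panel(),
                             min_margin = 0.25) {
  scores <- score_clusters(processed$nm, processed$labels, panel)
  assign_subpopulations(scores, processed$labels,
                        .align_cells(table, list(counts = processed$nm$values)),
                        min_margin)
}
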