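#' Chi-squared tests on subpopulation proportions
#'
#' Overall mode runs the full datasets x subpopulations contingency test;
#' pairwise mode tests, for every dataset pair and every subpopulation, the
#' 2x2 table of (subpopulation vs rest) counts. The statistic is the closed
#' form `sum((O - E)^2 / E)`; Yates continuity correction is off by default
#' (available via `correct = TRUE` for the pairwise 2x2 tables).
#'
#' @param pt a [proportions_table()] result (counts are used, never
#'   percentages).
#' @param mode `"overall"` or `"pairwise"`.
#' @param correct apply Yates continuity correction to 2x2 tables.
#' @return data.frame with columns `comparison`, `subpop`, `statistic`,
#'   `df`, `p`, `low_expected` (TRUE when any expected cell < 1, with a
#'   warning).
#' @export
proportion_chisq <- function(pt, mode = c("overall", "pairwise"),
                             correct = FALSE) {
  mode <- match.arg(mode)
  counts <- pt$counts
  if (mode == "overall") {
    res <- .chisq_table(counts, correct = FALSE)
    out <- data.frame(comparison = "overall", subpop = "all",
                      statistic = res$statistic, df = res$df, p = res$p,
                      low_expected = res$low_expected,
                      stringsAsFactors = FALSE)
  } else {
    ds <- rownames(counts)
    if (length(ds) < 2L) stop("pairwise mode needs >= 2 datasets")
    pairs <- combn(ds, 2L, simplify = FALSE)
    rows <- list()
    for (pr in pairs) {
      for (s in colnames(counts)) {
        tab <- rbind(c(counts[pr[1L], s], sum(counts[pr[1L], ]) -
                         counts[pr[1L], s]),
                     c(counts[pr[2L], s], sum(counts[pr[2L], ]) -
                         counts[pr[2L], s]))
        res <- .chisq_table(tab, correct = correct)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = paste(pr, collapse = " vs "), subpop = s,
          statistic = res$statistic, df = res$df, p = res$p,
          low_expected = res$low_expected, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
  }
  if (any(out$low_expected))
    warning("expected cell count < 1 in some comparisons; see low_expected")
  out
}

# closed-form Pearson chi-squared on a contingency table
.chisq_table <- function(tab, correct = FALSE) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       low_expected = any(e < 1))
}

#' Housekeeping-gene noise between datasets
#'
#' Within one subpopulation, tests each housekeeping gene's log-normalized
#' expression across datasets: a one-way ANOVA (equal-variance F) per gene,
#' plus pairwise Welch t-tests per dataset pair. Bonferroni correction is
#' over genes for the ANOVA and over genes x pairs for the pairwise tests.
#'
#' @param nm_list list of [normalized_matrix()] objects (shared gene axis).
#' @param tables list of matching annotated [cell_table()]s.
#' @param hk_genes housekeeping gene symbols; absent genes are skipped with a
#'   warning.
#' @param subpop subpopulation analyzed.
#' @return list with `anova` (gene, F, df1, df2, p, p_adj), `pairwise`
#'   (gene, comparison, t, df, p, p_adj), and `means` (gene x dataset mean
#'   expression).
#' @export
housekeeping_noise <- function(nm_list, tables, hk_genes, subpop) {
  present <- Reduce(intersect, lapply(nm_list, function(nm)
    rownames(nm$values)))
  skipped <- setdiff(hk_genes, present)
  if (length(skipped)) {
    warning("housekeeping genes missing, skipped: ",
            paste(skipped, collapse = ", "))
    hk_genes <- intersect(hk_genes, present)
  }
  if (!length(hk_genes)) stop("no housekeeping genes present")
  vals <- mapply(function(nm, tab) {
    tab <- .align_cells(tab, list(counts = nm$values))
    cells <- which(tab$subpop == subpop)
    if (!length(cells)) stop("subpopulation '", subpop,
                             "' absent in dataset ", nm$dataset_id)
    .as_dense(nm$values[hk_genes, cells, drop = FALSE])
  }, nm_list, tables, SIMPLIFY = FALSE)
  ids <- vapply(nm_list, function(nm) nm$dataset_id, character(1))
  names(vals) <- ids
  means <- vapply(vals, rowMeans, numeric(length(hk_genes)))
  if (length(hk_genes) == 1L)
    means <- matrix(means, 1L, dimnames = list(hk_genes, ids))
  an <- do.call(rbind, lapply(seq_along(hk_genes), function(gi) {
    groups <- lapply(vals, function(v) v[gi, ])
    res <- .anova_f(groups)
    data.frame(gene = hk_genes[gi], F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, stringsAsFactors = FALSE)
  }))
  an$p_adj <- pmin(1, an$p * nrow(an))
  pairs <- combn(ids, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(seq_along(hk_genes), function(gi) {
    do.call(rbind, lapply(pairs, function(pr) {
      res <- .welch_t(vals[[pr[1L]]][gi, ], vals[[pr[2L]]][gi, ])
      data.frame(gene = hk_genes[gi],
                 comparison = paste(pr, collapse = " vs "),
                 t = res$t, df = res$df, p = res$p, stringsAsFactors = FALSE)
    }))
  }))
  pw$p_adj <- pmin(1, pw$p * nrow(pw))
  list(anova = an, pairwise = pw, means = means)
}

# classic one-way ANOVA F on a list of numeric vectors
.anova_f <- function(groups) {
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  gm <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- sum(n) - length(groups)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else f <- (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  if (ssb == 0) p <- 1
  list(F = f, df1 = df1, df2 = df2, p = p)
}

# Welch two-sample t-test
.welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pseudobulk profile
#'
#' Per-gene arithmetic mean of log-normalized expression over a set of cells.
#'
#' @param nm a [normalized_matrix()].
#' @param cells optional barcodes (default: all cells).
#' @return named numeric vector of per-gene means.
#' @export
pseudobulk <- function(nm, cells = NULL) {
  m <- nm$values
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(m))
    if (length(missing))
      stop("unknown barcodes: ", paste(head(missing, 5L), collapse = ", "))
    m <- m[, cells, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("empty cell subset")
  setNames(as.vector(Matrix::rowMeans(m)), rownames(m))
}

#' Pairwise correlation and regression of two profiles
#'
#' Pearson and Spearman coefficients plus least-squares linear and quadratic
#' fits of `v2` on `v1` (the identity line being the idealized
#' between-dataset relationship).
#'
#' @param v1,v2 equal-length numeric vectors (length >= 3).
#' @return list of class `pairwise_correlation`: `pearson_r`, `spearman_rho`,
#'   `linear` (intercept, slope), `quadratic` (intercept, slope, quad), `n`,
#'   `defined`. Zero-variance input yields `defined = FALSE` with a reason
#'   instead of silent NaNs.
#' @export
correlate_pairwise <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors differ in length")
  if (length(v1) < 3L) stop("need at least 3 points")
  if (sd(v1) == 0 || sd(v2) == 0) {
    return(structure(list(defined = FALSE,
                          reason = "zero-variance input",
                          n = length(v1)),
                     class = "pairwise_correlation"))
  }
  lin <- lm(v2 ~ v1)
  quad <- lm(v2 ~ v1 + I(v1^2))
  structure(list(defined = TRUE,
                 pearson_r = cor(v1, v2),
                 spearman_rho = cor(v1, v2, method = "spearman"),
                 linear = setNames(coef(lin), c("intercept", "slope")),
                 quadratic = setNames(coef(quad),
                                      c("intercept", "slope", "quad")),
                 n = length(v1)),
            class = "pairwise_correlation")
}

#' @exportS3Method base::print
print.pairwise_correlation <- function(x, ...) {
  if (!x$defined) {
    cat("<pairwise_correlation> undefined:", x$reason, "\n")
  } else {
    cat(sprintf("<pairwise_correlation> n=%d R=%.4f rho=%.4f slope=%.4f intercept=%.4f\n",
                x$n, x$pearson_r, x$spearman_rho, x$linear["slope"],
                x$linear["intercept"]))
  }
  invisible(x)
}

#' Signed ranking of a DE table
#'
#' Ranking metric: `sign(logfc) * (-log10 p)`, descending, so rank 1 is the
#' most upregulated gene and the last rank the most downregulated. Zero
#' p-values are floored at the smallest positive double before the log. Ties
#' break by `|logfc|` (descending) then symbol (ascending).
#'
#' @param de a DE table from [de_subpop_vs_rest()] or relatives.
#' @return data.frame (gene, metric, rank) ordered by rank.
#' @export
rank_genes <- function(de) {
  p <- pmax(de$p, .Machine$double.xmin)
  metric <- sign(de$logfc) * (-log10(p))
  o <- order(-metric, -abs(de$logfc), de$gene)
  data.frame(gene = de$gene[o], metric = metric[o],
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Rank-rank hypergeometric overlap
#'
#' For each pair of rank cutoffs `(i, j)` on a step grid, counts the overlap
#' `k` between the top `i` genes of `list1` and top `j` of `list2` and scores
#' the one-sided enrichment `P(X >= k)` under the hypergeometric null. The
#' grid entry is `-log10 p`. The complete-list corner `(N, N)` is always
#' included and forced to 0.
#'
#' @param list1,list2 ranked gene vectors (or [rank_genes()] outputs) over
#'   the same universe.
#' @param step rank step between cutoffs; default `max(1, floor(N/50))`,
#'   giving at most a ~50 x 50 grid.
#' @return object of class `rrho_grid`: list with `grid` (matrix of
#'   `-log10 p`), `thresholds_1`, `thresholds_2`, `N`, `step`, `metric`.
#' @export
rrho <- function(list1, list2, step = NULL) {
  g1 <- if (is.data.frame(list1)) list1$gene else as.character(list1)
  g2 <- if (is.data.frame(list2)) list2$gene else as.character(list2)
  if (length(g1) != length(g2) || !setequal(g1, g2) ||
      anyDuplicated(g1) || anyDuplicated(g2))
    stop("lists must be complete rankings of the same gene universe")
  n <- length(g1)
  if (is.null(step)) step <- max(1L, n %/% 50L)
  th <- unique(c(seq(step, n, by = step), n))
  pos2 <- match(g1, g2)              # rank in list2 of list1's genes
  grid <- matrix(NA_real_, length(th), length(th),
                 dimnames = list(th, th))
  for (a in seq_along(th)) {
    r2 <- sort(pos2[seq_len(th[a])])
    k <- findInterval(th, r2)        # overlap with top-j of list2
    p <- phyper(k - 1L, th[a], n - th[a], th, lower.tail = FALSE)
    grid[a, ] <- -log10(pmax(p, .Machine$double.xmin))
  }
  grid[length(th), length(th)] <- 0  # full overlap, p = 1 exactly
  structure(list(grid = grid, thresholds_1 = th, thresholds_2 = th,
                 N = n, step = step,
                 metric = "sign(logfc) * -log10(p), rank 1 most upregulated"),
            class = "rrho_grid")
}

#' @exportS3Method base::print
print.rrho_grid <- function(x, ...) {
  cat(sprintf("<rrho_grid> N=%d step=%d grid %dx%d, max -log10 p = %.2f\n",
              x$N, x$step, nrow(x$grid), ncol(x$grid), max(x$grid)))
  invisible(x)
}

#' Top-k abundant transcript agreement
#'
#' Within a subpopulation, ranks genes by pseudobulk mean normalized
#' expression in each of two datasets and counts how many of the top `k`
#' genes coincide.
#'
#' @param nm_ref,nm_other [normalized_matrix()] objects on a shared gene
#'   axis.
#' @param table_ref,table_other matching annotated [cell_table()]s.
#' @param subpop subpopulation analyzed.
#' @param k list length (default 100).
#' @return list with `n_matched`, `genes_ref`, `genes_other`, `shared`.
#' @export
topk_agreement <- function(nm_ref, nm_other, table_ref, table_other,
                           subpop, k = 100L) {
  if (!identical(rownames(nm_ref$values), rownames(nm_other$values)))
    stop("gene axes differ; harmonize first")
  if (nrow(nm_ref$values) < k)
    stop("fewer than k genes in the universe")
  top <- function(nm, tab) {
    tab <- .align_cells(tab, list(counts = nm$values))
    cells <- tab$barcode[tab$subpop == subpop & !is.na(tab$subpop)]
    if (!length(cells)) stop("subpop '", subpop, "' absent in ",
                             nm$dataset_id)
    pb <- pseudobulk(nm, cells)
    names(sort(pb, decreasing = TRUE))[seq_len(k)]
  }
  a <- top(nm_ref, table_ref)
  b <- top(nm_other, table_other)
  list(n_matched = length(intersect(a, b)), genes_ref = a, genes_other = b,
       shared = intersect(a, b))
}
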