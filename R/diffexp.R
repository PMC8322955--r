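#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration of the rank-sum null (over all assignments of the
#' observed, possibly tied, ranks to group 1) whenever the number of
#' combinations is at most `exact_max`; otherwise the normal approximation
#' with tie correction (no continuity correction). The exact two-sided
#' p-value is the probability, under random assignment, of a rank sum at
#' least as far from its expectation as observed (reflection convention,
#' which coincides with tail doubling for the untied, symmetric null).
#'
#' @param x,y numeric samples.
#' @param exact_max maximum `choose(n, n1)` for exact enumeration
#'   (default 20000; group sizes up to 8 are always exact).
#' @return two-sided p-value.
#' @export
wilcox_p <- function(x, y, exact_max = 20000) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  if (choose(n, n1) <= exact_max) {
    sums <- combn(n, n1, FUN = function(i) sum(r[i]))
    return(mean(abs(sums - e) >= abs(w - e) - 1e-9))
  }
  ties <- base::table(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(1)
  2 * pnorm(-abs(w - e) / sqrt(v))
}

# vectorized over genes: m1, m2 dense genes x cells matrices
.wilcox_rows <- function(m1, m2, exact_max = 20000) {
  n1 <- ncol(m1); n2 <- ncol(m2); n <- n1 + n2
  exact <- choose(n, n1) <= exact_max
  combs <- if (exact) combn(n, n1) else NULL
  vapply(seq_len(nrow(m1)), function(g) {
    r <- rank(c(m1[g, ], m2[g, ]))
    w <- sum(r[seq_len(n1)])
    e <- n1 * (n + 1) / 2
    if (exact) {
      sums <- colSums(matrix(r[combs], nrow = n1))
      return(mean(abs(sums - e) >= abs(w - e) - 1e-9))
    }
    ties <- base::table(r)
    v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) return(1)
    2 * pnorm(-abs(w - e) / sqrt(v))
  }, numeric(1))
}

# shared DE core: group matrices -> DE table
.de_core <- function(m1, m2, comparison = "") {
  m1 <- .as_dense(m1); m2 <- .as_dense(m2)
  mean1 <- rowMeans(m1)
  mean2 <- rowMeans(m2)
  logfc <- mean1 - mean2
  p <- .wilcox_rows(m1, m2)
  de <- data.frame(gene = rownames(m1), mean1 = mean1, mean2 = mean2,
                   logfc = logfc, ratio = exp(logfc), p = p,
                   p_adj = pmin(1, p * nrow(m1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  de <- classify_de(de)
  attr(de, "comparison") <- comparison
  attr(de, "n1") <- ncol(m1)
  attr(de, "n2") <- ncol(m2)
  de
}

#' Dual-threshold DE classification
#'
#' A gene is flagged differentially expressed when its expression ratio
#' (exponentiated log fold change, natural log scale) is `>= ratio_high` or
#' `<= ratio_low` (inclusive boundaries) AND its Bonferroni-adjusted p-value
#' is strictly below `alpha`. Adds/refreshes `de_flag` and a volcano `class`
#' column (`"DE"` / `"non-DE"`).
#'
#' @param de a DE table with `ratio` and `p_adj` columns.
#' @param ratio_low,ratio_high dual ratio thresholds (defaults 0.8 / 1.25).
#' @param alpha adjusted-p cutoff (default 0.05, strict `<`).
#' @return the table with `de_flag` and `class` columns.
#' @export
classify_de <- function(de, ratio_low = 0.8, ratio_high = 1.25,
                        alpha = 0.05) {
  de$de_flag <- (de$ratio >= ratio_high | de$ratio <= ratio_low) &
    de$p_adj < alpha
  de$class <- ifelse(de$de_flag, "DE", "non-DE")
  de
}

#' Subpopulation-vs-rest differential expression
#'
#' Wilcoxon rank-sum test per gene on log-normalized values between one
#' subpopulation and all other cells of the same dataset. `logfc` is the
#' difference of mean log-normalized expression (subpopulation minus rest),
#' `ratio = exp(logfc)`; Bonferroni correction is over the genes tested.
#'
#' @param nm a [normalized_matrix()].
#' @param table matching annotated [cell_table()].
#' @param subpop subpopulation of interest.
#' @param min_cells minimum cells required in each group (default 3).
#' @return a DE table (data.frame).
#' @export
de_subpop_vs_rest <- function(nm, table, subpop, min_cells = 3L) {
  tab <- .align_cells(table, list(counts = nm$values))
  in_pop <- !is.na(tab$subpop) & tab$subpop == subpop
  rest <- !is.na(tab$subpop) & tab$subpop != subpop &
    tab$subpop != "Unassigned"
  if (sum(in_pop) < min_cells || sum(rest) < min_cells)
    stop(sprintf("fewer than %d cells in a group (%d vs %d)", min_cells,
                 sum(in_pop), sum(rest)))
  .de_core(nm$values[, in_pop, drop = FALSE],
           nm$values[, rest, drop = FALSE],
           comparison = sprintf("%s: %s vs rest", nm$dataset_id, subpop))
}

#' Between-dataset differential expression within a subpopulation
#'
#' Same machinery as [de_subpop_vs_rest()], with the two groups being the
#' same subpopulation in two datasets. Swapping the dataset order flips the
#' sign of every `logfc`.
#'
#' @param nm1,nm2 [normalized_matrix()] objects on a shared gene axis.
#' @param table1,table2 matching annotated [cell_table()]s.
#' @param subpop subpopulation analyzed.
#' @param min_cells minimum cells per group.
#' @return a DE table.
#' @export
de_between_datasets <- function(nm1, nm2, table1, table2, subpop,
                                min_cells = 3L) {
  if (!identical(rownames(nm1$values), rownames(nm2$values)))
    stop("gene axes differ; harmonize first")
  pick <- function(nm, tab) {
    tab <- .align_cells(tab, list(counts = nm$values))
    sel <- !is.na(tab$subpop) & tab$subpop == subpop
    if (sum(sel) < min_cells)
      stop("subpopulation '", subpop, "' has fewer than ", min_cells,
           " cells in ", nm$dataset_id)
    nm$values[, sel, drop = FALSE]
  }
  .de_core(pick(nm1, table1), pick(nm2, table2),
           comparison = sprintf("%s vs %s: %s", nm1$dataset_id,
                                nm2$dataset_id, subpop))
}

#' Difference-of-differences (DoD) statistic
#'
#' For each gene, `delta1` is the (subpopulation minus rest) difference of
#' mean log-normalized expression in dataset 1, `delta2` the same in dataset
#' 2, and `dod = delta1 - delta2`. DoD is tested with a Welch four-group
#' contrast: `t = dod / sqrt(sum_i s_i^2 / n_i)` over the four groups, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p, Bonferroni
#' corrected over genes. A gene's `dod_flag` requires both the
#' between-dataset DE flag (same subpopulation across the two datasets, dual
#' thresholds) and DoD `p_adj < alpha`: it marks between-dataset DE that is
#' subpopulation-specific rather than a uniform dataset shift.
#'
#' @param nm1,nm2 [normalized_matrix()] objects on a shared gene axis.
#' @param table1,table2 matching annotated [cell_table()]s.
#' @param subpop subpopulation of interest.
#' @param alpha significance level for the DoD flag (default 0.05).
#' @param de_between optional precomputed [de_between_datasets()] table for
#'   the same comparison (computed if missing).
#' @return a DoD table: gene, delta1, delta2, dod, t, df, p, p_adj, de_flag
#'   (between-dataset), dod_flag.
#' @export
dod <- function(nm1, nm2, table1, table2, subpop, alpha = 0.05,
                de_between = NULL) {
  if (!identical(rownames(nm1$values), rownames(nm2$values)))
    stop("gene axes differ; harmonize first")
  grab <- function(nm, tab) {
    tab <- .align_cells(tab, list(counts = nm$values))
    in_pop <- !is.na(tab$subpop) & tab$subpop == subpop
    rest <- !is.na(tab$subpop) & tab$subpop != subpop &
      tab$subpop != "Unassigned"
    if (sum(in_pop) < 2L || sum(rest) < 2L)
      stop("each group needs >= 2 cells (variance undefined) in ",
           nm$dataset_id)
    list(pop = .as_dense(nm$values[, in_pop, drop = FALSE]),
         rest = .as_dense(nm$values[, rest, drop = FALSE]))
  }
  g1 <- grab(nm1, table1)
  g2 <- grab(nm2, table2)
  stat <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    s2 <- rowSums((m - mu)^2) / (n - 1L)
    list(mu = mu, se2 = s2 / n, df_term = (s2 / n)^2 / (n - 1L))
  }
  s11 <- stat(g1$pop); s12 <- stat(g1$rest)
  s21 <- stat(g2$pop); s22 <- stat(g2$rest)
  delta1 <- s11$mu - s12$mu
  delta2 <- s21$mu - s22$mu
  dodv <- delta1 - delta2
  se2 <- s11$se2 + s12$se2 + s21$se2 + s22$se2
  df <- se2^2 / (s11$df_term + s12$df_term + s21$df_term + s22$df_term)
  t <- ifelse(se2 > 0, dodv / sqrt(se2), 0)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), 1)
  if (is.null(de_between))
    de_between <- de_between_datasets(nm1, nm2, table1, table2, subpop)
  out <- data.frame(gene = rownames(nm1$values),
                    delta1 = delta1, delta2 = delta2, dod = dodv,
                    t = t, df = df, p = p,
                    p_adj = pmin(1, p * length(p)),
                    de_flag = de_between$de_flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$dod_flag <- out$de_flag & out$p_adj < alpha
  attr(out, "comparison") <- sprintf("%s vs %s: %s", nm1$dataset_id,
                                     nm2$dataset_id, subpop)
  out
}

#' Partition between-dataset DE into explained and DoD components
#'
#' @param de_between a [de_between_datasets()] table.
#' @param dod_tab the matching [dod()] table.
#' @return list with `n_de`, `n_dod`, `pct_dod_of_de` (NA and marked
#'   undefined when no DE genes exist).
#' @export
dod_explained_summary <- function(de_between, dod_tab) {
  if (!identical(de_between$gene, dod_tab$gene))
    stop("mismatched comparisons: gene universes differ")
  n_de <- sum(de_between$de_flag)
  n_dod <- sum(dod_tab$dod_flag)
  list(n_de = n_de, n_dod = n_dod,
       pct_dod_of_de = if (n_de > 0) 100 * n_dod / n_de else NA_real_,
       defined = n_de > 0)
}

#' Gene x cell z-score matrix for heatmaps
#'
#' Z-scores each listed gene over ALL cells (not per group); columns are
#' ordered by subpopulation blocks (NKT, Myeloid, Plasma, B, Unassigned) and
#' rows follow the gene list, which may be a named list grouping genes by
#' source subpopulation.
#'
#' @param nm a [normalized_matrix()] (dataset or atlas).
#' @param genes character vector or named list of gene symbols.
#' @param table matching annotated [cell_table()].
#' @return z-score matrix with `row_group` and `col_subpop` attributes.
#' @export
heatmap_matrix <- function(nm, genes, table) {
  glist <- if (is.list(genes)) genes else list(all = genes)
  flat <- unlist(glist, use.names = FALSE)
  absent <- setdiff(flat, rownames(nm$values))
  if (length(absent))
    stop("genes absent: ", paste(absent, collapse = ", "))
  tab <- .align_cells(table, list(counts = nm$values))
  ord <- order(factor(tab$subpop, levels = SUBPOP_LEVELS))
  z <- scale_genes(nm, genes = flat, clip = Inf)[, ord, drop = FALSE]
  attr(z, "row_group") <- rep(names(glist), lengths(glist))
  attr(z, "col_subpop") <- tab$subpop[ord]
  z
}

#' Merge per-dataset top DE genes into a master list
#'
#' Takes the top `n_top` flagged genes of each dataset's DE table (ordered by
#' adjusted p, ties by |logfc| descending), unions them and records which
#' datasets contributed each gene.
#'
#' @param de_tables named list of DE tables (one per dataset) for the same
#'   subpopulation comparison.
#' @param n_top genes taken per dataset (default 10).
#' @return data.frame (gene, n_datasets, datasets) ordered by support then
#'   gene.
#' @export
top_de_master_list <- function(de_tables, n_top = 10L) {
  if (!length(de_tables)) stop("need at least one DE table")
  if (is.null(names(de_tables)))
    names(de_tables) <- sprintf("dataset%d", seq_along(de_tables))
  picks <- lapply(de_tables, function(de) {
    de <- de[de$de_flag, , drop = FALSE]
    de <- de[order(de$p_adj, -abs(de$logfc), de$gene), , drop = FALSE]
    head(de$gene, n_top)
  })
  genes <- sort(unique(unlist(picks)))
  support <- lapply(genes, function(g)
    names(picks)[vapply(picks, function(p) g %in% p, logical(1))])
  out <- data.frame(gene = genes,
                    n_datasets = lengths(support),
                    datasets = vapply(support, paste, character(1),
                                      collapse = ","),
                    stringsAsFactors = FALSE)
  out[order(-out$n_datasets, out$gene), , drop = FALSE]
}

#' Volcano-plot export rows
#'
#' @param de a classified DE table.
#' @return data.frame with `gene`, `x` (logfc), `y` (-log10 adjusted p) and
#'   `class`.
#' @export
volcano_rows <- function(de) {
  data.frame(gene = de$gene, x = de$logfc,
             y = -log10(pmax(de$p_adj, .Machine$double.xmin)),
             class = de$class, stringsAsFactors = FALSE)
}
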