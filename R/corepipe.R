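#' Library-size log normalization
#'
#' Each raw count `x` in a cell with library size `L` (total UMIs) becomes
#' `log(1 + scale_factor * x / L)` (natural log). Zeros map to zeros, so the
#' sparse structure is preserved, and the transform is exactly invertible
#' given the library sizes (see [denormalize()]).
#'
#' @param cm a [count_matrix()].
#' @param scale_factor scale factor, default 10,000.
#' @return A [normalized_matrix()].
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  libs <- Matrix::colSums(cm$counts)
  if (any(libs == 0))
    stop("zero library size for barcode(s): ",
         paste(head(colnames(cm$counts)[libs == 0], 5L), collapse = ", "))
  v <- cm$counts
  j <- rep.int(seq_len(ncol(v)), diff(v@p))
  v@x <- log1p(scale_factor * v@x / libs[j])
  normalized_matrix(v, scale_factor, cm$dataset_id,
                    setNames(libs, colnames(cm$counts)))
}

#' Invert log normalization back to raw counts
#'
#' @param nm a [normalized_matrix()] carrying library sizes.
#' @return sparse genes x cells matrix of counts.
#' @export
denormalize <- function(nm) {
  if (is.null(nm$library_sizes))
    stop("normalized matrix carries no library sizes")
  v <- nm$values
  j <- rep.int(seq_len(ncol(v)), diff(v@p))
  v@x <- expm1(v@x) * nm$library_sizes[j] / nm$scale_factor
  v
}

#' Per-gene standardization
#'
#' Center each gene to mean 0 and scale to unit variance across cells, using
#' the population SD convention (divide by n). Constant genes map to all-zero
#' rows; values are clipped at `+/- clip` to bound outlier leverage.
#'
#' @param x a [normalized_matrix()], or a genes x cells matrix.
#' @param clip clipping bound in SD units (default 10).
#' @param genes optional subset of gene symbols to scale (e.g. HVGs).
#' @return dense genes x cells matrix of scaled values.
#' @export
scale_genes <- function(x, clip = 10, genes = NULL) {
  m <- if (inherits(x, "normalized_matrix")) x$values else x
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("genes absent: ", paste(missing, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  m <- .as_dense(m)
  if (ncol(m) < 2L) stop("need at least two cells to scale")
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))       # population SD (divide by n)
  out <- (m - mu) / ifelse(sdp > 0, sdp, 1)
  out[sdp == 0, ] <- 0
  pmin(pmax(out, -clip), clip)
}

#' Select highly variable genes
#'
#' Standardized-dispersion selection: genes are binned by mean normalized
#' expression (20 bins) and the dispersion (variance/mean) is z-scored within
#' each bin; the top `n` genes by standardized dispersion are returned.
#'
#' @param nm a [normalized_matrix()].
#' @param n number of genes to keep (default 2000, capped at the universe).
#' @return character vector of gene symbols.
#' @export
select_hvg <- function(nm, n = 2000L) {
  m <- nm$values
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- pmax(ex2 - mu^2, 0)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, 0.05))),
              include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    i <- which(bins == b)
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  head(rownames(m)[order(-z)], min(n, nrow(m)))
}

#' Principal component reduction
#'
#' @param scaled genes x cells scaled matrix (from [scale_genes()]).
#' @param n_components number of PCs (default 30); truncated with a warning
#'   if it exceeds `min(genes, cells) - 1`.
#' @param seed accepted for interface symmetry; the SVD is deterministic.
#'   Loading signs are fixed so the largest-magnitude loading of each PC is
#'   positive.
#' @return list with `scores` (cells x k), `loadings` (genes x k), `sdev`.
#' @export
reduce_pca <- function(scaled, n_components = 30L, seed = 1L) {
  k_max <- min(dim(scaled)) - 1L
  if (n_components > k_max) {
    warning(sprintf("n_components truncated from %d to %d", n_components,
                    k_max))
    n_components <- k_max
  }
  p <- prcomp(t(scaled), center = FALSE, scale. = FALSE,
              rank. = n_components)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  rownames(scores) <- colnames(scaled)
  list(scores = scores, loadings = loadings,
       sdev = p$sdev[seq_len(n_components)])
}

# brute-force k nearest neighbours (excluding self); rows of the returned
# matrix are neighbour indices
.knn_indices <- function(scores, k) {
  n <- nrow(scores)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(dist(scores))
  diag(d) <- Inf
  t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
}

#' Graph clustering of cells
#'
#' Builds a shared-nearest-neighbor graph (Jaccard weights over the k-nearest
#' neighbour sets including the cell itself, pruned below `prune`) and
#' partitions it with Leiden modularity community detection.
#'
#' @param scores cells x PCs matrix.
#' @param k_neighbors neighbourhood size (default 20).
#' @param resolution modularity resolution (default 0.8).
#' @param seed RNG seed for the community detection.
#' @param prune discard SNN edges with Jaccard weight below this (default
#'   1/15).
#' @return integer cluster labels `0..C-1`, one per cell.
#' @export
build_graph_and_cluster <- function(scores, k_neighbors = 20L,
                                    resolution = 0.8, seed = 1L,
                                    prune = 1 / 15) {
  n <- nrow(scores)
  nn <- .knn_indices(scores, min(k_neighbors, n - 1L))
  k <- ncol(nn)
  # adjacency including self so each cell's neighbour set has size k + 1
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                            j = c(as.vector(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)               # |Ni  intersect  Nj|
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1L) - jac@x)       # Jaccard
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
  as.integer(igraph::membership(comm)) - 1L
}

#' Deterministic 2D embedding of cells
#'
#' Classical multidimensional scaling of Euclidean distances in PC space.
#' Used for export/visualization only; any neighbourhood-preserving embedding
#' satisfies the pipeline contract, and MDS is chosen for determinism.
#'
#' @param scores cells x PCs matrix.
#' @param seed accepted for interface symmetry; MDS is deterministic.
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(scores, seed = 1L) {
  set.seed(seed)
  xy <- cmdscale(dist(scores), k = 2L)
  colnames(xy) <- c("DIM1", "DIM2")
  rownames(xy) <- rownames(scores)
  xy
}

#' Mutual-nearest-neighbor integration
#'
#' A simplified anchor-based batch correction. All datasets are jointly
#' scaled and reduced to PC space; each non-reference dataset is corrected
#' toward the first dataset using mutual nearest neighbour (MNN) anchor
#' pairs. The per-cell correction is a Gaussian-kernel weighted average of
#' anchor difference vectors, with kernel distances measured to the anchor
#' pair midpoints — a symmetry-preserving choice under which two identical
#' datasets produce exactly zero correction. Corrections live in PC space;
#' normalized expression values are never altered.
#'
#' @param nm_list list of [normalized_matrix()] objects on an identical gene
#'   axis.
#' @param k_anchor neighbours searched when pairing anchors (default 5).
#' @param n_pcs PCs of the joint reduction (default 30).
#' @param hvg_n highly variable genes for the joint reduction (default 1000).
#' @param seed RNG seed (joint PCA sign fixing is deterministic; kept for
#'   interface symmetry).
#' @return list with `anchors` (data.frame: dataset, cell_query, cell_ref,
#'   score), `corrected` (cells x PCs), `uncorrected`, `dataset` (per-cell
#'   dataset id), and `loadings`.
#' @export
integrate_datasets <- function(nm_list, k_anchor = 5L, n_pcs = 30L,
                               hvg_n = 1000L, seed = 1L) {
  if (length(nm_list) < 2L) stop("need at least two datasets to integrate")
  genes <- rownames(nm_list[[1L]]$values)
  for (nm in nm_list[-1L])
    if (!identical(rownames(nm$values), genes))
      stop("gene axes differ; run harmonize_genes() first")
  combined <- do.call(cbind, lapply(nm_list, function(nm) nm$values))
  ds <- rep(vapply(nm_list, function(nm) nm$dataset_id, character(1)),
            vapply(nm_list, function(nm) ncol(nm$values), integer(1)))
  joint <- normalized_matrix(combined, nm_list[[1L]]$scale_factor, "joint")
  hvg <- select_hvg(joint, hvg_n)
  scaled <- scale_genes(joint, genes = hvg)
  pca <- reduce_pca(scaled, n_pcs, seed = seed)
  scores <- pca$scores
  ref_id <- nm_list[[1L]]$dataset_id
  ref_idx <- which(ds == ref_id)
  corrected <- scores
  anchors <- list()
  for (d in seq_along(nm_list)[-1L]) {
    qid <- nm_list[[d]]$dataset_id
    q_idx <- which(ds == qid)
    pairs <- .mnn_pairs(scores[q_idx, , drop = FALSE],
                        scores[ref_idx, , drop = FALSE], k_anchor)
    if (!nrow(pairs))
      stop("zero anchors found between '", qid, "' and '", ref_id,
           "'; increase k_anchor")
    qa <- scores[q_idx[pairs$i], , drop = FALSE]
    ra <- scores[ref_idx[pairs$j], , drop = FALSE]
    delta <- ra - qa                       # query -> reference
    mid <- (ra + qa) / 2
    d2 <- .cross_dist2(scores[q_idx, , drop = FALSE], mid)
    sigma2 <- stats::median(apply(d2, 1L, min)) + 1e-12
    w <- exp(-d2 / (2 * sigma2))
    w <- w / pmax(rowSums(w), 1e-300)
    corrected[q_idx, ] <- scores[q_idx, , drop = FALSE] + w %*% delta
    anchors[[qid]] <- data.frame(
      dataset = qid,
      cell_query = rownames(scores)[q_idx[pairs$i]],
      cell_ref = rownames(scores)[ref_idx[pairs$j]],
      score = 1 / (1 + sqrt(rowSums((ra - qa)^2))),
      stringsAsFactors = FALSE)
  }
  list(anchors = do.call(rbind, c(anchors, list(make.row.names = FALSE))),
       corrected = corrected, uncorrected = scores, dataset = ds,
       loadings = pca$loadings)
}

# mutual nearest neighbours between two score matrices
.mnn_pairs <- function(q, r, k) {
  d2 <- .cross_dist2(q, r)
  k_q <- min(k, ncol(d2))
  k_r <- min(k, nrow(d2))
  nn_q <- t(apply(d2, 1L, function(x) order(x)[seq_len(k_q)]))
  nn_r <- t(apply(d2, 2L, function(x) order(x)[seq_len(k_r)]))
  i <- rep(seq_len(nrow(d2)), k_q)
  j <- as.vector(nn_q)
  mutual <- vapply(seq_along(i), function(t) i[t] %in% nn_r[j[t], ],
                   logical(1))
  data.frame(i = i[mutual], j = j[mutual])
}

# squared Euclidean distances between rows of a and rows of b
.cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  pmax(outer(an, bn, `+`) - 2 * tcrossprod(a, b), 0)
}

#' kNN batch-mixing entropy
#'
#' Mean Shannon entropy (natural log) of the dataset-label distribution in
#' each cell's k nearest neighbourhood. Higher means better mixing; the
#' maximum is `log(number of datasets)` under perfect interdigitation.
#'
#' @param scores cells x PCs matrix.
#' @param dataset per-cell dataset labels.
#' @param k neighbourhood size (default 20).
#' @return single number, the mean entropy.
#' @export
mixing_entropy <- function(scores, dataset, k = 20L) {
  nn <- .knn_indices(scores, k)
  dataset <- as.character(dataset)
  ent <- apply(nn, 1L, function(idx) {
    p <- table(dataset[idx]) / length(idx)
    -sum(p * log(p))
  })
  mean(ent)
}

#' Mean silhouette width
#'
#' Standard silhouette on Euclidean distances: for each cell, `a` is the mean
#' distance to its own cluster, `b` the smallest mean distance to another
#' cluster, and the width is `(b - a) / max(a, b)`.
#'
#' @param scores cells x PCs matrix.
#' @param labels per-cell cluster/subpopulation labels.
#' @return mean silhouette width over cells in non-singleton clusters.
#' @export
mean_silhouette <- function(scores, labels) {
  labels <- as.character(labels)
  d <- as.matrix(dist(scores))
  lv <- unique(labels)
  sizes <- table(labels)
  s <- vapply(seq_len(nrow(d)), function(i) {
    li <- labels[i]
    if (sizes[[li]] < 2L) return(NA_real_)
    a <- sum(d[i, labels == li]) / (sizes[[li]] - 1L)
    b <- min(vapply(setdiff(lv, li), function(l) mean(d[i, labels == l]),
                    numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s, na.rm = TRUE)
}

#' Agreement between two clusterings of the same cells
#'
#' For each cluster in `labels_a`, agreement is the percentage of its cells
#' falling in the best-matching cluster of `labels_b` (matching by overlap,
#' not by name); the overall value is the cell-weighted mean.
#'
#' @param labels_a,labels_b label vectors over the same cells.
#' @return list with `per_cluster` (named percentages) and `overall`.
#' @export
cluster_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  la <- as.character(labels_a)
  lb <- as.character(labels_b)
  tab <- table(la, lb)
  per <- 100 * apply(tab, 1L, max) / rowSums(tab)
  overall <- 100 * sum(apply(tab, 1L, max)) / length(la)
  list(per_cluster = per, overall = overall)
}

#' One-stop per-dataset processing
#'
#' Convenience wrapper: normalize, select HVGs, scale, PCA, cluster, embed.
#'
#' @param cm a [count_matrix()].
#' @param hvg_n,n_pcs,k_neighbors,resolution,seed stage parameters.
#' @param embed compute the 2D export embedding (the slowest step on large
#'   datasets; skip when only labels are needed).
#' @return list with `nm`, `hvg`, `pca`, `labels`, `embedding` (NULL when
#'   `embed = FALSE`).
#' @export
process_dataset <- function(cm, hvg_n = 500L, n_pcs = 30L, k_neighbors = 20L,
                            resolution = 0.8, seed = 1L, embed = TRUE) {
  nm <- lognormalize(cm)
  hvg <- select_hvg(nm, hvg_n)
  scaled <- scale_genes(nm, genes = hvg)
  pca <- reduce_pca(scaled, n_pcs, seed = seed)
  labels <- build_graph_and_cluster(pca$scores, k_neighbors, resolution,
                                    seed = seed)
  list(nm = nm, hvg = hvg, pca = pca, labels = labels,
       embedding = if (embed) embed_2d(pca$scores, seed = seed))
}
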