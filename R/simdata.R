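#' Configuration for the multi-dataset synthetic scRNA-seq generator
#'
#' The generator emulates a collection of independently produced liver-immune
#' scRNA-seq datasets: four immune subpopulations (NKT, Myeloid, Plasma, B) at
#' uneven, dataset-specific proportions; a shared marker-gene structure built
#' around the canonical panel symbols (CD3D, KLRF1, FCGR3A, CD14, CD19, SDC1,
#' plus PTPRC expressed by every immune cell); lognormal library sizes;
#' per-dataset multiplicative batch effects, both uniform across
#' subpopulations and restricted to a single subpopulation; additive ambient
#' contamination by hepatocyte transcripts (ALB-like); and a housekeeping set
#' with a high stable baseline.
#'
#' Counts are negative binomial: for cell `c` of subpopulation `s` in dataset
#' `d`, gene `g` has mean `L_c * w_eff(g, s, d) / sum_g w_eff(g, s, d)` where
#' `w_eff = baseline * marker_mult * uniform_batch * specific_batch`, and
#' gene-level dispersion is lognormal.
#'
#' @param n_datasets number of liver-like datasets (>= 1).
#' @param cells_per_dataset integer vector of cell numbers, recycled to
#'   `n_datasets`.
#' @param n_genes total gene universe size (must fit all named genes).
#' @param subpop_proportions matrix (datasets x 4, columns NKT/Myeloid/
#'   Plasma/B) of proportions, each row summing to 1. Defaults preserve the
#'   abundance ranking NKT > Myeloid > Plasma > B in every dataset.
#' @param marker_effect fold-change multiplier (> 1) applied to a marker gene
#'   in its own subpopulation. `marker_effect = 1` yields exchangeable
#'   subpopulations (no planted signal).
#' @param n_extra_markers synthetic marker genes planted per subpopulation in
#'   addition to the canonical panel.
#' @param batch_sigma_uniform SD of the per-dataset, per-gene log-multiplicative
#'   factor applied to all subpopulations.
#' @param batch_sigma_specific SD (or fixed magnitude, see
#'   `batch_specific_mode`) of the factor applied to `specific_subpop` only.
#' @param frac_specific_genes fraction of the synthetic (unnamed) genes
#'   receiving subpopulation-specific batch effects.
#' @param batch_specific_mode `"lognormal"` draws the specific log-factor
#'   N(0, sigma) independently per dataset and gene; `"fixed"` leaves dataset 1
#'   untouched and applies a log-factor of magnitude `batch_sigma_specific`
#'   with random sign per (dataset, gene) to datasets 2..D, so a known
#'   interaction contrast is planted between dataset 1 and any other.
#' @param specific_subpop the subpopulation receiving specific batch effects.
#' @param libsize_logmean,libsize_logsd lognormal library-size parameters.
#' @param contamination_genes ambient hepatocyte transcript symbols.
#' @param contamination_rate per-dataset expected fraction of a cell's library
#'   arriving as ambient contamination counts; default 0 everywhere except a
#'   2% rate in the last dataset.
#' @param housekeeping_genes symbols given a high stable baseline.
#' @param baseline_logsd lognormal SD of gene baseline expression weights.
#' @param dispersion_logmean,dispersion_logsd lognormal parameters of the NB
#'   gene dispersion (size = 1/dispersion).
#' @param tissue_mix named numeric vector of tissue-tag fractions applied to
#'   each dataset (default all cells tagged "liver"). Tags only affect
#'   barcodes/metadata, never counts.
#' @param seed integer seed; fully determines the generator output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 3L,
                       cells_per_dataset = c(1200L, 1000L, 1600L),
                       n_genes = 1000L,
                       subpop_proportions = NULL,
                       marker_effect = 4,
                       n_extra_markers = 30L,
                       batch_sigma_uniform = 0.15,
                       batch_sigma_specific = 0,
                       frac_specific_genes = 0.2,
                       batch_specific_mode = c("lognormal", "fixed"),
                       specific_subpop = "NKT",
                       libsize_logmean = log(2500),
                       libsize_logsd = 0.35,
                       contamination_genes = c("ALB", "APOA1", "ORM1"),
                       contamination_rate = NULL,
                       housekeeping_genes = c("ACTB", "GAPDH", "B2M",
                                              "RPL13A", "UBC", "PPIA",
                                              "TBP", "HPRT1"),
                       baseline_logsd = 1,
                       dispersion_logmean = log(0.3),
                       dispersion_logsd = 0.5,
                       tissue_mix = c(liver = 1),
                       seed = 1L) {
  batch_specific_mode <- match.arg(batch_specific_mode)
  n_datasets <- as.integer(n_datasets)
  cells_per_dataset <- as.integer(rep_len(cells_per_dataset, n_datasets))
  if (n_datasets < 1L || any(cells_per_dataset < 1L))
    stop("n_datasets and cells_per_dataset must all be >= 1")
  if (is.null(subpop_proportions)) {
    base <- rbind(c(0.60, 0.25, 0.10, 0.05),
                  c(0.55, 0.28, 0.11, 0.06),
                  c(0.66, 0.20, 0.09, 0.05))
    subpop_proportions <- base[rep_len(seq_len(nrow(base)), n_datasets), ,
                               drop = FALSE]
  }
  subpop_proportions <- as.matrix(subpop_proportions)
  if (is.null(colnames(subpop_proportions)))
    colnames(subpop_proportions) <- SUBPOPS
  subpop_proportions <- subpop_proportions[, SUBPOPS, drop = FALSE]
  if (nrow(subpop_proportions) != n_datasets)
    stop("subpop_proportions needs one row per dataset")
  if (any(abs(rowSums(subpop_proportions) - 1) > 1e-9))
    stop("subpopulation proportions must sum to 1 per dataset")
  if (any(subpop_proportions < 0))
    stop("proportions must be non-negative")
  if (marker_effect < 1)
    stop("marker_effect must be >= 1 (1 = no planted signal)")
  if (is.null(contamination_rate)) {
    contamination_rate <- rep(0, n_datasets)
    contamination_rate[n_datasets] <- 0.02
  }
  contamination_rate <- rep_len(contamination_rate, n_datasets)
  if (abs(sum(tissue_mix) - 1) > 1e-9 || is.null(names(tissue_mix)))
    stop("tissue_mix must be a named vector summing to 1")
  cfg <- list(n_datasets = n_datasets,
              cells_per_dataset = cells_per_dataset,
              n_genes = as.integer(n_genes),
              subpop_proportions = subpop_proportions,
              marker_effect = marker_effect,
              n_extra_markers = as.integer(n_extra_markers),
              batch_sigma_uniform = batch_sigma_uniform,
              batch_sigma_specific = batch_sigma_specific,
              frac_specific_genes = frac_specific_genes,
              batch_specific_mode = batch_specific_mode,
              specific_subpop = specific_subpop,
              libsize_logmean = libsize_logmean,
              libsize_logsd = libsize_logsd,
              contamination_genes = contamination_genes,
              contamination_rate = contamination_rate,
              housekeeping_genes = housekeeping_genes,
              baseline_logsd = baseline_logsd,
              dispersion_logmean = dispersion_logmean,
              dispersion_logsd = dispersion_logsd,
              tissue_mix = tissue_mix,
              seed = as.integer(seed))
  named <- .sim_named_genes(cfg)
  if (cfg$n_genes < length(named) + 4L * cfg$n_extra_markers + 1L)
    stop("n_genes too small for the named genes and planted markers")
  class(cfg) <- "sim_config"
  cfg
}

# canonical panel + pan-immune + housekeeping + contamination symbols
.sim_named_genes <- function(cfg) {
  unique(c("CD3D", "KLRF1", "FCGR3A", "CD14", "CD19", "SDC1", "PTPRC",
           cfg$housekeeping_genes, cfg$contamination_genes))
}

# gene universe + per-gene static properties (baseline, dispersion, marker
# multipliers); drawn from the config RNG stream
.sim_gene_model <- function(cfg) {
  named <- .sim_named_genes(cfg)
  n_syn <- cfg$n_genes - length(named)
  symbols <- c(named, sprintf("G%04d", seq_len(n_syn)))
  baseline <- exp(rnorm(cfg$n_genes, 0, cfg$baseline_logsd))
  names(baseline) <- symbols
  # housekeeping: high, stable (low dispersion) baseline
  baseline[cfg$housekeeping_genes] <- exp(2.2 + rnorm(
    length(cfg$housekeeping_genes), 0, 0.1))
  # ambient transcripts: near-zero endogenous immune expression
  baseline[cfg$contamination_genes] <- 0.02
  # pan-immune CD45 high so positivity filters keep immune cells
  baseline["PTPRC"] <- exp(2)
  # canonical markers get a solid mid/high baseline so their boost is visible
  panel <- c("CD3D", "KLRF1", "FCGR3A", "CD14", "CD19", "SDC1")
  baseline[panel] <- exp(1.2)
  dispersion <- rlnorm(cfg$n_genes, cfg$dispersion_logmean,
                       cfg$dispersion_logsd)
  dispersion[match(cfg$housekeeping_genes, symbols)] <- 0.05
  names(dispersion) <- symbols

  mult <- matrix(1, cfg$n_genes, length(SUBPOPS),
                 dimnames = list(symbols, SUBPOPS))
  marker_of <- setNames(rep(NA_character_, cfg$n_genes), symbols)
  plant <- function(sym, subpops) {
    mult[sym, subpops] <<- cfg$marker_effect
    marker_of[sym] <<- paste(subpops, collapse = ",")
  }
  plant("CD3D", "NKT")
  plant("KLRF1", "NKT")
  plant("FCGR3A", c("NKT", "Myeloid"))  # NK and myeloid share FCGR3A
  plant("CD14", "Myeloid")
  plant("CD19", "B")
  plant("SDC1", "Plasma")
  syn <- symbols[-seq_along(named)]
  extra <- matrix(syn[seq_len(4L * cfg$n_extra_markers)],
                  ncol = length(SUBPOPS))
  colnames(extra) <- SUBPOPS
  for (s in SUBPOPS) for (g in extra[, s]) plant(g, s)
  # specific-batch-eligible genes: synthetic non-markers
  eligible <- setdiff(syn, as.vector(extra))
  n_spec <- round(cfg$frac_specific_genes * length(eligible))
  specific_genes <- if (n_spec > 0 && cfg$batch_sigma_specific > 0)
    sort(sample(eligible, n_spec)) else character(0)
  list(symbols = symbols, baseline = baseline, dispersion = dispersion,
       marker_mult = mult, marker_of = marker_of,
       specific_genes = specific_genes)
}

# one dataset's batch factors; specific factors hit specific_subpop only
.sim_batch_factors <- function(cfg, gm, d) {
  n <- cfg$n_genes
  uni <- exp(rnorm(n, 0, cfg$batch_sigma_uniform))
  names(uni) <- gm$symbols
  spec <- matrix(1, n, length(SUBPOPS),
                 dimnames = list(gm$symbols, SUBPOPS))
  if (length(gm$specific_genes)) {
    k <- length(gm$specific_genes)
    lf <- switch(cfg$batch_specific_mode,
      lognormal = rnorm(k, 0, cfg$batch_sigma_specific),
      fixed = if (d == 1L) {
        sample(c(-1, 1), k, replace = TRUE) * 0  # keep RNG stream aligned
      } else {
        sample(c(-1, 1), k, replace = TRUE) * cfg$batch_sigma_specific
      })
    spec[gm$specific_genes, cfg$specific_subpop] <- exp(lf)
  }
  list(uniform = uni, specific = spec)
}

# simulate one dataset given gene model + batch factors
.sim_dataset <- function(cfg, gm, batch, d, n_cells, props, dataset_id) {
  subpop <- sample(SUBPOPS, n_cells, replace = TRUE, prob = props)
  tissue <- sample(names(cfg$tissue_mix), n_cells, replace = TRUE,
                   prob = cfg$tissue_mix)
  libsize <- rlnorm(n_cells, cfg$libsize_logmean, cfg$libsize_logsd)
  counts <- matrix(0L, cfg$n_genes, n_cells)
  size <- 1 / gm$dispersion
  for (s in SUBPOPS) {
    idx <- which(subpop == s)
    if (!length(idx)) next
    w <- gm$baseline * gm$marker_mult[, s] * batch$uniform * batch$specific[, s]
    p <- w / sum(w)
    mu <- outer(p, libsize[idx])
    counts[, idx] <- rnbinom(length(mu), mu = mu, size = size)
  }
  rate <- cfg$contamination_rate[d]
  if (rate > 0) {
    ci <- match(cfg$contamination_genes, gm$symbols)
    lam <- outer(rep(rate / length(ci), length(ci)), libsize)
    counts[ci, ] <- counts[ci, ] + rpois(length(lam), lam)
  }
  barcodes <- sprintf("%s_%s_%05d", dataset_id, tissue, seq_len(n_cells))
  dimnames(counts) <- list(gm$symbols, barcodes)
  cm <- count_matrix(counts, dataset_id)
  cells <- cell_table(barcode = barcodes, dataset_id = dataset_id,
                      tissue_tag = tissue)
  list(cm = cm, cells = cells, subpop = subpop)
}

#' Generate a synthetic multi-dataset collection with ground truth
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (list of `count_matrix`), `cells` (combined
#'   `cell_table`), and `truth` (list: per-cell `cells` data.frame with the
#'   true subpopulation, per-gene `genes` data.frame with marker-of labels and
#'   specific-batch flags, `batch_uniform` genes x datasets matrix,
#'   `batch_specific` list of genes x subpop matrices per dataset, and the
#'   configured `proportions`).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gm <- .sim_gene_model(config)
  ids <- sprintf("DS%d", seq_len(config$n_datasets))
  counts <- vector("list", config$n_datasets)
  names(counts) <- ids
  cells <- list()
  truth_cells <- list()
  batch_uni <- matrix(NA_real_, config$n_genes, config$n_datasets,
                      dimnames = list(gm$symbols, ids))
  batch_spec <- vector("list", config$n_datasets)
  names(batch_spec) <- ids
  for (d in seq_len(config$n_datasets)) {
    batch <- .sim_batch_factors(config, gm, d)
    sim <- .sim_dataset(config, gm, batch, d, config$cells_per_dataset[d],
                        config$subpop_proportions[d, ], ids[d])
    counts[[d]] <- sim$cm
    cells[[d]] <- sim$cells
    truth_cells[[d]] <- data.frame(barcode = sim$cells$barcode,
                                   dataset_id = ids[d],
                                   subpop = sim$subpop,
                                   stringsAsFactors = FALSE)
    batch_uni[, d] <- batch$uniform
    batch_spec[[d]] <- batch$specific
  }
  cells <- do.call(rbind, cells)
  class(cells) <- c("cell_table", "data.frame")
  truth <- list(
    cells = do.call(rbind, truth_cells),
    genes = data.frame(symbol = gm$symbols,
                       marker_of = unname(gm$marker_of),
                       specific_batch = gm$symbols %in% gm$specific_genes,
                       stringsAsFactors = FALSE),
    batch_uniform = batch_uni,
    batch_specific = batch_spec,
    proportions = config$subpop_proportions)
  list(counts = counts, cells = cells, truth = truth)
}

#' Generate a reference-compartment dataset (PBMC-like)
#'
#' Shares the gene universe and subpopulation structure of a [sim_config()]
#' but represents a separate compartment: selected genes are shifted by
#' `shift_logfc` in log-mean, optionally in a subset of subpopulations only.
#' A positive `shift_logfc` raises reference expression, so the liver-side
#' comparison recovers those genes as downregulated (ratio <= 0.8 at
#' `shift_logfc = log(2)`).
#'
#' @param config a [sim_config()]; the reference reuses its gene model (same
#'   seed-derived universe) but draws its own cells and batch factors.
#' @param shift_genes gene symbols to shift (must exist in the universe).
#' @param shift_logfc shift in natural-log mean expression.
#' @param subpops subpopulations receiving the shift (default all four).
#' @param n_cells number of reference cells.
#' @param dataset_id identifier, default `"REF"`.
#' @return list with `cm` (`count_matrix`), `cells` (`cell_table` including
#'   true subpopulation in `subpop`), and `shift_genes`.
#' @export
generate_reference_compartment <- function(config, shift_genes = character(0),
                                           shift_logfc = 0,
                                           subpops = SUBPOPS,
                                           n_cells = 1000L,
                                           dataset_id = "REF") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)           # replay the gene-model stream
  gm <- .sim_gene_model(config)
  unknown <- setdiff(shift_genes, gm$symbols)
  if (length(unknown))
    stop("unknown gene symbols: ", paste(unknown, collapse = ", "))
  bad <- setdiff(subpops, SUBPOPS)
  if (length(bad)) stop("unknown subpopulations: ", paste(bad, collapse = ", "))
  set.seed(config$seed + 99991L)  # independent cell/batch stream
  mult <- gm$marker_mult
  mult[shift_genes, subpops] <- mult[shift_genes, subpops] * exp(shift_logfc)
  gm$marker_mult <- mult
  batch <- .sim_batch_factors(config, gm, 1L)
  sim <- .sim_dataset(config, gm, batch, 1L, as.integer(n_cells),
                      config$subpop_proportions[1L, ], dataset_id)
  cells <- sim$cells
  cells$subpop <- sim$subpop
  list(cm = sim$cm, cells = cells, shift_genes = shift_genes)
}

#' Write a simulated collection as plain-text fixtures
#'
#' One subdirectory per dataset containing `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv`, plus `truth_cells.tsv` and `truth_genes.tsv` at the top
#' level. Round-trips through [read_counts()].
#'
#' @param collection output of [generate_collection()].
#' @param dir target directory (created if absent).
#' @return invisibly, the vector of dataset directories written.
#' @export
write_fixture <- function(collection, dir) {
  if (is.null(collection$counts) || !length(collection$counts))
    stop("empty dataset list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (cm in collection$counts) {
    sub <- file.path(dir, cm$dataset_id)
    dir.create(sub, showWarnings = FALSE)
    Matrix::writeMM(cm$counts, file.path(sub, "matrix.mtx"))
    writeLines(colnames(cm$counts), file.path(sub, "barcodes.tsv"))
    writeLines(rownames(cm$counts), file.path(sub, "features.tsv"))
    out <- c(out, sub)
  }
  if (!is.null(collection$truth)) {
    write.table(collection$truth$cells, file.path(dir, "truth_cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(collection$truth$genes, file.path(dir, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
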