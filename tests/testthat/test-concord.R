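.pt_from_counts <- function(counts) {
  structure(list(counts = counts,
                 percent = 100 * counts / rowSums(counts),
                 unassigned = setNames(rep(0L, nrow(counts)),
                                       rownames(counts))),
            class = "proportion_table")
}

test_that("chi-squared matches the closed form on 2x2 tables", {
  tab <- matrix(c(90, 10, 10, 90), 2, byrow = TRUE,
                dimnames = list(c("D1", "D2"), c("NKT", "Myeloid")))
  pt <- .pt_from_counts(cbind(tab, Plasma = 0, B = 0)[, c("NKT", "Myeloid",
                                                          "Plasma", "B")])
  res <- proportion_chisq(structure(list(counts = tab),
                                    class = "proportion_table"), "overall")
  expect_equal(res$statistic, 128)
  expect_equal(res$df, 1L)
  expect_equal(res$statistic, oracle_chisq(tab))
  # homogeneous table -> 0, p = 1
  hom <- matrix(c(50, 50, 50, 50), 2, dimnames = dimnames(tab))
  res0 <- proportion_chisq(structure(list(counts = hom),
                                     class = "proportion_table"), "overall")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # doubling all counts doubles the statistic
  res2 <- proportion_chisq(structure(list(counts = tab * 2),
                                     class = "proportion_table"), "overall")
  expect_equal(res2$statistic, 2 * res$statistic)
})

test_that("chi-squared agrees with stats::chisq.test on random tables", {
  set.seed(33)
  for (i in 1:5) {
    tab <- matrix(rpois(8, 40) + 1, 2, 4,
                  dimnames = list(c("D1", "D2"), SUBPOPS))
    mine <- proportion_chisq(.pt_from_counts(tab), "overall")
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("pairwise chi-squared produces one 2x2 test per pair x subpop", {
  counts <- matrix(c(120, 50, 20, 10, 130, 40, 25, 5, 110, 60, 15, 15),
                   3, 4, byrow = TRUE,
                   dimnames = list(c("D1", "D2", "D3"), SUBPOPS))
  res <- proportion_chisq(.pt_from_counts(counts), "pairwise")
  expect_equal(nrow(res), 3 * 4)
  # spot-check one cell against the closed form
  row <- res[res$comparison == "D1 vs D2" & res$subpop == "B", ]
  tab22 <- rbind(c(10, 190), c(5, 195))
  expect_equal(row$statistic, oracle_chisq(tab22), tolerance = 1e-9)
  expect_equal(row$df, 1L)
  # Yates correction reduces the statistic
  resy <- proportion_chisq(.pt_from_counts(counts), "pairwise",
                           correct = TRUE)
  expect_true(all(resy$statistic <= res$statistic + 1e-12))
})

test_that("housekeeping noise is null on identical data and powered on shifts", {
  nms <- small_normalized()[1:2]
  tabs <- truth_tables(small_collection())[1:2]
  hk <- c("ACTB", "GAPDH", "B2M")
  # identical datasets: F exactly 0, all pairwise p = 1
  same <- housekeeping_noise(list(nms[[1]], nms[[1]]),
                             list(tabs[[1]], tabs[[1]]), hk, "NKT")
  expect_true(all(abs(same$anova$F) < 1e-20))
  expect_true(all(same$pairwise$p > 1 - 1e-12))
  # +1 log-unit shift on hk genes in one dataset: everything significant
  shifted <- nms[[2]]
  v <- as.matrix(shifted$values)
  v[hk, ] <- v[hk, ] + 1
  shifted <- nm_from_values(v, "DS2")
  res <- housekeeping_noise(list(nms[[1]], shifted),
                            list(tabs[[1]], tabs[[2]]), hk, "NKT")
  expect_true(all(res$anova$p_adj < 0.05))
  expect_true(all(res$pairwise$p_adj < 0.05))
  expect_warning(housekeeping_noise(nms, tabs, c(hk, "NOPE"), "NKT"),
                 "NOPE")
})

test_that("housekeeping ANOVA holds its type-I error on null draws", {
  set.seed(91)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(60))
    m <- do.call(cbind, groups)
    v <- matrix(c(m), 1, dimnames = list("HK", sprintf("c%03d", 1:180)))
    nm1 <- nm_from_values(v[, 1:60, drop = FALSE], "A")
    nm2 <- nm_from_values(v[, 61:120, drop = FALSE], "B")
    nm3 <- nm_from_values(v[, 121:180, drop = FALSE], "C")
    tabs <- lapply(list(nm1, nm2, nm3), function(nm)
      cell_table(colnames(nm$values), nm$dataset_id, subpop = "NKT"))
    res <- housekeeping_noise(list(nm1, nm2, nm3), tabs, "HK", "NKT")
    hits <- hits + (res$anova$p < 0.05)
    total <- total + 1L
  }
  expect_lte(hits / total, 0.25)   # 20 null draws, alpha 0.05
})

test_that("pseudobulk is a mean with the expected algebra", {
  nm <- small_normalized()[[1]]
  one <- colnames(nm$values)[1]
  expect_equal(pseudobulk(nm, one),
               setNames(as.vector(nm$values[, one]), rownames(nm$values)))
  cells <- colnames(nm$values)[1:40]
  a <- pseudobulk(nm, cells[1:20])
  b <- pseudobulk(nm, cells[21:40])
  expect_equal(pseudobulk(nm, cells), (a + b) / 2, tolerance = 1e-12)
  expect_error(pseudobulk(nm, "missing-barcode"), "unknown barcodes")
})

test_that("correlation fits recover planted relationships", {
  v <- seq(0.1, 5, length.out = 50)
  id <- correlate_pairwise(v, v)
  expect_equal(id$pearson_r, 1)
  expect_equal(id$spearman_rho, 1)
  expect_equal(unname(id$linear), c(0, 1), tolerance = 1e-10)
  aff <- correlate_pairwise(v, 2 * v + 3)
  expect_equal(aff$pearson_r, 1)
  expect_equal(unname(aff$linear), c(3, 2), tolerance = 1e-10)
  # quadratic fit recovers a planted parabola
  qd <- correlate_pairwise(v, 1 + 2 * v + 0.5 * v^2)
  expect_equal(unname(qd$quadratic), c(1, 2, 0.5), tolerance = 1e-8)
  rev <- correlate_pairwise(v, rev(v))
  expect_equal(rev$spearman_rho, -1)
  flat <- correlate_pairwise(rep(1, 10), 1:10)
  expect_false(flat$defined)
  expect_match(flat$reason, "zero-variance")
})

test_that("gene ranking uses the signed -log10 p metric with stated ties", {
  de <- data.frame(gene = c("B", "A", "C", "D"),
                   logfc = c(1, 1, -1, 1),
                   p = c(0.01, 0.01, 0.001, 0.1))
  r <- rank_genes(de)
  # A and B tie on metric and |logfc|: symbol order breaks the tie
  expect_identical(r$gene, c("A", "B", "D", "C"))
  # stronger p ranks higher at equal logfc
  expect_lt(which(r$gene == "B"), which(r$gene == "D"))
  # flipping group labels (negating logfc) reverses a tie-free ranking
  de_free <- data.frame(gene = c("B", "A", "C", "D"),
                        logfc = c(1, 1, -1, 1),
                        p = c(0.01, 0.02, 0.001, 0.1))
  de_neg <- de_free; de_neg$logfc <- -de_neg$logfc
  expect_identical(rank_genes(de_neg)$gene, rev(rank_genes(de_free)$gene))
  # p = 0 is floored, not infinite
  de3 <- de; de3$p[1] <- 0
  expect_true(all(is.finite(rank_genes(de3)$metric)))
})

test_that("RRHO matches brute-force hypergeometric tails", {
  set.seed(17)
  for (n in c(20L, 50L)) {
    genes <- sprintf("g%03d", 1:n)
    l1 <- sample(genes)
    l2 <- sample(genes)
    grid <- rrho(l1, l2, step = 1L)
    pos2 <- match(l1, l2)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        k <- sum(pos2[seq_len(i)] <= j)
        expect_equal(grid$grid[i, j],
                     -log10(max(oracle_hyper_tail(k, i, j, n),
                                .Machine$double.xmin)),
                     tolerance = 1e-10)
      }
    }
    # the (N, N) corner is forced to 0
    expect_equal(grid$grid[n, n], 0)
  }
  # identical lists: the (1,1) cell is -log10(1/N)
  genes <- sprintf("g%03d", 1:5)
  gid <- rrho(genes, genes, step = 1L)
  expect_equal(gid$grid["1", "1"], -log10(1 / 5), tolerance = 1e-10)
  expect_error(rrho(genes, sprintf("h%03d", 1:5)), "same gene universe")
})

test_that("top-k agreement counts shared abundant transcripts", {
  nms <- small_normalized()
  tabs <- truth_tables(small_collection())
  self <- topk_agreement(nms[[1]], nms[[1]], tabs[[1]], tabs[[1]],
                         "NKT", k = 50L)
  expect_equal(self$n_matched, 50L)
  # disjoint supports -> zero overlap
  v1 <- matrix(0, 20, 10, dimnames = list(sprintf("g%02d", 1:20),
                                          sprintf("a%02d", 1:10)))
  v2 <- v1
  dimnames(v2)[[2]] <- sprintf("b%02d", 1:10)
  v1[1:10, ] <- 5
  v2[11:20, ] <- 5
  t1 <- cell_table(colnames(v1), "A", subpop = "B")
  t2 <- cell_table(colnames(v2), "B", subpop = "B")
  dis <- topk_agreement(nm_from_values(v1, "A"), nm_from_values(v2, "B"),
                        t1, t2, "B", k = 10L)
  expect_equal(dis$n_matched, 0L)
  # planted 90 shared + 10 dataset-specific top genes
  n_cells <- 6
  base <- matrix(0.1, 120, n_cells,
                 dimnames = list(sprintf("g%03d", 1:120),
                                 sprintf("a%02d", 1:n_cells)))
  top_shared <- sprintf("g%03d", 1:90)
  w1 <- base; w1[top_shared, ] <- 10; w1[sprintf("g%03d", 91:100), ] <- 8
  w2 <- base; dimnames(w2)[[2]] <- sprintf("b%02d", 1:n_cells)
  w2[top_shared, ] <- 10; w2[sprintf("g%03d", 101:110), ] <- 8
  tt1 <- cell_table(colnames(w1), "A", subpop = "NKT")
  tt2 <- cell_table(colnames(w2), "B", subpop = "NKT")
  res <- topk_agreement(nm_from_values(w1, "A"), nm_from_values(w2, "B"),
                        tt1, tt2, "NKT", k = 100L)
  expect_equal(res$n_matched, 90L)
  expect_setequal(res$shared, top_shared)
})
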