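test_that("Wilcoxon p agrees with enumeration and base R", {
  set.seed(41)
  # exact route vs the independent DP oracle, with and without ties
  for (rep in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- sample(0:4, n1, replace = TRUE)          # heavy ties
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(wilcox_p(x, y), oracle_wilcox_p(x, y), tolerance = 1e-9)
    xc <- rnorm(n1); yc <- rnorm(n2)              # continuous, no ties
    expect_equal(wilcox_p(xc, yc), oracle_wilcox_p(xc, yc),
                 tolerance = 1e-9)
    # untied case also matches base R's exact test
    expect_equal(wilcox_p(xc, yc),
                 wilcox.test(xc, yc, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  # large-sample normal approximation tracks base R's (uncorrected) approx
  x <- rnorm(80); y <- rnorm(90, 0.3)
  expect_equal(wilcox_p(x, y),
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("DE table fields obey their contracts", {
  nms <- small_normalized()
  tabs <- truth_tables(small_collection())
  de <- de_subpop_vs_rest(nms[[1]], tabs[[1]], "Myeloid")
  expect_true(all(de$ratio > 0))
  expect_true(all(de$p_adj >= de$p - 1e-15))           # Bonferroni monotone
  expect_true(all(de$p_adj <= 1))
  expect_equal(de$logfc, de$mean1 - de$mean2)
  expect_equal(de$ratio, exp(de$logfc))
  # markers of the subpopulation surface with ratio above the gate
  expect_true(de$de_flag[de$gene == "CD14"])
  expect_gt(de$ratio[de$gene == "CD14"], 1.25)
  # flag invariance to gene order
  perm <- sample(nrow(nms[[1]]$values))
  nm_perm <- normalized_matrix(nms[[1]]$values[perm, ], 1e4, "DS1")
  de_perm <- de_subpop_vs_rest(nm_perm, tabs[[1]], "Myeloid")
  m <- match(de$gene, de_perm$gene)
  expect_identical(de$de_flag, de_perm$de_flag[m])
  expect_error(de_subpop_vs_rest(nms[[1]], tabs[[1]], "NKT",
                                 min_cells = 1e6), "fewer than")
})

test_that("identical groups give p = 1 and logfc = 0", {
  v <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 2), 2,
              dimnames = list(c("g1", "g2"), sprintf("c%d", 1:6)))
  nm <- nm_from_values(v)
  tab <- cell_table(colnames(v), "X", subpop = rep(c("NKT", "B"), each = 3))
  de <- de_subpop_vs_rest(nm, tab, "NKT")
  expect_equal(de$p, c(1, 1))
  expect_equal(de$logfc, c(0, 0))
})

test_that("dual-threshold classification has inclusive ratio and strict alpha", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   ratio = c(1.25, 1.10, 0.5, 0.8, 1.3),
                   p_adj = c(0.049, 1e-30, 0.05, 0.049, 0.05))
  de$logfc <- log(de$ratio)
  cl <- classify_de(de)
  expect_true(cl$de_flag[cl$gene == "a"])     # ratio boundary inclusive
  expect_false(cl$de_flag[cl$gene == "b"])    # effect-size gate
  expect_false(cl$de_flag[cl$gene == "c"])    # alpha boundary strict
  expect_true(cl$de_flag[cl$gene == "d"])     # 0.8 boundary inclusive
  expect_identical(cl$class[cl$gene == "a"], "DE")
})

test_that("between-dataset DE is antisymmetric and null on self-comparison", {
  nms <- small_normalized()
  tabs <- truth_tables(small_collection())
  # a dataset against a relabeled copy of itself: no flags
  copy_v <- nms[[1]]$values
  colnames(copy_v) <- paste0("CP_", colnames(copy_v))
  nm_cp <- normalized_matrix(copy_v, 1e4, "CP")
  tab_cp <- cell_table(colnames(copy_v), "CP", subpop = tabs[[1]]$subpop)
  de_self <- de_between_datasets(nms[[1]], nm_cp, tabs[[1]], tab_cp, "NKT")
  expect_equal(sum(de_self$de_flag), 0L)
  expect_true(all(de_self$p > 1 - 1e-9))
  # swapping dataset order flips every logfc
  de_ab <- de_between_datasets(nms[[1]], nms[[2]], tabs[[1]], tabs[[2]], "B")
  de_ba <- de_between_datasets(nms[[2]], nms[[1]], tabs[[2]], tabs[[1]], "B")
  expect_equal(de_ab$logfc, -de_ba$logfc)
  expect_equal(de_ab$p, de_ba$p)
})

test_that("DoD reproduces the hand-computed four-group contrast", {
  # groups: subpop/ds1 (3,4,5), rest/ds1 (1,2,3), subpop/ds2 (2,3,4),
  # rest/ds2 (1,2,3) -> delta1 = 2, delta2 = 1, dod = 1
  vals <- c(3, 4, 5, 1, 2, 3, 2, 3, 4, 1, 2, 3)
  mk <- function(v, id) {
    m <- matrix(v, 1, dimnames = list("g", sprintf("%s_c%d", id,
                                                   seq_along(v))))
    nm_from_values(m, id)
  }
  nm1 <- mk(vals[1:6], "D1"); nm2 <- mk(vals[7:12], "D2")
  t1 <- cell_table(colnames(nm1$values), "D1",
                   subpop = rep(c("B", "NKT"), each = 3))
  t2 <- cell_table(colnames(nm2$values), "D2",
                   subpop = rep(c("B", "NKT"), each = 3))
  dd <- dod(nm1, nm2, t1, t2, "B")
  expect_equal(dd$delta1, 2)
  expect_equal(dd$delta2, 1)
  expect_equal(dd$dod, 1)
  # independent contrast computation: all four variances are 1, n = 3
  se2 <- 4 * (1 / 3)
  t_exp <- 1 / sqrt(se2)
  df_exp <- se2^2 / (4 * (1 / 3)^2 / 2)
  expect_equal(dd$t, t_exp, tolerance = 1e-12)
  expect_equal(dd$df, df_exp, tolerance = 1e-12)
  expect_equal(dd$p, 2 * pt(-abs(t_exp), df_exp), tolerance = 1e-12)
  # dataset swap negates dod, leaves p unchanged
  dd_swap <- dod(nm2, nm1, t2, t1, "B")
  expect_equal(dd_swap$dod, -dd$dod)
  expect_equal(dd_swap$p, dd$p)
  # simple arithmetic example: delta1 = 1.0, delta2 = 0.5 -> dod = 0.5
  expect_equal((1.0 - 0.5), 0.5)
  # group of one cell is rejected (variance undefined)
  t_bad <- cell_table(colnames(nm1$values), "D1",
                      subpop = c("B", rep("NKT", 5)))
  expect_error(dod(nm1, nm2, t_bad, t2, "B"), ">= 2 cells")
})

test_that("dod_flag is contained in de_flag and summary partitions them", {
  nms <- small_normalized()
  tabs <- truth_tables(small_collection())
  deb <- de_between_datasets(nms[[1]], nms[[2]], tabs[[1]], tabs[[2]], "NKT")
  dd <- dod(nms[[1]], nms[[2]], tabs[[1]], tabs[[2]], "NKT",
            de_between = deb)
  expect_true(all(!dd$dod_flag | dd$de_flag))
  s <- dod_explained_summary(deb, dd)
  expect_equal(s$n_dod, sum(dd$dod_flag))
  expect_equal(s$n_de, sum(deb$de_flag))
  if (s$n_de > 0) expect_equal(s$pct_dod_of_de, 100 * s$n_dod / s$n_de)
  # no DE genes -> undefined percentage
  deb0 <- deb; deb0$de_flag <- FALSE
  dd0 <- dd; dd0$dod_flag <- FALSE
  s0 <- dod_explained_summary(deb0, dd0)
  expect_false(s0$defined)
  expect_true(is.na(s0$pct_dod_of_de))
  expect_error(dod_explained_summary(deb[-1, ], dd), "mismatched")
})

test_that("heatmap z-scores have the stated row and block structure", {
  coll <- small_collection()
  nm <- small_normalized()[[1]]
  tab <- truth_tables(coll)[[1]]
  genes <- list(NKT = c("CD3D", "KLRF1"), Myeloid = "CD14",
                B = "CD19", Plasma = "SDC1", other = "ACTB")
  z <- heatmap_matrix(nm, genes, tab)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-10)
  expect_equal(unname(rowMeans(z^2)), rep(1, nrow(z)), tolerance = 1e-10)
  # columns ordered by subpopulation blocks
  expect_false(is.unsorted(match(attr(z, "col_subpop"),
                                 c("NKT", "Myeloid", "Plasma", "B",
                                   "Unassigned"))))
  # marker rows: mean z inside their own block above the outside mean
  blocks <- attr(z, "col_subpop")
  for (g in c("CD3D", "CD14", "CD19", "SDC1")) {
    own <- attr(z, "row_group")[match(g, rownames(z))]
    expect_gt(mean(z[g, blocks == own]), 0)
    expect_gt(mean(z[g, blocks == own]), mean(z[g, blocks != own]))
  }
  # constant gene -> all-zero row
  v <- as.matrix(nm$values)
  v["ACTB", ] <- 3
  z2 <- heatmap_matrix(nm_from_values(v, "DS1"), "ACTB", tab)
  expect_true(all(z2 == 0))
  expect_error(heatmap_matrix(nm, "ABSENT", tab), "absent")
})

test_that("master lists union per-dataset top genes with provenance", {
  de <- data.frame(gene = sprintf("g%02d", 1:20),
                   logfc = rep(1, 20), ratio = rep(3, 20),
                   p = 10^-(20:1), p_adj = 10^-(18:-1))
  de <- classify_de(de)
  same <- top_de_master_list(list(A = de, B = de), n_top = 5L)
  expect_equal(nrow(same), 5L)
  expect_true(all(same$n_datasets == 2L))
  # disjoint top sets from 3 datasets -> 3 * n_top genes
  mk <- function(offset) {
    d <- de
    d$gene <- sprintf("h%02d", offset + 1:20)
    d
  }
  dis <- top_de_master_list(list(A = mk(0), B = mk(20), C = mk(40)),
                            n_top = 4L)
  expect_equal(nrow(dis), 12L)
  expect_true(all(dis$n_datasets == 1L))
})
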