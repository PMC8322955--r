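# shared fixtures (memoised: built once per test run) and independent oracles

.fixture_env <- new.env(parent = emptyenv())

SUBPOPS <- c("NKT", "Myeloid", "Plasma", "B")

small_config <- function(...) {
  args <- utils::modifyList(list(cells_per_dataset = c(300L, 250L, 350L),
                                 n_genes = 300L, n_extra_markers = 10L,
                                 seed = 101L),
                            list(...))
  do.call(sim_config, args)
}

small_collection <- function() {
  if (is.null(.fixture_env$coll))
    .fixture_env$coll <- generate_collection(small_config())
  .fixture_env$coll
}

# cell tables carrying the TRUE subpopulation labels (bypasses clustering,
# for tests of downstream statistics)
truth_tables <- function(coll) {
  tc <- coll$truth$cells
  out <- lapply(names(coll$counts), function(d) {
    td <- tc[tc$dataset_id == d, ]
    cell_table(td$barcode, d, subpop = td$subpop)
  })
  names(out) <- names(coll$counts)
  out
}

small_normalized <- function() {
  if (is.null(.fixture_env$nms))
    .fixture_env$nms <- lapply(small_collection()$counts, lognormalize)
  .fixture_env$nms
}

# tiny deterministic count matrix
toy_cm <- function(m = NULL, id = "TOY") {
  if (is.null(m)) {
    m <- matrix(c(5L, 0L, 0L, 0L, 0L, 7L), 3, 2,
                dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  }
  count_matrix(m, id)
}

# --- independent oracles -------------------------------------------------

# hypergeometric upper tail P(X >= k) by explicit pmf summation
oracle_hyper_tail <- function(k, i, j, n) {
  if (k <= 0) return(1)
  xs <- k:min(i, j)
  if (!length(xs) || k > min(i, j)) return(0)
  sum(choose(i, xs) * choose(n - i, j - xs)) / choose(n, j)
}

# exact two-sided rank-sum p by dynamic programming over subset sums of the
# observed (possibly tied) ranks, reflection convention about the mean
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))     # doubled ranks are integers
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, n1 + 1L, smax + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    for (k in seq(min(n1, n1), 1L)) {
      shifted <- c(rep(0, v), dp[k, seq_len(smax + 1L - v)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  probs <- dp[n1 + 1L, ] / choose(n, n1)
  w2 <- sum(r2[seq_len(n1)])
  e2 <- n1 * (n + 1)                              # doubled expectation
  sums <- 0:smax
  sum(probs[abs(sums - e2) >= abs(w2 - e2) - 1e-9])
}

# closed-form chi-squared on a table, written independently of the package
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# normalized matrix from a dense value matrix (for hand-built examples)
nm_from_values <- function(values, id = "X") {
  normalized_matrix(as(as(as(Matrix::Matrix(values, sparse = TRUE),
                             "dMatrix"), "generalMatrix"), "CsparseMatrix"),
                    1e4, id)
}
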