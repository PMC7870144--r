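toy_cm <- function(counts, batch = NULL, group = NULL) {
  n <- ncol(counts)
  cells <- data.frame(batch = batch %||% rep("b1", n),
                      group = group %||% rep("a", n))
  count_matrix(counts, cells)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cell QC applies the detected-gene and mitochondrial thresholds", {
  # 1000 genes; cell1 healthy (600 detected), cell2 only 400 detected,
  # cell3 healthy but 6% mitochondrial
  set.seed(1)
  counts <- matrix(0L, 1000, 3,
                   dimnames = list(c(sprintf("G%03d", 1:990),
                                     sprintf("MT-%02d", 1:10)), NULL))
  counts[1:600, 1] <- 1L
  counts[1:400, 2] <- 1L
  counts[1:600, 3] <- 1L
  counts["MT-01", 1] <- 10L   # 10/610 < 5%
  counts["MT-01", 3] <- 40L   # 40/640 > 5%
  cm <- toy_cm(counts)
  out <- qc_cells(cm)
  expect_identical(unname(attr(out, "kept")), c(TRUE, FALSE, FALSE))

  # over-complex cell: > 6000 detected genes
  big <- matrix(0L, 7000, 2)
  big[1:1500, 1] <- 1L
  big[1:6500, 2] <- 1L
  out2 <- qc_cells(toy_cm(big))
  expect_identical(unname(attr(out2, "kept")), c(TRUE, FALSE))

  # idempotence
  once <- qc_cells(cm)
  twice <- qc_cells(once)
  expect_identical(once$counts, twice$counts)
})

test_that("cell QC matches the generator's planted expectations exactly", {
  sim <- simulate_counts(counts_gen_params(
    n_genes = 1500, n_cells_a = 60, n_cells_b = 60, base_meanlog = log(1),
    n_deg = 0, n_high_mito_cells = 4, n_low_gene_cells = 4), seed = 5)
  out <- qc_cells(sim$cm)
  expect_identical(attr(out, "kept"), sim$truth$qc_keep)
})

test_that("gene QC keeps genes whose best per-batch mean exceeds 0.1", {
  counts <- rbind(zero = c(0L, 0L, 0L, 0L),
                  weak = c(1L, 0L, 0L, 0L),     # batch means 0.25... split below
                  strong = c(1L, 1L, 2L, 1L))
  # batches: b1 = cells 1:2, b2 = cells 3:4 -> weak has means {0.5, 0}
  cm <- toy_cm(counts, batch = c("b1", "b1", "b2", "b2"))
  out <- qc_genes(cm)
  expect_identical(unname(attr(out, "kept")), c(FALSE, TRUE, TRUE))

  # brute-force oracle on a random matrix
  set.seed(2)
  rc <- matrix(stats::rpois(3000, 0.12), 150, 20)
  rcm <- toy_cm(rc, batch = rep(c("x", "y"), each = 10))
  kept <- attr(qc_genes(rcm), "kept")
  oracle <- apply(rc, 1, function(g)
    max(mean(g[1:10]), mean(g[11:20])) > 0.1)
  expect_identical(unname(kept), unname(oracle))

  # idempotence
  once <- qc_genes(rcm)
  expect_identical(once$counts, qc_genes(once)$counts)
})

test_that("toy DEG p-values equal the exact rank-sum enumeration", {
  set.seed(3)
  # tie-free construction: distinct counts per gene, equal column depths so
  # normalization preserves distinctness and wilcox.test stays on its exact
  # path
  counts <- t(vapply(1:10, function(g) sample(1:30, 6), integer(6)))
  filler <- max(colSums(counts)) + 50L - colSums(counts)
  counts <- rbind(counts, filler)
  rownames(counts) <- sprintf("G%02d", seq_len(nrow(counts)))
  cm <- toy_cm(counts, group = rep(c("a", "b"), each = 3))
  degs <- find_degs(cm, cm$cells$group == "a", cm$cells$group == "b")
  nm <- normalize_cp10k(cm)$log1p
  for (g in 1:10) {
    w <- wilcox.test(nm[g, 1:3], nm[g, 4:6], exact = TRUE, correct = FALSE)
    expect_equal(degs$p_value[g], w$p.value, tolerance = 1e-12)
  }
  expect_true(all(degs$adjusted_p >= degs$p_value))
  expect_identical(degs$deg_flag,
                   degs$adjusted_p < 0.05 & degs$log2_fold_change > 0.25)
  expect_error(find_degs(cm, 1:2, 3:6), "at least 3")
})

test_that("planted DEGs are recovered with few false flags", {
  sim <- simulate_counts(counts_gen_params(
    n_genes = 800, n_cells_a = 100, n_cells_b = 100, n_deg = 40), seed = 6)
  cm <- qc_genes(sim$cm)
  degs <- find_degs(cm, cm$cells$group == "a", cm$cells$group == "b")
  planted <- degs$gene %in% sim$truth$deg_genes
  expect_gte(mean(degs$deg_flag[planted]), 0.9)
  expect_lte(mean(degs$deg_flag[!planted]), 0.01)
})

test_that("null count matrices produce essentially no DEG flags", {
  flags <- vapply(1:5, function(s) {
    sim <- simulate_counts(counts_gen_params(
      n_genes = 500, n_cells_a = 50, n_cells_b = 50, n_deg = 0),
      seed = 800 + s)
    cm <- qc_genes(sim$cm)
    sum(find_degs(cm, cm$cells$group == "a", cm$cells$group == "b")$deg_flag)
  }, 0L)
  expect_lte(sum(flags), 1L)
})

test_that("binomial enrichment equals brute-force tail summation", {
  sets <- gene_set_collection(list(T1 = sprintf("g%d", 1:50)))
  background <- sprintf("g%d", 1:1000)
  # DEG fraction equals the background fraction -> not enriched
  degs <- c(sprintf("g%d", 1:5), sprintf("g%d", 101:195))  # k=5, n=100
  res <- binomial_enrichment(degs, sets, background)
  expect_equal(res$p_value, brute_binom_tail(5, 100, 0.05), tolerance = 1e-12)
  expect_gt(res$p_value, 0.5)
  expect_false(res$enriched_flag)

  # closed form: every DEG in the term, K/N = 0.5, n = 10
  sets2 <- gene_set_collection(list(T = sprintf("g%d", 1:500)))
  res2 <- binomial_enrichment(sprintf("g%d", 1:10), sets2, background)
  expect_equal(res2$p_value, 0.5^10, tolerance = 1e-15)

  # grid agreement to 1e-12 and monotonicity in k
  set.seed(7)
  for (i in 1:25) {
    N <- sample(400:2000, 1); K <- sample(5:100, 1)
    n <- sample(10:min(150, N - K), 1); k <- sample(0:min(n, K), 1)
    bg <- sprintf("g%d", 1:N)
    st <- gene_set_collection(list(T = bg[1:K]))
    dg <- c(if (k > 0) bg[1:k], if (n > k) bg[(K + 1):(K + n - k)])
    r <- binomial_enrichment(dg, st, bg)
    expect_equal(r$p_value, brute_binom_tail(k, n, K / N), tolerance = 1e-12)
  }
  p_by_k <- vapply(0:20, function(k) {
    bg <- sprintf("g%d", 1:500)
    st <- gene_set_collection(list(T = bg[1:50]))
    dg <- c(if (k > 0) bg[1:k], if (k < 20) bg[51:(50 + 20 - k)])
    binomial_enrichment(dg, st, bg)$p_value
  }, 0)
  expect_true(all(diff(p_by_k) < 0))

  expect_error(binomial_enrichment("zzz", sets, background), "subset")
  expect_warning(
    binomial_enrichment(sprintf("g%d", 1:5),
                        gene_set_collection(list(T = "not_there")),
                        background),
    "skipped")
})

test_that("Fisher enrichment equals the hypergeometric tail with BH control", {
  bg <- sprintf("g%d", 1:100)
  st <- gene_set_collection(list(T = bg[1:10]))       # K = 10
  dg <- c(bg[1:8], bg[11:12])                          # k = 8, n = 10
  r <- fisher_enrichment_fdr(dg, st, bg)
  expect_equal(r$p_value, brute_hyper_tail(8, 10, 10, 100), tolerance = 1e-12)
  # cross-check against fisher.test one-sided
  ft <- stats::fisher.test(matrix(c(8, 2, 2, 88), 2), alternative = "greater")
  expect_equal(r$p_value, ft$p.value, tolerance = 1e-9)

  # k = 0: empty overlap is never enriched
  r0 <- fisher_enrichment_fdr(bg[21:30], st, bg)
  expect_equal(r0$p_value, 1)
  expect_false(r0$enriched_flag)

  set.seed(8)
  for (i in 1:25) {
    N <- sample(300:1500, 1); K <- sample(5:80, 1)
    n <- sample(5:min(120, N - K), 1); k <- sample(0:min(n, K), 1)
    bg <- sprintf("g%d", 1:N)
    st <- gene_set_collection(list(T = bg[1:K]))
    dg <- c(if (k > 0) bg[1:k], if (n > k) bg[(K + 1):(K + n - k)])
    r <- fisher_enrichment_fdr(dg, st, bg)
    expect_equal(r$p_value, brute_hyper_tail(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and dominates raw p-values", {
  set.seed(9)
  p <- stats::runif(200)^2
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("null gene sets stay below the false-enrichment budget", {
  set.seed(10)
  m <- 40
  bg <- sprintf("g%d", 1:800)
  false_flags <- vapply(1:20, function(s) {
    dg <- sample(bg, 60)   # random "DEGs": every term is null
    sets <- gene_set_collection(
      stats::setNames(lapply(1:m, function(i) sample(bg, 30)),
                      sprintf("T%02d", 1:m)))
    sum(fisher_enrichment_fdr(dg, sets, bg)$enriched_flag)
  }, 0L)
  expect_lte(mean(false_flags), 0.05 * m)
  expect_lte(mean(false_flags / m), 0.05)
})

test_that("enrichment correlation follows the Pearson formula and mask", {
  prof <- cbind(a = c(1e-5, 0.2, 0.6, 0.01, 0.9),
                b = c(1e-4, 0.3, 0.5, 0.05, 0.8))
  r <- enrichment_correlation(prof)
  expect_equal(r$r["a", "a"], 1)
  x <- -log10(prof)
  manual <- sum((x[, 1] - mean(x[, 1])) * (x[, 2] - mean(x[, 2]))) /
    sqrt(sum((x[, 1] - mean(x[, 1]))^2) * sum((x[, 2] - mean(x[, 2]))^2))
  expect_equal(r$r["a", "b"], manual, tolerance = 1e-12)
  expect_identical(r$mask["a", "b"], manual > 0.7)

  neg <- enrichment_correlation(cbind(a = c(1, 2, 3), b = c(-1, -2, -3)),
                                transform = "raw")
  expect_equal(neg$r["a", "b"], -1)

  expect_warning(
    z <- enrichment_correlation(cbind(a = c(0.5, 0.5, 0.5), b = c(0.1, 0.2, 0.3))),
    "zero-variance")
  expect_true(is.na(z$r["a", "b"]))
})

test_that("count matrices load from MTX triples and dense CSV", {
  set.seed(30)
  m <- matrix(stats::rpois(60, 1), 10, 6,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("c%d", 1:6)))
  d <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(d, "m.mtx"))
  writeLines(rownames(m), file.path(d, "genes.tsv"))
  writeLines(colnames(m), file.path(d, "barcodes.tsv"))
  ann <- data.frame(cell_id = rev(colnames(m)),
                    batch = rep(c("b1", "b2"), 3))
  utils::write.csv(ann, file.path(d, "cells.csv"), row.names = FALSE)
  cm <- read_count_matrix(file.path(d, "m.mtx"),
                          cell_annotations = file.path(d, "cells.csv"))
  expect_equal(unname(cm$counts), unname(m))
  expect_identical(rownames(cm$counts), rownames(m))
  # annotations realigned to barcode order
  expect_identical(cm$cells$batch,
                   ann$batch[match(colnames(m), ann$cell_id)])

  dense <- file.path(d, "m.csv")
  utils::write.csv(data.frame(gene = rownames(m), m, check.names = FALSE),
                   dense, row.names = FALSE)
  cm2 <- read_count_matrix(dense)
  expect_equal(unname(cm2$counts), unname(m))
})

test_that("GMT files round-trip through the collection", {
  sets <- gene_set_collection(list(A = c("g1", "g2"), B = c("g3", "g4", "g5")),
                              names = c(A = "first", B = "second"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(back$ids, sets$ids)
  expect_identical(back$genes, sets$genes)
  expect_identical(unname(back$names["A"]), "first")
  writeLines("BAD\tonly-description", f)
  expect_error(read_gmt(f), "line 1")
})
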