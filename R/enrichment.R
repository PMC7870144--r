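#' Construct a gene-by-cell count matrix with annotations
#'
#' @param counts non-negative integer matrix, genes in rows (rownames = gene
#'   ids), cells in columns (colnames = cell ids).
#' @param cells data.frame of per-cell annotations (one row per column of
#'   `counts`); typically `species`, `line`, `day`, `batch`, `cluster`,
#'   `group`.
#' @param genes optional data.frame of per-gene annotations; a logical
#'   `mito` column flags mitochondrial genes (default: gene id starts with
#'   "MT-").
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cells, genes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
  if (nrow(cells) != ncol(counts))
    stop("cell annotations do not match the number of columns")
  if (is.null(genes)) genes <- data.frame(row.names = rownames(counts))
  if (nrow(genes) != nrow(counts))
    stop("gene annotations do not match the number of rows")
  if (is.null(genes$mito)) genes$mito <- startsWith(rownames(counts), "MT-")
  rownames(cells) <- colnames(counts)
  rownames(genes) <- rownames(counts)
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

subset_count_matrix <- function(cm, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  if (is.null(cells)) cells <- seq_len(ncol(cm$counts))
  count_matrix(cm$counts[genes, cells, drop = FALSE],
               cm$cells[cells, , drop = FALSE],
               cm$genes[genes, , drop = FALSE])
}

#' Read a count matrix from MatrixMarket or dense CSV
#'
#' MatrixMarket input (`.mtx`) follows the common triple convention: the
#' sparse matrix plus one-gene-per-line and one-barcode-per-line sidecar
#' files. Dense CSV input has gene ids in the first column and cell ids as
#' the header.
#'
#' @param path `.mtx` or `.csv` counts file.
#' @param genes_path,barcodes_path sidecar files (MTX only); default to
#'   `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @param cell_annotations optional CSV with one row per cell (matched to
#'   barcodes by a `cell_id` column when present, otherwise by order),
#'   carrying species/line/day/batch/cluster labels.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, genes_path = NULL, barcodes_path = NULL,
                              cell_annotations = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path, warn = FALSE)
    colnames(m) <- readLines(barcodes_path, warn = FALSE)
  } else {
    d <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
  }
  storage.mode(m) <- "integer"
  cells <- if (is.null(cell_annotations))
    data.frame(row.names = colnames(m))
  else {
    ann <- utils::read.csv(cell_annotations)
    if ("cell_id" %in% names(ann))
      ann <- ann[match(colnames(m), ann$cell_id), , drop = FALSE]
    ann
  }
  count_matrix(m, cells)
}

#' Cell-level quality control
#'
#' Retains cells with `min_genes` to `max_genes` genes detected (count > 0)
#' and a mitochondrial transcript fraction of at most `max_mito_frac`.
#'
#' @param cm a [count_matrix()].
#' @param min_genes,max_genes detected-gene bounds (default 500 and 6000).
#' @param max_mito_frac maximal mitochondrial fraction (default 0.05).
#' @return the filtered [count_matrix()], with attribute `kept` (logical per
#'   input cell).
#' @export
qc_cells <- function(cm, min_genes = 500, max_genes = 6000,
                     max_mito_frac = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  detected <- colSums(cm$counts > 0)
  total <- colSums(cm$counts)
  mito <- cm$genes$mito
  mito_counts <- if (any(mito)) colSums(cm$counts[mito, , drop = FALSE]) else 0
  mito_frac <- ifelse(total > 0, mito_counts / total, 0)
  keep <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  out <- subset_count_matrix(cm, cells = which(keep))
  attr(out, "kept") <- keep
  out
}

#' Gene-level quality control
#'
#' Keeps a gene iff its mean count (sum of counts over the cells of a batch
#' divided by the number of cells in that batch) exceeds `min_batch_mean` in
#' at least one batch.
#'
#' @param cm a [count_matrix()]; `cm$cells$batch` must be present.
#' @param min_batch_mean threshold (default 0.1).
#' @return the filtered [count_matrix()], with attribute `kept`.
#' @export
qc_genes <- function(cm, min_batch_mean = 0.1) {
  stopifnot(inherits(cm, "count_matrix"))
  batch <- cm$cells$batch
  if (is.null(batch)) stop("cells need a batch annotation")
  ub <- unique(batch)
  sizes <- table(batch)
  if (any(sizes == 0)) stop("empty batch")
  bm <- vapply(ub, function(b)
    rowSums(cm$counts[, batch == b, drop = FALSE]) / sum(batch == b),
    numeric(nrow(cm$counts)))
  keep <- apply(as.matrix(bm), 1, max) > min_batch_mean
  out <- subset_count_matrix(cm, genes = which(keep))
  attr(out, "kept") <- keep
  out
}

#' Counts-per-10k log1p normalization
#'
#' @param cm a [count_matrix()].
#' @return list: `log1p` (log1p of counts-per-10k), `cp10k`.
#' @export
normalize_cp10k <- function(cm) {
  tot <- colSums(cm$counts)
  tot[tot == 0] <- 1
  cp10k <- sweep(cm$counts, 2, tot, "/") * 1e4
  list(log1p = log1p(cp10k), cp10k = cp10k)
}

#' Wilcoxon differential expression between two cell groups
#'
#' Expression is normalized to counts-per-10k and log1p-transformed; each
#' gene is tested with a two-sided Wilcoxon rank-sum test (exact enumeration
#' for tiny groups, normal approximation with tie correction otherwise), and
#' p-values are Benjamini-Hochberg adjusted. The log2 fold change is
#' `log2(mean_a + eps) - log2(mean_b + eps)` on the counts-per-10k scale.
#' A gene is flagged as differentially expressed (higher in `group_a`) when
#' the adjusted p is below `alpha` and the log2 fold change exceeds
#' `lfc_cutoff`.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b cell selections (column indices, names, or logical).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_cutoff log2 fold-change cutoff (default 0.25).
#' @param eps pseudo-count on normalized means (default 1e-9).
#' @return data.frame: `gene`, `log2_fold_change`, `p_value`, `adjusted_p`,
#'   `deg_flag`.
#' @export
find_degs <- function(cm, group_a, group_b, alpha = 0.05,
                      lfc_cutoff = 0.25, eps = 1e-9) {
  stopifnot(inherits(cm, "count_matrix"))
  ia <- cell_index(cm, group_a); ib <- cell_index(cm, group_b)
  if (length(ia) < 3L || length(ib) < 3L)
    stop("both groups need at least 3 cells")
  nm <- normalize_cp10k(cm)
  xa <- nm$log1p[, ia, drop = FALSE]
  xb <- nm$log1p[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(cm$counts)), function(g)
    mann_whitney(xa[g, ], xb[g, ])$p_value, 0)
  mean_a <- rowMeans(nm$cp10k[, ia, drop = FALSE])
  mean_b <- rowMeans(nm$cp10k[, ib, drop = FALSE])
  lfc <- log2(mean_a + eps) - log2(mean_b + eps)
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(cm$counts),
             log2_fold_change = lfc,
             p_value = p,
             adjusted_p = adj,
             deg_flag = adj < alpha & lfc > lfc_cutoff,
             row.names = NULL)
}

cell_index <- function(cm, sel) {
  if (is.logical(sel)) which(sel)
  else if (is.character(sel)) match(sel, colnames(cm$counts))
  else as.integer(sel)
}

#' Gene-set collection
#'
#' @param genes named list of character vectors (term id -> member genes).
#' @param names optional named character vector of term descriptions.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(genes, names = NULL) {
  stopifnot(is.list(genes), !is.null(base::names(genes)))
  if (any(lengths(genes) == 0L)) stop("gene sets must be non-empty")
  genes <- lapply(genes, unique)
  if (is.null(names))
    names <- stats::setNames(base::names(genes), base::names(genes))
  structure(list(ids = base::names(genes), names = names, genes = genes),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-separated: id, description, genes...).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("GMT parse error at line %d: need id, description and >= 1 gene",
                 bad[1]))
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  genes <- lapply(parts, function(x) x[-(1:2)])
  names(genes) <- ids
  gene_set_collection(genes, stats::setNames(desc, ids))
}

#' Write gene sets in GMT format
#'
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets$ids, function(id)
    paste(c(id, sets$names[[id]], sets$genes[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

enrichment_table <- function(degs, sets, background) {
  degs <- unique(degs); background <- unique(background)
  if (!all(degs %in% background))
    stop("DEG list must be a subset of the background")
  n <- length(degs); N <- length(background)
  rows <- lapply(sets$ids, function(id) {
    members <- intersect(sets$genes[[id]], background)
    K <- length(members)
    if (K == 0L) {
      warning(sprintf("term %s has no background genes; skipped", id))
      return(NULL)
    }
    k <- length(intersect(degs, members))
    data.frame(term_id = id, term_name = unname(sets$names[[id]]),
               k = k, n = n, K = K, N = N, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact-binomial gene-set enrichment
#'
#' For each term, tests whether the fraction of differentially expressed
#' genes falling in the term exceeds the background fraction: one-sided
#' upper-tail p = P(X >= k), X ~ Binomial(n, K/N). A term is enriched when
#' p < `alpha` (raw p, as used for flat GO-term screens); BH-adjusted values
#' are also reported.
#'
#' @param degs character vector of DEG ids (must lie in `background`).
#' @param sets a [gene_set_collection()].
#' @param background character vector of background gene ids.
#' @param alpha enrichment cutoff on the raw p (default 0.05).
#' @return data.frame: `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `fdr`, `enriched_flag`.
#' @export
binomial_enrichment <- function(degs, sets, background, alpha = 0.05) {
  tab <- enrichment_table(degs, sets, background)
  if (is.null(tab)) return(NULL)
  tab$p_value <- stats::pbinom(tab$k - 1, tab$n, tab$K / tab$N,
                               lower.tail = FALSE)
  tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  tab$enriched_flag <- tab$p_value < alpha
  tab
}

#' One-sided Fisher gene-set enrichment with FDR control
#'
#' For each term, the one-sided Fisher exact test on the 2x2 table
#' (in-term/out-of-term x DEG/non-DEG), i.e. the hypergeometric upper tail
#' P(X >= k); Benjamini-Hochberg FDR across terms; a term is enriched when
#' fdr < `alpha`.
#'
#' @inheritParams binomial_enrichment
#' @param alpha enrichment cutoff on the FDR (default 0.05).
#' @return data.frame as in [binomial_enrichment()].
#' @export
fisher_enrichment_fdr <- function(degs, sets, background, alpha = 0.05) {
  tab <- enrichment_table(degs, sets, background)
  if (is.null(tab)) return(NULL)
  tab$p_value <- stats::phyper(tab$k - 1, tab$K, tab$N - tab$K, tab$n,
                               lower.tail = FALSE)
  tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  tab$enriched_flag <- tab$fdr < alpha
  tab
}

#' Pearson correlation of enrichment profiles
#'
#' Correlates per-term enrichment profiles (columns = groups, rows = terms)
#' across groups, by default on the -log10 p scale, and masks pairs whose
#' correlation exceeds `threshold`.
#'
#' @param profiles numeric matrix of per-term p-values (terms x groups) or,
#'   with `transform = "raw"`, arbitrary enrichment values.
#' @param transform `"neglog10"` (default) or `"raw"`.
#' @param threshold mask cutoff (default 0.7).
#' @return list: `r` (correlation matrix; NA for zero-variance profiles,
#'   with a warning), `mask` (`r > threshold`).
#' @export
enrichment_correlation <- function(profiles, transform = c("neglog10", "raw"),
                                   threshold = 0.7) {
  transform <- match.arg(transform)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L || nrow(profiles) < 3L)
    stop("need >= 2 profiles of length >= 3")
  x <- if (transform == "neglog10") -log10(profiles) else profiles
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance profile(s): correlations set to NA")
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  list(r = r, mask = r > threshold)
}
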