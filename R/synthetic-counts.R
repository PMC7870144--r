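#' Parameters for the synthetic count-matrix generator
#'
#' Negative-binomial counts with per-gene base means, a planted set of
#' differentially expressed genes at a common fold change in group "a",
#' per-cell mitochondrial fractions and optional planted quality-control
#' violations (low-complexity cells, high-mitochondrial cells,
#' over-complex cells).
#'
#' Planted DEGs are drawn from genes whose base mean is at least
#' `deg_min_base` so that they survive the batch-mean gene filter.
#'
#' @param n_genes number of genes (mitochondrial genes included).
#' @param n_cells_a,n_cells_b cells per group.
#' @param base_meanlog,base_sdlog lognormal base-mean parameters.
#' @param dispersion negative-binomial size parameter.
#' @param n_deg number of planted DEGs (0 for a null matrix).
#' @param deg_fold fold elevation of planted DEGs in group "a".
#' @param deg_min_base minimum base mean of planted DEGs.
#' @param n_mito_genes number of "MT-" genes.
#' @param mito_frac mitochondrial fraction of normal cells.
#' @param n_high_mito_cells cells planted at `high_mito_frac`.
#' @param high_mito_frac planted violating fraction (default 0.10).
#' @param n_low_gene_cells cells planted below the detected-genes floor.
#' @param low_gene_target detected genes of a planted low cell (default 300).
#' @param batches batch labels cycled over cells.
#' @return list of class `counts_gen_params`.
#' @export
counts_gen_params <- function(n_genes = 2000, n_cells_a = 200, n_cells_b = 200,
                              base_meanlog = log(0.5), base_sdlog = 1,
                              dispersion = 2,
                              n_deg = 100, deg_fold = 4, deg_min_base = 0.2,
                              n_mito_genes = 10, mito_frac = 0.02,
                              n_high_mito_cells = 0, high_mito_frac = 0.10,
                              n_low_gene_cells = 0, low_gene_target = 300,
                              batches = c("b1", "b2")) {
  stopifnot(n_genes > n_mito_genes, n_cells_a > 0, n_cells_b > 0,
            dispersion > 0, deg_fold > 0, n_deg >= 0)
  structure(as.list(environment()), class = "counts_gen_params")
}

#' Generate a ground-truthed synthetic count matrix
#'
#' @param p a [counts_gen_params()].
#' @param seed optional RNG seed.
#' @return list with `cm` (a [count_matrix()]) and `truth`:
#'   `deg_genes`, `base_means`, `qc_keep` (planted expectation per cell),
#'   `high_mito_cells`, `low_gene_cells`.
#' @export
simulate_counts <- function(p = counts_gen_params(), seed = NULL) {
  stopifnot(inherits(p, "counts_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  n_expr <- p$n_genes - p$n_mito_genes
  gene_ids <- c(sprintf("G%04d", seq_len(n_expr)),
                sprintf("MT-%02d", seq_len(p$n_mito_genes)))
  mu <- stats::rlnorm(n_expr, p$base_meanlog, p$base_sdlog)
  eligible <- which(mu >= p$deg_min_base)
  if (p$n_deg > length(eligible))
    stop("not enough genes above deg_min_base to plant the requested DEGs")
  deg_idx <- if (p$n_deg > 0) sort(sample(eligible, p$n_deg)) else integer(0)

  n_cells <- p$n_cells_a + p$n_cells_b
  group <- rep(c("a", "b"), c(p$n_cells_a, p$n_cells_b))
  mu_mat <- matrix(mu, n_expr, n_cells)
  if (length(deg_idx))
    mu_mat[deg_idx, group == "a"] <- mu_mat[deg_idx, group == "a"] * p$deg_fold
  counts <- matrix(stats::rnbinom(n_expr * n_cells, mu = mu_mat,
                                  size = p$dispersion),
                   n_expr, n_cells)

  # planted low-complexity cells: keep only `low_gene_target` gene slots
  low_cells <- if (p$n_low_gene_cells > 0)
    sample(n_cells, p$n_low_gene_cells) else integer(0)
  for (cc in low_cells) {
    keep <- sample(n_expr, p$low_gene_target)
    z <- counts[, cc]
    z[-keep] <- 0L
    z[keep][z[keep] == 0L] <- 1L   # exactly low_gene_target detected genes
    counts[, cc] <- z
  }

  # mitochondrial counts matching a per-cell target fraction
  frac <- rep(p$mito_frac, n_cells)
  high_cells <- if (p$n_high_mito_cells > 0)
    sample(setdiff(seq_len(n_cells), low_cells), p$n_high_mito_cells)
  else integer(0)
  frac[high_cells] <- p$high_mito_frac
  tot <- colSums(counts)
  mito_tot <- round(frac * tot / (1 - frac))
  mito <- vapply(seq_len(n_cells), function(cc) {
    if (mito_tot[cc] == 0) return(integer(p$n_mito_genes))
    as.integer(stats::rmultinom(1, mito_tot[cc], rep(1, p$n_mito_genes)))
  }, integer(p$n_mito_genes))
  counts <- rbind(counts, matrix(mito, nrow = p$n_mito_genes))
  rownames(counts) <- gene_ids
  colnames(counts) <- sprintf("c%04d", seq_len(n_cells))

  cells <- data.frame(group = group,
                      batch = rep_len(p$batches, n_cells),
                      stringsAsFactors = FALSE)
  cm <- count_matrix(counts, cells)

  detected <- colSums(counts > 0)
  mito_frac_real <- colSums(counts[startsWith(gene_ids, "MT-"), , drop = FALSE]) /
    pmax(colSums(counts), 1)
  qc_keep <- rep(TRUE, n_cells)
  qc_keep[low_cells] <- FALSE
  qc_keep[high_cells] <- FALSE
  # construction sanity: planted cells really violate, normal cells really pass
  stopifnot(all(detected[low_cells] < 500),
            all(mito_frac_real[high_cells] > 0.05))
  truth <- list(deg_genes = gene_ids[deg_idx],
                base_means = stats::setNames(mu, gene_ids[seq_len(n_expr)]),
                qc_keep = stats::setNames(qc_keep, colnames(counts)),
                high_mito_cells = colnames(counts)[high_cells],
                low_gene_cells = colnames(counts)[low_cells])
  list(cm = cm, truth = truth)
}

#' Generate gene sets with planted enrichment
#'
#' Builds a gene-set collection over a background: `planted_terms` sets draw
#' `planted_deg_frac` of their members from the supplied DEG list (strong
#' enrichment), the rest are uniform draws from the background (null terms).
#'
#' @param background character vector of background gene ids.
#' @param deg_genes character vector of DEG ids (subset of background).
#' @param n_terms total number of terms.
#' @param term_size genes per term.
#' @param planted_terms number of enriched terms.
#' @param planted_deg_frac fraction of a planted term drawn from DEGs.
#' @param seed optional RNG seed.
#' @return list: `sets` (a [gene_set_collection()]), `truth` (ids of
#'   planted terms).
#' @export
generate_gene_sets <- function(background, deg_genes, n_terms = 20,
                               term_size = 50, planted_terms = 2,
                               planted_deg_frac = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(planted_terms <= n_terms, term_size <= length(background))
  ids <- sprintf("TERM%03d", seq_len(n_terms))
  genes <- vector("list", n_terms)
  names(genes) <- ids
  for (i in seq_len(n_terms)) {
    if (i <= planted_terms && length(deg_genes) > 0) {
      k <- min(round(planted_deg_frac * term_size), length(deg_genes))
      genes[[i]] <- unique(c(sample(deg_genes, k),
                             sample(setdiff(background, deg_genes),
                                    term_size - k)))
    } else {
      genes[[i]] <- sample(background, term_size)
    }
  }
  list(sets = gene_set_collection(genes),
       truth = ids[seq_len(planted_terms)])
}
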