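#' Demo study configuration
#'
#' Builds a complete configuration for a synthetic two-group study
#' (ape = pooled chimpanzee/bonobo lines vs human lines) exercising every
#' stage: morphology cohorts over differentiation days, patch-clamp
#' recordings (passive properties, action-potential families, spontaneous
#' EPSCs) and a count matrix with planted differential expression and
#' gene-set enrichment. All thresholds default to the study values
#' (DEG adjusted p < 0.05 and log2 FC > 0.25; enrichment p/FDR < 0.05;
#' correlation mask 0.7; cell QC 500-6000 genes and 5% mitochondrial
#' fraction; gene QC batch mean > 0.1).
#'
#' @param seed integer seed driving every stage.
#' @param scale `"small"` (default) or `"tiny"` (fast smoke-test sizes).
#' @return a named list (`study_config`).
#' @export
demo_study_config <- function(seed = 1, scale = c("small", "tiny")) {
  scale <- match.arg(scale)
  tiny <- scale == "tiny"
  config <- list(
    seed = as.integer(seed),
    group_map = list(ape = c("ape_line1", "ape_line2"),
                     human = c("human_line1", "human_line2")),
    morphology = list(
      days = if (tiny) c(7, 35) else c(7, 14, 21, 35),
      n_per_line_day = if (tiny) 3L else 6L,
      n_batches = 2L,
      sholl_step = 10, min_primary = 5,
      # early growth advantage of the ape lines, gone by d21
      group_scale = list(ape = c(`7` = 1.4, `14` = 1.4, `21` = 1, `35` = 1),
                         human = c(`7` = 1, `14` = 1, `21` = 1, `35` = 1))),
    ephys = list(
      days = if (tiny) c(14, 35) else c(7, 14, 21, 35),
      n_per_group_day = if (tiny) 2L else 3L,
      epsc_duration = if (tiny) 20 else 60,
      rs_range = c(12, 20), rcell_range = c(300, 900),
      ccell_range = c(15, 45), vrmp_range = c(-80, -70)),
    enrichment = list(
      n_genes = if (tiny) 1200L else 1500L,
      n_cells = if (tiny) 40L else 80L,
      n_deg = if (tiny) 40L else 80L,
      deg_fold = 4,
      n_terms = 20L, term_size = 40L, planted_terms = 2L),
    thresholds = list(deg_alpha = 0.05, deg_lfc = 0.25,
                      binom_alpha = 0.05, fisher_fdr = 0.05,
                      cor_threshold = 0.7))
  class(config) <- c("study_config", "list")
  config
}

#' Read a study configuration from YAML
#'
#' Fields present in the file override the [demo_study_config()] defaults.
#'
#' @param path YAML file.
#' @return a `study_config` list.
#' @export
read_study_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- demo_study_config(seed = user$seed %||% 1)
  merge_rec <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_rec(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  merge_rec(config, user)
}

#' Per-day, per-group summary of a metric with group contrasts
#'
#' For every (day, group) cell: n, mean, median, SD, SEM; for every day on
#' which both groups are observed, the two-group contrast (Mann-Whitney U or
#' Welch t).
#'
#' @param df data.frame with columns `day`, `group` and the metric column.
#' @param value_col metric column name (default `"value"`).
#' @param test `"mann_whitney"` (default) or `"welch_t"`.
#' @return data.frame: one row per (day, group) with summary statistics and,
#'   on the first group's row of each testable day, `p`, `stars`.
#' @export
summarize_metric <- function(df, value_col = "value",
                             test = c("mann_whitney", "welch_t")) {
  test <- match.arg(test)
  stopifnot(all(c("day", "group", value_col) %in% names(df)))
  df <- df[!is.na(df[[value_col]]), , drop = FALSE]
  groups <- sort(unique(df$group))
  days <- sort(unique(df$day))
  rows <- list()
  for (d in days) {
    dd <- df[df$day == d, , drop = FALSE]
    p <- NA_real_
    present <- intersect(groups, unique(dd$group))
    if (length(present) >= 2L) {
      va <- dd[[value_col]][dd$group == present[1]]
      vb <- dd[[value_col]][dd$group == present[2]]
      ok <- if (test == "welch_t") length(va) >= 2 && length(vb) >= 2
      else length(va) >= 1 && length(vb) >= 1
      if (ok) {
        cmp <- if (test == "mann_whitney") mann_whitney(va, vb)
        else welch_t(va, vb)
        p <- cmp$p_value
      }
    }
    for (g in present) {
      v <- dd[[value_col]][dd$group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, group = g, n = length(v),
        mean = mean(v), median = stats::median(v),
        sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)),
        p = if (g == present[1]) p else NA_real_,
        stars = if (g == present[1]) significance_stars(p) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- study stages ------------------------------------------------------

run_morphology_stage <- function(config, log_fn) {
  mc <- config$morphology
  records <- list()
  # a batch is one differentiation experiment covering all lines and species
  for (batch in seq_len(mc$n_batches)) {
    batch_scale <- stats::runif(1, 0.8, 1.2)
    for (group in names(config$group_map)) {
      for (line in config$group_map[[group]]) {
        for (day in mc$days) {
          gs <- mc$group_scale[[group]][as.character(day)] %||% 1
          params <- morph_gen_params(species_scale = unname(gs),
                                     batch_scale = batch_scale)
          for (i in seq_len(mc$n_per_line_day)) {
            id <- sprintf("%s_b%d_d%d_%02d", line, batch, day, i)
            gen <- generate_morphology(params, day = day, cell_id = id,
                                       metadata = list(species = group,
                                                       line = line,
                                                       batch = sprintf("batch%d", batch)))
            records[[length(records) + 1L]] <-
              morphometry(gen$morphology, step = mc$sholl_step,
                          min_primary_length = mc$min_primary)
          }
        }
      }
    }
  }
  tab <- morphometry_table(records)
  cells <- tab$cells
  log_fn("morphology: traced cells", nrow(cells))
  cells_np <- cells[is.na(cells$polarity_class) |
                      cells$polarity_class != "unipolar", , drop = FALSE]
  log_fn("morphology: after excluding unipolar cells", nrow(cells_np))
  norm <- batch_normalize(data.frame(cell_id = cells_np$cell_id,
                                     group = cells_np$species,
                                     batch = cells_np$batch,
                                     value = cells_np$axon_length))
  cells_np$normalized_axon_length <- norm$normalized

  tests <- list()
  for (metric in c("total_neurite_length", "normalized_axon_length",
                   "dendrite_length", "sholl_total")) {
    s <- summarize_metric(data.frame(day = cells_np$day,
                                     group = cells_np$species,
                                     value = cells_np[[metric]]))
    s$metric <- metric
    tests[[metric]] <- s
  }
  list(cells = cells_np, tests = do.call(rbind, tests))
}

# planted maturation rules for the synthetic ephys cohort: spiking capacity
# rises with day, with the human lines lagging at early time points
planted_ap_max <- function(day, group) {
  lag <- if (group == "human" && day <= 21) 0.35 else 1
  round(min(30, max(0, (day - 3) * 0.8)) * lag)
}

planted_epsc_rate <- function(day, group) {
  if (day < 14) return(0)
  lag <- if (group == "human" && day <= 28) 0.3 else 1
  0.1 + 0.02 * (day - 14) * lag
}

run_ephys_stage <- function(config, log_fn) {
  ec <- config$ephys
  sp <- step_protocol()
  rp <- ramp_protocol()
  rows <- list()
  for (group in names(config$group_map)) {
    for (day in ec$days) {
      for (i in seq_len(ec$n_per_group_day)) {
        p <- membrane_sim_params(
          rcell = stats::runif(1, ec$rcell_range[1], ec$rcell_range[2]),
          ccell = stats::runif(1, ec$ccell_range[1], ec$ccell_range[2]),
          rs = stats::runif(1, ec$rs_range[1], ec$rs_range[2]),
          vrmp = stats::runif(1, ec$vrmp_range[1], ec$vrmp_range[2]))
        fam <- simulate_step_family(p, sp)
        ramp <- simulate_voltage_clamp(p, rp)
        pp <- estimate_passive_properties(fam$traces, ramp$trace,
                                          sp, rp, rs = p$rs)
        ap_true <- max(0L, planted_ap_max(day, group) +
                         sample(-2:2, 1))   # cell-to-cell variability
        n_steps <- 10L
        counts <- pmax(0L, round(seq(0, ap_true, length.out = n_steps)))
        cc <- simulate_current_clamp(p, step_currents = seq(20, 200, length.out = n_steps),
                                     n_spikes = counts)
        aps <- count_aps(cc$traces)
        ep <- epsc_train_params(rate = planted_epsc_rate(day, group),
                                duration = ec$epsc_duration)
        tr <- simulate_epsc_trace(ep)
        det <- detect_epscs(tr$trace)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = sprintf("%s_d%d_%02d", group, day, i),
          group = group, day = day,
          vrmp = pp$vrmp, rcell = pp$rcell, ccell = pp$ccell, tau = pp$tau,
          max_aps = aps$max_count,
          epsc_freq = det$frequency,
          log10_epsc_freq = det$log10_frequency,
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, rows)
  log_fn("ephys: recorded cells", nrow(cells))
  tests <- list()
  for (metric in c("max_aps", "log10_epsc_freq")) {
    s <- summarize_metric(data.frame(day = cells$day, group = cells$group,
                                     value = cells[[metric]]),
                          test = "welch_t")
    s$metric <- metric
    tests[[metric]] <- s
  }
  anova_rows <- lapply(c("vrmp", "rcell", "ccell", "tau", "max_aps"),
                       function(metric) {
    a <- two_way_anova(cells[[metric]], cells$day, cells$group,
                       names = c("day", "species"))
    a$metric <- metric
    a
  })
  list(cells = cells, tests = do.call(rbind, tests),
       anova = do.call(rbind, anova_rows))
}

run_enrichment_stage <- function(config, log_fn) {
  nc <- config$enrichment
  th <- config$thresholds
  profiles <- list(); deg_tabs <- list(); bin_tabs <- list(); fish_tabs <- list()
  qc_rows <- list()
  for (group in names(config$group_map)) {
    sim <- simulate_counts(counts_gen_params(
      n_genes = nc$n_genes, n_cells_a = nc$n_cells, n_cells_b = nc$n_cells,
      base_meanlog = log(1),    # depth chosen so healthy cells clear the QC floor
      n_deg = nc$n_deg, deg_fold = nc$deg_fold,
      n_high_mito_cells = 2L, n_low_gene_cells = 2L, low_gene_target = 100L))
    cm <- qc_cells(sim$cm)
    cm <- qc_genes(cm)
    qc_rows[[group]] <- data.frame(
      group = group,
      cells_in = ncol(sim$cm$counts), cells_kept = ncol(cm$counts),
      genes_in = nrow(sim$cm$counts), genes_kept = nrow(cm$counts))
    log_fn(sprintf("enrichment (%s): cells kept", group), ncol(cm$counts))
    degs <- find_degs(cm, cm$cells$group == "a", cm$cells$group == "b",
                      alpha = th$deg_alpha, lfc_cutoff = th$deg_lfc)
    degs$group <- group
    deg_tabs[[group]] <- degs
    background <- rownames(cm$counts)
    gs <- generate_gene_sets(background, degs$gene[degs$deg_flag],
                             n_terms = nc$n_terms, term_size = nc$term_size,
                             planted_terms = nc$planted_terms)
    bt <- binomial_enrichment(degs$gene[degs$deg_flag], gs$sets, background,
                              alpha = th$binom_alpha)
    ft <- fisher_enrichment_fdr(degs$gene[degs$deg_flag], gs$sets, background,
                                alpha = th$fisher_fdr)
    bt$group <- group; ft$group <- group
    bin_tabs[[group]] <- bt; fish_tabs[[group]] <- ft
    profiles[[group]] <- stats::setNames(bt$p_value, bt$term_id)
  }
  pm <- do.call(cbind, profiles)
  corr <- enrichment_correlation(pm, threshold = th$cor_threshold)
  corr_df <- as.data.frame(as.table(corr$r))
  names(corr_df) <- c("group_a", "group_b", "pearson_r")
  corr_df$above_threshold <- as.vector(corr$mask)
  list(qc = do.call(rbind, qc_rows),
       degs = do.call(rbind, deg_tabs),
       binomial = do.call(rbind, bin_tabs),
       fisher = do.call(rbind, fish_tabs),
       correlation = corr_df)
}

#' Run the full synthetic study
#'
#' Executes morphology -> group statistics, electrophysiology -> group
#' statistics and the count-matrix QC/DEG/enrichment stage on synthetic
#' cohorts drawn under `config$seed`, and assembles the figure-level summary
#' tables. Deterministic given the configuration.
#'
#' @param config a `study_config` (see [demo_study_config()],
#'   [read_study_config()]).
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV along with a JSON provenance block and a plain-text log.
#' @return object of class `study_report`: `tables` (named list of
#'   data.frames), `log` (character), `provenance`.
#' @export
run_study <- function(config = demo_study_config(), out_dir = NULL) {
  set.seed(config$seed)
  log_lines <- character(0)
  log <- function(msg, n = NULL) {
    line <- if (is.null(n)) msg else sprintf("%s: %d", msg, n)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  morph <- stage("morphology", function() run_morphology_stage(config, log))
  ephys <- stage("ephys", function() run_ephys_stage(config, log))
  enr <- stage("enrichment", function() run_enrichment_stage(config, log))

  tables <- list(
    morphology_cells = morph$cells,
    morphology_tests = morph$tests,
    ephys_cells = ephys$cells,
    ephys_tests = ephys$tests,
    ephys_anova = ephys$anova,
    enrichment_qc = enr$qc,
    deg_table = enr$degs,
    enrichment_binomial = enr$binomial,
    enrichment_fisher = enr$fisher,
    enrichment_correlation = enr$correlation)

  provenance <- list(
    seed = config$seed,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("neuromaturation")))
  report <- structure(list(tables = tables, log = log_lines,
                           provenance = provenance),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report to disk
#'
#' One CSV per table, `provenance.json` and `log.txt`. Output is
#' deterministic: rerunning with the same configuration and seed reproduces
#' the table files byte for byte.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n tables:\n")
  for (nm in names(x$tables))
    cat(sprintf("  - %s (%d rows)\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}
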