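# End-to-end runner: simulate -> screen test -> integrate -> high-content
# score -> enrichment -> IHC, writing TSV/JSON outputs plus a provenance
# echo of the resolved configuration and seed.

sk_log <- function(con, level, fmt, ..., log_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] < levels[[log_level]]) return(invisible())
  line <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  writeLines(line, con)
  invisible()
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on simulated inputs
#'
#' Executes every stage on synthetic data with planted ground truth:
#' simulates `n_screens` pooled screens and analyses each (NB test +
#' alpha-RRA + hit calling), integrates the hit tables into core resistance
#' genes, simulates and scores an arrayed high-content screen, runs gene-set
#' and TF enrichment on a simulated DE list, and computes IHC H-scores. All
#' randomness derives from `config$seed`; re-running with the same config
#' reproduces every output byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param n_screens Number of pooled screens to simulate and integrate.
#' @param screen_cfg A [screen_sim_config()] template (its seed is
#'   reassigned per screen from `config$seed`).
#' @param cell_cfg A [cell_sim_config()] for the arrayed stage (seed
#'   reassigned likewise).
#' @param log_level "debug", "info" or "warn".
#' @return Invisibly, a list with the main stage results and `manifest`
#'   (paths of all files written).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         n_screens = 6L,
                         screen_cfg = screen_sim_config(n_genes = 200L,
                                                        n_resistant = 10L),
                         cell_cfg = cell_sim_config(cells_per_well = 500L),
                         log_level = "info") {
  sk_assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  n_screens <- sk_check_count(n_screens, "n_screens")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  add <- function(p) manifest[length(manifest) + 1L] <<- p

  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  add(write_config(config, file.path(out_dir, "config.yaml")))
  sk_log(con, "info", "resolved config echoed; seed = %d", config$seed,
         log_level = log_level)

  # --- pooled screens ------------------------------------------------------
  hit_tables <- list()
  for (i in seq_len(n_screens)) {
    scfg <- screen_cfg
    scfg$seed <- config$seed + i
    sim <- simulate_pooled_screen(scfg)
    res <- screen_test(sim$counts, sim$sheet,
                       within_config_seed(config, config$seed + 1000L + i))
    dir_i <- file.path(out_dir, sprintf("screen_%02d", i))
    dir.create(dir_i, showWarnings = FALSE)
    add(write_tsv(fmt_num(res$guide_stats), file.path(dir_i, "guide_stats.tsv")))
    add(write_tsv(fmt_num(res$gene_stats), file.path(dir_i, "gene_stats.tsv")))
    add(write_tsv(fmt_num(res$hits), file.path(dir_i, "hits.tsv")))
    hit_tables[[sprintf("screen_%02d", i)]] <- res$hits
    sk_log(con, "info", "screen %d: %d hits", i, sum(res$hits$hit),
           log_level = log_level)
  }

  # --- integration ---------------------------------------------------------
  core <- count_recurrence(hit_tables, config$recurrence_min)
  add(write_tsv(core, file.path(out_dir, "core_genes.tsv")))
  hist <- recurrence_histogram(core)
  jsonlite::write_json(as.list(hist), file.path(out_dir, "recurrence_histogram.json"),
                       auto_unbox = TRUE)
  add(file.path(out_dir, "recurrence_histogram.json"))
  sk_log(con, "info", "integration: %d core genes", sum(core$core),
         log_level = log_level)

  # --- arrayed high-content screen ----------------------------------------
  ccfg <- cell_cfg
  ccfg$seed <- config$seed + 2000L
  if (identical(names(ccfg$planted_fold), "NTC"))
    ccfg$planted_fold <- c(NTC = 1, GENE_A = 1.5, GENE_B = 1.0)
  design <- expand.grid(perturbation = names(ccfg$planted_fold),
                        treatment = c("vehicle", "drug"),
                        stringsAsFactors = FALSE)
  design$plate <- "P1"
  design$well <- sprintf("W%02d", seq_len(nrow(design)))
  cells <- simulate_cell_table(ccfg, design)
  add(write_cell_table(fmt_num(cells), file.path(out_dir, "cells.csv")))
  arr <- score_arrayed_screen(cells, config)
  add(write_tsv(fmt_num(arr$wells), file.path(out_dir, "well_summaries.tsv")))
  add(write_tsv(fmt_num(arr$gene_table), file.path(out_dir, "arrayed_gene_table.tsv")))
  jsonlite::write_json(list(p = arr$fisher$p,
                            table = as.data.frame(arr$fisher$table)),
                       file.path(out_dir, "fisher.json"), auto_unbox = TRUE,
                       digits = NA)
  add(file.path(out_dir, "fisher.json"))
  sk_log(con, "info", "arrayed screen: %d translocation hits",
         sum(unique(arr$gene_table[, c("perturbation", "yap_hit")])$yap_hit,
             na.rm = TRUE), log_level = log_level)

  # --- enrichment ----------------------------------------------------------
  n_bg <- 2000L
  labels <- sim_gene_labels(n_bg)
  sets <- structure(lapply(1:10, function(i)
    labels[((i - 1) * 100 + 1):(i * 100)]), class = c("gene_sets", "list"))
  names(sets) <- sprintf("SET_%02d", 1:10)
  de <- simulate_de_lists(n_bg, sets, active_sets = "SET_01",
                          enrichment_factor = 5, seed = config$seed + 3000L)
  enr <- hypergeometric_enrich(de$de, sets, de$background)
  add(write_tsv(fmt_num(enr), file.path(out_dir, "enrichment.tsv")))
  tf <- infer_tf_activity(de$de, sets, de$background)
  add(write_tsv(fmt_num(tf), file.path(out_dir, "tf_activity.tsv")))
  sk_log(con, "info", "enrichment: top set %s (p = %.3g)",
         enr$set[which.min(enr$p)], min(enr$p), log_level = log_level)

  # --- IHC -----------------------------------------------------------------
  ihc_a <- lapply(1:5, function(i)
    simulate_ihc(c(0.5, 0.3, 0.15, 0.05), seed = config$seed + 4000L + i))
  ihc_b <- lapply(1:5, function(i)
    simulate_ihc(c(0.1, 0.2, 0.3, 0.4), seed = config$seed + 4100L + i))
  scores_a <- vapply(ihc_a, h_score, 0)
  scores_b <- vapply(ihc_b, h_score, 0)
  ihc_tab <- data.frame(
    sample = c(sprintf("A%d", 1:5), sprintf("B%d", 1:5)),
    group = rep(c("A", "B"), each = 5),
    compartment = "nucleus",
    h_score = c(scores_a, scores_b))
  add(write_tsv(fmt_num(ihc_tab), file.path(out_dir, "ihc_scores.tsv")))
  cmp <- compare_groups(scores_a, scores_b)
  jsonlite::write_json(list(p = cmp, n_a = 5, n_b = 5),
                       file.path(out_dir, "ihc_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "ihc_comparison.json"))
  sk_log(con, "info", "IHC comparison p = %.3g", cmp, log_level = log_level)
  add(log_path)

  invisible(list(hit_tables = hit_tables, core = core, arrayed = arr,
                 enrichment = enr, tf = tf, ihc = ihc_tab,
                 manifest = manifest))
}

# Declared pipeline outputs for a run with n_screens screens (used by the
# smoke test to compare against the written manifest).
#' Declared output files of [run_pipeline()]
#' @param out_dir Output directory.
#' @param n_screens Number of screens in the run.
#' @return Character vector of expected file paths.
#' @export
pipeline_manifest <- function(out_dir, n_screens = 6L) {
  per_screen <- unlist(lapply(seq_len(n_screens), function(i)
    file.path(out_dir, sprintf("screen_%02d", i),
              c("guide_stats.tsv", "gene_stats.tsv", "hits.tsv"))))
  c(file.path(out_dir, "config.yaml"), per_screen,
    file.path(out_dir, c("core_genes.tsv", "recurrence_histogram.json",
                         "cells.csv", "well_summaries.tsv",
                         "arrayed_gene_table.tsv", "fisher.json",
                         "enrichment.tsv", "tf_activity.tsv",
                         "ihc_scores.tsv", "ihc_comparison.json", "run.log")))
}

# copy of a config with a different seed (keeps validation)
within_config_seed <- function(config, seed) {
  config$seed <- as.integer(seed %% .Machine$integer.max)
  config
}

# Deterministic text formatting for numeric columns so identical runs give
# byte-identical files across platforms.
fmt_num <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  df
}
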