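# Generators for every input the pipeline consumes, with planted ground
# truth: NB-distributed pooled-screen counts, per-cell high-content tables,
# DE gene lists with planted set membership, and IHC intensity distributions.

#' Configuration for the pooled-screen simulator
#'
#' Counts follow a negative-binomial model with variance mu + phi * mu^2
#' (phi = `dispersion`, shared across guides). Guides of resistant genes are
#' enriched under drug by `resistant_log2fc` on the log2 scale; a fraction
#' `dropout_fraction` of those guides is inert (no enrichment), mimicking
#' inefficient guides.
#'
#' @param n_genes Number of genes in the library.
#' @param guides_per_gene Guides per gene.
#' @param n_resistant Number of planted resistance genes.
#' @param resistant_log2fc Planted log2 enrichment of effective guides of
#'   resistant genes under drug.
#' @param mean_depth Expected sequencing count per guide.
#' @param dispersion NB overdispersion phi; variance = mu + phi * mu^2.
#' @param n_replicates Replicates per arm (vehicle and drug).
#' @param dropout_fraction Probability that a guide of a resistant gene has
#'   no effect.
#' @param seed Integer seed.
#' @return A validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 1000L, guides_per_gene = 5L,
                              n_resistant = 20L, resistant_log2fc = 2,
                              mean_depth = 300, dispersion = 0.1,
                              n_replicates = 2L, dropout_fraction = 0,
                              seed = 1L) {
  cfg <- list(
    n_genes = sk_check_count(n_genes, "n_genes"),
    guides_per_gene = sk_check_count(guides_per_gene, "guides_per_gene"),
    n_resistant = sk_check_count(n_resistant, "n_resistant", min = 0L),
    resistant_log2fc = as.numeric(resistant_log2fc),
    mean_depth = sk_check_pos(mean_depth, "mean_depth"),
    dispersion = sk_check_pos(dispersion, "dispersion"),
    n_replicates = sk_check_count(n_replicates, "n_replicates"),
    dropout_fraction = sk_check_prob(dropout_fraction, "dropout_fraction",
                                     open_low = FALSE, open_high = FALSE),
    seed = sk_check_count(seed, "seed", min = -.Machine$integer.max)
  )
  sk_assert(cfg$n_resistant <= cfg$n_genes, "n_resistant must not exceed n_genes")
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Simulate a pooled CRISPR resistance screen
#'
#' Generates a plasmid sample plus vehicle and drug replicate counts.
#' Vehicle counts are NB(mu, phi); drug counts are NB(mu * 2^delta, phi)
#' where delta is the planted per-guide log2 fold change (nonzero only for
#' effective guides of resistant genes).
#'
#' @param cfg A `screen_sim_config`.
#' @return List with elements `counts` (a [guide_counts()] object), `sheet`
#'   (a [sample_sheet()]), and `truth` (resistant gene set and per-guide true
#'   log2 fold change).
#' @export
simulate_pooled_screen <- function(cfg) {
  sk_assert(inherits(cfg, "screen_sim_config"), "cfg must be a screen_sim_config")
  with_seed(cfg$seed, {
    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    guides <- paste0(rep(genes, each = cfg$guides_per_gene), "_g",
                     rep(seq_len(cfg$guides_per_gene), cfg$n_genes))
    g2g <- stats::setNames(rep(genes, each = cfg$guides_per_gene), guides)
    n_guides <- length(guides)

    resistant <- if (cfg$n_resistant > 0L)
      sample(genes, cfg$n_resistant) else character(0)
    delta <- numeric(n_guides)
    in_res <- g2g %in% resistant
    effective <- in_res &
      stats::runif(n_guides) >= cfg$dropout_fraction
    delta[effective] <- cfg$resistant_log2fc

    size <- 1 / cfg$dispersion
    mu <- cfg$mean_depth
    draw <- function(mu_vec) stats::rnbinom(n_guides, mu = mu_vec, size = size)
    samples <- list(plasmid = draw(rep(mu, n_guides)))
    for (r in seq_len(cfg$n_replicates))
      samples[[paste0("vehicle_", r)]] <- draw(rep(mu, n_guides))
    for (r in seq_len(cfg$n_replicates))
      samples[[paste0("drug_", r)]] <- draw(mu * 2^delta)
    counts <- do.call(cbind, samples)
    rownames(counts) <- guides

    sheet <- sample_sheet(
      sample_id = colnames(counts),
      cell_line = "SIM",
      arm = c("plasmid", rep("vehicle", cfg$n_replicates),
              rep("drug", cfg$n_replicates)),
      replicate = c(1L, seq_len(cfg$n_replicates), seq_len(cfg$n_replicates)),
      drug_name = c(NA, rep(NA, cfg$n_replicates),
                    rep("drug", cfg$n_replicates)))

    list(counts = guide_counts(counts, g2g),
         sheet = sheet,
         truth = list(resistant_genes = sort(resistant),
                      guide_log2fc = stats::setNames(delta, guides)))
  })
}

#' Configuration for the per-cell high-content simulator
#'
#' Emulates a segmented-image per-cell table: lognormal cell areas, border
#' flags, lognormal cytoplasmic intensities, and nuclear intensities set by
#' the planted Nuc:Cyt fold per perturbation. Pathway-marker channels are
#' multiplicatively suppressed under drug (`drug_effect`) unless the
#' perturbation rescues them (`marker_rescue`).
#'
#' @param cells_per_well Cells simulated per well.
#' @param baseline_nuc_cyt True Nuc:Cyt ratio of the translocation channel in
#'   NTC cells.
#' @param planted_fold Named numeric: true Nuc:Cyt fold over NTC per
#'   perturbation ("NTC" is forced to 1).
#' @param intensity_noise_cv Coefficient of variation of the multiplicative
#'   intensity noise.
#' @param border_fraction Probability a cell touches the image border.
#' @param area_meanlog,area_sdlog Lognormal cell-area parameters
#'   (area in square microns).
#' @param cyt_baseline Baseline cytoplasmic intensity (arbitrary units).
#' @param drug_effect Named numeric: multiplicative intensity change of each
#'   channel under drug (translocation channel "yap" should be 1; ratios are
#'   scale-free).
#' @param marker_rescue Named list: perturbation -> character vector of
#'   channels exempt from `drug_effect` (planted pathway preservation).
#' @param seed Integer seed.
#' @return A validated list of class `cell_sim_config`.
#' @export
cell_sim_config <- function(cells_per_well = 2000L, baseline_nuc_cyt = 1.0,
                            planted_fold = c(NTC = 1),
                            intensity_noise_cv = 0.3,
                            border_fraction = 0.1,
                            area_meanlog = log(400), area_sdlog = 0.35,
                            cyt_baseline = 1000,
                            drug_effect = c(yap = 1, pakt = 0.25, perk = 0.25),
                            marker_rescue = list(), seed = 1L) {
  sk_assert(length(names(planted_fold)) == length(planted_fold),
            "planted_fold must be a named vector")
  planted_fold["NTC"] <- 1
  cfg <- list(
    cells_per_well = sk_check_count(cells_per_well, "cells_per_well"),
    baseline_nuc_cyt = sk_check_pos(baseline_nuc_cyt, "baseline_nuc_cyt"),
    planted_fold = planted_fold,
    intensity_noise_cv = sk_check_pos(intensity_noise_cv, "intensity_noise_cv"),
    border_fraction = sk_check_prob(border_fraction, "border_fraction",
                                    open_low = FALSE, open_high = FALSE),
    area_meanlog = as.numeric(area_meanlog),
    area_sdlog = sk_check_pos(area_sdlog, "area_sdlog"),
    cyt_baseline = sk_check_pos(cyt_baseline, "cyt_baseline"),
    drug_effect = drug_effect,
    marker_rescue = marker_rescue,
    seed = sk_check_count(seed, "seed", min = -.Machine$integer.max)
  )
  sk_assert(all(cfg$planted_fold > 0), "planted_fold values must be positive")
  sk_assert("yap" %in% names(drug_effect), "drug_effect must include the 'yap' channel")
  class(cfg) <- "cell_sim_config"
  cfg
}

#' Simulate a per-cell high-content table
#'
#' @param cfg A `cell_sim_config`.
#' @param design Data.frame with columns plate, well, perturbation,
#'   treatment ("vehicle" or "drug"); one row per well.
#' @return Data.frame of cell records (one row per cell) in the cell-table
#'   CSV schema.
#' @export
simulate_cell_table <- function(cfg, design) {
  sk_assert(inherits(cfg, "cell_sim_config"), "cfg must be a cell_sim_config")
  need <- c("plate", "well", "perturbation", "treatment")
  sk_assert(all(need %in% names(design)), "design needs plate, well, perturbation, treatment")
  sk_assert(all(design$treatment %in% c("vehicle", "drug")),
            "treatment must be 'vehicle' or 'drug'")
  unknown <- setdiff(unique(design$perturbation), names(cfg$planted_fold))
  sk_assert(length(unknown) == 0L,
            sprintf("unknown perturbation label(s): %s", paste(unknown, collapse = ", ")))

  channels <- names(cfg$drug_effect)
  sdlog <- sqrt(log(1 + cfg$intensity_noise_cv^2))
  with_seed(cfg$seed, {
    per_well <- lapply(seq_len(nrow(design)), function(i) {
      w <- design[i, ]
      n <- cfg$cells_per_well
      rec <- data.frame(
        plate = w$plate, well = w$well,
        perturbation = w$perturbation, treatment = w$treatment,
        area = stats::rlnorm(n, cfg$area_meanlog, cfg$area_sdlog),
        is_border = stats::runif(n) < cfg$border_fraction)
      rescued <- cfg$marker_rescue[[w$perturbation]]
      for (ch in channels) {
        eff <- if (w$treatment == "drug" && !(ch %in% rescued))
          cfg$drug_effect[[ch]] else 1
        cyt <- stats::rlnorm(n, log(cfg$cyt_baseline), sdlog) * eff
        ratio <- if (ch == "yap")
          cfg$baseline_nuc_cyt * cfg$planted_fold[[w$perturbation]] else 1
        nuc <- cyt * ratio * stats::rlnorm(n, 0, sdlog)
        rec[[paste0("nuclear_mean.", ch)]] <- nuc
        rec[[paste0("cytoplasm_mean.", ch)]] <- cyt
      }
      rec
    })
    do.call(rbind, per_well)
  })
}

#' Simulate differential-expression gene lists with planted set enrichment
#'
#' Each background gene enters the DE list independently; membership
#' probability is multiplied by `enrichment_factor` for genes belonging to
#' any active set (capped at 1). With `enrichment_factor = 1` the draw is
#' exchangeable across genes, so downstream hypergeometric p-values are
#' honestly calibrated.
#'
#' @param n_genes Background size; genes are labelled g00001, g00002, ...
#' @param gene_sets A `gene_sets` collection (members drawn from the same
#'   label space).
#' @param active_sets Character vector of set names with planted enrichment.
#' @param enrichment_factor Multiplier (>= 0) on the DE membership
#'   probability of active-set genes.
#' @param base_rate Baseline DE membership probability (default 0.1).
#' @param seed Integer seed.
#' @return List with `de` (DE gene list) and `background`.
#' @export
simulate_de_lists <- function(n_genes, gene_sets, active_sets = character(0),
                              enrichment_factor = 1, base_rate = 0.1,
                              seed = 1L) {
  n_genes <- sk_check_count(n_genes, "n_genes")
  sk_assert(n_genes >= 1L, "empty background")
  sk_assert(all(active_sets %in% names(gene_sets)),
            "active_sets must name sets in the collection")
  sk_check_prob(base_rate, "base_rate")
  sk_assert(enrichment_factor >= 0, "enrichment_factor must be >= 0")
  background <- sim_gene_labels(n_genes)
  active_genes <- unique(unlist(gene_sets[active_sets], use.names = FALSE))
  prob <- rep(base_rate, n_genes)
  prob[background %in% active_genes] <- pmin(1, base_rate * enrichment_factor)
  with_seed(seed, {
    de <- background[stats::runif(n_genes) < prob]
    list(de = de, background = background)
  })
}

#' Gene labels used by the DE-list simulator
#' @param n_genes Number of labels.
#' @return Character vector g00001 ... g<n>.
#' @export
sim_gene_labels <- function(n_genes) sprintf("g%05d", seq_len(n_genes))

#' Simulate an IHC intensity-category distribution
#'
#' Draws `n_cells` tumour cells from the given category probabilities
#' (intensity 0, 1+, 2+, 3+) and converts counts to percentages.
#'
#' @param prob Numeric length 4, category probabilities summing to 1.
#' @param n_cells Number of cells drawn.
#' @param compartment "nucleus" or "cytoplasm".
#' @param seed Integer seed.
#' @return An [intensity_distribution()].
#' @export
simulate_ihc <- function(prob, n_cells = 1000L, compartment = "nucleus",
                         seed = 1L) {
  sk_assert(length(prob) == 4L && all(prob >= 0), "prob must be 4 non-negative values")
  sk_assert(abs(sum(prob) - 1) < 1e-9, "category probabilities must sum to 1")
  n_cells <- sk_check_count(n_cells, "n_cells")
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_cells, prob))
    pct <- 100 * counts / n_cells
    intensity_distribution(compartment, pct[1], pct[2], pct[3], pct[4])
  })
}
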