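# Pooled-screen statistics: median-of-ratios normalization, per-guide
# negative-binomial enrichment/depletion tests, and alpha-RRA gene-level
# aggregation with a permutation p-value.

#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors against the geometric-mean
#' pseudo-reference over guides with all-positive counts (the normalization
#' DESeq-family tools use for count matrices).
#'
#' @param x A [guide_counts()] object or a non-negative integer matrix.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "guide_counts")) x$counts else x
  sk_assert(is.matrix(m) && all(m >= 0), "counts must be a non-negative matrix")
  zero_sample <- colSums(m) == 0
  sk_assert(!any(zero_sample),
            sprintf("sample(s) with all-zero counts: %s",
                    paste(colnames(m)[zero_sample], collapse = ", ")))
  pos <- rowSums(m > 0) == ncol(m)
  sk_assert(any(pos), "no guide has positive counts in every sample")
  lm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm)                      # log geometric mean per guide
  sf <- exp(apply(lm - ref, 2, stats::median))
  stats::setNames(sf, colnames(m))
}

# Moment-matched NB parameters for a sum of independent NB counts sharing a
# base mean mu0 but scaled by per-sample size factors s_j:
#   mean = mu0 * sum(s), var = sum(mu0 s_j + phi mu0^2 s_j^2).
# The sum of NBs is not NB; we use the NB with matched first two moments.
nb_sum_params <- function(mu0, phi, s) {
  mu_sum <- mu0 * sum(s)
  var_sum <- sum(mu0 * s + phi * mu0^2 * s^2)
  phi_sum <- max((var_sum - mu_sum) / mu_sum^2, 1e-8)
  list(mu = mu_sum, size = 1 / phi_sum)
}

#' Per-guide negative-binomial enrichment test
#'
#' For each guide, compares the summed drug count with its expectation under
#' the vehicle arm. Counts are normalized by median-of-ratios size factors;
#' the NB dispersion is a single method-of-moments estimate pooled across
#' guides from the vehicle replicates (floored at 1e-8). `p_enrich` is the
#' upper-tail NB probability of the observed drug sum, `p_deplete` the lower
#' tail; `u_enrich`/`u_deplete` are normalized mid-ranks of the p-values in
#' (0, 1], the substrate for alpha-RRA.
#'
#' @param x A [guide_counts()] object.
#' @param sheet A [sample_sheet()] matching the count-matrix columns.
#' @param sizes Optional precomputed size factors (default: recomputed).
#' @return Data.frame with one row per guide: guide, gene, log2fc, p_enrich,
#'   p_deplete, u_enrich, u_deplete.
#' @export
guide_test <- function(x, sheet, sizes = NULL) {
  validate_screen_inputs(x, sheet)
  m <- x$counts
  if (is.null(sizes)) sizes <- size_factors(m)
  sk_assert(all(colnames(m) %in% names(sizes)), "sizes must cover all samples")
  veh <- sheet$sample_id[sheet$arm == "vehicle"]
  drg <- sheet$sample_id[sheet$arm == "drug"]

  norm <- sweep(m, 2, sizes[colnames(m)], "/")
  veh_mean <- rowMeans(norm[, veh, drop = FALSE])
  drg_mean <- rowMeans(norm[, drg, drop = FALSE])
  log2fc <- log2((drg_mean + 0.5) / (veh_mean + 0.5))

  # Pooled method-of-moments dispersion from vehicle replicates:
  # regression-through-origin of (sample variance - mean) on mean^2.
  phi <- 1e-8
  if (length(veh) >= 2L) {
    vm <- norm[, veh, drop = FALSE]
    gm <- rowMeans(vm)
    gv <- apply(vm, 1, stats::var)
    keep <- gm > 0
    phi <- max(sum(gv[keep] - gm[keep]) / sum(gm[keep]^2), 1e-8)
  }

  s_drg <- sizes[drg]
  drug_sum <- rowSums(m[, drg, drop = FALSE])
  p_enrich <- p_deplete <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    par <- nb_sum_params(max(veh_mean[i], 1e-8), phi, s_drg)
    p_enrich[i] <- stats::pnbinom(drug_sum[i] - 1, mu = par$mu,
                                  size = par$size, lower.tail = FALSE)
    p_deplete[i] <- stats::pnbinom(drug_sum[i], mu = par$mu, size = par$size)
  }

  n <- nrow(m)
  data.frame(guide = rownames(m),
             gene = unname(x$guide_to_gene),
             log2fc = unname(log2fc),
             p_enrich = p_enrich,
             p_deplete = p_deplete,
             u_enrich = rank(p_enrich) / n,   # mid-rank ties
             u_deplete = rank(p_deplete) / n,
             row.names = NULL)
}

# Alpha-RRA gene score: with sorted normalized ranks u_(1) <= ... <= u_(k)
# and selection flags (guide-level p < alpha), rho is the minimum over
# selected order positions j of P(Beta(j, k - j + 1) <= u_(j)); 1 if no
# guide is selected.
rra_rho <- function(u, selected, alpha) {
  k <- length(u)
  o <- order(u)
  u <- u[o]; selected <- selected[o]
  if (!any(selected)) return(1)
  j <- which(selected)
  min(stats::pbeta(u[j], j, k - j + 1))
}

#' Alpha-RRA gene-level aggregation
#'
#' Aggregates per-guide normalized ranks into a gene-level rho score and a
#' permutation p-value, separately for the enriched and depleted directions.
#' Only guides whose directional p-value is below `alpha` contribute
#' evidence; genes whose guides all fail the threshold get rho = 1. The null
#' distribution of rho is obtained by randomly reassigning guide ranks to
#' genes (preserving guides-per-gene): `n_permutations` Monte-Carlo draws per
#' guide-count stratum, with p = (b + 1) / (B + 1), or exhaustive enumeration
#' of all C(N, k) assignments (p = b / B) when `exhaustive = TRUE`.
#'
#' @param stats_df Output of [guide_test()].
#' @param alpha Guide-level selection threshold in (0, 1).
#' @param n_permutations Monte-Carlo permutations B.
#' @param seed Integer seed for the permutation draw.
#' @param exhaustive If TRUE, enumerate all assignments (feasible for toy
#'   universes only).
#' @return Data.frame with one row per gene per direction: gene, n_guides,
#'   rho, p_perm, fdr, gene_log2fc (median guide log2fc), direction.
#' @export
rra_aggregate <- function(stats_df, alpha = 0.05, n_permutations = 10000L,
                          seed = 1L, exhaustive = FALSE) {
  sk_check_prob(alpha, "alpha")
  n_permutations <- sk_check_count(n_permutations, "n_permutations")
  need <- c("guide", "gene", "log2fc", "p_enrich", "p_deplete",
            "u_enrich", "u_deplete")
  sk_assert(all(need %in% names(stats_df)), "stats_df must come from guide_test()")

  genes <- unique(stats_df$gene)
  gidx <- split(seq_len(nrow(stats_df)), stats_df$gene)[genes]
  med_fc <- vapply(gidx, function(i) stats::median(stats_df$log2fc[i]), 0)

  one_direction <- function(p, u, direction, seed_dir) {
    sel <- p < alpha
    rho <- vapply(gidx, function(i) rra_rho(u[i], sel[i], alpha), 0)
    ks <- lengths(gidx)
    p_perm <- numeric(length(genes))
    if (exhaustive) {
      for (k in unique(ks)) {
        idx <- utils::combn(length(u), k)
        null_rho <- apply(idx, 2, function(i) rra_rho(u[i], sel[i], alpha))
        for (g in which(ks == k))
          p_perm[g] <- sum(null_rho <= rho[g] + 1e-12) / length(null_rho)
      }
    } else {
      with_seed(seed_dir, {
        for (k in unique(ks)) {
          null_rho <- vapply(seq_len(n_permutations), function(b) {
            i <- sample.int(length(u), k)
            rra_rho(u[i], sel[i], alpha)
          }, 0)
          for (g in which(ks == k))
            p_perm[g] <- (sum(null_rho <= rho[g] + 1e-12) + 1) /
              (n_permutations + 1)
        }
      })
    }
    data.frame(gene = genes, n_guides = unname(ks), rho = unname(rho),
               p_perm = p_perm, fdr = stats::p.adjust(p_perm, "BH"),
               gene_log2fc = unname(med_fc), direction = direction,
               row.names = NULL)
  }

  rbind(one_direction(stats_df$p_enrich, stats_df$u_enrich, "enriched", seed),
        one_direction(stats_df$p_deplete, stats_df$u_deplete, "depleted",
                      seed + 1L))
}

#' Call pooled-screen resistance hits
#'
#' A gene is a resistance hit when it is enriched under drug with linear
#' fold change at or above `fc_cutoff` and permutation p below `p_cutoff`
#' (defaults: fold change >= 2, p < 0.005). The full enriched-direction
#' table is returned with a boolean `hit` flag.
#'
#' @param genes Output of [rra_aggregate()].
#' @param fc_cutoff Linear fold-change cut-off (default 2).
#' @param p_cutoff Permutation p cut-off (default 0.005).
#' @param fc_strict If TRUE, require fold change strictly > `fc_cutoff`.
#' @return Data.frame of enriched-direction gene statistics plus `fc`
#'   (linear fold change) and `hit`.
#' @export
call_screen_hits <- function(genes, fc_cutoff = 2, p_cutoff = 0.005,
                             fc_strict = FALSE) {
  sk_check_pos(fc_cutoff, "fc_cutoff")
  sk_check_prob(p_cutoff, "p_cutoff")
  tab <- genes[genes$direction == "enriched", , drop = FALSE]
  tab$fc <- 2^tab$gene_log2fc
  pass_fc <- if (isTRUE(fc_strict)) tab$fc > fc_cutoff else tab$fc >= fc_cutoff
  tab$hit <- pass_fc & tab$p_perm < p_cutoff
  rownames(tab) <- NULL
  tab
}

#' Run the full pooled-screen comparison
#'
#' Convenience wrapper: size factors, per-guide NB test, alpha-RRA
#' aggregation and hit calling in one step.
#'
#' @param x A [guide_counts()] object.
#' @param sheet A [sample_sheet()].
#' @param config A [pipeline_config()].
#' @return An object of class `screen_result` with components `guide_stats`,
#'   `gene_stats`, `hits`, `size_factors` and `config`.
#' @export
screen_test <- function(x, sheet, config = pipeline_config()) {
  sk_assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  sf <- size_factors(x)
  gs <- guide_test(x, sheet, sf)
  agg <- rra_aggregate(gs, alpha = config$rra_alpha,
                       n_permutations = config$n_permutations,
                       seed = config$seed)
  hits <- call_screen_hits(agg, config$fc_cutoff, config$p_cutoff,
                           config$fc_strict)
  structure(list(guide_stats = gs, gene_stats = agg, hits = hits,
                 size_factors = sf, config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Pooled-screen result: %d guides, %d genes, %d resistance hits\n",
              nrow(x$guide_stats), length(unique(x$hits$gene)), sum(x$hits$hit)))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, n = 10L, ...) {
  hits <- object$hits[object$hits$hit, , drop = FALSE]
  hits <- hits[order(hits$p_perm, -hits$fc), , drop = FALSE]
  cat(sprintf("%d resistance hits (fc >= %g, p < %g); top %d:\n",
              nrow(hits), object$config$fc_cutoff, object$config$p_cutoff,
              min(n, nrow(hits))))
  print(utils::head(hits[, c("gene", "n_guides", "rho", "p_perm", "fdr", "fc")], n),
        row.names = FALSE)
  invisible(object)
}
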