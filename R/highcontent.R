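# Arrayed high-content screen scoring: per-cell quality filtering,
# nuclear:cytoplasmic ratios, two-point plate normalization anchored on the
# non-targeting control, translocation hit calling, and the rank-sum /
# Fisher statistics used around them.

#' Quality-filter segmented cells
#'
#' Removes border-touching cells, then, within each well, removes cells in
#' the lowest and highest area deciles (floor(n * 0.1) cells trimmed at each
#' end; ties broken by stable input order).
#'
#' @param cells Cell-record data.frame (cell-table schema).
#' @return The retained subset, same columns.
#' @export
filter_cells <- function(cells) {
  if (nrow(cells) == 0L) {
    warning("empty cell table")
    return(cells)
  }
  cells <- cells[!cells$is_border, , drop = FALSE]
  if (nrow(cells) == 0L) return(cells)
  well_id <- paste(cells$plate, cells$well, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(cells)), well_id), function(i) {
    n <- length(i)
    if (n < 10L)
      warning(sprintf("well with only %d non-border cells", n))
    trim <- floor(n * 0.1)
    if (trim == 0L) return(i)
    o <- order(cells$area[i])            # stable for ties
    i[o][seq.int(trim + 1L, n - trim)]
  }), use.names = FALSE)
  cells[sort(keep), , drop = FALSE]
}

#' Per-cell nuclear:cytoplasmic ratio
#'
#' @param cells Cell-record data.frame.
#' @param channel Channel name (default "yap", the translocation readout).
#' @return Numeric vector, one ratio per cell; NA for cells with
#'   non-positive cytoplasmic signal (excluded rather than clamped).
#' @export
nuc_cyt_ratio <- function(cells, channel = "yap") {
  nuc <- cells[[paste0("nuclear_mean.", channel)]]
  cyt <- cells[[paste0("cytoplasm_mean.", channel)]]
  sk_assert(!is.null(nuc) && !is.null(cyt),
            sprintf("channel '%s' not present in cell table", channel))
  out <- ifelse(cyt > 0, nuc / cyt, NA_real_)
  as.numeric(out)
}

#' Summarise wells after filtering
#'
#' Per well: the median per-cell Nuc:Cyt ratio of the translocation channel
#' and, per channel, the median per-cell mean intensity (average of nuclear
#' and cytoplasmic means) — the statistic fed into two-point normalization.
#'
#' @param cells Filtered cell-record data.frame.
#' @param ratio_channel Translocation channel (default "yap").
#' @return Data.frame: plate, well, perturbation, treatment,
#'   n_cells_retained, nuc_cyt_median and one `intensity.<channel>` column
#'   per channel.
#' @export
summarise_wells <- function(cells, ratio_channel = "yap") {
  sk_assert(nrow(cells) > 0L, "no cells to summarise")
  channels <- cell_channels(cells)
  sk_assert(ratio_channel %in% channels, "ratio channel missing from table")
  ratio <- nuc_cyt_ratio(cells, ratio_channel)
  well_id <- paste(cells$plate, cells$well, sep = "\r")
  rows <- lapply(split(seq_len(nrow(cells)), well_id), function(i) {
    rec <- data.frame(plate = cells$plate[i[1]], well = cells$well[i[1]],
                      perturbation = cells$perturbation[i[1]],
                      treatment = cells$treatment[i[1]],
                      n_cells_retained = length(i),
                      nuc_cyt_median = stats::median(ratio[i], na.rm = TRUE))
    for (ch in channels) {
      m <- (cells[[paste0("nuclear_mean.", ch)]][i] +
              cells[[paste0("cytoplasm_mean.", ch)]][i]) / 2
      rec[[paste0("intensity.", ch)]] <- stats::median(m)
    }
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-point normalization scale from NTC reference wells
#'
#' `ref_max` is the mean well statistic of NTC vehicle wells (maps to 0);
#' `ref_min` the mean of NTC drug wells (maps to -100).
#'
#' @param wells Well summaries from [summarise_wells()].
#' @param stat Column of `wells` holding the statistic (e.g.
#'   "intensity.perk").
#' @param ntc Label of the non-targeting control (default "NTC").
#' @return List of class `two_point_scale` with ref_max and ref_min.
#' @export
two_point_scale <- function(wells, stat, ntc = "NTC") {
  sk_assert(stat %in% names(wells), sprintf("no column '%s' in well table", stat))
  v <- wells$perturbation == ntc & wells$treatment == "vehicle"
  d <- wells$perturbation == ntc & wells$treatment == "drug"
  sk_assert(any(v) && any(d), "need >= 1 NTC vehicle and >= 1 NTC drug well")
  ref_max <- mean(wells[[stat]][v])
  ref_min <- mean(wells[[stat]][d])
  sk_assert(ref_max != ref_min, "degenerate assay window: ref_max == ref_min")
  structure(list(ref_max = ref_max, ref_min = ref_min),
            class = "two_point_scale")
}

#' Two-point normalization
#'
#' Affine rescaling anchoring the NTC-vehicle reference at 0 and the
#' NTC-drug reference at -100: normalized(x) =
#' -100 * (ref_max - x) / (ref_max - ref_min). Values above `ref_max` come
#' out positive.
#'
#' @param x Numeric vector of well statistics.
#' @param scale A [two_point_scale()].
#' @return Numeric vector of normalized values.
#' @export
two_point_normalize <- function(x, scale) {
  sk_assert(inherits(scale, "two_point_scale"), "scale must be a two_point_scale")
  -100 * (scale$ref_max - x) / (scale$ref_max - scale$ref_min)
}

#' Call nuclear-translocation hits
#'
#' Per perturbation, the Nuc:Cyt fold change over NTC is the ratio of the
#' perturbation's well medians (averaged across replicate wells) to the mean
#' NTC well median under the same treatment. A perturbation is a hit when
#' the fold change exceeds 1 + `threshold` (default: >20% increase).
#'
#' @param wells Well summaries from [summarise_wells()].
#' @param threshold Fractional increase required (default 0.20).
#' @param treatment Which arm to evaluate (default "drug").
#' @param cells Optional filtered cell table; if given, a two-sided Wilcoxon
#'   rank-sum p comparing per-cell ratios of the perturbation vs NTC is
#'   reported.
#' @param ntc Non-targeting control label.
#' @return Data.frame: perturbation, fold_change_over_ntc, yap_hit,
#'   wilcoxon_p (NA unless `cells` supplied).
#' @export
call_yap_hits <- function(wells, threshold = 0.20, treatment = "drug",
                          cells = NULL, ntc = "NTC") {
  sk_check_pos(threshold, "threshold")
  w <- wells[wells$treatment == treatment, , drop = FALSE]
  ntc_rows <- w$perturbation == ntc
  sk_assert(any(ntc_rows),
            sprintf("no %s wells under treatment '%s'", ntc, treatment))
  ref <- mean(w$nuc_cyt_median[ntc_rows])
  perts <- setdiff(unique(w$perturbation), ntc)
  ratio_by_pert <- NULL
  if (!is.null(cells)) {
    cc <- cells[cells$treatment == treatment, , drop = FALSE]
    ratio_by_pert <- split(nuc_cyt_ratio(cc), cc$perturbation)
  }
  out <- do.call(rbind, lapply(perts, function(p) {
    fold <- mean(w$nuc_cyt_median[w$perturbation == p]) / ref
    pw <- NA_real_
    if (!is.null(ratio_by_pert) && !is.null(ratio_by_pert[[p]]))
      pw <- wilcoxon_rank_sum(ratio_by_pert[[p]], ratio_by_pert[[ntc]])
    data.frame(perturbation = p, fold_change_over_ntc = fold,
               yap_hit = fold > 1 + threshold, wilcoxon_p = pw)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by enumeration of all rank assignments when both samples have at
#' most 8 observations (valid with ties, via mid-ranks); otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples (non-empty).
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(a, b) {
  sk_assert(length(a) >= 1L && length(b) >= 1L, "both samples must be non-empty")
  sk_assert(all(is.finite(a)) && all(is.finite(b)), "samples must be finite")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  if (n1 <= 8L && n2 <= 8L) {
    # exact: enumerate all C(n, n1) assignments of ranks to sample a
    sets <- utils::combn(n, n1)
    w_null <- colSums(matrix(r[sets], nrow = n1))
    mu <- n1 * (n + 1) / 2
    p <- mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
    return(min(1, p))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)                 # all values identical
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_association <- function(tab) {
  sk_assert(is.matrix(tab) && all(dim(tab) == 2L), "tab must be a 2x2 matrix")
  sk_assert(all(tab >= 0) && all(tab == floor(tab)),
            "cells must be non-negative integers")
  sk_assert(sum(tab) >= 1, "grand total must be >= 1")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Score an arrayed high-content screen
#'
#' Runs the full arrayed-screen analysis: cell filtering, well summaries,
#' two-point normalization of each pathway-marker channel, Nuc:Cyt fold
#' change and translocation hit calling under drug, and a 2x2 Fisher test
#' associating translocation-hit status with pathway preservation
#' (normalized marker effect >= `preserve_cutoff` on any marker channel).
#'
#' @param cells Raw cell-record data.frame.
#' @param config A [pipeline_config()] (supplies yap_hit_threshold).
#' @param ratio_channel Translocation channel (default "yap").
#' @param marker_channels Pathway-marker channels to normalize (default: all
#'   channels except `ratio_channel`).
#' @param preserve_cutoff Normalized effect at or above which a marker
#'   counts as preserved (default -50, half-rescue).
#' @param ntc Non-targeting control label.
#' @return List of class `arrayed_result`: `wells`, `gene_table` (one row
#'   per perturbation x marker with normalized_effect, plus nuc_cyt_fold,
#'   yap_hit, wilcoxon_p), `fisher` (p-value and the underlying 2x2 table).
#' @export
score_arrayed_screen <- function(cells, config = pipeline_config(),
                                 ratio_channel = "yap",
                                 marker_channels = NULL,
                                 preserve_cutoff = -50, ntc = "NTC") {
  kept <- filter_cells(cells)
  wells <- summarise_wells(kept, ratio_channel)
  if (is.null(marker_channels))
    marker_channels <- setdiff(cell_channels(cells), ratio_channel)

  calls <- call_yap_hits(wells, threshold = config$yap_hit_threshold,
                         treatment = "drug", cells = kept, ntc = ntc)

  drug_wells <- wells[wells$treatment == "drug", , drop = FALSE]
  perts <- unique(wells$perturbation)
  marker_rows <- list()
  for (ch in marker_channels) {
    stat <- paste0("intensity.", ch)
    sc <- two_point_scale(wells, stat, ntc)
    eff <- vapply(perts, function(p) {
      v <- drug_wells[[stat]][drug_wells$perturbation == p]
      if (length(v) == 0L) return(NA_real_)
      mean(two_point_normalize(v, sc))
    }, 0)
    marker_rows[[ch]] <- data.frame(perturbation = perts, marker = ch,
                                    normalized_effect = unname(eff))
  }
  gene_table <- do.call(rbind, marker_rows)
  gene_table <- merge(gene_table,
                      calls[, c("perturbation", "fold_change_over_ntc",
                                "yap_hit", "wilcoxon_p")],
                      by = "perturbation", all.x = TRUE)
  rownames(gene_table) <- NULL

  # Fisher 2x2: translocation-hit status vs pathway preservation, over
  # non-control perturbations with complete calls.
  per_gene <- calls[!is.na(calls$yap_hit), , drop = FALSE]
  preserved <- vapply(per_gene$perturbation, function(p) {
    eff <- gene_table$normalized_effect[gene_table$perturbation == p]
    any(eff >= preserve_cutoff, na.rm = TRUE)
  }, TRUE)
  tab <- matrix(c(sum(per_gene$yap_hit & preserved),
                  sum(per_gene$yap_hit & !preserved),
                  sum(!per_gene$yap_hit & preserved),
                  sum(!per_gene$yap_hit & !preserved)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("yap_hit", "no_hit"),
                                c("preserved", "lost")))
  structure(list(wells = wells, gene_table = gene_table,
                 fisher = list(p = fisher_association(tab), table = tab)),
            class = "arrayed_result")
}

#' @export
print.arrayed_result <- function(x, ...) {
  calls <- unique(x$gene_table[, c("perturbation", "yap_hit")])
  cat(sprintf("Arrayed-screen result: %d wells, %d perturbations, %d translocation hits\n",
              nrow(x$wells), nrow(calls), sum(calls$yap_hit, na.rm = TRUE)))
  cat(sprintf("Fisher (hit vs pathway preservation): p = %.4g\n", x$fisher$p))
  invisible(x)
}
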