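# Immunohistochemistry H-scoring: percentage-weighted intensity categories
# per cellular compartment, range 0-300.

#' Intensity-category distribution of tumour cells
#'
#' Percentages of cells at staining intensity 0 (negative), 1+ (weak),
#' 2+ (moderate) and 3+ (strong) for one cellular compartment.
#'
#' @param compartment "nucleus" or "cytoplasm".
#' @param pct0,pct1,pct2,pct3 Percentages summing to 100.
#' @return List of class `intensity_distribution`.
#' @export
intensity_distribution <- function(compartment, pct0, pct1, pct2, pct3) {
  compartment <- match.arg(compartment, c("nucleus", "cytoplasm"))
  pct <- c(pct0, pct1, pct2, pct3)
  sk_assert(all(is.finite(pct)) && all(pct >= 0),
            "percentages must be finite and non-negative")
  sk_assert(abs(sum(pct) - 100) < 1e-9,
            sprintf("percentages must sum to 100 (got %.10g)", sum(pct)))
  structure(list(compartment = compartment, pct0 = pct0, pct1 = pct1,
                 pct2 = pct2, pct3 = pct3),
            class = "intensity_distribution")
}

#' Convert per-cell category counts to an intensity distribution
#'
#' @param counts Integer vector of length 4: cells at intensity 0, 1+, 2+,
#'   3+.
#' @param compartment "nucleus" or "cytoplasm".
#' @return An [intensity_distribution()] (full-precision percentages).
#' @export
counts_to_distribution <- function(counts, compartment = "nucleus") {
  sk_assert(length(counts) == 4L && all(counts >= 0) && sum(counts) > 0,
            "counts must be 4 non-negative values with a positive total")
  pct <- 100 * counts / sum(counts)
  intensity_distribution(compartment, pct[1], pct[2], pct[3], pct[4])
}

#' Compartment H-score
#'
#' H-score = %1+ + 2 * %2+ + 3 * %3+, out of a maximum of 300 (all cells at
#' the strongest intensity).
#'
#' @param dist An [intensity_distribution()].
#' @return Numeric H-score in \[0, 300\].
#' @export
h_score <- function(dist) {
  sk_assert(inherits(dist, "intensity_distribution"),
            "dist must be an intensity_distribution")
  dist$pct1 + 2 * dist$pct2 + 3 * dist$pct3
}

#' Compare H-scores between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test on the score values (see
#' [wilcoxon_rank_sum()]).
#'
#' @param scores_a,scores_b Numeric vectors of H-scores.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(scores_a, scores_b) {
  sk_assert(length(scores_a) >= 1L && length(scores_b) >= 1L,
            "both groups must be non-empty")
  wilcoxon_rank_sum(scores_a, scores_b)
}
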