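# Gene-set and transcription-factor enrichment: hypergeometric over-
# representation with BH correction and a combined score, pre-ranked
# running-sum enrichment, and per-cell signature (module) scores.

#' Hypergeometric gene-set over-representation
#'
#' For each set, tests whether the query (e.g. a DE gene list) overlaps the
#' set more than expected given the background: upper-tail hypergeometric p
#' on the overlap, BH FDR across sets, odds ratio from the 2x2 overlap table
#' (Haldane 0.5 correction when any cell is zero), and the combined score
#' -ln(p) * odds_ratio.
#'
#' @param query Character vector; must be a subset of `background`.
#' @param sets A `gene_sets` collection (intersected with the background
#'   before testing).
#' @param background Character vector of tested genes.
#' @return Data.frame: set, k (overlap), K (set size in background), n
#'   (query size), N (background size), p, fdr, odds_ratio, combined_score.
#' @export
hypergeometric_enrich <- function(query, sets, background) {
  background <- unique(background)
  query <- unique(query)
  sk_assert(all(query %in% background), "query must be a subset of background")
  if (length(query) == 0L) warning("empty query: all p-values are 1")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    K <- length(s)
    k <- length(intersect(s, query))
    # upper tail: P(X >= k)
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tab <- c(k, K - k, n - k, N - K - n + k)
    if (any(tab == 0)) tab <- tab + 0.5
    or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               odds_ratio = or)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out$combined_score <- combined_score(out$p, out$odds_ratio)
  out[, c("set", "k", "K", "n", "N", "p", "fdr", "odds_ratio",
          "combined_score")]
}

#' Combined enrichment score
#'
#' Summarises an enrichment as -ln(p) * odds_ratio, weighting significance
#' by the strength of over-representation. This is this package's combined
#' score; it is not numerically interchangeable with scores from
#' rank-simulation-based web tools.
#'
#' @param p Hypergeometric p-value(s) in (0, 1].
#' @param odds_ratio Corresponding odds ratio(s).
#' @return Numeric score(s); 0 when p = 1.
#' @export
combined_score <- function(p, odds_ratio) {
  sk_assert(all(p > 0 & p <= 1), "p must lie in (0,1]")
  -log(p) * odds_ratio
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]), returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  sk_assert(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
            "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the differential-expression filter
#'
#' Selects genes with p below `p_cutoff` and absolute linear fold change at
#' or above `fc_cutoff` (defaults: p < 0.01, |FC| >= 1.5).
#'
#' @param de Data.frame with columns gene, log2fc, p.
#' @param p_cutoff P-value cut-off (default 0.01).
#' @param fc_cutoff Linear fold-change cut-off (default 1.5).
#' @return Character vector of DE gene symbols.
#' @export
de_filter <- function(de, p_cutoff = 0.01, fc_cutoff = 1.5) {
  sk_assert(all(c("gene", "log2fc", "p") %in% names(de)),
            "de needs columns gene, log2fc, p")
  de$gene[de$p < p_cutoff & 2^abs(de$log2fc) >= fc_cutoff]
}

#' Infer transcription-factor activity from target-set enrichment
#'
#' Enriches the DE list against TF target sets; TFs with p below `p_cutoff`
#' (default 0.01) are flagged significant. For display, combined scores are
#' min-max scaled across the profile and log2(1 + scaled)-transformed.
#'
#' @param de_genes DE gene list.
#' @param tf_sets `gene_sets` of TF target sets.
#' @param background Background gene list.
#' @param p_cutoff Significance cut-off on the enrichment p.
#' @return Data.frame: tf, k, K, p, fdr, combined_score, activity (display
#'   scale), significant.
#' @export
infer_tf_activity <- function(de_genes, tf_sets, background, p_cutoff = 0.01) {
  res <- hypergeometric_enrich(de_genes, tf_sets, background)
  rng <- range(res$combined_score)
  scaled <- if (diff(rng) > 0)
    (res$combined_score - rng[1]) / diff(rng) else rep(0, nrow(res))
  data.frame(tf = res$set, k = res$k, K = res$K, p = res$p, fdr = res$fdr,
             combined_score = res$combined_score,
             activity = log2(1 + scaled),
             significant = res$p < p_cutoff)
}

#' Pre-ranked running-sum enrichment score
#'
#' Weighted Kolmogorov-Smirnov statistic over a ranked gene list: member
#' genes advance the running sum proportionally to |score|^`weight`,
#' non-members retreat it by 1/(N - |S|); the enrichment score is the
#' signed extreme of the running sum. The p-value comes from gene-label
#' permutations matched to the sign of the observed score.
#'
#' @param genes Character vector, ranked best-to-worst.
#' @param scores Numeric ranking scores aligned with `genes` (descending).
#' @param gene_set Character vector of member genes.
#' @param weight Exponent on |score| (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @param n_permutations Label permutations for the p-value (0 to skip).
#' @param seed Integer seed.
#' @return List: es (in \[-1, 1\]), p (NA when n_permutations = 0),
#'   running (the running-sum vector).
#' @export
preranked_es <- function(genes, scores, gene_set, weight = 1,
                         n_permutations = 1000L, seed = 1L) {
  sk_assert(length(genes) == length(scores), "genes and scores must align")
  sk_assert(!anyDuplicated(genes), "ranked gene list must be duplicate-free")
  member <- genes %in% gene_set
  sk_assert(any(member), "gene set does not intersect the ranked list")
  if (all(member)) {
    warning("gene set covers the entire ranked list; ES = 0 by convention")
    return(list(es = 0, p = NA_real_, running = rep(0, length(genes))))
  }
  run_of <- function(mb) {
    w <- abs(scores)^weight
    hit <- ifelse(mb, w, 0)
    hs <- sum(hit)
    hit <- if (hs == 0) ifelse(mb, 1, 0) / sum(mb) else hit / hs
    miss <- ifelse(mb, 0, 1) / sum(!mb)
    cumsum(hit - miss)
  }
  es_of <- function(mb) {
    running <- run_of(mb)
    running[which.max(abs(running))]
  }
  running <- run_of(member)
  es <- running[which.max(abs(running))]
  p <- NA_real_
  if (n_permutations > 0L) {
    k <- sum(member)
    with_seed(seed, {
      null_es <- vapply(seq_len(n_permutations), function(b) {
        mb <- logical(length(genes))
        mb[sample.int(length(genes), k)] <- TRUE
        es_of(mb)
      }, 0)
    })
    b <- if (es >= 0) sum(null_es >= es - 1e-12) else sum(null_es <= es + 1e-12)
    p <- (b + 1) / (n_permutations + 1)
  }
  list(es = es, p = p, running = running)
}

#' Library-size normalization for expression matrices
#'
#' Scales each cell to a common total of `scale_factor` counts and applies
#' log1p — the normalization expected by [module_score()].
#'
#' @param counts Gene x cell count matrix.
#' @param scale_factor Target total per cell (default 1e4).
#' @return Normalized matrix, same dimensions.
#' @export
normalize_expression <- function(counts, scale_factor = 1e4) {
  sk_assert(is.matrix(counts) && all(counts >= 0), "counts must be a non-negative matrix")
  tot <- colSums(counts)
  sk_assert(all(tot > 0), "every cell needs a positive total count")
  log1p(sweep(counts, 2, tot, "/") * scale_factor)
}

#' Per-cell signature (module) score
#'
#' Mean normalized expression of the signature genes minus the mean of
#' control genes drawn, per signature gene, from the same average-expression
#' bin (genes binned into `n_bins` equal-size bins by their mean expression
#' across cells; `n_controls` control genes sampled per signature gene).
#'
#' @param expr Normalized gene x cell matrix (see [normalize_expression()]).
#' @param signature Character vector of signature genes.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_controls Control genes per signature gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Numeric vector of per-cell scores (length = ncol(expr)).
#' @export
module_score <- function(expr, signature, n_bins = 24L, n_controls = 100L,
                         seed = 1L) {
  sk_assert(is.matrix(expr) && !is.null(rownames(expr)),
            "expr must be a matrix with gene rownames")
  missing <- setdiff(signature, rownames(expr))
  if (length(missing) > 0L) {
    warning(sprintf("dropping %d signature gene(s) absent from the matrix",
                    length(missing)))
    signature <- setdiff(signature, missing)
  }
  sk_assert(length(signature) > 0L, "empty signature after dropping absent genes")
  n_bins <- sk_check_count(n_bins, "n_bins")
  n_controls <- sk_check_count(n_controls, "n_controls")

  avg <- rowMeans(expr)
  n_bins <- min(n_bins, nrow(expr))
  # equal-size bins by rank of average expression, ties broken stably
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(expr) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  genes_by_bin <- split(rownames(expr), bin)

  with_seed(seed, {
    ctrl <- unlist(lapply(signature, function(g) {
      pool <- genes_by_bin[[as.character(bin[[which(rownames(expr) == g)]])]]
      sample(pool, min(n_controls, length(pool)))
    }), use.names = FALSE)
  })
  sig_mean <- colMeans(expr[signature, , drop = FALSE])
  ctrl_mean <- colMeans(expr[unique(ctrl), , drop = FALSE])
  unname(sig_mean - ctrl_mean)
}
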