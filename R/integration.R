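# Cross-screen integration: recurrence counting and the core
# resistance-gene set ("hit in at least recurrence_min of the screens").

#' Count hit recurrence across screens
#'
#' @param tables Named list of hit tables (each the output of
#'   [call_screen_hits()], or any data.frame with columns gene and hit);
#'   names are unique screen ids (cell line x drug x modality).
#' @param recurrence_min Minimum number of screens for a core call
#'   (default 4).
#' @return Data.frame of class `core_gene_set`: gene, recurrence, core;
#'   genes absent from a screen count as non-hit there. Attribute
#'   `n_screens` records the number of screens integrated.
#' @export
count_recurrence <- function(tables, recurrence_min = 4L) {
  sk_assert(is.list(tables) && length(tables) >= 1L, "need >= 1 hit table")
  ids <- names(tables)
  sk_assert(!is.null(ids) && all(nzchar(ids)) && !anyDuplicated(ids),
            "tables must be uniquely named by screen id")
  recurrence_min <- sk_check_count(recurrence_min, "recurrence_min")
  for (tb in tables)
    sk_assert(all(c("gene", "hit") %in% names(tb)) && !anyDuplicated(tb$gene),
              "each table needs unique genes and columns gene, hit")
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  hitmat <- vapply(tables, function(tb) {
    hit <- stats::setNames(as.logical(tb$hit), tb$gene)
    out <- hit[genes]
    out[is.na(out)] <- FALSE
    out
  }, logical(length(genes)))
  rec <- rowSums(matrix(hitmat, nrow = length(genes)))
  out <- data.frame(gene = genes, recurrence = as.integer(rec),
                    core = rec >= recurrence_min, row.names = NULL)
  attr(out, "n_screens") <- length(tables)
  class(out) <- c("core_gene_set", "data.frame")
  out
}

#' Recurrence histogram
#'
#' Number of genes at each recurrence level >= 1; the histogram sums to the
#' number of genes hit in at least one screen.
#'
#' @param core A `core_gene_set` from [count_recurrence()].
#' @return Named integer vector, names = recurrence level ("1", "2", ...).
#' @export
recurrence_histogram <- function(core) {
  sk_assert(all(c("gene", "recurrence") %in% names(core)),
            "core must come from count_recurrence()")
  r <- core$recurrence[core$recurrence >= 1L]
  if (length(r) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(factor(r, levels = seq_len(max(r))))
  stats::setNames(as.integer(tab), names(tab))
}
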