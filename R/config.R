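#' Pipeline configuration
#'
#' Builds and validates the configuration object shared by all pipeline
#' stages. Defaults encode the study's published decision rules: a resistance
#' hit requires linear fold change >= 2 and permutation p < 0.005; a core
#' resistance gene recurs in at least 4 screens; an arrayed-screen
#' translocation hit requires a >20% Nuc:Cyt increase over the non-targeting
#' control.
#'
#' @param fc_cutoff Linear fold-change cut-off for pooled-screen hits
#'   (default 2).
#' @param p_cutoff Permutation p-value cut-off for pooled-screen hits
#'   (default 0.005).
#' @param recurrence_min Minimum number of screens a gene must be a hit in to
#'   be called a core resistance gene (default 4).
#' @param rra_alpha Guide-level significance threshold used by alpha-RRA to
#'   select informative guides (default 0.05).
#' @param n_permutations Number of Monte-Carlo permutations for the alpha-RRA
#'   gene p-value (default 10000).
#' @param yap_hit_threshold Fractional Nuc:Cyt increase over NTC required to
#'   call a nuclear-translocation hit (default 0.20, i.e. >20%).
#' @param fdr_method Multiple-testing correction; only "benjamini_hochberg"
#'   is supported.
#' @param fc_strict If TRUE the fold-change cut-off is strict (> rather
#'   than >=).
#' @param seed Integer seed used by all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_cutoff = 2, p_cutoff = 0.005,
                            recurrence_min = 4L, rra_alpha = 0.05,
                            n_permutations = 10000L, yap_hit_threshold = 0.20,
                            fdr_method = "benjamini_hochberg",
                            fc_strict = FALSE, seed = 1L) {
  cfg <- list(
    fc_cutoff = sk_check_pos(fc_cutoff, "fc_cutoff"),
    p_cutoff = sk_check_prob(p_cutoff, "p_cutoff"),
    recurrence_min = sk_check_count(recurrence_min, "recurrence_min", min = 1L),
    rra_alpha = sk_check_prob(rra_alpha, "rra_alpha"),
    n_permutations = sk_check_count(n_permutations, "n_permutations", min = 1L),
    yap_hit_threshold = sk_check_pos(yap_hit_threshold, "yap_hit_threshold"),
    fdr_method = match.arg(fdr_method, "benjamini_hochberg"),
    fc_strict = isTRUE(fc_strict),
    seed = sk_check_count(seed, "seed", min = -.Machine$integer.max)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a flat key/value document; keys absent from the file keep the
#' package defaults. `overrides` (e.g. parsed command-line flags) take
#' precedence over file values.
#'
#' @param path Path to a YAML config file, or NULL for pure defaults.
#' @param overrides Named list overriding file values.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    sk_assert(file.exists(path), sprintf("config file not found: %s", path))
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  sk_assert(length(bad) == 0L,
            sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' Write a resolved configuration to YAML (provenance echo)
#'
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  sk_assert(inherits(config, "pipeline_config"), "not a pipeline_config")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}
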