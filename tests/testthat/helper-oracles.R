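# Independent oracles used across the suite. Each is written as a direct,
# brute-force evaluation of the defining formula or sample space, never
# calling the implementation path it checks.

# Beta CDF via the binomial identity P(Beta(j, k-j+1) <= x) = P(Bin(k, x) >= j),
# summed term by term (independent of stats::pbeta).
oracle_beta_cdf <- function(x, j, k) {
  i <- j:k
  sum(choose(k, i) * x^i * (1 - x)^(k - i))
}

# Alpha-RRA rho for one gene from its guides' normalized ranks and
# selection flags.
oracle_rho <- function(u, selected) {
  o <- order(u)
  u <- u[o]; selected <- selected[o]
  k <- length(u)
  if (!any(selected)) return(1)
  min(vapply(which(selected), function(j) oracle_beta_cdf(u[j], j, k), 0))
}

# Exhaustive permutation p for a gene with k guides in a universe of guides
# carrying (u, selected): enumerate every C(N, k) assignment.
oracle_rra_perm_p <- function(u, selected, gene_idx) {
  k <- length(gene_idx)
  rho_obs <- oracle_rho(u[gene_idx], selected[gene_idx])
  sets <- utils::combn(length(u), k)
  null_rho <- apply(sets, 2, function(i) oracle_rho(u[i], selected[i]))
  sum(null_rho <= rho_obs + 1e-12) / ncol(sets)
}

# NB upper/lower tail mass by direct pmf summation (smallest terms first
# for accuracy).
oracle_nb_upper <- function(q, mu, size, cap = 500000) {
  sum(rev(stats::dnbinom(q:cap, mu = mu, size = size)))
}
oracle_nb_lower <- function(q, mu, size) {
  sum(stats::dnbinom(0:q, mu = mu, size = size))
}

# Exact two-sided rank-sum p via the Mann-Whitney U statistic, enumerating
# every assignment of the pooled observations to group A.
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  center <- n1 * (n - n1) / 2
  u_obs <- u_stat(a, b)
  sets <- utils::combn(n, n1)
  u_null <- apply(sets, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(u_null - center) >= abs(u_obs - center) - 1e-9)
}

# Two-sided Fisher p by summing dhyper over every table with the observed
# margins whose probability does not exceed the observed table's.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail by pmf summation.
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(stats::dhyper(ks, K, N - K, n))
}

# Hand-rolled running-sum enrichment score (weighted KS).
oracle_preranked_es <- function(scores, member, weight = 1) {
  w <- abs(scores)^weight
  hit <- ifelse(member, w, 0); hit <- hit / sum(hit)
  miss <- ifelse(member, 0, 1) / sum(!member)
  running <- cumsum(hit - miss)
  running[which.max(abs(running))]
}

# Small deterministic cell-table fixture: explicit rows, no simulator.
make_cell_fixture <- function(n_per_well = 20, folds = c(NTC = 1, GENE_X = 2),
                              treatments = c("vehicle", "drug"),
                              baseline = 1.0, seed = 42) {
  withr::with_seed(seed, {
    rows <- list()
    wi <- 0
    for (p in names(folds)) for (tr in treatments) {
      wi <- wi + 1
      cyt <- rlnorm(n_per_well, log(1000), 0.1)
      rows[[length(rows) + 1]] <- data.frame(
        plate = "P1", well = sprintf("W%02d", wi),
        perturbation = p, treatment = tr,
        area = rlnorm(n_per_well, log(400), 0.3),
        is_border = FALSE,
        nuclear_mean.yap = cyt * baseline * folds[[p]],
        cytoplasm_mean.yap = cyt,
        nuclear_mean.perk = cyt, cytoplasm_mean.perk = cyt)
    }
    do.call(rbind, rows)
  })
}
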