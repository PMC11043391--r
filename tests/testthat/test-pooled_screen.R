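# Pooled-screen statistics: normalization, per-guide NB test, alpha-RRA
# aggregation, hit calling.

test_that("size factors are symmetric, scale-equivariant and centre ratios at 1", {
  m <- matrix(rpois(200, 50) + 1L, ncol = 2,
              dimnames = list(sprintf("g%03d", 1:100), c("A", "B")))
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(A = m[, 1], B = 2L * m[, 1])
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  sim <- simulate_pooled_screen(screen_sim_config(n_genes = 300L, seed = 13L))
  sf <- size_factors(sim$counts)
  norm <- sweep(sim$counts$counts, 2, sf, "/")
  ref <- exp(rowMeans(log(norm + 0.5)))
  med <- apply(norm / ref, 2, median)
  expect_true(all(abs(med - 1) < 0.05))

  m3 <- m; m3[, 1] <- 0L
  expect_error(size_factors(m3), "all-zero")
})

test_that("size factors agree with the DESeq median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_pooled_screen(screen_sim_config(n_genes = 200L, seed = 17L))
  ours <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("guide test: null guides give log2fc 0, p_enrich >= 0.5, mid-rank ties", {
  counts <- matrix(20L, nrow = 4, ncol = 4,
                   dimnames = list(sprintf("g%d", 1:4),
                                   c("v1", "v2", "d1", "d2")))
  gc <- guide_counts(counts, setNames(paste0("G", 1:4), rownames(counts)))
  sheet <- sample_sheet(colnames(counts), "L", c("vehicle", "vehicle",
                                                 "drug", "drug"), c(1, 2, 1, 2))
  gs <- guide_test(gc, sheet)
  expect_equal(gs$log2fc, rep(0, 4))
  expect_true(all(gs$p_enrich >= 0.5))
  # all guides tied -> all mid-rank u equal
  expect_equal(gs$u_enrich, rep(mean(seq_len(4)) / 4, 4))
})

test_that("NB tail p-values equal direct pmf summation", {
  # vehicle mean 10 per replicate, drug sum 40: planted enrichment case
  counts <- matrix(c(10L, 30L, 10L, 30L, 20L, 60L, 20L, 60L), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("v1", "v2", "d1", "d2")))
  gc <- guide_counts(counts, c(gA = "GA", gB = "GB"))
  sheet <- sample_sheet(colnames(counts), "L",
                        c("vehicle", "vehicle", "drug", "drug"), c(1, 2, 1, 2))
  sizes <- setNames(rep(1, 4), colnames(counts))
  gs <- guide_test(gc, sheet, sizes)

  # oracle: same definitions, independent tail summation
  norm <- counts
  veh_mean <- rowMeans(norm[, 1:2]);
  gm <- veh_mean; gv <- apply(norm[, 1:2], 1, var)
  phi <- max(sum(gv - gm) / sum(gm^2), 1e-8)
  for (i in 1:2) {
    mu_sum <- veh_mean[i] * 2
    var_sum <- 2 * veh_mean[i] + phi * veh_mean[i]^2 * 2
    size <- 1 / max((var_sum - mu_sum) / mu_sum^2, 1e-8)
    drug_sum <- sum(counts[i, 3:4])
    expect_lt(abs(gs$p_enrich[i] - oracle_nb_upper(drug_sum, mu_sum, size)),
              1e-10)
    expect_lt(abs(gs$p_deplete[i] - oracle_nb_lower(drug_sum, mu_sum, size)),
              1e-10)
  }
})

test_that("alpha-RRA rho matches the order-statistic oracle and rank-invariance", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      u <- runif(k)
      sel <- runif(k) < 0.7
      expect_equal(screenkit:::rra_rho(u, sel, 0.5), oracle_rho(u, sel))
    }
  })
  # rho depends on guide p-values only through their ranks
  stats_df <- data.frame(
    guide = sprintf("g%d", 1:6), gene = rep(c("A", "B"), each = 3),
    log2fc = 0, p_enrich = c(.01, .2, .3, .02, .5, .6),
    p_deplete = .5, u_enrich = NA, u_deplete = NA)
  stats_df$u_enrich <- rank(stats_df$p_enrich) / 6
  stats_df$u_deplete <- rank(stats_df$p_deplete) / 6
  mono <- stats_df
  mono$p_enrich <- stats_df$p_enrich^0.5        # monotone transform
  mono$u_enrich <- rank(mono$p_enrich) / 6
  a <- rra_aggregate(stats_df, alpha = 0.9, n_permutations = 50L, seed = 1)
  b <- rra_aggregate(mono, alpha = 0.95, n_permutations = 50L, seed = 1)
  expect_equal(a$rho[a$direction == "enriched"],
               b$rho[b$direction == "enriched"])
})

test_that("exhaustive alpha-RRA permutation p matches full enumeration", {
  # 6-guide universe, gene A holds 2 guides: all C(6,2) = 15 assignments
  withr::with_seed(7, {
    p <- runif(6)
    stats_df <- data.frame(
      guide = sprintf("g%d", 1:6),
      gene = c("A", "A", "B", "C", "D", "E"),
      log2fc = rnorm(6), p_enrich = p, p_deplete = 1 - p,
      u_enrich = rank(p) / 6, u_deplete = rank(1 - p) / 6)
  })
  agg <- rra_aggregate(stats_df, alpha = 0.6, exhaustive = TRUE)
  enr <- agg[agg$direction == "enriched", ]
  sel <- stats_df$p_enrich < 0.6
  expect_equal(enr$p_perm[enr$gene == "A"],
               oracle_rra_perm_p(stats_df$u_enrich, sel, 1:2))
  # depleted direction too
  dep <- agg[agg$direction == "depleted", ]
  seld <- stats_df$p_deplete < 0.6
  expect_equal(dep$p_perm[dep$gene == "A"],
               oracle_rra_perm_p(stats_df$u_deplete, seld, 1:2))

  # single-gene universe: no alternative assignment, p = 1
  one <- stats_df
  one$gene <- "Z"
  agg1 <- rra_aggregate(one, alpha = 0.6, exhaustive = TRUE)
  expect_true(all(agg1$p_perm == 1))
})

test_that("extreme guide ranks attain the permutation floor 1/(B+1)", {
  n <- 5000
  withr::with_seed(15, p <- runif(n, 0.01, 1))
  p[1:3] <- c(1e-6, 2e-6, 3e-6)
  genes <- c(rep("HIT", 3), paste0("G", seq_len(n - 3)))
  stats_df <- data.frame(guide = paste0("g", 1:n), gene = genes,
                         log2fc = 0, p_enrich = p, p_deplete = 1 - p,
                         u_enrich = rank(p) / n, u_deplete = rank(1 - p) / n)
  agg <- rra_aggregate(stats_df, alpha = 0.05, n_permutations = 10000L,
                       seed = 2)
  hit <- agg[agg$gene == "HIT" & agg$direction == "enriched", ]
  expect_equal(hit$p_perm, 1 / 10001)
})

test_that("hit calling applies the dual cut-offs", {
  genes <- data.frame(gene = c("A", "B", "C"), n_guides = 4, rho = 0.01,
                      p_perm = c(0.001, 0.01, 1e-6), fdr = 0.01,
                      gene_log2fc = log2(c(2.5, 2.5, 1.5)),
                      direction = "enriched")
  hits <- call_screen_hits(genes)
  expect_identical(hits$hit, c(TRUE, FALSE, FALSE))
  # boundary: fold change exactly 2 passes with >=, fails strict >
  at2 <- data.frame(gene = "D", n_guides = 4, rho = .01, p_perm = 1e-4,
                    fdr = .01, gene_log2fc = 1, direction = "enriched")
  expect_true(call_screen_hits(at2)$hit)
  expect_false(call_screen_hits(at2, fc_strict = TRUE)$hit)
})

test_that("alpha-RRA rewards partial guide evidence under dropout", {
  cfg <- screen_sim_config(n_genes = 200L, guides_per_gene = 5L,
                           n_resistant = 10L, resistant_log2fc = 2,
                           dropout_fraction = 0.4, seed = 19L)
  sim <- simulate_pooled_screen(cfg)
  gs <- guide_test(sim$counts, sim$sheet)
  agg <- rra_aggregate(gs, n_permutations = 2000L, seed = 19L)
  hits <- call_screen_hits(agg)
  sens <- mean(sim$truth$resistant_genes %in% hits$gene[hits$hit])
  # genes keep being called as long as a majority of guides is effective
  # (with 40% inert guides that is ~2/3 of planted genes)
  expect_gte(sens, 0.5)
})
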