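# Arrayed high-content scoring: filtering, ratios, two-point normalization,
# hit calling, and the rank-sum / Fisher machinery.

test_that("cell filter removes border cells then trims area deciles per well", {
  cells <- data.frame(plate = "P1", well = "W1",
                      perturbation = "NTC", treatment = "vehicle",
                      area = seq_len(100), is_border = rep(c(TRUE, FALSE),
                                                           c(10, 90)),
                      nuclear_mean.yap = 1, cytoplasm_mean.yap = 1)
  kept <- suppressWarnings(filter_cells(cells))
  expect_equal(nrow(kept), 90 - 2 * floor(90 * 0.1))  # 72 retained
  # the 9 smallest and 9 largest non-border areas are gone
  nb_areas <- cells$area[!cells$is_border]
  expect_equal(range(kept$area), range(sort(nb_areas)[10:81]))

  all_border <- transform(cells, is_border = TRUE)
  expect_equal(nrow(filter_cells(all_border)), 0L)
  expect_warning(filter_cells(cells[0, ]), "empty")
})

test_that("tied areas trim by stable input order, count unchanged", {
  n <- 37
  cells <- data.frame(plate = "P1", well = "W1", perturbation = "NTC",
                      treatment = "vehicle", area = rep(5, n),
                      is_border = FALSE, cell_id = seq_len(n),
                      nuclear_mean.yap = 1, cytoplasm_mean.yap = 1)
  kept <- filter_cells(cells)
  trim <- floor(n * 0.1)
  expect_equal(nrow(kept), n - 2 * trim)
  # stable order: the first `trim` and last `trim` rows are removed
  expect_equal(kept$cell_id, seq.int(trim + 1, n - trim))
})

test_that("nuc:cyt ratio arithmetic and zero-cytoplasm exclusion", {
  cells <- data.frame(nuclear_mean.yap = c(200, 100, 50),
                      cytoplasm_mean.yap = c(100, 100, 0))
  r <- nuc_cyt_ratio(cells)
  expect_equal(r[1:2], c(2, 1))
  expect_true(is.na(r[3]))                  # excluded, not an exception
  expect_error(nuc_cyt_ratio(cells, "missing"), "not present")
})

test_that("two-point normalization hits its anchors and is affine-invariant", {
  cells <- make_cell_fixture(n_per_well = 30)
  wells <- summarise_wells(filter_cells(cells))
  # fixture has no drug effect on perk, so force an assay window
  wells$intensity.perk[wells$perturbation == "NTC" &
                         wells$treatment == "drug"] <- 100
  sc <- two_point_scale(wells, "intensity.perk")
  expect_true(two_point_normalize(sc$ref_max, sc) == 0)
  expect_true(two_point_normalize(sc$ref_min, sc) == -100)
  expect_equal(two_point_normalize((sc$ref_max + sc$ref_min) / 2, sc), -50)
  expect_gt(two_point_normalize(sc$ref_max + 1, sc), 0)

  # affine invariance: transforming data and scale together changes nothing
  x <- c(150, 400, 1000)
  sc2 <- structure(list(ref_max = 3 * sc$ref_max + 7,
                        ref_min = 3 * sc$ref_min + 7),
                   class = "two_point_scale")
  expect_equal(two_point_normalize(3 * x + 7, sc2),
               two_point_normalize(x, sc))

  degen <- wells
  degen$intensity.perk <- 1
  expect_error(two_point_scale(degen, "intensity.perk"), "degenerate")
})

test_that("translocation hit calling uses a strict >20% rule over NTC", {
  wells <- data.frame(plate = "P1", well = sprintf("W%d", 1:4),
                      perturbation = c("NTC", "A", "B", "C"),
                      treatment = "drug", n_cells_retained = 100,
                      nuc_cyt_median = c(1.0, 1.25, 1.10, 1.20))
  calls <- call_yap_hits(wells)
  expect_equal(setNames(calls$yap_hit, calls$perturbation),
               c(A = TRUE, B = FALSE, C = FALSE))  # exactly 1.20 is no hit
  expect_equal(calls$fold_change_over_ntc,
               c(1.25, 1.10, 1.20))
  expect_error(call_yap_hits(wells[wells$perturbation != "NTC", ]), "NTC")
})

test_that("rank-sum test matches exhaustive enumeration and wilcox.test", {
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5)), 1)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(wilcoxon_rank_sum(a, b), oracle_wilcoxon(a, b))
  expect_equal(wilcoxon_rank_sum(a, b), 0.1, tolerance = 1e-12)  # 2/C(6,3)*... hand: 2*1/20
  withr::with_seed(37, {
    for (i in 1:25) {
      x <- sample(1:6, sample(2:8, 1), replace = TRUE)   # ties included
      y <- sample(1:6, sample(2:8, 1), replace = TRUE)
      expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon(x, y),
                   info = paste(i))
    }
    # tie-free exact case agrees with the reference implementation
    x <- runif(7); y <- runif(8) + 0.2
    expect_equal(wilcoxon_rank_sum(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value)
  })
  # planted shift at per-cell scale is overwhelmingly significant
  withr::with_seed(41, {
    v <- rlnorm(500, 0, 0.3)
    d <- rlnorm(500, log(1.5), 0.3)
  })
  expect_lt(wilcoxon_rank_sum(v, d), 1e-3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  expect_equal(fisher_association(matrix(c(5, 5, 5, 5), 2)), 1)
  tab <- matrix(c(8, 1, 2, 9), 2)          # [[8,2],[1,9]] row-major
  expect_equal(fisher_association(tab), oracle_fisher(tab), tolerance = 1e-12)
  withr::with_seed(43, {
    for (i in 1:25) {
      tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
      if (sum(tab) == 0) next
      expect_equal(fisher_association(tab), oracle_fisher(tab),
                   tolerance = 1e-12, info = paste(i))
    }
  })
  expect_equal(fisher_association(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_association(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("arrayed scoring recovers planted marker rescue and calls no null hits", {
  cfg <- cell_sim_config(cells_per_well = 2000L,
                         planted_fold = c(NTC = 1, RESCUER = 1, NULL1 = 1,
                                          NULL2 = 1),
                         drug_effect = c(yap = 1, pakt = 0.2, perk = 0.2),
                         marker_rescue = list(RESCUER = "perk"), seed = 47L)
  perts <- names(cfg$planted_fold)
  design <- rbind(
    data.frame(plate = "P1", well = paste0("V", seq_along(perts)),
               perturbation = perts, treatment = "vehicle"),
    data.frame(plate = "P1", well = paste0("D", seq_along(perts)),
               perturbation = perts, treatment = "drug"))
  cells <- simulate_cell_table(cfg, design)
  res <- score_arrayed_screen(cells, pipeline_config())
  gt <- res$gene_table
  # full pERK rescue scores near the vehicle anchor (0)
  expect_lt(abs(gt$normalized_effect[gt$perturbation == "RESCUER" &
                                       gt$marker == "perk"]), 10)
  # unrescued null genes sit near the drug anchor (-100)
  expect_lt(abs(gt$normalized_effect[gt$perturbation == "NULL1" &
                                       gt$marker == "perk"] + 100), 10)
  # no translocation hits among fold-1 genes (NTC itself carries no call)
  calls <- unique(gt[, c("perturbation", "yap_hit")])
  expect_false(any(calls$yap_hit, na.rm = TRUE))
  expect_true(all(dim(res$fisher$table) == 2))
})
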