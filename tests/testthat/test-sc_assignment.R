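# Pseudobulk, signature cell typing, the Spearman fold-change assignment
# arithmetic and the printed-table composition summaries.

test_that("pseudobulk is the per-gene mean of log2 cpm", {
  counts <- matrix(c(2L, 0L, 8L,
                     4L, 1L, 5L,
                     0L, 3L, 7L), 3, 3, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  # single cell: its own normalized profile
  expect_equal(pseudobulk(counts, "c1"), log2_cpm(counts)[, "c1"])
  # two identical cells average to the same profile
  two <- counts[, c(1, 1)]
  colnames(two) <- c("c1", "c1b")
  expect_equal(unname(pseudobulk(two)), unname(log2_cpm(counts)[, "c1"]))
  # three-cell fixture: hand-computed per-gene means
  norm <- log2_cpm(counts)
  expect_equal(pseudobulk(counts), rowMeans(norm))
  expect_error(pseudobulk(counts, character(0)), "empty")
})

test_that("signature cell typing follows marker expression", {
  sigs <- list(
    mac = gene_signature("mac", "macrophage", genes = paste0("m", 1:5)),
    tc = gene_signature("tc", "T_cell", genes = paste0("t", 1:5))
  )
  genes <- c(paste0("m", 1:5), paste0("t", 1:5), paste0("x", 1:20))
  counts <- matrix(1L, length(genes), 3,
                   dimnames = list(genes, c("cm", "ct", "cu")))
  counts[paste0("m", 1:5), "cm"] <- 60L
  counts[paste0("t", 1:5), "ct"] <- 60L
  # cu stays uniform -> margin 0 -> unknown
  labels <- assign_cell_types_by_signature(counts, sigs, min_margin = 0.02)
  expect_equal(unname(labels[c("cm", "ct", "cu")]),
               c("macrophage", "T_cell", "unknown"))
  expect_error(assign_cell_types_by_signature(counts, sigs["mac"]),
               "2 cell types")
})

test_that("simulated cell types are recovered from their signatures", {
  cfg <- small_config(seed = 71, sc = list(
    n_cells = 150,
    proportions = list(
      "NIR-like" = c(macrophage = 0.4, CD8_T_cell = 0.3, neuron = 0.3),
      "PIR-like" = c(macrophage = 0.2, CD8_T_cell = 0.4, neuron = 0.4))))
  uni <- make_universe_and_signatures(cfg)
  s <- simulate_sc_sample(cfg, uni, profile = "NIR-like", seed = 711)
  labels <- assign_cell_types_by_signature(s$counts, uni$signatures)
  known <- labels != "unknown"
  acc <- mean(labels[known] == s$truth$cell_type[names(labels)][known])
  expect_gte(acc, 0.9)
  expect_gte(mean(known), 0.8)
})

test_that("Spearman correlations to bulk hit their closed-form extremes", {
  set.seed(72)
  bulk <- matrix(runif(30 * 4), 30, 4,
                 dimnames = list(paste0("sig", 1:30), paste0("s", 1:4)))
  sc <- bulk[, "s2"]
  rhos <- spearman_to_bulk(sc, bulk)
  expect_equal(unname(rhos["s2"]), 1)
  rev_sc <- stats::setNames(max(sc) - sc, names(sc))
  expect_equal(unname(spearman_to_bulk(rev_sc, bulk)["s2"]), -1)
  # monotone transform of the profile leaves rho unchanged
  expect_equal(spearman_to_bulk(exp(3 * sc), bulk), rhos)
  expect_error(spearman_to_bulk(sc[1:4], bulk), "fewer than 5")
  # independent profiles of length 50 rarely reach |rho| = 0.5
  set.seed(73)
  null_ok <- mean(replicate(200, {
    b <- matrix(runif(50), 50, 1, dimnames = list(paste0("f", 1:50), "s1"))
    v <- stats::setNames(runif(50), rownames(b))
    abs(spearman_to_bulk(v, b)) < 0.5
  }))
  expect_gte(null_ok, 0.95)
})

test_that("fold-change arithmetic follows the retain-positive rule", {
  rhos <- stats::setNames(c(0.5, 0.7, -0.2, 0.3, 0.3),
                          paste0("s", 1:5))
  labels <- stats::setNames(c("PIR", "PIR", "PIR", "NIR", "NIR"),
                            names(rhos))
  fc <- cohort_fold_change(rhos, labels)
  expect_equal(fc$fc, 0.6 / 0.3)  # mean positives: {0.5,0.7} vs {0.3,0.3}
  expect_equal(fc$n_positive_pir, 2L)
  expect_true(fc$usable)
  # symmetric correlations give a fold change of exactly 1
  sym <- stats::setNames(c(0.4, 0.2, 0.4, 0.2), paste0("s", 1:4))
  lab2 <- stats::setNames(c("PIR", "PIR", "NIR", "NIR"), names(sym))
  expect_equal(cohort_fold_change(sym, lab2)$fc, 1)
  # all-negative NIR correlations make the cohort unusable
  neg <- stats::setNames(c(0.5, -0.1, -0.3), paste0("s", 1:3))
  lab3 <- stats::setNames(c("PIR", "NIR", "NIR"), names(neg))
  fc3 <- cohort_fold_change(neg, lab3)
  expect_false(fc3$usable)
  expect_true(is.na(fc3$fc))
  expect_error(cohort_fold_change(rhos, stats::setNames("PIR", "zz")),
               "match")
})

test_that("total fold changes multiply and map to labels", {
  a <- total_assignment(c(2.0, 1.5, 0.9, 1.2), sc_sample_id = "x")
  expect_equal(a$total_fc, 3.24, tolerance = 1e-12)
  expect_equal(a$label, "PIR")
  expect_equal(a$n_usable_cohorts, 4L)
  # all fold changes exactly 1 -> boundary -> unassigned
  expect_equal(total_assignment(c(1, 1, 1))$label, "unassigned")
  # fewer than two usable cohorts -> unassigned
  one <- list(list(fc = 2, usable = TRUE), list(fc = NA_real_, usable = FALSE))
  expect_equal(total_assignment(one)$label, "unassigned")
  # swapping PIR/NIR inverts every fold change, hence the total and label
  b <- total_assignment(1 / c(2.0, 1.5, 0.9, 1.2))
  expect_equal(b$total_fc, 1 / a$total_fc, tolerance = 1e-12)
  expect_equal(b$label, "NIR")
})

test_that("composition summaries reproduce the printed worked example", {
  tab <- table2_rows()
  for (i in seq_len(nrow(tab))) {
    labels <- labels_from_counts(tab$macrophage[i], tab$microglia[i],
                                 tab$all_cells[i])
    cs <- composition_summary(labels, sample_id = tab$sample[i])
    expect_equal(cs$total_cells, tab$all_cells[i])
    expect_equal(cs$macrophage_pct, tab$pct[i],
                 info = tab$sample[i])
    if (is.na(tab$ratio[i])) {
      expect_true(is.na(cs$mac_microglia_ratio))
    } else {
      expect_equal(cs$mac_microglia_ratio, tab$ratio[i],
                   info = tab$sample[i])
    }
    expect_equal(cs$mac_microglia_ratio_label, tab$ratio_label[i])
    expect_equal(sum(cs$counts), cs$total_cells)
  }
  # degenerate cases
  expect_equal(composition_summary(rep("macrophage", 7))$macrophage_pct, 100)
  expect_error(composition_summary(character(0)), "zero cells")
})

test_that("the rank-sum comparison is exact and symmetric", {
  a <- c(10, 12, 14, 16, 18, 20)
  b <- c(30, 32, 34, 36, 38, 40)
  p <- compare_fraction_groups(a, b)
  expect_equal(p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(p, ranksum_enumeration_p(a, b), tolerance = 1e-12)
  expect_equal(compare_fraction_groups(b, a), p)
  ident <- c(1, 2, 3, 4)
  expect_equal(compare_fraction_groups(ident, ident), 1)
  expect_error(compare_fraction_groups(c(1, 2), b), "at least 3")
})
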