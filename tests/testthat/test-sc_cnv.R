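# Single-cell CNV profiling: the detection filter, log2(cpm + 1), the
# moving-average profile against a naive oracle, deviation scores and the
# chr7-gain / chr10-loss transformed-cell call.

test_that("the min-cells filter sits exactly at its stated boundary", {
  n_cells <- 60
  counts <- matrix(0L, 5, n_cells,
                   dimnames = list(paste0("g", 1:5),
                                   paste0("c", seq_len(n_cells))))
  # genes detected in 3, 10, 11, 50 and 0 cells
  counts[1, 1:3] <- 1L
  counts[2, 1:10] <- 1L
  counts[3, 1:11] <- 1L
  counts[4, 1:50] <- 1L
  kept <- filter_genes_min_cells(counts, threshold = 10L)
  expect_equal(rownames(kept), c("g3", "g4"))  # 11 and 50 survive, 10 does not
  expect_error(filter_genes_min_cells(counts, threshold = 60L), "all genes")
  # sparse input follows the same rule
  kept_sp <- filter_genes_min_cells(methods::as(counts, "CsparseMatrix"),
                                    threshold = 10L)
  expect_equal(rownames(kept_sp), c("g3", "g4"))
})

test_that("log2 cpm has its closed forms and library-size invariance", {
  counts <- matrix(c(0L, 5L, 3L, 7L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- log2_cpm(counts)
  expect_identical(norm["g1", "c1"], 0)           # zero count -> exactly 0
  expect_equal(norm["g2", "c1"], log2(1e6 + 1))   # single expressed gene
  expect_equal(log2_cpm(counts * 2L)[, "c2"], norm[, "c2"])  # doubling
  bad <- counts
  bad[, 1] <- 0L
  expect_error(log2_cpm(bad), "zero total")
})

test_that("the moving average equals the naive windowed-mean oracle", {
  set.seed(51)
  # two chromosomes, 200 + 60 genes, 3 cells
  ann <- data.frame(gene = paste0("g", 1:260),
                    chromosome = rep(c("chr1", "chr2"), c(200, 60)),
                    position = c(seq_len(200), seq_len(60)) * 10)
  x <- matrix(rnorm(260 * 3), 260, 3,
              dimnames = list(ann$gene, paste0("c", 1:3)))
  prof <- moving_average_profile(x, ann, window = 100)
  for (cell in colnames(x)) {
    expect_equal(prof$values[1:200, cell],
                 moving_average_oracle(x[1:200, cell], 100),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(prof$values[201:260, cell],
                 moving_average_oracle(x[201:260, cell], 100),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # the documented interior case: gene 100 of a 200-gene chromosome
  # averages genes 51..150
  expect_equal(prof$values["g100", "c1"], mean(x[51:150, "c1"]),
               tolerance = 1e-12)
  # constant input is a fixed point of smoothing
  const <- matrix(2.5, 260, 2, dimnames = list(ann$gene, c("c1", "c2")))
  expect_true(all(moving_average_profile(const, ann)$values == 2.5))
})

test_that("smoothing never crosses a chromosome boundary", {
  ann <- data.frame(gene = paste0("g", 1:120),
                    chromosome = rep(c("chr1", "chr2"), each = 60),
                    position = rep(seq_len(60), 2) * 5)
  # step profile: chr1 all zero, chr2 all ten
  x <- matrix(rep(c(0, 10), each = 60), 120, 1,
              dimnames = list(ann$gene, "c1"))
  prof <- moving_average_profile(x, ann, window = 30)
  expect_true(all(prof$values[prof$genes$chromosome == "chr1", ] == 0))
  expect_true(all(prof$values[prof$genes$chromosome == "chr2", ] == 10))
})

test_that("short chromosomes are skipped and flagged, not fatal", {
  ann <- data.frame(gene = paste0("g", 1:70),
                    chromosome = rep(c("chr1", "chr2"), c(60, 10)),
                    position = c(seq_len(60), seq_len(10)))
  x <- matrix(rnorm(70 * 2), 70, 2, dimnames = list(ann$gene, c("a", "b")))
  prof <- moving_average_profile(x, ann, window = 30, window_min = 25)
  expect_equal(attr(prof, "skipped_chromosomes"), "chr2")
  expect_false("chr2" %in% prof$genes$chromosome)
})

test_that("deviation scores isolate a shift planted on one chromosome", {
  ann <- data.frame(gene = paste0("g", 1:150),
                    chromosome = rep(c("chr1", "chr7", "chr10"), each = 50),
                    position = rep(seq_len(50), 3))
  base <- matrix(5, 150, 4, dimnames = list(ann$gene, paste0("c", 1:4)))
  shifted <- base
  shifted[ann$gene[ann$chromosome == "chr7"], "c2"] <-
    shifted[ann$gene[ann$chromosome == "chr7"], "c2"] + 0.5
  prof <- moving_average_profile(shifted, ann, window = 20)
  # reference = the cell's own profile -> scores exactly zero
  dev_self <- chromosome_deviation(prof, reference = prof$values[, "c2"])
  expect_equal(unname(dev_self["c2", ]), c(0, 0, 0), tolerance = 1e-12)
  # against the default (median across cells) reference, c2 carries
  # exactly +0.5 on chr7 and 0 elsewhere
  dev <- chromosome_deviation(prof)
  expect_equal(unname(dev["c2", c("chr1", "chr7", "chr10")]),
               c(0, 0.5, 0), tolerance = 1e-12)
  expect_true(all(abs(dev["c1", ]) < 1e-12))
  expect_error(chromosome_deviation(prof, reference = c(x = 1)), "cover")
})

test_that("the transformed-cell rules apply their thresholds literally", {
  dev <- matrix(c(0.4, -0.3,
                  0.4, 0.1,
                  0.1, -0.4,
                  -0.2, -0.4), 4, 2, byrow = TRUE,
                dimnames = list(paste0("c", 1:4), c("chr7", "chr10")))
  calls <- call_transformed(dev, tau = 0.15)
  expect_equal(calls$transformed, c(TRUE, FALSE, FALSE, FALSE))
  # alternative karyotype rule: any configured chromosome beyond tau
  calls2 <- call_transformed(dev, rule = "any_chromosome", tau = 0.35,
                             chromosomes = c("chr7", "chr10"))
  expect_equal(calls2$transformed, c(TRUE, TRUE, TRUE, TRUE))
  expect_error(call_transformed(dev, gain_chrom = "chrX"), "chrX")
  expect_error(call_transformed(dev, rule = "any_chromosome",
                                chromosomes = "chr13"), "chr13")
})

test_that("planted malignant cells are recovered in a labeled simulation", {
  cfg <- small_config(seed = 61, sc = list(
    n_cells = 400, cnv_delta = 0.5,
    proportions = list(
      "NIR-like" = c(malignant = 0.5, macrophage = 0.25, microglia = 0.05,
                     CD8_T_cell = 0.1, neuron = 0.1),
      "PIR-like" = c(malignant = 0.5, macrophage = 0.05, microglia = 0.05,
                     CD8_T_cell = 0.3, neuron = 0.1))))
  uni <- make_universe_and_signatures(cfg)
  s <- simulate_sc_sample(cfg, uni, profile = "NIR-like", seed = 611)
  calls <- identify_transformed_cells(s$counts, uni$annotation)
  acc <- mean(calls$transformed == s$truth$malignant[calls$cell_id])
  expect_gte(acc, 0.9)
})
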