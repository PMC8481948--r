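# Z-scoring, two-cluster hierarchical stratification, log-rank testing and
# the PIR/NIR labeling rule.

test_that("z-scores use the population standard deviation", {
  m <- matrix(c(1, 2, 3, 4, 6, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  z <- zscore_by_signature(m, c("a", "b"))
  expect_equal(unname(z["a", ]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(z^2)) - 1) < 1e-12))
})

test_that("degenerate z-score inputs are dropped or rejected", {
  m <- matrix(c(1, 2, 3, 5, 5, 5, 2, 4, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "const", "b"), c("s1", "s2", "s3")))
  expect_warning(z <- zscore_by_signature(m, rownames(m)), "zero-variance")
  expect_equal(rownames(z), c("a", "b"))
  expect_error(suppressWarnings(zscore_by_signature(m, c("a", "const"))),
               "fewer than 2")
  expect_error(zscore_by_signature(m, c("a", "nope")), "absent")
})

test_that("well-separated blobs are recovered exactly and order-invariantly", {
  set.seed(41)
  n_per <- 15
  z <- cbind(matrix(rnorm(10 * n_per, -3), 10),
             matrix(rnorm(10 * n_per, 3), 10))
  colnames(z) <- paste0("s", seq_len(2 * n_per))
  truth <- rep(1:2, each = n_per)
  cl <- cluster_two(z)
  expect_equal(length(unique(cl)), 2L)
  # partition matches the blobs exactly (up to label swap)
  agree <- mean(cl == truth)
  expect_true(agree %in% c(0, 1))
  # permutation invariance up to label swap
  perm <- sample(colnames(z))
  cl_p <- cluster_two(z[, perm])[colnames(z)]
  expect_true(all(cl_p == cl) || all(cl_p == (3L - cl)))
  expect_error(cluster_two(z[, 1:3]), "4 samples")
})

test_that("log-rank behaves at its boundary cases", {
  # two groups that are exact copies of each other: observed = expected
  surv <- data.frame(sample = c(paste0("a", 1:10), paste0("b", 1:10)),
                     time = rep(c(50, 100, 150, 200, 250,
                                  300, 350, 400, 450, 500), 2),
                     event = rep(c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1), 2))
  groups <- stats::setNames(rep(1:2, each = 10), surv$sample)
  expect_equal(logrank_test(groups, surv), 1)
  # empty group / no events rejected
  expect_error(logrank_test(stats::setNames(rep(1, 20), surv$sample), surv),
               "two non-empty")
  surv0 <- surv
  surv0$event[1:10] <- 0
  expect_error(logrank_test(groups, surv0), "at least one event")
})

test_that("log-rank holds its nominal size and detects a doubled hazard", {
  set.seed(42)
  null_rej <- mean(replicate(200, {
    surv <- data.frame(sample = paste0("s", 1:200),
                       time = rexp(200, 1 / 300),
                       event = rbinom(200, 1, 0.8))
    g <- stats::setNames(rep(1:2, each = 100), surv$sample)
    logrank_test(g, surv) <= 0.05
  }))
  expect_lt(abs(null_rej - 0.05), 0.03)

  power <- mean(replicate(50, {
    g <- stats::setNames(rep(1:2, each = 100), paste0("s", 1:200))
    surv <- data.frame(sample = names(g),
                       time = rexp(200, rate = ifelse(g == 2, 2, 1) / 300),
                       event = rep(1, 200))
    logrank_test(g, surv) <= 0.05
  }))
  expect_gte(power, 0.9)
})

test_that("PIR goes to the longer-surviving cluster, CD8 breaks ties", {
  # cluster 2 has clearly longer survival
  surv <- data.frame(sample = paste0("s", 1:40),
                     time = c(rexp(20, 1 / 150), rexp(20, 1 / 700)) + 1,
                     event = rep(1, 40))
  assignment <- stats::setNames(rep(1:2, each = 20), surv$sample)
  res <- label_pir_nir(assignment, surv)
  expect_equal(unname(res$label_map["2"]), "PIR")
  pir_med <- res$median_survival["PIR"]
  nir_med <- res$median_survival["NIR"]
  expect_true(is.na(nir_med) || is.na(pir_med) || pir_med >= nir_med)
  expect_equal(sort(as.integer(res$n_per_label)), c(20L, 20L))

  # identical survival in both clusters: the CD8 tie-break decides
  surv_tie <- data.frame(sample = paste0("s", 1:20),
                         time = rep(c(100, 200, 300, 400, 500), 4),
                         event = rep(1, 20))
  assign_tie <- stats::setNames(rep(1:2, 10), surv_tie$sample)
  # cluster-2 samples (even positions) share the same survival multiset
  nes <- matrix(0.4, 2, 20,
                dimnames = list(c("cd8_sig", "other"), surv_tie$sample))
  nes["cd8_sig", assign_tie == 2] <- 0.7
  res_tie <- label_pir_nir(assign_tie, surv_tie, nes = nes,
                           cd8_signature_ids = "cd8_sig")
  expect_equal(unname(res_tie$label_map["2"]), "PIR")
  # and without any tie-break information: an error demanding manual labels
  expect_error(label_pir_nir(assign_tie, surv_tie), "manually")
})

test_that("recovered clusters separate survival on planted cohorts", {
  # planted two-group structure; problem size chosen so the log-rank test
  # has adequate power (about 84 expected events at a group hazard ratio
  # of 2)
  cfg <- sim_config(seed = 5, n_genes = 2000, n_samples = 120,
                    pir_fraction = 0.5, group_effect = 1.5)
  uni <- make_universe_and_signatures(cfg)
  sig_types <- vapply(uni$signatures, function(s) s$cell_type, character(1))
  disc <- names(uni$signatures)[
    sig_types %in% cfg$cell_types$cell_type[cfg$cell_types$nir_shift != 0]]
  cd8 <- names(uni$signatures)[sig_types == "CD8_T_cell"]
  hits <- vapply(1:50, function(r) {
    coh <- simulate_bulk_cohort(cfg, uni, seed = 900 + r,
                                group_hazard_ratio = 2)
    nes <- compute_nes_matrix(coh$expr, uni$signatures)
    strat <- stratify_cohort(nes, disc, coh$survival,
                             cd8_signature_ids = cd8)
    strat$logrank_p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("cluster NES comparisons are symmetric and calibrated", {
  set.seed(43)
  sigs <- list(st1 = gene_signature("st1", "stromal_cell", genes = "G1"),
               st2 = gene_signature("st2", "stromal_cell", genes = "G2"))
  samples <- paste0("s", 1:40)
  nes <- matrix(rnorm(80, 0.5, 0.05), 2, 40,
                dimnames = list(c("st1", "st2"), samples))
  labels <- stats::setNames(rep(c("NIR", "PIR"), each = 20), samples)
  res <- structure(list(labels = labels), class = "stratification_result")
  out <- compare_cluster_nes(nes, res, "stromal_cell", sigs)
  expect_equal(nrow(out), 2L)
  # swapping the group labels leaves p unchanged
  res_sw <- structure(list(labels = stats::setNames(
    ifelse(labels == "NIR", "PIR", "NIR"), samples)),
    class = "stratification_result")
  out_sw <- compare_cluster_nes(nes, res_sw, "stromal_cell", sigs)
  expect_equal(out$p_value, out_sw$p_value)
  # identical groups -> t = 0, p = 1
  nes_id <- nes
  nes_id[, labels == "PIR"] <- nes_id[, labels == "NIR"]
  out_id <- compare_cluster_nes(nes_id, res, "stromal_cell", sigs)
  expect_equal(out_id$t, c(0, 0))
  expect_equal(out_id$p_value, c(1, 1))
  # a planted +0.15 NES shift in NIR is detected in >= 90% of 50 reps
  hits <- vapply(1:50, function(r) {
    set.seed(500 + r)
    m <- matrix(rnorm(100, 0.5, 0.05), 2, 50,
                dimnames = list(c("st1", "st2"), paste0("s", 1:50)))
    lab <- stats::setNames(rep(c("NIR", "PIR"), each = 25), colnames(m))
    m[, lab == "NIR"] <- m[, lab == "NIR"] + 0.15
    rr <- structure(list(labels = lab), class = "stratification_result")
    all(compare_cluster_nes(m, rr, "stromal_cell", sigs)$p_value <= 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
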