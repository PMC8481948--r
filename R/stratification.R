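# Cohort stratification: z-score the prognostic signatures' NES across
# samples, hierarchically cluster the samples (Euclidean distance, complete
# linkage, k = 2), test survival separation with the log-rank statistic and
# name the clusters: the longer-surviving cluster is the positive immune
# response (PIR) class, the other the negative immune response (NIR) class.

#' Z-score a NES matrix signature-by-signature
#'
#' Each retained signature row is centred and scaled to population standard
#' deviation 1 (divisor n, not n-1; documented because heatmap z-scores
#' differ between conventions). Zero-variance rows are dropped with a
#' warning.
#'
#' @param nes A `nes_matrix` or bare signatures x samples matrix.
#' @param prognostic_ids Signature ids to retain (rows must exist).
#' @return Matrix of z-scores, retained signatures x samples.
#' @export
zscore_by_signature <- function(nes, prognostic_ids) {
  scores <- nes_scores(nes)
  missing <- setdiff(prognostic_ids, rownames(scores))
  if (length(missing))
    stop("prognostic ids absent from NES matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- scores[prognostic_ids, , drop = FALSE]
  if (anyNA(m)) {
    drop_na <- rowSums(is.na(m)) > 0
    if (any(drop_na)) {
      warning("dropped ", sum(drop_na), " signature(s) with NA NES")
      m <- m[!drop_na, , drop = FALSE]
    }
  }
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  zero <- sd_pop == 0
  if (any(zero)) {
    warning("dropped ", sum(zero), " zero-variance signature row(s)")
    m <- m[!zero, , drop = FALSE]
    mu <- mu[!zero]
    sd_pop <- sd_pop[!zero]
  }
  if (nrow(m) < 2L)
    stop("fewer than 2 usable prognostic signatures after filtering")
  (m - mu) / sd_pop
}

#' Cut a sample dendrogram into two clusters
#'
#' Agglomerative hierarchical clustering of samples (columns) on Euclidean
#' distance with complete linkage, cut at k = 2. Fully deterministic.
#'
#' @param zmatrix Signatures x samples z-score matrix (>= 4 samples).
#' @return Named integer vector (values 1/2), one entry per sample.
#' @export
cluster_two <- function(zmatrix) {
  if (ncol(zmatrix) < 4L) stop("need at least 4 samples to cluster")
  hc <- stats::hclust(stats::dist(t(zmatrix), method = "euclidean"),
                      method = "complete")
  stats::cutree(hc, k = 2L)
}

#' Two-group log-rank test
#'
#' @param groups Named vector (names = sample ids) with exactly two distinct
#'   values; samples absent from `survival` are ignored.
#' @param survival Clinical `data.frame` (`sample`, `time`, `event`).
#' @return Two-sided log-rank p-value.
#' @export
logrank_test <- function(groups, survival) {
  ids <- intersect(names(groups), survival$sample)
  g <- factor(groups[ids])
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("log-rank test needs two non-empty groups")
  surv <- survival[match(ids, survival$sample), , drop = FALSE]
  if (any(tapply(surv$event, g, sum) < 1))
    stop("each group needs at least one event")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
}

# Kaplan-Meier median survival of one group; NA when the curve never
# crosses 0.5.
km_median <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tbl <- summary(fit)$table
  unname(tbl["median"])
}

#' Label a two-cluster assignment as PIR / NIR
#'
#' The cluster with the longer Kaplan-Meier median survival becomes the
#' positive immune response (PIR) class. When the medians tie or are both
#' undefined, the cluster with the higher mean CD8 T-cell NES becomes PIR
#' (the PIR class is characteristically CD8-enriched); if that also ties,
#' an error asks for a manual label. Samples without survival records are
#' clustered but excluded from the log-rank test and median estimates.
#'
#' @param assignment Named 1/2 vector from [cluster_two()].
#' @param survival Clinical `data.frame`.
#' @param nes NES matrix, used only for the CD8 tie-break.
#' @param cd8_signature_ids Ids of CD8 T-cell signatures (tie-break; may be
#'   `NULL` when the medians decide).
#' @return `stratification_result`: list with `cluster_assignment`,
#'   `label_map`, `labels` (per sample), `logrank_p`, `median_survival`
#'   (per label, days, NA when undefined) and `n_per_label`.
#' @export
label_pir_nir <- function(assignment, survival, nes = NULL,
                          cd8_signature_ids = NULL) {
  if (length(unique(assignment)) != 2L)
    stop("assignment must contain exactly two clusters")
  meds <- vapply(1:2, function(k) {
    ids <- intersect(names(assignment)[assignment == k], survival$sample)
    if (!length(ids)) return(NA_real_)
    surv <- survival[match(ids, survival$sample), , drop = FALSE]
    km_median(surv$time, surv$event)
  }, numeric(1))
  pir_cluster <- NA_integer_
  if (!anyNA(meds) && meds[1] != meds[2]) {
    pir_cluster <- which.max(meds)
  } else if (sum(is.na(meds)) == 1L) {
    # an undefined median means the curve never falls below 0.5:
    # that cluster outlives the one with a defined median
    pir_cluster <- which(is.na(meds))
  } else {
    if (is.null(nes) || is.null(cd8_signature_ids))
      stop("median survival ties and no CD8 signatures supplied; ",
           "label the clusters manually")
    scores <- nes_scores(nes)
    cd8 <- scores[intersect(cd8_signature_ids, rownames(scores)), ,
                  drop = FALSE]
    cd8_mean <- vapply(1:2, function(k) {
      mean(cd8[, names(assignment)[assignment == k], drop = FALSE],
           na.rm = TRUE)
    }, numeric(1))
    if (!all(is.finite(cd8_mean)) || cd8_mean[1] == cd8_mean[2])
      stop("both the survival medians and the CD8 enrichment tie; ",
           "label the clusters manually")
    pir_cluster <- which.max(cd8_mean)
  }
  label_map <- c("NIR", "NIR")
  label_map[pir_cluster] <- "PIR"
  names(label_map) <- c("1", "2")
  labels <- stats::setNames(label_map[as.character(assignment)],
                            names(assignment))
  p <- logrank_test(assignment, survival)
  structure(
    list(cluster_assignment = assignment,
         label_map = label_map,
         labels = labels,
         logrank_p = p,
         median_survival = stats::setNames(meds, label_map),
         n_per_label = table(labels)),
    class = "stratification_result"
  )
}

#' @exportS3Method base::print
print.stratification_result <- function(x, ...) {
  cat("<stratification_result> PIR n =", sum(x$labels == "PIR"),
      ", NIR n =", sum(x$labels == "NIR"),
      ", log-rank p =", signif(x$logrank_p, 4), "\n")
  invisible(x)
}

#' Stratify one cohort end to end
#'
#' Convenience wrapper: z-score the prognostic signatures, cluster the
#' samples into two groups, and attach PIR/NIR labels.
#'
#' @inheritParams zscore_by_signature
#' @inheritParams label_pir_nir
#' @return A `stratification_result` (see [label_pir_nir()]).
#' @export
stratify_cohort <- function(nes, prognostic_ids, survival,
                            cd8_signature_ids = NULL) {
  if (!length(prognostic_ids)) stop("no prognostic signatures")
  z <- zscore_by_signature(nes, prognostic_ids)
  cl <- cluster_two(z)
  label_pir_nir(cl, survival, nes = nes,
                cd8_signature_ids = cd8_signature_ids)
}

#' Compare NES between NIR and PIR clusters for one cell type
#'
#' Two-sided two-sample Student's t-test per signature of the given cell
#' type, NIR versus PIR samples.
#'
#' @param nes NES matrix.
#' @param result A `stratification_result`.
#' @param cell_type Cell type whose signatures to test.
#' @param signatures Signature list (maps ids to cell types).
#' @return `data.frame`: `signature_id`, `t`, `p_value`, `mean_nir`,
#'   `mean_pir`.
#' @export
compare_cluster_nes <- function(nes, result, cell_type, signatures) {
  scores <- nes_scores(nes)
  ids <- signature_ids(signatures)[signature_cell_types(signatures) == cell_type]
  ids <- intersect(ids, rownames(scores))
  if (!length(ids)) stop("no signatures of cell type '", cell_type, "'")
  nir <- names(result$labels)[result$labels == "NIR"]
  pir <- names(result$labels)[result$labels == "PIR"]
  if (length(nir) < 2L || length(pir) < 2L)
    stop("each label needs at least 2 samples for a t-test")
  rows <- lapply(ids, function(id) {
    a <- scores[id, nir]
    b <- scores[id, pir]
    if (stats::var(c(a, b)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    data.frame(signature_id = id, t = unname(tt$statistic),
               p_value = tt$p.value, mean_nir = mean(a), mean_pir = mean(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
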