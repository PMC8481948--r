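# Assignment of scRNA-seq samples to the bulk-derived NIR/PIR classes.
# The sample's pseudobulk profile is scored with the same NES statistic,
# Spearman-correlated with every bulk sample over the shared prognostic
# signatures, and summarized per cohort as
#   FC_c = mean(positive rho over PIR samples) / mean(positive rho over NIR)
# The product of the per-cohort fold changes decides the label: > 1 PIR,
# < 1 NIR. Cell-composition summaries (counts, macrophage percentage,
# macrophage:microglia ratio) mirror the study's printed table layout.

#' Pseudobulk expression of a set of cells
#'
#' Per-gene mean of log2(cpm + 1) values across the chosen cells (default:
#' all cells, i.e. the whole sample).
#'
#' @param counts Genes x cells count matrix.
#' @param cells Optional cell ids / indices to average over.
#' @return Named per-gene numeric vector.
#' @export
pseudobulk <- function(counts, cells = NULL) {
  if (!is.null(cells)) {
    if (!length(cells)) stop("empty cell subset")
    counts <- counts[, cells, drop = FALSE]
  }
  if (ncol(counts) == 0L) stop("empty cell subset")
  rowMeans(log2_cpm(counts))
}

#' Signature-based cell typing
#'
#' A deliberately simple marker-signature classifier: each cell's
#' log2(cpm + 1) profile is NES-scored against every signature, scores are
#' averaged per cell type, and the cell takes the top-scoring type. Cells
#' whose top-two margin falls below `min_margin`, or with no computable
#' signature, are labeled `"unknown"`.
#'
#' @param counts Genes x cells count matrix.
#' @param signatures Signature list covering >= 2 cell types.
#' @param min_margin Minimum NES margin between the best and second-best
#'   cell type (default 0.02).
#' @param min_genes Passed to [compute_nes_matrix()].
#' @return Named character vector: cell id -> cell type.
#' @export
assign_cell_types_by_signature <- function(counts, signatures,
                                           min_margin = 0.02,
                                           min_genes = 3L) {
  types <- signature_cell_types(signatures)
  if (length(unique(types)) < 2L)
    stop("signatures must cover at least 2 cell types")
  norm <- log2_cpm(counts)
  nes <- compute_nes_matrix(norm, signatures, min_genes = min_genes)$nes
  type_means <- rowsum(nes, group = types, na.rm = TRUE) /
    rowsum((!is.na(nes)) * 1, group = types)
  labels <- apply(type_means, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return("unknown")
    ord <- order(v, decreasing = TRUE)
    if (v[ord[1]] - v[ord[2]] < min_margin) return("unknown")
    names(v)[ord[1]]
  })
  stats::setNames(labels, colnames(counts))
}

#' Spearman correlation of a single-cell profile with every bulk sample
#'
#' Works on any matched feature space: a pseudobulk expression vector
#' against a bulk expression matrix (gene space), or an NES vector against
#' a bulk NES matrix (signature space).
#'
#' @param sc_nes Named numeric profile of the single-cell sample (names
#'   are features: gene symbols or signature ids).
#' @param bulk_nes Bulk features x samples matrix (or `nes_matrix`) in the
#'   same feature space.
#' @param signature_ids Optional restriction to a feature subset (e.g.
#'   the cohort's prognostic signatures).
#' @return Named numeric vector of Spearman rho, one per bulk sample.
#' @export
spearman_to_bulk <- function(sc_nes, bulk_nes, signature_ids = NULL) {
  scores <- nes_scores(bulk_nes)
  shared <- intersect(names(sc_nes)[!is.na(sc_nes)], rownames(scores))
  if (!is.null(signature_ids)) shared <- intersect(shared, signature_ids)
  if (length(shared) < 5L)
    stop("fewer than 5 shared features between the single-cell profile ",
         "and the bulk matrix")
  sub <- scores[shared, , drop = FALSE]
  ok <- colSums(is.na(sub)) == 0
  drop(stats::cor(sc_nes[shared], sub[, ok, drop = FALSE],
                  method = "spearman"))[colnames(sub)[ok]]
}

#' Per-cohort fold change of positive correlations
#'
#' Only strictly positive rho are retained; the fold change is the mean
#' positive rho over the cohort's PIR samples divided by the mean positive
#' rho over its NIR samples. When either class retains no positive rho the
#' cohort is unusable and is excluded from the total product (flagged).
#'
#' @param rhos Named per-bulk-sample Spearman rho from [spearman_to_bulk()].
#' @param bulk_labels Named `"PIR"`/`"NIR"` labels of the bulk samples.
#' @return List: `fc`, `usable`, `n_positive_pir`, `n_positive_nir`.
#' @export
cohort_fold_change <- function(rhos, bulk_labels) {
  ids <- intersect(names(rhos), names(bulk_labels))
  if (!length(ids)) stop("no bulk labels match the correlation vector")
  labs <- bulk_labels[ids]
  if (!all(labs %in% c("PIR", "NIR")))
    stop("bulk labels must be 'PIR' or 'NIR'")
  r <- rhos[ids]
  pos_pir <- r[labs == "PIR" & r > 0]
  pos_nir <- r[labs == "NIR" & r > 0]
  if (!length(pos_pir) || !length(pos_nir)) {
    return(list(fc = NA_real_, usable = FALSE,
                n_positive_pir = length(pos_pir),
                n_positive_nir = length(pos_nir)))
  }
  list(fc = mean(pos_pir) / mean(pos_nir), usable = TRUE,
       n_positive_pir = length(pos_pir),
       n_positive_nir = length(pos_nir))
}

#' Combine per-cohort fold changes into a class assignment
#'
#' The usable cohorts' fold changes are multiplied; a total fold change
#' above 1 assigns the sample to PIR, below 1 to NIR. With fewer than two
#' usable cohorts, or a total of exactly 1, the sample stays unassigned.
#'
#' @param fcs List of [cohort_fold_change()] results (or a bare numeric
#'   vector of fold changes).
#' @param sc_sample_id Identifier stored in the result.
#' @return `sc_assignment` list: `sc_sample_id`, `fold_changes`,
#'   `total_fc`, `n_usable_cohorts`, `label`.
#' @export
total_assignment <- function(fcs, sc_sample_id = "sc_sample") {
  if (is.numeric(fcs)) fcs <- lapply(fcs, function(f) list(fc = f, usable = is.finite(f)))
  usable <- vapply(fcs, `[[`, logical(1), "usable")
  fc_vec <- vapply(fcs, `[[`, numeric(1), "fc")
  n_usable <- sum(usable)
  if (n_usable < 2L) {
    total <- NA_real_
    label <- "unassigned"
  } else {
    total <- prod(fc_vec[usable])
    label <- if (total > 1) "PIR" else if (total < 1) "NIR" else "unassigned"
  }
  structure(list(sc_sample_id = sc_sample_id,
                 fold_changes = fc_vec,
                 total_fc = total,
                 n_usable_cohorts = n_usable,
                 label = label),
            class = "sc_assignment")
}

#' @exportS3Method base::print
print.sc_assignment <- function(x, ...) {
  cat("<sc_assignment> ", x$sc_sample_id, ": total FC = ",
      signif(x$total_fc, 4), " over ", x$n_usable_cohorts,
      " cohorts -> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Assign one single-cell sample to the bulk NIR/PIR classes
#'
#' End-to-end wrapper: pseudobulk the sample, Spearman-correlate it with
#' every sample of every bulk cohort, form the per-cohort positive-rho fold
#' changes and multiply. By default the correlation runs in gene space
#' (pseudobulk log2(cpm + 1) against each bulk expression profile over the
#' shared genes): with thousands of shared genes the correlations are
#' predominantly positive, which is the regime the retain-positive /
#' mean-ratio rule assumes. `space = "nes"` instead correlates
#' NES vectors over the cohort's prognostic signatures; with only tens of
#' coordinates many correlations go negative and whole cohorts can drop
#' out as unusable, so this variant is offered for comparison rather than
#' as the default.
#'
#' @param sc_counts Genes x cells count matrix of the sample.
#' @param signatures Signature list shared with the bulk analysis.
#' @param bulk_nes_list List of per-cohort bulk `nes_matrix` objects
#'   (`space = "nes"` only; may be `NULL` otherwise).
#' @param bulk_labels_list List of per-cohort named PIR/NIR label vectors.
#' @param prognostic_ids_list List of per-cohort prognostic signature ids
#'   (`space = "nes"` only).
#' @param sc_sample_id Identifier for the result.
#' @param cells Optional cell subset for the pseudobulk (default all).
#' @param space `"genes"` (default) or `"nes"`.
#' @param bulk_expr_list List of per-cohort genes x samples expression
#'   matrices (`space = "genes"` only).
#' @return An `sc_assignment` (see [total_assignment()]).
#' @export
assign_sc_sample <- function(sc_counts, signatures, bulk_nes_list = NULL,
                             bulk_labels_list = NULL,
                             prognostic_ids_list = NULL,
                             sc_sample_id = "sc_sample", cells = NULL,
                             space = c("genes", "nes"),
                             bulk_expr_list = NULL) {
  space <- match.arg(space)
  pb <- pseudobulk(sc_counts, cells)
  if (space == "genes") {
    if (is.null(bulk_expr_list) || is.null(bulk_labels_list))
      stop("space = 'genes' needs bulk_expr_list and bulk_labels_list")
    stopifnot(length(bulk_expr_list) == length(bulk_labels_list))
    fcs <- lapply(seq_along(bulk_expr_list), function(c_i) {
      rhos <- spearman_to_bulk(pb, bulk_expr_list[[c_i]])
      cohort_fold_change(rhos, bulk_labels_list[[c_i]])
    })
  } else {
    if (is.null(bulk_nes_list) || is.null(prognostic_ids_list))
      stop("space = 'nes' needs bulk_nes_list and prognostic_ids_list")
    stopifnot(length(bulk_nes_list) == length(bulk_labels_list),
              length(bulk_nes_list) == length(prognostic_ids_list))
    sc_nes <- compute_nes_matrix(matrix(pb, ncol = 1,
                                        dimnames = list(names(pb), "pb")),
                                 signatures)$nes[, 1]
    fcs <- lapply(seq_along(bulk_nes_list), function(c_i) {
      rhos <- spearman_to_bulk(sc_nes, bulk_nes_list[[c_i]],
                               signature_ids = prognostic_ids_list[[c_i]])
      cohort_fold_change(rhos, bulk_labels_list[[c_i]])
    })
  }
  total_assignment(fcs, sc_sample_id = sc_sample_id)
}

#' Cell-composition summary of a single-cell sample
#'
#' Counts per cell type plus the two headline quantities of the study's
#' summary table: the macrophage percentage of all cells (half-up rounded
#' to 2 decimals) and the macrophage:microglia ratio (half-up rounded to 2
#' decimals, formatted em-dash when no microglia are present).
#'
#' @param cell_labels Named character vector, cell id -> cell type
#'   (`"unknown"` counts as its own type).
#' @param sample_id Identifier stored in the summary.
#' @param macrophage_label,microglia_label Type labels to summarize.
#' @return List of class `composition_summary`: `sample_id`, `counts`
#'   (named vector), `total_cells`, `macrophage_pct`,
#'   `mac_microglia_ratio` (NA when microglia = 0) and
#'   `mac_microglia_ratio_label` (`"—"` when undefined).
#' @export
composition_summary <- function(cell_labels, sample_id = "sample",
                                macrophage_label = "macrophage",
                                microglia_label = "microglia") {
  if (!length(cell_labels)) stop("zero cells")
  counts <- table(cell_labels)
  total <- length(cell_labels)
  n_mac <- if (macrophage_label %in% names(counts))
    as.integer(counts[[macrophage_label]]) else 0L
  n_mic <- if (microglia_label %in% names(counts))
    as.integer(counts[[microglia_label]]) else 0L
  pct <- round_half_up(100 * n_mac / total, 2L)
  if (n_mic > 0L) {
    ratio <- round_half_up(n_mac / n_mic, 2L)
    ratio_label <- format(ratio)
  } else {
    ratio <- NA_real_
    ratio_label <- "—"
  }
  structure(list(sample_id = sample_id,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 total_cells = total,
                 macrophage_pct = pct,
                 mac_microglia_ratio = ratio,
                 mac_microglia_ratio_label = ratio_label),
            class = "composition_summary")
}

#' @exportS3Method base::print
print.composition_summary <- function(x, ...) {
  cat("<composition_summary> ", x$sample_id, ": ", x$total_cells,
      " cells, macrophage ", x$macrophage_pct, "%, mac:microglia ",
      x$mac_microglia_ratio_label, "\n", sep = "")
  invisible(x)
}

#' Compare cell-fraction percentages between two groups
#'
#' Two-sided Wilcoxon rank-sum test; exact when the combined sample size is
#' at most 20 (and ties permit), normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors of per-sample percentages, each
#'   with at least 3 values.
#' @return Two-sided p-value.
#' @export
compare_fraction_groups <- function(group_a, group_b) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 values")
  n <- length(group_a) + length(group_b)
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = n <= 20,
                       correct = n > 20)$p.value
  )
}
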