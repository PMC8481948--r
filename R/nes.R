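# Normalized enrichment score (NES): the Mann-Whitney-Wilcoxon rank
# construction. For one signature in one sample, all measured genes are
# ranked ascending; with T the rank-sum of the m in-set genes and n the
# number of genes outside the set,
#
#   U   = n*m + m*(m+1)/2 - T
#   NES = 1 - U / (m*n)
#
# which equals the probability that a randomly chosen signature gene is
# expressed above a randomly chosen non-signature gene (ties count 1/2).
# NES = 1 means the signature occupies the top of the expression ranking.

#' Ascending ranks with average ties
#'
#' Midranks over a finite numeric vector: ties receive the average of the
#' rank positions they span, so the rank-sum is always N(N+1)/2.
#'
#' @param values Finite numeric vector, length >= 2.
#' @return Numeric vector of ranks.
#' @export
rank_with_ties <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to rank")
  if (any(!is.finite(values))) stop("non-finite values cannot be ranked")
  rank(values, ties.method = "average")
}

#' NES of one signature in one sample
#'
#' @param sample_values Named numeric vector: expression of every measured
#'   gene in one sample (names are gene symbols).
#' @param signature A [gene_signature()].
#' @param min_genes Minimum number of signature genes that must be present
#'   in the sample for a score to be returned; below it the result is `NA`.
#' @return NES in `[0, 1]`, or `NA` when fewer than `min_genes` signature
#'   genes are measured.
#' @export
compute_nes <- function(sample_values, signature, min_genes = 3L) {
  if (!length(sample_values)) stop("empty sample")
  if (is.null(names(sample_values))) stop("sample values must be gene-named")
  in_set <- names(sample_values) %in% signature$genes
  m <- sum(in_set)
  if (m < min_genes) return(NA_real_)
  n <- length(sample_values) - m
  if (n == 0L)
    stop("signature '", signature$signature_id,
         "' covers every measured gene; NES is undefined (n = 0)")
  r <- rank_with_ties(sample_values)
  T_sum <- sum(r[in_set])
  U <- n * m + m * (m + 1) / 2 - T_sum
  1 - U / (m * n)
}

#' NES matrix: every signature scored in every sample
#'
#' The per-sample ranking of the full gene universe (all rows of `expr`) is
#' computed once and reused across signatures. Signatures matching fewer
#' than `min_genes` measured genes yield `NA` for every sample.
#'
#' @param expr Genes x samples numeric matrix (see [expression_matrix()]);
#'   any strictly monotone transform of expression gives identical NES.
#' @param signatures Non-empty list of [gene_signature()] objects.
#' @param min_genes Minimum matched genes per signature (default 3).
#' @return An object of class `nes_matrix`: list with `nes` (signatures x
#'   samples matrix in `[0,1]` or `NA`) and `m_used` (matched gene counts,
#'   same shape).
#' @export
compute_nes_matrix <- function(expr, signatures, min_genes = 3L) {
  if (!length(signatures)) stop("no signatures supplied")
  if (!is.matrix(expr) || nrow(expr) < 2L || ncol(expr) < 1L)
    stop("expr must be a genes x samples matrix with >= 2 genes")
  if (any(!is.finite(expr))) stop("expression matrix has non-finite values")
  N <- nrow(expr)
  ranks <- apply(expr, 2L, rank, ties.method = "average")
  ids <- signature_ids(signatures)
  nes <- matrix(NA_real_, length(signatures), ncol(expr),
                dimnames = list(ids, colnames(expr)))
  m_used <- matrix(0L, length(signatures), ncol(expr),
                   dimnames = dimnames(nes))
  for (i in seq_along(signatures)) {
    idx <- which(rownames(expr) %in% signatures[[i]]$genes)
    m <- length(idx)
    m_used[i, ] <- m
    if (m < min_genes) next
    n <- N - m
    if (n == 0L)
      stop("signature '", ids[i], "' covers the whole gene universe")
    T_sum <- colSums(ranks[idx, , drop = FALSE])
    nes[i, ] <- 1 - (n * m + m * (m + 1) / 2 - T_sum) / (m * n)
  }
  if (all(is.na(nes)))
    stop("every signature matched fewer than min_genes = ", min_genes,
         " measured genes")
  structure(list(nes = nes, m_used = m_used, min_genes = min_genes),
            class = "nes_matrix")
}

#' @exportS3Method base::print
print.nes_matrix <- function(x, ...) {
  cat("<nes_matrix> ", nrow(x$nes), " signatures x ", ncol(x$nes),
      " samples (", sum(rowSums(!is.na(x$nes)) > 0), " scored, min_genes = ",
      x$min_genes, ")\n", sep = "")
  invisible(x)
}

# Accept either a nes_matrix or a bare signatures x samples matrix.
nes_scores <- function(x) {
  if (inherits(x, "nes_matrix")) x$nes else x
}

#' Write a NES matrix (and its matched-gene counts) to TSV
#'
#' @param nes A `nes_matrix`.
#' @param path Output TSV for the scores (signatures x samples).
#' @param m_used_path Optional TSV path for the matched-gene counts.
#' @return `path`, invisibly.
#' @export
write_nes_matrix <- function(nes, path, m_used_path = NULL) {
  write_expression_matrix(nes$nes, path, id_column = "signature_id")
  if (!is.null(m_used_path))
    write_expression_matrix(nes$m_used, m_used_path, id_column = "signature_id")
  invisible(path)
}
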