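# Readers and writers for the external formats the pipeline touches. All
# loaders validate strictly and reject malformed records rather than coercing
# them; downstream modules only ever see validated in-memory objects.

#' Lineage categories recognised for gene signatures
#'
#' Cell types are grouped into hematopoietic stem cells, the lymphoid and
#' myeloid hematopoietic lineages, stromal cells, and a catch-all for
#' everything else (neurons, astrocytes, epithelium, ...).
#'
#' @return Character vector of the five category names.
#' @export
signature_categories <- function() {
  c("HSC", "lymphoid", "myeloid", "stromal", "other")
}

#' Construct a gene signature
#'
#' A gene signature is a named set of marker genes tied to one cell type and
#' one lineage category. Several signatures (from different sources) may
#' describe the same cell type; the cell-type field is what links them when
#' risk directions are aggregated.
#'
#' @param signature_id Unique signature identifier.
#' @param cell_type Cell type the signature marks.
#' @param category One of [signature_categories()].
#' @param source Free-text provenance string.
#' @param genes Character vector of gene symbols (duplicates are collapsed;
#'   must be non-empty).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(signature_id, cell_type, category = "other",
                           source = "", genes) {
  stopifnot(is.character(signature_id), length(signature_id) == 1L,
            nzchar(signature_id))
  category <- match.arg(category, signature_categories())
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) < 1L)
    stop("signature '", signature_id, "': gene set is empty")
  structure(
    list(signature_id = signature_id,
         cell_type = as.character(cell_type),
         category = category,
         source = as.character(source),
         genes = genes),
    class = "gene_signature"
  )
}

#' @exportS3Method base::print
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$signature_id, " (", x$cell_type, ", ",
      x$category, "): ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

signature_ids <- function(signatures) {
  vapply(signatures, `[[`, character(1), "signature_id")
}

signature_cell_types <- function(signatures) {
  vapply(signatures, `[[`, character(1), "cell_type")
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' When the description matches `cell_type|category|source` (with a known
#' category) those fields are split out; otherwise the whole description is
#' kept as the source and the cell type defaults to the signature name.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_signature()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i,
           ": expected at least 3 tab-separated fields (name, description, genes)")
    name <- fields[[1]]
    desc <- fields[[2]]
    genes <- fields[-(1:2)]
    parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
    if (length(parts) == 3L && parts[[2]] %in% signature_categories()) {
      sigs[[i]] <- gene_signature(name, parts[[1]], parts[[2]], parts[[3]], genes)
    } else {
      sigs[[i]] <- gene_signature(name, cell_type = name, category = "other",
                                  source = desc, genes = genes)
    }
  }
  ids <- signature_ids(sigs)
  if (anyDuplicated(ids))
    stop("duplicate signature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sigs) <- ids
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures List of [gene_signature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    paste(c(s$signature_id,
            paste(s$cell_type, s$category, s$source, sep = "|"),
            s$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names and no missing values.
#' @param scale Either `"linear"` or `"log"`; carried as an attribute so
#'   downstream code can document what it received (the NES is rank-based and
#'   indifferent to strictly monotone rescaling).
#' @return The matrix with a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  attr(values, "scale") <- scale
  values
}

#' Read a bulk expression matrix from TSV
#'
#' The first column holds identifiers, the header the other dimension's
#' identifiers. Regardless of the file's orientation the result is genes x
#' samples. Duplicate gene symbols are collapsed to their per-sample mean
#' (with a warning); missing or non-numeric cells are an error, never
#' imputed.
#'
#' @param path TSV file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale Declared scale of the values, `"linear"` or `"log"`.
#' @return A genes x samples [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows"),
                                   scale = c("linear", "log")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    stop("empty expression matrix in ", path)
  ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric value at row ", bad[1], ", column '",
             colnames(vals)[j], "' of ", path)
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing value at row ", idx[1], ", column '",
         colnames(mat)[idx[2]], "' of ", path)
  }
  if (orientation == "samples_in_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) {
    n_dup <- sum(duplicated(rownames(mat)))
    groups <- rownames(mat)
    mat <- rowsum(mat, group = groups, reorder = FALSE) /
      as.vector(table(factor(groups, levels = unique(groups))))
    warning("collapsed ", n_dup, " duplicate gene row(s) by per-sample mean")
  }
  expression_matrix(mat, scale = scale)
}

#' Write an expression matrix (or any named numeric matrix) to TSV
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name of the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a clinical survival table
#'
#' Expects columns `sample`, `time` (overall survival, days, strictly
#' positive) and `event` (1 = death, 0 = censored). Offending rows are
#' reported by number and position; samples without expression data are
#' reported via a warning but kept.
#'
#' @param path TSV file path.
#' @param expression_samples Optional character vector of sample ids present
#'   in the matched expression matrix, used only to report discrepancies.
#' @return `data.frame` with columns `sample`, `time`, `event`.
#' @export
read_clinical <- function(path, expression_samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sample <- as.character(df$sample)
  df$time <- suppressWarnings(as.numeric(df$time))
  df$event <- suppressWarnings(as.numeric(df$event))
  bad <- which(is.na(df$time) | df$time <= 0 |
                 is.na(df$event) | !(df$event %in% c(0, 1)))
  if (length(bad))
    stop("invalid clinical rows (time must be > 0, event in {0,1}): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in clinical table: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (!is.null(expression_samples)) {
    missing <- setdiff(df$sample, expression_samples)
    if (length(missing))
      warning(length(missing),
              " clinical sample(s) absent from the expression matrix: ",
              paste(utils::head(missing, 10), collapse = ", "))
  }
  df
}

#' @rdname read_clinical
#' @param clinical A validated clinical `data.frame`.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t")
  invisible(path)
}

#' Read a gene annotation table (gene, chromosome, position)
#'
#' BED-like 0-based positions. The result is sorted by (chromosome,
#' position) with natural chromosome ordering, which is the gene order the
#' moving-average CNV profile smooths along.
#'
#' @param path TSV file path with columns `gene`, `chromosome`, `position`.
#' @return Sorted `data.frame` with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene", "chromosome", "position")
  if (!all(need %in% colnames(df)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$gene <- as.character(df$gene)
  df$chromosome <- as.character(df$chromosome)
  df$position <- suppressWarnings(as.numeric(df$position))
  if (any(is.na(df$position) | df$position < 0))
    stop("gene annotation positions must be numeric and >= 0")
  if (anyDuplicated(df$gene))
    stop("duplicate genes in annotation: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df <- df[order_by_chromosome(df$chromosome, df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_gene_annotation
#' @param annotation A gene annotation `data.frame`.
#' @export
write_gene_annotation <- function(annotation, path) {
  data.table::fwrite(annotation, path, sep = "\t")
  invisible(path)
}

#' Read a single-cell count matrix
#'
#' Accepts either MatrixMarket (`.mtx`, with companion `features`/`barcodes`
#' TSVs, genes in rows) or a dense TSV laid out like
#' [read_expression_matrix()]. Counts must be non-negative integers.
#'
#' @param path Count matrix path (`.mtx` or TSV).
#' @param features,barcodes Companion files for `.mtx` input: one gene id /
#'   one cell id per line (first column used).
#' @return A genes x cells `dgCMatrix` (MTX input) or base matrix (TSV).
#' @export
read_sc_counts <- function(path, features = NULL, barcodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(features) || is.null(barcodes))
      stop("MTX input requires 'features' and 'barcodes' files")
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    feat <- data.table::fread(features, header = FALSE, data.table = FALSE)
    bc <- data.table::fread(barcodes, header = FALSE, data.table = FALSE)
    if (nrow(feat) != nrow(m) || nrow(bc) != ncol(m))
      stop("features/barcodes dimensions do not match the matrix")
    dimnames(m) <- list(as.character(feat[[1]]), as.character(bc[[1]]))
    counts <- m
    vals <- counts@x
  } else {
    counts <- unclass(read_expression_matrix(path))
    attr(counts, "scale") <- NULL
    vals <- counts
  }
  if (any(vals < 0) || any(vals != round(vals)))
    stop("single-cell counts must be non-negative integers")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or cell ids in count matrix")
  counts
}

#' @rdname read_sc_counts
#' @param counts Genes x cells count matrix (sparse or dense).
#' @export
write_sc_counts <- function(counts, path, features = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(features) || is.null(barcodes))
      stop("MTX output requires 'features' and 'barcodes' paths")
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"), path)
    writeLines(rownames(counts), features)
    writeLines(colnames(counts), barcodes)
  } else {
    write_expression_matrix(as.matrix(counts), path)
  }
  invisible(path)
}
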