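# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes -- a signature registry with several partially overlapping
# signatures per cell type, bulk cohorts whose two latent groups differ in
# cell-type enrichment and survival, and droplet-scale single-cell samples
# with planted copy-number shifts -- with full ground truth, so every
# pipeline stage is testable without any external download.

#' Default cell-type panel for simulations
#'
#' A compact panel mirroring the structure of the glioblastoma
#' microenvironment analysis: myeloid and stromal risk types enriched in
#' the short-survival (NIR-like) group, CD8/plasma protective types
#' enriched in the long-survival (PIR-like) group, and neutral types.
#' `beta` is the per-unit log-hazard of the type's latent enrichment;
#' `nir_shift` is +1 / -1 / 0 for NIR-enriched / PIR-enriched / neutral.
#'
#' @return `data.frame` with columns `cell_type`, `category`, `beta`,
#'   `nir_shift`.
#' @export
default_cell_types <- function() {
  data.frame(
    cell_type = c("macrophage", "mesenchymal_stem_cell", "astrocyte",
                  "CD8_T_cell", "CD8_naive_T_cell", "plasma_cell",
                  "microglia", "neuron"),
    category = c("myeloid", "stromal", "other",
                 "lymphoid", "lymphoid", "lymphoid",
                 "myeloid", "other"),
    beta = c(0.8, 0.8, 0.8, -0.8, -0.8, -0.8, 0, 0),
    nir_shift = c(1, 1, 1, -1, -1, -1, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic generators. Defaults
#' are desk-scale study conditions: 4 cohorts of 100 samples over a
#' 2,000-gene universe on 10 chromosomes, 3 signatures of 40 genes per cell
#' type, a 1.5-noise-sd group effect on discriminating signatures,
#' exponential survival with per-type log-hazards of magnitude 0.8 and 30%
#' censoring, and single-cell samples of 2,000 cells with a 0.5 log2
#' copy-number shift and negative-binomial dispersion 0.5.
#'
#' @param seed Master seed (integer).
#' @param n_genes Gene-universe size.
#' @param n_chromosomes Chromosomes (`chr1..chrN`, genes split evenly).
#' @param n_samples Samples per bulk cohort.
#' @param n_cohorts Number of bulk cohorts.
#' @param pir_fraction Fraction of PIR-like samples per cohort.
#' @param group_effect Log-expression shift on group-discriminating
#'   signature genes, in units of `noise_sd`.
#' @param noise_sd Per-gene log-expression noise sd.
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param censoring_fraction Expected fraction of censored samples.
#' @param cell_types Cell-type panel (see [default_cell_types()]).
#' @param signatures_per_type,signature_size Registry shape.
#' @param sc List of single-cell knobs: `n_cells`, `cnv_delta` (log2 shift
#'   on chr7/chr10 of malignant cells), `nb_dispersion`,
#'   `libsize_meanlog`, `libsize_sdlog`, `type_effect` (log2 boost of a
#'   cell's own signature genes), `proportions` (per-profile named
#'   cell-type proportion vectors, must each sum to 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_chromosomes = 10L,
                       n_samples = 100L,
                       n_cohorts = 4L,
                       pir_fraction = 0.4,
                       group_effect = 1.5,
                       noise_sd = 1,
                       baseline_hazard = 1 / 500,
                       censoring_fraction = 0.3,
                       cell_types = default_cell_types(),
                       signatures_per_type = 3L,
                       signature_size = 40L,
                       sc = list()) {
  sc_defaults <- list(
    n_cells = 2000L,
    cnv_delta = 0.5,
    nb_dispersion = 0.5,
    libsize_meanlog = log(5000),
    libsize_sdlog = 0.3,
    type_effect = 2,
    proportions = list(
      "NIR-like" = c(malignant = 0.25, macrophage = 0.50, microglia = 0.02,
                     CD8_T_cell = 0.03, mesenchymal_stem_cell = 0.05,
                     astrocyte = 0.05, neuron = 0.10),
      "PIR-like" = c(malignant = 0.35, macrophage = 0.05, microglia = 0.05,
                     CD8_T_cell = 0.25, mesenchymal_stem_cell = 0.01,
                     astrocyte = 0.09, neuron = 0.20)
    )
  )
  sc <- utils::modifyList(sc_defaults, sc)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              n_samples = as.integer(n_samples),
              n_cohorts = as.integer(n_cohorts),
              pir_fraction = pir_fraction, group_effect = group_effect,
              noise_sd = noise_sd, baseline_hazard = baseline_hazard,
              censoring_fraction = censoring_fraction,
              cell_types = cell_types,
              signatures_per_type = as.integer(signatures_per_type),
              signature_size = as.integer(signature_size),
              sc = sc)
  with(cfg, {
    stopifnot(n_genes > 0, n_chromosomes > 0, n_samples > 0, n_cohorts > 0,
              signatures_per_type > 0, signature_size > 0,
              signature_size <= n_genes,
              pir_fraction > 0, pir_fraction < 1,
              noise_sd > 0, baseline_hazard > 0,
              censoring_fraction >= 0, censoring_fraction < 1,
              nrow(cell_types) >= 2)
  })
  for (p in cfg$sc$proportions) {
    if (abs(sum(p) - 1) > 1e-8)
      stop("single-cell type proportions must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Build the gene universe and signature registry
#'
#' Genes are spread evenly over `chr1..chrN` with ordered positions. Each
#' cell type receives a disjoint marker pool; every signature of a type is
#' built from a small shared core of canonical markers (10% of the
#' signature size, common to the type's signatures), a disjoint private
#' block, and a few genes drawn from the shared background pool -- giving
#' realistic partial overlaps while keeping every pairwise Jaccard index
#' far below 0.2.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (gene annotation `data.frame`) and
#'   `signatures` (named list of [gene_signature()]).
#' @export
make_universe_and_signatures <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  # even split in genome order: first block chr1, next chr2, ...
  per_chr <- ceiling(n / config$n_chromosomes)
  chrom <- paste0("chr", rep(seq_len(config$n_chromosomes),
                             each = per_chr))[seq_len(n)]
  position <- stats::ave(seq_len(n), chrom, FUN = seq_along) * 1000
  annotation <- data.frame(gene = genes, chromosome = chrom,
                           position = position, stringsAsFactors = FALSE)
  annotation <- annotation[order_by_chromosome(annotation$chromosome,
                                               annotation$position), ]
  rownames(annotation) <- NULL

  ct <- config$cell_types
  s <- config$signature_size
  k <- config$signatures_per_type
  n_core <- max(1L, ceiling(0.10 * s))
  n_bg <- max(1L, ceiling(0.05 * s))
  n_priv <- s - n_core - n_bg
  pool_size <- n_core + k * n_priv
  if (nrow(ct) * pool_size + n_bg > config$n_genes)
    stop("gene universe too small for the requested signature registry")
  shuffled <- sample(genes)
  signatures <- list()
  offset <- 0L
  for (t_i in seq_len(nrow(ct))) {
    pool <- shuffled[offset + seq_len(pool_size)]
    offset <- offset + pool_size
    core <- pool[seq_len(n_core)]
    private <- pool[-seq_len(n_core)]
    for (j in seq_len(k)) {
      priv_j <- private[(j - 1L) * n_priv + seq_len(n_priv)]
      bg_j <- sample(shuffled[-seq_len(nrow(ct) * pool_size)], n_bg)
      sig_id <- paste0(ct$cell_type[t_i], "_sig", j)
      signatures[[sig_id]] <- gene_signature(
        sig_id, cell_type = ct$cell_type[t_i],
        category = ct$category[t_i],
        source = "synthetic", genes = c(core, priv_j, bg_j))
    }
  }
  list(annotation = annotation, signatures = signatures)
}

#' Simulate one bulk expression cohort with survival
#'
#' Each sample belongs to a latent NIR-like or PIR-like group. Per cell
#' type the sample's latent enrichment is `e_k = 0.2 + 0.3` when the group
#' matches the type's enrichment direction (`+ N(0, 0.05)` jitter, clipped
#' to `[0, 1]`). Log-expression of gene `g` is its baseline plus
#' `group_effect * noise_sd * sum_k e_k` over the types whose signatures
#' contain `g`, plus `N(0, noise_sd)` noise. Survival is exponential with
#' hazard `baseline_hazard * exp(sum_k beta_k e_k)` (or, when
#' `group_hazard_ratio` is given, `baseline_hazard * HR^[group = NIR]`),
#' with independent uniform censoring at the configured fraction.
#'
#' @param config A [sim_config()].
#' @param universe Output of [make_universe_and_signatures()].
#' @param seed Seed for this cohort (default the config seed).
#' @param group_hazard_ratio Optional planted hazard ratio of the NIR-like
#'   group relative to PIR-like, replacing the beta-driven hazards.
#' @return List: `expr` (genes x samples log-scale matrix), `survival`
#'   (clinical `data.frame`), `truth` (list with `group`, `e` matrix of
#'   latent enrichments, `cell_types`).
#' @export
simulate_bulk_cohort <- function(config, universe, seed = config$seed,
                                 group_hazard_ratio = NULL) {
  set.seed(seed)
  ns <- config$n_samples
  genes <- universe$annotation$gene
  ct <- config$cell_types
  samples <- sprintf("s%03d", seq_len(ns))
  group <- ifelse(stats::runif(ns) < config$pir_fraction,
                  "PIR-like", "NIR-like")
  names(group) <- samples
  shift_dir <- stats::setNames(ct$nir_shift, ct$cell_type)
  e <- matrix(0.2, nrow(ct), ns,
              dimnames = list(ct$cell_type, samples))
  for (t_i in seq_len(nrow(ct))) {
    matches <- (group == "NIR-like" & ct$nir_shift[t_i] > 0) |
      (group == "PIR-like" & ct$nir_shift[t_i] < 0)
    e[t_i, ] <- pmin(1, pmax(0, 0.2 + 0.3 * matches +
                               stats::rnorm(ns, 0, 0.05)))
  }
  # membership: gene x type indicator over the type's signatures
  sig_types <- signature_cell_types(universe$signatures)
  member <- matrix(0, length(genes), nrow(ct),
                   dimnames = list(genes, ct$cell_type))
  for (i in seq_along(universe$signatures)) {
    member[universe$signatures[[i]]$genes, sig_types[i]] <- 1
  }
  mu <- stats::rnorm(length(genes), 3, 1)
  expr <- mu + config$group_effect * config$noise_sd * (member %*% e) +
    matrix(stats::rnorm(length(genes) * ns, 0, config$noise_sd),
           length(genes), ns)
  dimnames(expr) <- list(genes, samples)
  if (is.null(group_hazard_ratio)) {
    loghaz <- drop(crossprod(e, ct$beta))
  } else {
    loghaz <- log(group_hazard_ratio) * (group == "NIR-like")
  }
  hazard <- config$baseline_hazard * exp(loghaz)
  time <- stats::rexp(ns, rate = hazard)
  event <- rep(1, ns)
  cens <- stats::runif(ns) < config$censoring_fraction
  time[cens] <- stats::runif(sum(cens), 0, time[cens])
  event[cens] <- 0
  time <- pmax(time, 0.5)  # strictly positive, half-day floor
  survival <- data.frame(sample = samples, time = time, event = event,
                         stringsAsFactors = FALSE)
  list(expr = expression_matrix(expr, scale = "log"),
       survival = survival,
       truth = list(group = group, e = e, cell_types = ct))
}

#' Simulate one single-cell sample with planted CNVs
#'
#' Cell types (including `"malignant"`) are drawn from the profile's
#' proportions. Each cell's expected expression is a per-gene baseline plus
#' a `type_effect` log2 boost on its own type's signature genes; malignant
#' cells additionally gain `cnv_delta` log2 units on chromosome 7 genes and
#' lose the same on chromosome 10. Counts are negative binomial around
#' library sizes drawn log-normally.
#'
#' @param config A [sim_config()].
#' @param universe Output of [make_universe_and_signatures()].
#' @param profile `"NIR-like"` (macrophage-rich) or `"PIR-like"`
#'   (CD8-rich), selecting the configured proportions.
#' @param seed Seed for this sample.
#' @param n_cells Optional override of `config$sc$n_cells`.
#' @return List: `counts` (genes x cells integer matrix), `truth` (list
#'   with `cell_type`, `malignant`, `profile`).
#' @export
simulate_sc_sample <- function(config, universe,
                               profile = c("NIR-like", "PIR-like"),
                               seed = config$seed, n_cells = NULL) {
  profile <- match.arg(profile)
  set.seed(seed)
  sc <- config$sc
  n_cells <- n_cells %||% sc$n_cells
  props <- sc$proportions[[profile]]
  ann <- universe$annotation
  genes <- ann$gene
  types <- sample(names(props), n_cells, replace = TRUE, prob = props)
  cells <- sprintf("c%05d", seq_len(n_cells))
  base <- stats::rnorm(length(genes), 1.5, 0.5)
  names(base) <- genes
  sig_types <- signature_cell_types(universe$signatures)
  boost <- matrix(0, length(genes), length(props),
                  dimnames = list(genes, names(props)))
  for (i in seq_along(universe$signatures)) {
    tt <- sig_types[i]
    if (tt %in% colnames(boost))
      boost[universe$signatures[[i]]$genes, tt] <- sc$type_effect
  }
  chr7 <- genes[ann$chromosome == "chr7"]
  chr10 <- genes[ann$chromosome == "chr10"]
  libsize <- stats::rlnorm(n_cells, sc$libsize_meanlog, sc$libsize_sdlog)
  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, cells))
  size <- 1 / sc$nb_dispersion
  for (j in seq_len(n_cells)) {
    logmean <- base + boost[, types[j]]
    if (types[j] == "malignant") {
      logmean[chr7] <- logmean[chr7] + sc$cnv_delta
      logmean[chr10] <- logmean[chr10] - sc$cnv_delta
    }
    p <- 2^logmean
    mu <- libsize[j] * p / sum(p)
    counts[, j] <- stats::rnbinom(length(genes), mu = mu, size = size)
  }
  list(counts = counts,
       truth = list(cell_type = stats::setNames(types, cells),
                    malignant = stats::setNames(types == "malignant", cells),
                    profile = profile))
}
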