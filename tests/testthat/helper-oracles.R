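# Independent oracles and small fixture builders shared across tests.
# Each oracle re-derives the quantity from first principles, never through
# the package's own code path.

# Pairwise-counting oracle for the NES: fraction of (in-set, out-set) gene
# pairs where the in-set gene is higher, ties counting one half.
nes_pairwise_oracle <- function(values, in_set_genes) {
  a <- values[names(values) %in% in_set_genes]
  b <- values[!(names(values) %in% in_set_genes)]
  wins <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(wins)
}

# Naive windowed mean along one chromosome: nominal window
# [i - (c-1), i + (w-c)] with c = ceiling(w/2), clipped to the ends.
moving_average_oracle <- function(x, window) {
  L <- length(x)
  ctr <- ceiling(window / 2)
  vapply(seq_len(L), function(i) {
    lo <- max(1L, i - (ctr - 1L))
    hi <- min(L, i + (window - ctr))
    mean(x[lo:hi])
  }, numeric(1))
}

# Exact two-sided rank-sum p by exhaustive enumeration of all C(n, na)
# group assignments of the pooled ranks.
ranksum_enumeration_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  na <- length(a)
  r <- rank(vals)
  obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  sums <- colSums(matrix(r[combs], nrow = na))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Compact simulation config for fast unit tests; overrides win.
small_config <- function(seed = 42L, ...) {
  args <- list(seed = seed, n_genes = 1000L, n_samples = 50L,
               n_cohorts = 2L, signature_size = 30L,
               sc = list(n_cells = 150L))
  dots <- list(...)
  if (!is.null(dots$sc)) dots$sc <- utils::modifyList(args$sc, dots$sc)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# The printed single-cell summary table used as the worked example:
# per-sample macrophage / microglia / total cell counts with the published
# percentage and ratio columns.
table2_rows <- function() {
  data.frame(
    sample = c("PJ016", "PJ017", "PJ018", "PJ025",
               "PJ030", "PJ032", "PJ035", "PJ048"),
    macrophage = c(0, 588, 50, 101, 258, 759, 306, 0),
    microglia = c(0, 6, 13, 33, 108, 22, 232, 0),
    all_cells = c(3085, 1261, 2197, 5924, 3097, 1377, 3768, 3084),
    pct = c(0, 46.63, 2.28, 1.70, 8.33, 55.12, 8.12, 0),
    ratio = c(NA, 98, 3.85, 3.06, 2.39, 34.5, 1.32, NA),
    ratio_label = c("—", "98", "3.85", "3.06", "2.39", "34.5",
                    "1.32", "—"),
    stringsAsFactors = FALSE
  )
}

# Cell-label vector realizing given macrophage/microglia/total counts.
labels_from_counts <- function(n_mac, n_mic, n_all) {
  c(rep("macrophage", n_mac), rep("microglia", n_mic),
    rep("other", n_all - n_mac - n_mic))
}
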