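# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is round-half-even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Natural ordering rank for chromosome labels: numeric chromosomes first in
# numeric order, then the rest alphabetically ("chr" prefix optional).
chromosome_rank <- function(chroms) {
  stripped <- sub("^chr", "", as.character(chroms))
  num <- suppressWarnings(as.numeric(stripped))
  is_num <- !is.na(num)
  rank_key <- numeric(length(chroms))
  rank_key[is_num] <- num[is_num]
  # non-numeric labels sort after all numeric ones
  if (any(!is_num)) {
    offset <- if (any(is_num)) max(num[is_num]) else 0
    rank_key[!is_num] <- offset + 1 + match(stripped[!is_num],
                                            sort(unique(stripped[!is_num])))
  }
  rank_key
}

order_by_chromosome <- function(chromosome, position) {
  order(chromosome_rank(chromosome), position)
}

# Polynomial rolling hash over a serialized object; used only to fingerprint
# pipeline configs in the run manifest (no cryptographic intent).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
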