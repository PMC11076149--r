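# Internal helpers shared across modules.

# Locale-independent ordering (radix method = C collation), so that canonical
# row orders and tie-breaks are identical on every platform.
order_c <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vaxtwin <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "vaxtwin_error")))
}

# Multinomial draws with a per-column trial count and a per-column weight
# vector, vectorized across columns (cells). Uses the chain-rule
# decomposition of the multinomial into sequential binomials so that a
# single call serves all cells at once:
#   m_k | m_1..m_{k-1} ~ Binomial(n - sum(m_<k), w_k / sum(w_>=k)).
# Tail sums are accumulated bottom-up so the last positive-weight category
# of each column gets probability exactly 1 and counts are conserved
# exactly: colSums(result) == sizes whenever a column with sizes > 0 has at
# least one positive weight.
#
# sizes: length-M non-negative integers; weights: K x M non-negative matrix.
rmultinom_chain <- function(sizes, weights) {
  K <- nrow(weights)
  M <- ncol(weights)
  stopifnot(length(sizes) == M)
  counts <- matrix(0L, nrow = K, ncol = M)
  if (M == 0L || K == 0L) return(counts)
  tails <- weights
  if (K > 1L) {
    for (k in (K - 1L):1L) tails[k, ] <- tails[k + 1L, ] + weights[k, ]
  }
  bad <- sizes > 0 & tails[1L, ] <= 0
  if (any(bad)) {
    stop_vaxtwin(
      "all-zero weight vector with %d trials requested (first column: %d)",
      sizes[which(bad)[1L]], which(bad)[1L],
      class = "vaxtwin_degenerate_distribution")
  }
  remaining <- as.numeric(sizes)
  for (k in seq_len(K)) {
    p <- ifelse(tails[k, ] > 0, weights[k, ] / tails[k, ], 0)
    p <- pmin(p, 1)
    draw <- rbinom(M, size = remaining, prob = p)
    counts[k, ] <- as.integer(draw)
    remaining <- remaining - draw
  }
  counts
}

# Deterministic, seed-stable derivation of per-replicate seeds from a root
# seed. Keeps everything below 2^31.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Key used to index a peptide-MHC complex in named vectors / maps.
complex_key <- function(peptide, allele_name) paste(peptide, allele_name, sep = "/")

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == trunc(x)
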