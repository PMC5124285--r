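# Independent brute-force oracles the implementation is checked against.

# Maximum-gap selection by explicit enumeration: sort the absolute values,
# walk every consecutive gap, track the largest (ties -> the later gap), and
# collect the original indices of the values above it.
oracle_gap_select <- function(x) {
  a <- abs(x)
  C <- length(a)
  o <- order(a, method = "radix")
  s <- a[o]
  best_gap <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(C - 1)) {
    g <- s[i + 1] - s[i]
    if (g >= best_gap) {
      best_gap <- g
      best_i <- i
    }
  }
  if (best_gap == 0) return(integer(0))
  sort(o[(best_i + 1):C])
}

# Mean pairwise dot product over all unordered pairs of rows, by double loop.
oracle_within_correlation <- function(rows) {
  n <- nrow(rows)
  if (n == 1) return(1)
  tot <- 0
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(rows[i, ] * rows[j, ])
    cnt <- cnt + 1
  }
  tot / cnt
}

# Mean dot product over all cross pairs, by double loop.
oracle_between_correlation <- function(rows_a, rows_b) {
  tot <- 0
  for (i in seq_len(nrow(rows_a))) for (j in seq_len(nrow(rows_b))) {
    tot <- tot + sum(rows_a[i, ] * rows_b[j, ])
  }
  tot / (nrow(rows_a) * nrow(rows_b))
}

# Wrap a raw correlation matrix for the checkpoint functions.
corr_obj <- function(M) {
  structure(list(values = M, clusters = NULL), class = "cg_corr")
}

# Unit-norm matrix from a list of named rows.
unit_rows <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  m / sqrt(rowSums(m^2))
}

# Quick bicluster with sequential ids.
bc <- function(genes, conditions) bicluster(genes, conditions)
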