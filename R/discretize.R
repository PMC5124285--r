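# Maximum-gap discretization of expression profiles.
#
# The internal workhorses operate on whole matrices at once: rows are sorted
# with a single stable radix order() call, gaps are differenced columnwise and
# the per-row argmax located with max.col().  This keeps discretization of a
# ~20k-gene matrix in the tens of milliseconds, which matters because the
# random-matrix calibration discretizes hundreds of such matrices.

# Selected indices (ascending) of one vector under the maximum-gap rule.
# Scale-invariant; no normalization requirement.  Empty when all |x| equal.
gap_select <- function(x) {
  C <- length(x)
  if (C < 2) stop("need at least 2 entries to take consecutive differences")
  a <- abs(x)
  o <- order(a, method = "radix")          # stable: ties keep original order
  s <- a[o]
  g <- s[-1L] - s[-C]
  gmax <- max(g)
  if (gmax == 0) return(integer(0))
  istar <- max(which(g == gmax))           # tie-break: largest index
  sort(o[(istar + 1L):C])
}

# Signed states for every row of V (numeric matrix, C >= 2 columns).
# Returns an integer matrix in {-1, 0, +1}; signs taken from `raw` (defaults
# to V itself).  Rows whose absolute values are all equal come out all-zero.
gap_states <- function(V, raw = V) {
  n <- nrow(V)
  C <- ncol(V)
  if (C < 2) stop("need at least 2 conditions")
  A <- abs(V)
  o <- order(rep(seq_len(n), C), as.vector(A), method = "radix")
  sortedA <- matrix(as.vector(A)[o], nrow = n, byrow = TRUE)
  origcol <- matrix(as.integer((o - 1L) %/% n) + 1L, nrow = n, byrow = TRUE)
  gaps <- sortedA[, -1L, drop = FALSE] - sortedA[, -C, drop = FALSE]
  istar <- max.col(gaps, ties.method = "last")
  gmax <- gaps[cbind(seq_len(n), istar)]
  counts <- C - istar
  counts[gmax == 0] <- 0L
  rows_rep <- rep(seq_len(n), counts)
  cols_sorted <- sequence(counts, from = istar + 1L)
  sel <- cbind(rows_rep, origcol[cbind(rows_rep, cols_sorted)])
  states <- matrix(0L, n, C, dimnames = dimnames(V))
  states[sel] <- as.integer(sign(raw[sel]))
  states
}

new_discretization <- function(states, normalized, skip_report, n_input_genes,
                               method) {
  structure(list(states = states, normalized = normalized,
                 skip_report = skip_report, n_input_genes = n_input_genes,
                 method = method),
            class = "cg_discretization")
}

#' Discretize one normalized expression profile by its maximum gap
#'
#' The absolute values of the profile are sorted ascending (stable in the
#' original condition order for ties) and consecutive differences taken; the
#' conditions whose sorted rank lies above the largest difference are the
#' conditions where the gene is expressed.  Each selected condition carries
#' the sign of the gene's raw expression value there.  When every absolute
#' value is equal there is no gap and nothing is selected.
#'
#' @param normalized_row Numeric vector of length >= 2 with unit Euclidean
#'   norm (deviations beyond 1e-6 are a contract error); one row of
#'   [l2_normalize()] output.
#' @param raw_row Raw (pre-normalization) values used for the signs; defaults
#'   to `normalized_row`, which gives identical signs since normalization is a
#'   positive rescaling.
#'
#' @return An object of class `cg_profile`: a list with `states` (integer
#'   vector in \{-1, 0, +1\} over conditions) and `selected` (integer indices
#'   of the nonzero states).
#'
#' @examples
#' discretize_profile(c(0, 0, 1, 0))$selected     # single spike -> condition 3
#' @export
discretize_profile <- function(normalized_row, raw_row = normalized_row) {
  if (length(normalized_row) < 2) stop("profile needs at least 2 conditions")
  nrm <- sqrt(sum(normalized_row^2))
  if (abs(nrm - 1) > 1e-6)
    stop("input profile is not L2-normalized (norm = ", format(nrm), ")")
  if (length(raw_row) != length(normalized_row))
    stop("raw_row and normalized_row lengths differ")
  sel <- gap_select(normalized_row)
  states <- integer(length(normalized_row))
  states[sel] <- as.integer(sign(raw_row[sel]))
  names(states) <- names(normalized_row)
  structure(list(states = states, selected = sel), class = "cg_profile")
}

#' Discretize every gene of an expression matrix (maximum-gap rule)
#'
#' Applies [l2_normalize()] and then the maximum-gap rule of
#' [discretize_profile()] row by row, turning the real-valued matrix into a
#' signed discrete matrix.  Genes that cannot be discretized -- all-zero rows
#' (no norm) and rows whose absolute values are all equal (no gap) -- are
#' excluded from downstream clustering and listed in the skip report.
#'
#' @param matrix Numeric genes x conditions matrix.
#' @return A `cg_discretization` object: `states` (integer matrix in
#'   \{-1, 0, +1\} for the retained genes), `normalized` (their unit-norm
#'   profiles), `skip_report` (data frame of `gene_id`, `reason`), and
#'   `n_input_genes` (gene count of the input matrix, the `N` used by the
#'   selection score).
#' @seealso [discretize_foldchange()], [discretize_zscore()] for the
#'   fixed-threshold comparison discretizers.
#' @export
discretize_matrix <- function(matrix) {
  matrix <- validate_expression_matrix(matrix)
  norm <- l2_normalize(matrix)
  skip <- attr(norm, "skip_report")
  keep <- !(rownames(matrix) %in% skip$gene_id)
  V <- norm[keep, , drop = FALSE]
  attr(V, "skip_report") <- NULL
  states <- gap_states(V, raw = matrix[keep, , drop = FALSE])
  empty <- rowSums(states != 0L) == 0L
  if (any(empty)) {
    skip <- rbind(skip, data.frame(gene_id = rownames(V)[empty],
                                   reason = "no gap (all equal)",
                                   stringsAsFactors = FALSE))
  }
  new_discretization(states[!empty, , drop = FALSE], V[!empty, , drop = FALSE],
                     skip, nrow(matrix), "gap")
}

#' Discretize by a fixed fold-change cutoff
#'
#' Comparison discretizer: a condition is selected for a gene when the
#' absolute (log-scale) value reaches `log_threshold`.  With data on the log2
#' scale the default of 1.0 is the classical 2-fold cutoff; the boundary is
#' inclusive.  Signs come from the raw values.  Genes selecting nothing, and
#' all-zero genes, go to the skip report.
#'
#' @param matrix Numeric matrix of log fold changes.
#' @param log_threshold Selection threshold on `abs(value)`; default 1.0.
#' @return A `cg_discretization` object (see [discretize_matrix()]).
#' @export
discretize_foldchange <- function(matrix, log_threshold = 1.0) {
  matrix <- validate_expression_matrix(matrix)
  norm <- l2_normalize(matrix)
  skip <- attr(norm, "skip_report")
  keep <- !(rownames(matrix) %in% skip$gene_id)
  V <- norm[keep, , drop = FALSE]
  attr(V, "skip_report") <- NULL
  raw <- matrix[keep, , drop = FALSE]
  states <- array(0L, dim(raw), dimnames = dimnames(raw))
  hit <- abs(raw) >= log_threshold
  states[hit] <- as.integer(sign(raw[hit]))
  empty <- rowSums(states != 0L) == 0L
  if (any(empty)) {
    skip <- rbind(skip, data.frame(gene_id = rownames(V)[empty],
                                   reason = "below fold-change threshold",
                                   stringsAsFactors = FALSE))
  }
  new_discretization(states[!empty, , drop = FALSE], V[!empty, , drop = FALSE],
                     skip, nrow(matrix), "foldchange")
}

#' Discretize by a per-gene Z-score cutoff
#'
#' Comparison discretizer: for each gene the mean and standard deviation of
#' its expression across conditions are computed (sample standard deviation,
#' `n - 1` denominator) and a condition is selected when
#' `abs(value - mean) / sd >= z`.  The sign is that of `value - mean`.  Genes
#' with zero standard deviation select nothing.
#'
#' @param matrix Numeric genes x conditions matrix.
#' @param z Z-score cutoff; default 1.5.
#' @return A `cg_discretization` object (see [discretize_matrix()]).
#' @export
discretize_zscore <- function(matrix, z = 1.5) {
  matrix <- validate_expression_matrix(matrix)
  norm <- l2_normalize(matrix)
  skip <- attr(norm, "skip_report")
  keep <- !(rownames(matrix) %in% skip$gene_id)
  V <- norm[keep, , drop = FALSE]
  attr(V, "skip_report") <- NULL
  raw <- matrix[keep, , drop = FALSE]
  mu <- rowMeans(raw)
  sd <- apply(raw, 1, stats::sd)
  centred <- raw - mu
  zmat <- abs(centred) / ifelse(sd == 0, Inf, sd)
  states <- array(0L, dim(raw), dimnames = dimnames(raw))
  hit <- zmat >= z
  states[hit] <- as.integer(sign(centred[hit]))
  empty <- rowSums(states != 0L) == 0L
  if (any(empty)) {
    skip <- rbind(skip, data.frame(gene_id = rownames(V)[empty],
                                   reason = "below z-score threshold",
                                   stringsAsFactors = FALSE))
  }
  new_discretization(states[!empty, , drop = FALSE], V[!empty, , drop = FALSE],
                     skip, nrow(matrix), "zscore")
}

#' @export
print.cg_profile <- function(x, ...) {
  cat("signed discrete profile:", paste(x$states, collapse = " "),
      "\nselected conditions:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' @export
print.cg_discretization <- function(x, ...) {
  cat(sprintf("discretization (%s): %d of %d genes retained, %d skipped\n",
              x$method, nrow(x$states), x$n_input_genes, nrow(x$skip_report)))
  invisible(x)
}
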