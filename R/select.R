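# Selection score, random-matrix calibration of its cutoff, and filtering.

#' Combined size-correlation score of a cluster
#'
#' `score = y + log(x) / log(N)`, where `y` is the cluster's mean pairwise
#' correlation, `x` its size (number of genes) and `N` the number of genes in
#' the input matrix.  The log ratio is base independent; sizes are normalized
#' by `log(N)` so that the score -- and hence its noise-calibrated cutoff --
#' does not depend on the dimensions of the input matrix.
#'
#' @param x Cluster size(s), >= 1.
#' @param y Correlation(s) in `[-1, 1]`.
#' @param N Number of genes in the input matrix (>= 2).
#' @return Numeric score(s).
#' @examples
#' cluster_score(100, 0.95, 1000)  # 0.95 + 2/3
#' @export
cluster_score <- function(x, y, N) {
  if (any(x < 1)) stop("cluster size must be >= 1")
  if (length(N) != 1 || N < 2) stop("N must be a single gene count >= 2")
  y + log(x) / log(N)
}

#' Dimension-independent default score cutoff
#'
#' The mean calibrated cutoff across random matrices spanning a 10-fold range
#' of gene and condition counts; usable for a new dataset without generating
#' random matrix data.  See [calibrate_cutoff()] to calibrate for specific
#' dimensions instead.
#'
#' @return The constant 1.0887.
#' @export
default_cstar <- function() 1.0887

#' Keep the clusters scoring above the cutoff
#'
#' Computes [cluster_score()] for every cluster, stores it on the cluster,
#' and retains those with score strictly greater than `cstar`.  Order is
#' preserved and the operation is idempotent.
#'
#' @param clusters List of `cg_cluster` (or `cg_bicluster`) objects with
#'   `size` and `correlation` fields.
#' @param cstar Score cutoff, e.g. [default_cstar()] or a calibrated value.
#' @param N Number of genes in the input matrix (not the cluster count).
#' @return The filtered list, each element carrying its `score`.
#' @export
filter_clusters <- function(clusters, cstar, N) {
  scored <- lapply(clusters, function(cl) {
    cl$score <- cluster_score(cl$size, cl$correlation, N)
    cl
  })
  scored[vapply(scored, function(cl) cl$score > cstar, logical(1))]
}

# discretize -> group -> correlation -> checkpoints -> merge (no overlap, no
# select); the stage shared by run_cg and the random-matrix calibration.
cg_merge_stage <- function(matrix) {
  disc <- discretize_matrix(matrix)
  if (nrow(disc$states) == 0)
    return(list(clusters = list(), disc = disc))
  clusters <- group_by_profile(disc)
  corr <- cluster_correlation_matrix(clusters, disc$normalized)
  pairs <- consensus_pairs_fast(corr$values)
  merged <- merge_clusters(clusters, pairs, disc$normalized)
  list(clusters = merged, disc = disc, n_group_clusters = length(clusters),
       n_consensus_pairs = nrow(pairs))
}

sub_seed <- function(seed, level, index) {
  as.integer((as.double(seed) * 1000003 + level * 1009 + index * 7919) %%
               2147483647)
}

#' Calibrate the score cutoff on pure-noise random matrices
#'
#' The largest score a cluster can attain on data with no structure.  For
#' each noise level, `n_matrices` random N x C matrices with i.i.d.
#' `N(0, sd = noise)` entries are generated and run through the pipeline up
#' to and including the merge step (no overlap construction, no selection --
#' selection is what is being calibrated).  Per matrix, `c-bar` is the
#' maximum [cluster_score()] over its clusters; per noise level, `c-hat` is
#' the maximum of the level's `c-bar` values; the cutoff `c*` is the maximum
#' over levels.  Clusters scoring above `c*` on real data of the same
#' dimensions are deemed non-random.
#'
#' @param N,C Dimensions of the target data matrix (genes, conditions).
#' @param noise_levels Standard deviations of the zero-mean Gaussian noise;
#'   default `c(0.01, 0.05, 0.10)`.
#' @param n_matrices Random matrices per noise level; default 10.
#' @param seed Integer seed; each (level, matrix) combination draws from its
#'   own derived substream so individual matrices are reproducible.
#' @return A `cg_calibration` object: `cstar`, `per_noise_chat`,
#'   `per_matrix_cbar` (data frame with `noise`, `matrix_index`, `cbar`),
#'   `noise_levels`, `n_matrices_per_level`, `N`, `C`, `seed`.
#' @export
calibrate_cutoff <- function(N, C, noise_levels = c(0.01, 0.05, 0.10),
                             n_matrices = 10, seed) {
  if (missing(seed)) stop("calibration requires a seed")
  if (N < 2 || C < 2) stop("need N >= 2 and C >= 2")
  rows <- list()
  chat <- numeric(length(noise_levels))
  for (li in seq_along(noise_levels)) {
    sd <- noise_levels[li]
    cbars <- numeric(n_matrices)
    for (mi in seq_len(n_matrices)) {
      attempt <- 0L
      repeat {
        s <- sub_seed(seed, li, mi + attempt * (n_matrices + 1L))
        V <- generate_random_matrix(N, C, sd, s)
        st <- cg_merge_stage(V)
        if (length(st$clusters) > 0) break
        message("random matrix yielded no clusters; regenerating (level ",
                li, ", matrix ", mi, ")")
        attempt <- attempt + 1L
      }
      sizes <- vapply(st$clusters, `[[`, 0L, "size")
      ys <- vapply(st$clusters, `[[`, 0, "correlation")
      cbars[mi] <- max(cluster_score(sizes, ys, N))
      rows[[length(rows) + 1L]] <- data.frame(noise = sd, matrix_index = mi,
                                              cbar = cbars[mi])
    }
    chat[li] <- max(cbars)
  }
  structure(list(cstar = max(chat), per_noise_chat = chat,
                 per_matrix_cbar = do.call(rbind, rows),
                 noise_levels = noise_levels,
                 n_matrices_per_level = as.integer(n_matrices),
                 N = as.integer(N), C = as.integer(C),
                 seed = as.integer(seed)),
            class = "cg_calibration")
}

#' @export
print.cg_calibration <- function(x, ...) {
  cat(sprintf("score-cutoff calibration for %d genes x %d conditions\n", x$N, x$C))
  cat(sprintf("  noise levels: %s (%d matrices each)\n",
              paste(x$noise_levels, collapse = ", "), x$n_matrices_per_level))
  cat(sprintf("  per-level c-hat: %s\n",
              paste(format(x$per_noise_chat, digits = 5), collapse = ", ")))
  cat(sprintf("  c* = %.5f\n", x$cstar))
  invisible(x)
}
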