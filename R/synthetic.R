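# Synthetic expression data with implanted biclusters, and pure-noise
# random matrices.  All generators are pure functions of their arguments
# including the seed; the caller's RNG state is left untouched.

new_synthetic <- function(matrix, truth, noise_sd, overlap_degree, seed) {
  structure(list(matrix = matrix, truth = truth, noise_sd = noise_sd,
                 overlap_degree = as.integer(overlap_degree),
                 seed = as.integer(seed)),
            class = "cg_synthetic")
}

#' @export
print.cg_synthetic <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d x %d matrix, %d implanted bicluster(s), noise sd %g, overlap %d\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth$biclusters),
              x$noise_sd, x$overlap_degree))
  invisible(x)
}

#' Implanted diagonal-block dataset
#'
#' Builds a matrix of zeros with `n_blocks` blocks of ones placed along the
#' diagonal -- block b spans `block_genes` genes upregulated at `block_conds`
#' conditions -- and then adds `N(0, noise_sd)` noise to every entry.  With
#' `overlap_degree > 0` consecutive blocks share that many genes and
#' conditions (block origins shift by `block - overlap_degree`), the value in
#' the shared region remaining 1.  The pre-noise blocks are returned as the
#' ground-truth bicluster set for recovery/relevance scoring.
#'
#' With the defaults and `noise_sd = 0`, the result is the canonical
#' 100 x 100 matrix with ten 10 x 10 unit blocks on the diagonal.
#'
#' @param n_blocks Number of implanted blocks.
#' @param block_genes,block_conds Genes and conditions per block.
#' @param noise_sd Standard deviation of the added Gaussian noise (>= 0).
#' @param overlap_degree Genes-and-conditions shared by consecutive blocks;
#'   must be smaller than `min(block_genes, block_conds)`.
#' @param seed Integer seed for the noise.
#' @return A `cg_synthetic` object: `matrix`, `truth` (a
#'   `cg_bicluster_set`), `noise_sd`, `overlap_degree`, `seed`.
#' @export
generate_block_dataset <- function(n_blocks = 10, block_genes = 10,
                                   block_conds = 10, noise_sd = 0,
                                   overlap_degree = 0, seed = 1) {
  if (overlap_degree < 0 || overlap_degree >= min(block_genes, block_conds))
    stop("overlap_degree must be in [0, min(block_genes, block_conds) - 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  shift_g <- block_genes - overlap_degree
  shift_c <- block_conds - overlap_degree
  N <- block_genes + (n_blocks - 1) * shift_g
  C <- block_conds + (n_blocks - 1) * shift_c
  V <- matrix(0, N, C,
              dimnames = list(paste0("g", seq_len(N)), paste0("c", seq_len(C))))
  truth <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- (b - 1) * shift_g + seq_len(block_genes)
    cols <- (b - 1) * shift_c + seq_len(block_conds)
    V[rows, cols] <- 1
    truth[[b]] <- bicluster(rownames(V)[rows], colnames(V)[cols],
                            correlation = 1)
  }
  if (noise_sd > 0) {
    V <- V + withr::with_seed(seed, matrix(stats::rnorm(N * C, 0, noise_sd), N, C))
  }
  new_synthetic(V, bicluster_set(truth, source_shape = c(N, C)),
                noise_sd, overlap_degree, seed)
}

#' Narrow-block dataset: 100 x 50 with ten 10 x 5 blocks
#'
#' Variant with blocks much narrower than the condition space: a 100-gene x
#' 50-condition matrix carrying ten 10-gene x 5-condition diagonal unit
#' blocks plus Gaussian noise.
#'
#' @inheritParams generate_block_dataset
#' @return A `cg_synthetic` object.
#' @export
generate_narrow_block_dataset <- function(noise_sd = 0, seed = 1) {
  generate_block_dataset(n_blocks = 10, block_genes = 10, block_conds = 5,
                         noise_sd = noise_sd, overlap_degree = 0, seed = seed)
}

#' Append pure-noise genes to a synthetic dataset
#'
#' Doubles the gene dimension by appending as many `N(0, noise_sd)` rows as
#' the dataset already has; the implanted-truth biclusters are unchanged.
#' Used to probe whether selection can remove clusters formed by genes with
#' no implanted structure.
#'
#' @param ds A `cg_synthetic` dataset.
#' @param noise_sd Standard deviation of the appended rows.
#' @param seed Integer seed for the appended rows.
#' @return A `cg_synthetic` object with twice the genes.
#' @export
append_noisy_genes <- function(ds, noise_sd, seed) {
  if (!inherits(ds, "cg_synthetic")) stop("need a cg_synthetic dataset")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  N <- nrow(ds$matrix); C <- ncol(ds$matrix)
  noise <- withr::with_seed(seed, matrix(stats::rnorm(N * C, 0, noise_sd), N, C))
  rownames(noise) <- paste0("noisy", seq_len(N))
  colnames(noise) <- colnames(ds$matrix)
  out <- rbind(ds$matrix, noise)
  truth <- bicluster_set(ds$truth$biclusters, source_shape = c(2L * N, C))
  new_synthetic(out, truth, noise_sd, ds$overlap_degree, seed)
}

#' Pure-noise random expression matrix
#'
#' N x C matrix of i.i.d. `N(0, sd = noise_sd)` entries; the null input used
#' to calibrate the selection cutoff.
#'
#' @param N,C Dimensions (genes, conditions).
#' @param noise_sd Standard deviation (> 0).
#' @param seed Integer seed.
#' @return A numeric matrix with gene/condition dimnames.
#' @export
generate_random_matrix <- function(N, C, noise_sd, seed) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  V <- withr::with_seed(seed, matrix(stats::rnorm(N * C, 0, noise_sd), N, C))
  dimnames(V) <- list(paste0("g", seq_len(N)), paste0("c", seq_len(C)))
  V
}
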