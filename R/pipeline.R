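# The end-to-end CG pipeline.

#' Run the clustered-groups biclustering pipeline
#'
#' Executes, in order: unit-norm scaling and maximum-gap discretization of
#' every gene; grouping of identical signed profiles into clusters; the
#' cluster correlation matrix; the three merge checkpoints and merging of
#' consensus pairs; optionally the construction of gene-overlapping
#' biclusters; and optionally the selection of clusters scoring above the
#' noise-calibrated cutoff.  The pipeline itself is deterministic -- the seed
#' is only consumed when `cstar = "calibrate"` draws random matrices.
#'
#' The default mode (`overlap_param = 1`, `apply_select = FALSE`) keeps all
#' biclusters and allows gene overlap.  With `overlap_param = 0` no gene
#' appears in two output biclusters.
#'
#' @param matrix Numeric genes x conditions matrix (see
#'   [validate_expression_matrix()]).
#' @param overlap_param 1 to allow gene-overlapping biclusters, 0 to keep the
#'   gene-disjoint merge output.
#' @param apply_select Filter biclusters by score cutoff?
#' @param cstar Score cutoff used when `apply_select = TRUE`: a number, or
#'   `"default"` for [default_cstar()], or `"calibrate"` to calibrate on
#'   random matrices of matching dimensions (requires `seed`).
#' @param seed Integer seed, required only for `cstar = "calibrate"`.
#' @param verbose Emit per-stage counts as messages?
#' @return A `cg_bicluster_set`, sorted by decreasing size, then decreasing
#'   correlation, then smallest gene id; carries the discretization skip
#'   report as attribute `skip_report`.
#'
#' @examples
#' ds <- generate_block_dataset(noise_sd = 0)
#' out <- run_cg(ds$matrix, overlap_param = 0)
#' length(out)  # the 10 implanted blocks
#' @export
run_cg <- function(matrix, overlap_param = 1, apply_select = FALSE,
                   cstar = "default", seed = NULL, verbose = FALSE) {
  matrix <- validate_expression_matrix(matrix)
  if (!overlap_param %in% c(0, 1)) stop("overlap_param must be 0 or 1")
  N <- nrow(matrix)
  cstar_value <- NULL
  if (apply_select) {
    if (identical(cstar, "default")) {
      cstar_value <- default_cstar()
    } else if (identical(cstar, "calibrate")) {
      if (is.null(seed)) stop("cstar = \"calibrate\" requires a seed")
      cal <- calibrate_cutoff(N, ncol(matrix), seed = seed)
      cstar_value <- cal$cstar
    } else if (is.numeric(cstar) && length(cstar) == 1) {
      cstar_value <- cstar
    } else stop("cstar must be a number, \"default\" or \"calibrate\"")
  }

  st <- cg_merge_stage(matrix)
  if (verbose) {
    message(nrow(st$disc$states), " gene(s) discretized, ",
            nrow(st$disc$skip_report), " skipped")
    message(st$n_group_clusters %||% 0L, " profile cluster(s), ",
            st$n_consensus_pairs %||% 0L, " consensus pair(s), ",
            length(st$clusters), " cluster(s) after merge")
  }
  set <- bicluster_set(lapply(st$clusters, cluster_to_bicluster),
                       source_shape = dim(matrix))

  if (overlap_param == 1) {
    set <- build_overlapping_biclusters(set, normalized = st$disc$normalized)
    if (verbose) message(length(set), " bicluster(s) after overlap construction")
  }

  bl <- set$biclusters
  if (N >= 2) {
    bl <- lapply(bl, function(b) {
      b$score <- cluster_score(b$size, b$correlation, N)
      b
    })
  } else if (apply_select) {
    stop("selection needs at least 2 genes in the input matrix")
  }
  if (apply_select) {
    bl <- bl[vapply(bl, function(b) b$score > cstar_value, logical(1))]
    if (verbose) message(length(bl), " bicluster(s) selected at c* = ",
                         format(cstar_value, digits = 5))
  }
  out <- bicluster_set(sort_biclusters(bl), source_shape = dim(matrix))
  attr(out, "skip_report") <- st$disc$skip_report
  attr(out, "cstar") <- cstar_value
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
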