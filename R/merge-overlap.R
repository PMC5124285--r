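# Merge checkpoints, consensus pairs, cluster merging, and the optional
# construction of gene-overlapping biclusters.
#
# The three checkpoints are independent tests on the cluster correlation
# matrix; a pair must pass all three ("consensus pair") to be merged.  The
# exported check1()/check2()/check3() evaluate each test on every unordered
# pair, which is what small-to-moderate problems and the unit tests use.  The
# pipeline evaluates the same intersection lazily (CHECK3 first, CHECK1 on
# its candidates, CHECK2 on the survivors) because CHECK2 costs O(K) per
# pair; the two routes are provably and test-verifiedly identical.

pairs_matrix <- function(i, j) {
  m <- cbind(i = as.integer(i), j = as.integer(j))
  if (nrow(m)) m[order(m[, 1], m[, 2]), , drop = FALSE] else m
}

pair_keys <- function(p) paste(p[, 1], p[, 2], sep = "-")

#' Merge checkpoint 1: mutual presence in discretized correlation profiles
#'
#' Each row of the correlation matrix (a cluster's correlation profile) is
#' discretized with the maximum-gap rule; a pair (x, y) passes when y lies in
#' the selected set of row x and x lies in the selected set of row y.  The
#' diagonal (a row nearly always selects itself) carries no information and
#' is ignored.
#'
#' @param corr A `cg_corr` object from [cluster_correlation_matrix()].
#' @return Integer matrix with columns `i`, `j` (i < j), one row per passing
#'   pair; zero rows when none (in particular when K = 1).
#' @export
check1 <- function(corr) {
  M <- corr$values
  K <- nrow(M)
  if (K < 2) return(pairs_matrix(integer(0), integer(0)))
  sel <- gap_states(M) != 0L
  mutual <- sel & t(sel)
  idx <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  pairs_matrix(idx[, 1], idx[, 2])
}

# CHECK2 verdict for one unordered pair on correlation matrix M
check2_pair <- function(M, x, y) {
  p <- M[x, ] * M[y, ]
  if (all(p == 0)) return(FALSE)
  sel <- gap_select(p / sqrt(sum(p^2)))
  length(sel) == 2L && sel[1] == min(x, y) && sel[2] == max(x, y)
}

#' Merge checkpoint 2: the product of correlation profiles selects the pair
#'
#' For each unordered pair the element-wise product of the two correlation
#' profiles is formed, L2-normalized (the gap location is scale invariant, so
#' this only serves the discretizer's contract) and gap-discretized; the pair
#' passes when the selected set is exactly the pair itself.  An all-zero
#' product fails.
#'
#' @inheritParams check1
#' @return Integer matrix with columns `i`, `j` (i < j).
#' @export
check2 <- function(corr) {
  M <- corr$values
  K <- nrow(M)
  if (K < 2) return(pairs_matrix(integer(0), integer(0)))
  res_i <- integer(0); res_j <- integer(0)
  for (x in seq_len(K - 1)) for (y in (x + 1):K) {
    if (check2_pair(M, x, y)) { res_i <- c(res_i, x); res_j <- c(res_j, y) }
  }
  pairs_matrix(res_i, res_j)
}

#' Merge checkpoint 3: between-correlation beats the weaker self-correlation
#'
#' A pair (x, y) passes when its between-cluster correlation is strictly
#' greater than the smaller of the two self-correlations.
#'
#' @inheritParams check1
#' @return Integer matrix with columns `i`, `j` (i < j).
#' @export
check3 <- function(corr) {
  M <- corr$values
  K <- nrow(M)
  if (K < 2) return(pairs_matrix(integer(0), integer(0)))
  d <- diag(M)
  pass <- (M > d) | t(t(M) > d)          # M[i,j] > min(d[i], d[j])
  idx <- which(pass & upper.tri(pass), arr.ind = TRUE)
  pairs_matrix(idx[, 1], idx[, 2])
}

#' Intersect the three checkpoint results into the consensus pair set
#'
#' @param c1,c2,c3 Pair matrices from [check1()], [check2()], [check3()].
#' @return A `cg_consensus` object: list with `pairs` (the intersection) and
#'   the three inputs.
#' @export
consensus_pairs <- function(c1, c2, c3) {
  keys <- intersect(intersect(pair_keys(c1), pair_keys(c2)), pair_keys(c3))
  keep <- c1[pair_keys(c1) %in% keys, , drop = FALSE]
  if (any(keep[, 1] == keep[, 2])) stop("self-pair in consensus set")
  structure(list(pairs = keep, check1 = c1, check2 = c2, check3 = c3),
            class = "cg_consensus")
}

# Lazy evaluation of the same intersection, used by the pipeline.
# CHECK3 candidates are found columnwise (no K x K temporaries), CHECK1 row
# discretizations are computed only for rows appearing in a candidate, and
# CHECK2 runs only on pairs that already passed both.
consensus_pairs_fast <- function(M) {
  K <- nrow(M)
  if (K < 2) return(pairs_matrix(integer(0), integer(0)))
  d <- diag(M)
  ci <- integer(0); cj <- integer(0)
  for (jc in 2:K) {
    col <- M[seq_len(jc - 1L), jc]
    hit <- which(col > d[seq_len(jc - 1L)] | col > d[jc])
    if (length(hit)) { ci <- c(ci, hit); cj <- c(cj, rep(jc, length(hit))) }
  }
  if (length(ci)) {
    rows_needed <- unique(c(ci, cj))
    selsets <- lapply(rows_needed, function(r) gap_select(M[r, ]))
    names(selsets) <- as.character(rows_needed)
    keep <- vapply(seq_along(ci), function(p) {
      (cj[p] %in% selsets[[as.character(ci[p])]]) &&
        (ci[p] %in% selsets[[as.character(cj[p])]])
    }, logical(1))
    ci <- ci[keep]; cj <- cj[keep]
  }
  if (length(ci)) {
    keep <- vapply(seq_along(ci), function(p) check2_pair(M, ci[p], cj[p]),
                   logical(1))
    ci <- ci[keep]; cj <- cj[keep]
  }
  pairs_matrix(ci, cj)
}

#' Merge consensus cluster pairs
#'
#' Connected components of the consensus-pair graph are each collapsed into a
#' single cluster by taking the union of genes and the union of conditions;
#' clusters touched by no pair pass through unchanged.  Size and correlation
#' of merged clusters are recomputed; this is a single round -- the
#' correlation matrix is not re-derived afterwards.
#'
#' @param clusters List of `cg_cluster` objects.
#' @param consensus A `cg_consensus` object, or a 2-column pair matrix.
#' @param normalized Unit-row-norm matrix with gene rownames.
#' @return List of `cg_cluster` objects, ordered by each component's smallest
#'   input index.
#' @export
merge_clusters <- function(clusters, consensus, normalized) {
  pairs <- if (inherits(consensus, "cg_consensus")) consensus$pairs else consensus
  K <- length(clusters)
  if (K == 0) return(clusters)
  if (is.null(pairs) || nrow(pairs) == 0) return(clusters)
  if (max(pairs) > K || min(pairs) < 1) stop("consensus pair index out of range")
  g <- igraph::make_empty_graph(n = K, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  comp <- match(comp, unique(comp))       # renumber in first-appearance order
  lapply(seq_len(max(comp)), function(k) {
    members <- which(comp == k)
    if (length(members) == 1) return(clusters[[members]])
    genes <- sort(unique(unlist(lapply(clusters[members], `[[`, "genes"))))
    conds <- sort(unique(unlist(lapply(clusters[members], `[[`, "conditions"))))
    cl <- new_cluster(genes, conds)
    cl$correlation <- within_cluster_correlation(cl, normalized)
    cl
  })
}

#' Build gene-overlapping biclusters from a gene-disjoint set
#'
#' Before this step the pipeline's biclusters never share genes (only
#' conditions).  For each query bicluster q: (i) every other bicluster whose
#' condition set contains q's condition set is pooled with q -- the union of
#' their genes over the intersection of their conditions (which is q's
#' condition set) becomes a new overlapping bicluster; (ii) when no such
#' bicluster exists, the biclusters whose condition sets are strict subsets
#' of q's are examined: if the union of their conditions does not reach q's
#' condition set, q itself is kept, and otherwise q is already covered and is
#' dropped.  Identical outputs from different queries are deduplicated.
#'
#' @param set A `cg_bicluster_set` with pairwise gene-disjoint biclusters.
#' @param normalized Optional unit-row-norm matrix; when given, correlations
#'   of the emitted biclusters are (re)computed from it.
#' @return A `cg_bicluster_set`.
#' @export
build_overlapping_biclusters <- function(set, normalized = NULL) {
  bl <- set$biclusters
  n <- length(bl)
  if (n <= 1) return(set)
  conds <- lapply(bl, `[[`, "conditions")
  out <- list()
  for (q in seq_len(n)) {
    qc <- conds[[q]]
    others <- setdiff(seq_len(n), q)
    sup <- others[vapply(others, function(r) all(qc %in% conds[[r]]), logical(1))]
    if (length(sup)) {
      genes <- sort(unique(unlist(lapply(bl[c(q, sup)], `[[`, "genes"))))
      out[[length(out) + 1L]] <- bicluster(genes, qc)
    } else {
      sub <- others[vapply(others, function(r) {
        all(conds[[r]] %in% qc) && length(conds[[r]]) < length(qc)
      }, logical(1))]
      covered <- length(setdiff(qc, unlist(conds[sub]))) == 0
      if (!covered) out[[length(out) + 1L]] <- bl[[q]]
    }
  }
  keys <- vapply(out, function(b)
    paste(paste(sort(b$genes), collapse = ";"),
          paste(sort(b$conditions), collapse = ";"), sep = "|"), "")
  out <- out[!duplicated(keys)]
  if (!is.null(normalized)) {
    out <- lapply(out, function(b) {
      b$correlation <- within_cluster_correlation(b, normalized)
      b
    })
  }
  bicluster_set(out, source_shape = set$source_shape)
}
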