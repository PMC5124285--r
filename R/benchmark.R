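# Bicluster-set comparison: element-wise and conditions-only Jaccard,
# asymmetric match score, recovery/relevance, and the cluster-size
# power-law diagnostic.

#' Element-wise Jaccard similarity of two biclusters
#'
#' Treats each bicluster as the set of matrix cells it covers:
#' `|b1 ∩ b2| = |genes∩| * |conds∩|` and
#' `|b1 ∪ b2| = |b1| + |b2| - |b1 ∩ b2|` with `|b| = |genes| * |conds|`.
#' 1 means identical biclusters, 0 means disjoint (in genes or conditions).
#'
#' @param b1,b2 `cg_bicluster` objects.
#' @return A number in `[0, 1]`.
#' @export
jaccard_elements <- function(b1, b2) {
  ig <- length(intersect(b1$genes, b2$genes))
  ic <- length(intersect(b1$conditions, b2$conditions))
  inter <- ig * ic
  uni <- length(b1$genes) * length(b1$conditions) +
    length(b2$genes) * length(b2$conditions) - inter
  inter / uni
}

#' Conditions-only Jaccard similarity of two biclusters
#'
#' `|conds∩| / |conds∪|`; used when only the ability to group the right
#' samples matters (e.g. separating tumor from normal samples).
#'
#' @param b1,b2 `cg_bicluster` objects.
#' @return A number in `[0, 1]`.
#' @export
jaccard_conditions <- function(b1, b2) {
  inter <- length(intersect(b1$conditions, b2$conditions))
  inter / (length(b1$conditions) + length(b2$conditions) - inter)
}

#' Asymmetric match score between two bicluster sets
#'
#' `S(M1, M2)` = mean over the biclusters of `M1` of each one's best
#' similarity to any bicluster of `M2`.  It is deliberately asymmetric:
#' `S(E, F)` asks how well the found set F covers the actual set E
#' (recovery) while `S(F, E)` asks how much of F is real (relevance).
#'
#' @param M1,M2 `cg_bicluster_set` objects (both nonempty).
#' @param similarity `"elements"` (element-wise Jaccard) or `"conditions"`.
#' @return A number in `[0, 1]`.
#' @export
match_score <- function(M1, M2, similarity = c("elements", "conditions")) {
  similarity <- match.arg(similarity)
  simfun <- if (similarity == "elements") jaccard_elements else jaccard_conditions
  b1 <- if (inherits(M1, "cg_bicluster_set")) M1$biclusters else M1
  b2 <- if (inherits(M2, "cg_bicluster_set")) M2$biclusters else M2
  if (length(b1) == 0 || length(b2) == 0)
    stop("match score undefined for an empty bicluster set")
  mean(vapply(b1, function(x) max(vapply(b2, simfun, 0, b1 = x)), 0))
}

#' Recovery and relevance of a found bicluster set against the truth
#'
#' Recovery = `S(E, F)`: 1 when every actual bicluster is found.  Relevance =
#' `S(F, E)`: 1 when every found bicluster is an actual one.  Also records,
#' per actual bicluster, its best similarity to the found set (the
#' individual recovery scores).  An empty found set gives recovery 0 by
#' convention and is flagged.
#'
#' @param E Actual (ground truth) `cg_bicluster_set`.
#' @param F Found `cg_bicluster_set`.
#' @param similarity Passed to [match_score()].
#' @return A `cg_scores` object: `recovery`, `relevance`,
#'   `per_bicluster_best` (data frame `truth_index`, `best_similarity`),
#'   `flagged`.
#' @export
recovery_relevance <- function(E, F, similarity = c("elements", "conditions")) {
  similarity <- match.arg(similarity)
  simfun <- if (similarity == "elements") jaccard_elements else jaccard_conditions
  eb <- E$biclusters
  fb <- F$biclusters
  if (length(eb) == 0) stop("truth set is empty")
  if (length(fb) == 0) {
    per <- data.frame(truth_index = seq_along(eb),
                      best_similarity = rep(0, length(eb)))
    return(structure(list(recovery = 0, relevance = NA_real_,
                          per_bicluster_best = per, flagged = TRUE),
                     class = "cg_scores"))
  }
  best <- vapply(eb, function(x) max(vapply(fb, simfun, 0, b1 = x)), 0)
  structure(list(recovery = mean(best),
                 relevance = match_score(F, E, similarity),
                 per_bicluster_best = data.frame(truth_index = seq_along(eb),
                                                 best_similarity = best),
                 flagged = FALSE),
            class = "cg_scores")
}

#' @export
print.cg_scores <- function(x, ...) {
  cat(sprintf("recovery %.4f, relevance %s%s\n", x$recovery,
              format(x$relevance, digits = 4),
              if (x$flagged) " (empty found set)" else ""))
  invisible(x)
}

#' Power-law fit to the cumulative cluster-size distribution
#'
#' For every distinct cluster size s observed inside `size_range`, counts the
#' clusters of size >= s and fits a least-squares line to `log10(count)`
#' versus `log10(s)`.  A slope near -1 with high R-squared is the signature
#' of few large and many small clusters; randomly formed partitions deviate
#' from it.
#'
#' @param clusters List of `cg_cluster`/`cg_bicluster` objects, or directly a
#'   numeric vector of sizes.
#' @param size_range Numeric pair `c(min, max)`: sizes considered in the fit.
#' @return List with `slope`, `r2`, and the fitted points (`s`,
#'   `cumulative`).
#' @export
size_distribution_powerlaw <- function(clusters, size_range) {
  sizes <- if (is.numeric(clusters)) clusters
           else vapply(clusters, `[[`, 0L, "size")
  s <- sort(unique(sizes[sizes >= size_range[1] & sizes <= size_range[2]]))
  if (length(s) < 3)
    stop("need at least 3 distinct sizes in range for a power-law fit")
  cumulative <- vapply(s, function(v) sum(sizes >= v), 0)
  fit <- stats::lm(log10(cumulative) ~ log10(s))
  list(slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared,
       s = s, cumulative = cumulative)
}

#' Mean recovery/relevance over seeded replicates of a synthetic setting
#'
#' Benchmark protocol helper: for one (noise, overlap) setting, generates
#' `n_reps` datasets with derived seeds, runs [run_cg()] on each, scores
#' against the implanted truth, and reports per-replicate and mean scores.
#'
#' @param noise_sd,overlap_degree Setting of [generate_block_dataset()].
#' @param n_reps Number of replicates; default 10.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param noisy_genes Append pure-noise genes (doubling the gene count)?
#' @param overlap_param,apply_select,cstar Passed to [run_cg()].
#' @return List with `scores` (data frame of per-replicate recovery and
#'   relevance) and `mean_recovery`, `mean_relevance`.
#' @export
benchmark_replicates <- function(noise_sd, overlap_degree = 0, n_reps = 10,
                                 seed = 1, noisy_genes = FALSE,
                                 overlap_param = 0, apply_select = FALSE,
                                 cstar = "default") {
  rec <- rel <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    ds <- generate_block_dataset(noise_sd = noise_sd,
                                 overlap_degree = overlap_degree,
                                 seed = seed + r)
    if (noisy_genes)
      ds <- append_noisy_genes(ds, noise_sd = noise_sd, seed = seed + r + 10000L)
    found <- run_cg(ds$matrix, overlap_param = overlap_param,
                    apply_select = apply_select, cstar = cstar)
    sc <- recovery_relevance(ds$truth, found)
    rec[r] <- sc$recovery
    rel[r] <- if (is.na(sc$relevance)) 0 else sc$relevance
  }
  list(scores = data.frame(replicate = seq_len(n_reps), recovery = rec,
                           relevance = rel),
       mean_recovery = mean(rec), mean_relevance = mean(rel))
}
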