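test_that("checkpoint 1 requires mutual presence in discretized correlation profiles", {
  M <- rbind(c(1, 0.9, 0.05), c(0.9, 1, 0.05), c(0.05, 0.05, 1))
  # row 1 and 2 each select {1, 2} (largest gap below 0.9); row 3 selects {3}
  expect_identical(oracle_gap_select(M[1, ]), c(1L, 2L))
  expect_identical(oracle_gap_select(M[3, ]), 3L)
  p <- check1(corr_obj(M))
  expect_identical(p, rbind(c(i = 1L, j = 2L)))

  # identity matrix: every row's gap isolates the diagonal -> no pair
  expect_identical(nrow(check1(corr_obj(diag(3)))), 0L)
  # K = 1
  expect_identical(nrow(check1(corr_obj(matrix(1, 1, 1)))), 0L)
})

test_that("checkpoint 2 demands the profile product select exactly the pair", {
  M <- rbind(c(1, 0.9, 0), c(0.9, 1, 0), c(0, 0, 1))
  # product of rows 1,2 = (0.9, 0.9, 0): selects {1, 2} -> pass
  p <- check2(corr_obj(M))
  expect_identical(p, rbind(c(i = 1L, j = 2L)))

  # identity: products across distinct rows are all-zero -> fail
  expect_identical(nrow(check2(corr_obj(diag(3)))), 0L)

  # a three-way tie in the product selects three clusters -> strict set
  # equality makes the pair fail
  M3 <- rbind(c(1, 0.9, 0.9, 0.1), c(0.9, 1, 0.9, 0.1),
              c(0.9, 0.9, 1, 0.1), c(0.1, 0.1, 0.1, 1))
  prod12 <- M3[1, ] * M3[2, ]
  expect_identical(oracle_gap_select(prod12), c(1L, 2L, 3L))
  expect_false(any(check2(corr_obj(M3))[, 1] == 1 & check2(corr_obj(M3))[, 2] == 2))
})

test_that("checkpoint 3 compares between-correlation to the weaker self-correlation", {
  M <- function(between) rbind(c(0.9, between), c(between, 0.8))
  expect_identical(check3(corr_obj(M(0.85))), rbind(c(i = 1L, j = 2L)))
  expect_identical(nrow(check3(corr_obj(M(0.75)))), 0L)
  expect_identical(nrow(check3(corr_obj(M(0.80)))), 0L)  # strict inequality
})

test_that("consensus pairs are the intersection of the three checkpoints", {
  p <- function(...) matrix(unlist(list(...), use.names = FALSE) %||% integer(0),
                            ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("i", "j")))
  `%||%` <- function(a, b) if (is.null(a)) b else a
  c1 <- p(c(1L, 2L), c(2L, 3L)); c2 <- p(c(1L, 2L)); c3 <- p(c(1L, 2L), c(2L, 3L))
  cons <- consensus_pairs(c1, c2, c3)
  expect_identical(cons$pairs, p(c(1L, 2L)))
  empty <- p()
  expect_identical(nrow(consensus_pairs(c1, empty, c3)$pairs), 0L)
  expect_identical(consensus_pairs(c1, c1, c1)$pairs, c1)
})

test_that("the lazy consensus path agrees with the standalone checkpoint intersection", {
  set.seed(801)
  for (rep in 1:25) {
    V <- matrix(rnorm(80 * 6, 0, 0.1), 80, 6,
                dimnames = list(paste0("g", 1:80), paste0("c", 1:6)))
    # implant a couple of near-identical gene groups so merges actually occur
    V[1:6, 1:3] <- 1 + matrix(rnorm(18, 0, 0.05), 6, 3)
    d <- discretize_matrix(V)
    cl <- group_by_profile(d)
    co <- cluster_correlation_matrix(cl, d$normalized)
    full <- consensus_pairs(check1(co), check2(co), check3(co))$pairs
    fast <- cgbiclust:::consensus_pairs_fast(co$values)
    expect_identical(unname(fast), unname(full))
  }
})

test_that("checkpoints are symmetric in the pair", {
  set.seed(802)
  for (rep in 1:10) {
    A <- matrix(runif(25), 5, 5)
    M <- (A + t(A)) / 2
    for (fn in list(check1, check2, check3)) {
      pr <- fn(corr_obj(M))
      if (nrow(pr)) expect_true(all(pr[, 1] < pr[, 2]))
    }
    # explicit symmetry: verdict unchanged when the matrix is relabelled 2<->1
    perm <- c(2L, 1L, 3L, 4L, 5L)
    Mp <- M[perm, perm]
    for (fn in list(check1, check2, check3)) {
      a <- fn(corr_obj(M)); b <- fn(corr_obj(Mp))
      relabel <- function(p) {
        q <- apply(p, 1:2, function(v) perm[v])
        t(apply(q, 1, sort))
      }
      a_keys <- if (nrow(a)) sort(paste(a[, 1], a[, 2])) else character(0)
      b_keys <- if (nrow(b)) sort(apply(relabel(b), 1, paste, collapse = " ")) else character(0)
      expect_identical(a_keys, b_keys)
    }
  }
})

test_that("merging takes unions over connected components and conserves genes", {
  nm <- unit_rows(g1 = c(1, 0, 0), g2 = c(0, 1, 0), g3 = c(0, 0, 1))
  cl <- list(bc("g1", "c1"), bc("g2", "c2"), bc("g3", "c3"))

  merged <- merge_clusters(cl, cbind(i = 1L, j = 2L), nm)
  expect_length(merged, 2L)
  expect_setequal(merged[[1]]$genes, c("g1", "g2"))
  expect_setequal(merged[[1]]$conditions, c("c1", "c2"))

  # transitive merge through the shared cluster
  merged <- merge_clusters(cl, cbind(i = c(1L, 2L), j = c(2L, 3L)), nm)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]$genes, c("g1", "g2", "g3"))

  # empty consensus: identity
  expect_identical(merge_clusters(cl, cbind(i = integer(0), j = integer(0)), nm), cl)

  # gene conservation
  merged <- merge_clusters(cl, cbind(i = 1L, j = 3L), nm)
  expect_setequal(unlist(lapply(merged, `[[`, "genes")), c("g1", "g2", "g3"))
})

test_that("zero-noise blocks produce no consensus pairs", {
  ds <- generate_block_dataset(noise_sd = 0)
  d <- discretize_matrix(ds$matrix)
  co <- cluster_correlation_matrix(group_by_profile(d), d$normalized)
  cons <- consensus_pairs(check1(co), check2(co), check3(co))
  expect_identical(nrow(cons$pairs), 0L)
})

test_that("overlap construction pools gene sets sharing their condition support", {
  q <- bc(paste0("g", 1:10), paste0("c", 1:10))
  r <- bc(paste0("g", 11:20), paste0("c", 1:10))
  out <- build_overlapping_biclusters(bicluster_set(list(q, r)))
  expect_length(out, 1L)
  expect_setequal(out$biclusters[[1]]$genes, paste0("g", 1:20))
  expect_setequal(out$biclusters[[1]]$conditions, paste0("c", 1:10))
})

test_that("a query whose subset biclusters do not cover it survives overlap", {
  q <- bc(paste0("g", 1:10), paste0("c", 1:10))
  r <- bc(paste0("g", 11:20), paste0("c", 1:5))
  out <- build_overlapping_biclusters(bicluster_set(list(q, r)))
  keys <- vapply(out$biclusters, function(b) paste(sort(b$genes), collapse = ";"), "")
  expect_true(paste(sort(q$genes), collapse = ";") %in% keys)
})

test_that("overlap construction is the identity on disjoint condition supports", {
  q <- bc("g1", c("c1", "c2"))
  r <- bc("g2", c("c3", "c4"))
  out <- build_overlapping_biclusters(bicluster_set(list(q, r)))
  expect_length(out, 2L)
  single <- build_overlapping_biclusters(bicluster_set(list(q)))
  expect_length(single, 1L)
  expect_identical(single$biclusters[[1]]$genes, "g1")
})
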