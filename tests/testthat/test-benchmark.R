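test_that("element-wise Jaccard counts shared matrix cells", {
  b1 <- bc(paste0("g", 1:10), paste0("c", 1:10))
  b2 <- bc(paste0("g", 1:5), paste0("c", 1:10))
  expect_equal(jaccard_elements(b1, b1), 1)
  expect_equal(jaccard_elements(b1, b2), 0.5)  # 50 shared of 100 total
  expect_equal(jaccard_elements(b2, b1), 0.5)  # symmetric
  disj <- bc(paste0("h", 1:3), paste0("c", 1:10))
  expect_equal(jaccard_elements(b1, disj), 0)
  # 1 iff identical as (gene set, condition set)
  expect_lt(jaccard_elements(b1, bc(paste0("g", 1:10), paste0("c", 1:9))), 1)
})

test_that("conditions-only Jaccard counts shared conditions", {
  b1 <- bc("g1", paste0("c", 1:10))
  b2 <- bc("g2", paste0("c", 6:15))
  expect_equal(jaccard_conditions(b1, b2), 1 / 3)  # 5 of 15
  expect_equal(jaccard_conditions(b1, b1), 1)
  expect_equal(jaccard_conditions(b1, bc("g3", "c99")), 0)
})

test_that("the match score averages best matches and is asymmetric", {
  blockA <- bc(paste0("g", 1:10), paste0("c", 1:10))
  blockB <- bc(paste0("g", 11:20), paste0("c", 11:20))
  M1 <- bicluster_set(list(blockA, blockB))
  M2 <- bicluster_set(list(blockA))
  expect_equal(match_score(M1, M1), 1)
  expect_equal(match_score(M1, M2), 0.5)
  expect_equal(match_score(M2, M1), 1)
  expect_error(match_score(bicluster_set(), M1), "empty")
})

test_that("recovery and relevance take opposite orientations", {
  blocks <- lapply(1:10, function(b)
    bc(paste0("g", 10 * b - 9:0), paste0("c", 10 * b - 9:0)))
  E <- bicluster_set(blocks)

  sc <- recovery_relevance(E, E)
  expect_equal(sc$recovery, 1)
  expect_equal(sc$relevance, 1)
  expect_identical(nrow(sc$per_bicluster_best), 10L)

  # a spurious found bicluster costs relevance, not recovery
  spurious <- bc("x1", "c1")
  sc <- recovery_relevance(E, bicluster_set(c(blocks, list(spurious))))
  expect_equal(sc$recovery, 1)
  expect_lt(sc$relevance, 1)

  # missing half the truth costs recovery, not relevance
  sc <- recovery_relevance(E, bicluster_set(blocks[1:5]))
  expect_equal(sc$recovery, 0.5)
  expect_equal(sc$relevance, 1)

  # empty found set: recovery 0 by convention, flagged
  sc <- recovery_relevance(E, bicluster_set())
  expect_equal(sc$recovery, 0)
  expect_true(sc$flagged)
})

test_that("adding a found bicluster never decreases recovery", {
  set.seed(901)
  E <- bicluster_set(lapply(1:4, function(b)
    bc(paste0("g", sample(100, 8)), paste0("c", sample(20, 4)))))
  Fb <- lapply(1:6, function(b)
    bc(paste0("g", sample(100, 8)), paste0("c", sample(20, 4))))
  for (k in 2:6) {
    r1 <- recovery_relevance(E, bicluster_set(Fb[seq_len(k - 1)]))$recovery
    r2 <- recovery_relevance(E, bicluster_set(Fb[seq_len(k)]))$recovery
    expect_gte(r2, r1)
  }
})

test_that("a 1/s cumulative size distribution fits a slope of -1", {
  # construct sizes whose cumulative count at size s is exactly round(9009/s)
  smax <- 91
  cum <- function(s) round(9009 / s)
  sizes <- integer(0)
  for (s in 9:(smax - 1)) sizes <- c(sizes, rep(s, cum(s) - cum(s + 1)))
  sizes <- c(sizes, rep(smax, cum(smax)))
  fit <- size_distribution_powerlaw(sizes, c(9, 91))
  expect_lt(abs(fit$slope + 1), 0.05)
  expect_gt(fit$r2, 0.98)
})

test_that("degenerate or random size distributions do not fit the power law", {
  expect_error(size_distribution_powerlaw(rep(5L, 20), c(1, 10)), "3 distinct")
  # a random partition of 19303 members into 5299 clusters has thin,
  # fast-decaying tails: the log-log fit is much steeper than -1
  set.seed(902)
  sizes <- tabulate(sample(5299, 19303, replace = TRUE), 5299)
  fit <- size_distribution_powerlaw(sizes, c(1, max(sizes)))
  expect_lt(fit$slope, -1.5)
})
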