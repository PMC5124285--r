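test_that("row normalization has unit norms and flags zero rows", {
  m <- rbind(a = c(3, 4), b = c(0, 0), c = c(0, 5))
  out <- l2_normalize(m)
  expect_equal(out["a", ], c(0.6, 0.8))
  expect_equal(out["c", ], c(0, 1))
  skip <- attr(out, "skip_report")
  expect_identical(skip$gene_id, "b")
  expect_identical(skip$reason, "zero norm")
})

test_that("gap discretization selects the conditions above the largest gap", {
  # single spike
  p <- discretize_profile(c(0, 0, 1, 0))
  expect_identical(p$selected, 3L)
  expect_identical(unname(p$states), c(0L, 0L, 1L, 0L))

  # signed two-condition selection; cross-checked against the enumeration oracle
  raw <- c(3, -3, 0.1, 0.05)
  nr <- raw / sqrt(sum(raw^2))
  expect_identical(oracle_gap_select(nr), c(1L, 2L))
  p <- discretize_profile(nr, raw)
  expect_identical(p$selected, c(1L, 2L))
  expect_identical(unname(p$states), c(1L, -1L, 0L, 0L))

  # all-equal absolute values: no gap, nothing selected
  p <- discretize_profile(rep(0.5, 4))
  expect_identical(p$selected, integer(0))

  # contract: input must be normalized
  expect_error(discretize_profile(c(3, 4)), "not L2-normalized")
  expect_error(discretize_profile(1), "at least 2")
})

test_that("gap discretization matches the brute-force oracle on random vectors", {
  set.seed(601)
  for (rep in 1:300) {
    C <- sample(3:20, 1)
    x <- rnorm(C)
    x <- x / sqrt(sum(x^2))
    p <- discretize_profile(x)
    expect_identical(p$selected, oracle_gap_select(x))
  }
})

test_that("gap discretization is scale invariant with sign-tracking", {
  set.seed(602)
  for (rep in 1:50) {
    x <- rnorm(8)
    d1 <- discretize_matrix(matrix(x, 1, dimnames = list("g", NULL)))
    d2 <- discretize_matrix(matrix(2.5 * x, 1, dimnames = list("g", NULL)))
    d3 <- discretize_matrix(matrix(-x, 1, dimnames = list("g", NULL)))
    expect_identical(d1$states, d2$states)
    expect_identical(d1$states, -d3$states)
    # selected-set size within 1..C-1 when a unique positive gap exists
    k <- sum(d1$states != 0)
    expect_true(k >= 1 && k <= 7)
  }
})

test_that("matrix discretization excludes undiscretizable genes via the skip report", {
  m <- rbind(constant = c(2, 2, 2, 2), spiked = c(0, 0, 5, 0),
             zero = c(0, 0, 0, 0))
  d <- discretize_matrix(m)
  expect_identical(rownames(d$states), "spiked")
  expect_identical(unname(d$states["spiked", ]), c(0L, 0L, 1L, 0L))
  expect_setequal(d$skip_report$gene_id, c("constant", "zero"))
  expect_identical(d$n_input_genes, 3L)
})

test_that("zero-noise block genes select exactly their block conditions", {
  ds <- generate_block_dataset(noise_sd = 0)
  d <- discretize_matrix(ds$matrix)
  expect_identical(nrow(d$states), 100L)
  for (b in c(1, 4, 10)) {
    g <- paste0("g", 10 * b - 3)
    expect_identical(unname(which(d$states[g, ] != 0L)), as.integer(10 * b + (-9:0)))
    expect_true(all(d$states[g, d$states[g, ] != 0L] == 1L))
  }
})

test_that("fold-change discretizer applies an inclusive threshold", {
  m <- rbind(a = c(1.5, -0.2, -2.0), b = c(0.5, -0.9, 0.2),
             c = c(1.0, 0, 0))
  d <- discretize_foldchange(m)
  expect_identical(unname(d$states["a", ]), c(1L, 0L, -1L))
  expect_identical(unname(d$states["c", ]), c(1L, 0L, 0L))  # boundary kept
  expect_true("b" %in% d$skip_report$gene_id)               # all within (-1, 1)
})

test_that("z-score discretizer uses the sample standard deviation", {
  m <- rbind(a = c(0, 0, 0, 10), b = c(7, 7, 7, 7))
  # gene a: mean 2.5, sample sd 5, z of the spike = 1.5 -> selected inclusively
  d <- discretize_zscore(m, z = 1.5)
  expect_identical(unname(d$states["a", ]), c(0L, 0L, 0L, 1L))
  expect_true("b" %in% d$skip_report$gene_id)  # sd == 0 -> nothing selected
  # symmetric pair: each |z| = 1/sqrt(2) * ... = 0.707 under sample sd -> empty
  m2 <- rbind(s = c(-5, 5), t = c(1, 2))
  d2 <- discretize_zscore(m2, z = 1.5)
  expect_true("s" %in% d2$skip_report$gene_id)
})
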