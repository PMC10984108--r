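counts2 <- function(wt, ko, ids = sprintf("g%d", seq_along(wt))) {
  m <- cbind(WT_1 = wt, WT_2 = wt, KO_1 = ko, KO_2 = ko)
  rownames(m) <- ids
  m
}
design4 <- tibble::tibble(
  sample_id = c("WT_1", "WT_2", "KO_1", "KO_2"),
  group = c("WT", "WT", "KO", "KO")
)

test_that("size factors are scale-equivariant and match hand computation", {
  m <- matrix(c(10, 100, 40, 20, 200, 80), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2) # sample2 = 2 x sample1

  m3 <- matrix(c(4, 10, 20, 8, 10, 30, 16, 10, 90), ncol = 3,
               dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  # independent hand computation of median-of-ratios
  geo <- apply(m3, 1, function(r) prod(r)^(1 / 3))
  expected <- apply(sweep(m3, 1, geo, "/"), 2, median)
  expect_equal(size_factors(m3), expected)

  same <- matrix(5, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  nopos <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(nopos), "all-positive")
})

test_that("size factors agree with the DESeq2 reference on NB data", {
  b <- simulate_dataset(small_params(21))
  sf <- size_factors(b$rna$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(b$rna$counts)
  # the reference takes the median on the log-ratio scale; with an even
  # number of reference genes the two medians differ by the arithmetic vs
  # geometric mean of the two central ratios, which is tiny on real data
  expect_equal(unname(sf), unname(ref), tolerance = 0.01)
})

test_that("vectorised Welch p-values match stats::t.test", {
  withr::with_seed(99, {
    x <- matrix(rnorm(50 * 8), 50)
    a <- x[, 1:4]; b <- x[, 5:8]
    p_vec <- reguloncascade:::welch_rows(a, b)
    p_ref <- vapply(seq_len(nrow(x)), function(i) {
      stats::t.test(a[i, ], b[i, ])$p.value
    }, 0)
    expect_equal(p_vec, p_ref, tolerance = 1e-12)
  })
})

test_that("status assignment honours the fold-change and p thresholds", {
  # planted 4-fold change, no within-group noise; ballast genes keep the
  # size-factor medians neutral
  d <- call_degs(counts2(c(100, 80, 90, 70), c(400, 80, 90, 70)),
                 design4, c("KO", "WT"))
  expect_equal(d$status, c("up", "ns", "ns", "ns"))

  # small effect with tiny p stays ns: |log2fc| = 0.5 < 1
  t1 <- deg_table("g1", log2fc = 0.5, p_value = 0.001)
  expect_equal(t1$status, "ns")

  # boundary |log2fc| == 1: strict excludes, inclusive admits
  expect_equal(deg_table("g1", 1, 0)$status, "ns")
  expect_equal(deg_table("g1", 1, 0, thresholds(strict = FALSE))$status, "up")
  expect_equal(deg_table("g1", -1, 0, thresholds(strict = FALSE))$status, "down")
})

test_that("all-zero genes are ns with p = 1 and never NaN", {
  d <- call_degs(counts2(c(0, 50), c(0, 50)), design4, c("KO", "WT"))
  expect_equal(d$p_value[1], 1)
  expect_equal(d$status[1], "ns")
  expect_false(anyNA(d$p_value))
})

test_that("status is a pure function of its inputs", {
  b <- simulate_dataset(small_params(3))
  d1 <- call_degs(b$rna$counts, b$rna$design, b$rna$contrast)
  d2 <- call_degs(b$rna$counts, b$rna$design, b$rna$contrast)
  expect_identical(d1, d2)
})

test_that("DEG overlap partitions shared and exclusive genes", {
  ta <- deg_table(c("a", "b", "c"), c(2, 2, -2), c(0, 0, 0))
  expect_equal(deg_overlap(ta, ta)$shared, c("a", "b", "c"))
  expect_length(deg_overlap(ta, ta)$a_only, 0)

  tb <- deg_table(c("d", "e"), c(2, -2), c(0, 0))
  ov <- deg_overlap(ta, tb)
  expect_length(ov$shared, 0)

  # direction-aware: DEGs {a up, b up, c down} vs {b up, c up, d down}
  tc <- deg_table(c("b", "c", "d"), c(2, 2, -2), c(0, 0, 0))
  ov2 <- deg_overlap(ta, tc, direction_aware = TRUE)
  expect_equal(ov2$shared, "b")
  expect_setequal(ov2$a_only, c("a", "c"))
  expect_setequal(ov2$b_only, c("c", "d"))
})
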