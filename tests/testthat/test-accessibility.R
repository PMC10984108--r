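design4a <- tibble::tibble(
  sample_id = c("W1", "W2", "K1", "K2"),
  group = c("WT", "WT", "KO", "KO")
)

test_that("direction labels follow the differential engine", {
  m <- rbind(r1 = c(100, 100, 400, 400), r2 = c(100, 100, 100, 100),
             r3 = c(50, 50, 50, 50))
  colnames(m) <- design4a$sample_id
  da <- call_da_regions(m, design4a, c("KO", "WT"))
  expect_equal(da$direction, c("increased", "unchanged", "unchanged"))
})

test_that("planted accessibility directions are recovered with correct sign", {
  b <- simulate_dataset(small_params(41))
  da <- call_da_regions(b$atac$counts, b$atac$design, b$atac$contrast)
  truth <- b$truth$da_direction
  altered <- truth$direction != "unchanged"
  recovery <- mean(da$direction[altered] == truth$direction[altered])
  expect_gte(recovery, 0.9)
  # no sign flips among recovered regions
  wrong_sign <- sum(
    (truth$direction == "increased" & da$direction == "decreased") |
    (truth$direction == "decreased" & da$direction == "increased")
  )
  expect_equal(wrong_sign, 0)
})

test_that("unit labels match brute force and form a partition", {
  withr::with_seed(55, {
    units <- tibble::tibble(
      region_id = sprintf("u%02d", 1:40), chrom = "c1",
      start = s <- sample.int(5e4, 40), end = s + sample(100:1500, 40, TRUE)
    )
    coords <- tibble::tibble(
      region_id = sprintf("d%02d", 1:60), chrom = "c1",
      start = s2 <- sample.int(5e4, 60), end = s2 + sample(100:1500, 60, TRUE),
      score = NA_real_
    )
    da <- tibble::tibble(
      region_id = coords$region_id,
      direction = sample(c("increased", "decreased", "unchanged"), 60, TRUE)
    )
  })
  res <- chip_da_overlap(units, da, coords)
  labels <- attr(res, "labels")
  expect_equal(labels$label, bf_chip_labels(units, da, coords))
  expect_equal(res$n_increased + res$n_decreased + res$n_unchanged, res$n_chip_units)
  expect_equal(res$pct_altered, res$pct_increased + res$pct_decreased)
})

test_that("overlap accounting covers the degenerate extremes", {
  units <- tibble::tibble(region_id = c("u1", "u2"), chrom = "c1",
                          start = c(0, 1000), end = c(100, 1100))
  coords <- tibble::tibble(region_id = "d1", chrom = "c1",
                           start = 5000, end = 5100, score = NA_real_)
  da_inc <- tibble::tibble(region_id = "d1", direction = "increased")
  expect_equal(chip_da_overlap(units, da_inc, coords)$pct_altered, 0)

  on_units <- tibble::tibble(region_id = c("d1", "d2"), chrom = "c1",
                             start = c(0, 1000), end = c(100, 1100), score = NA_real_)
  da2 <- tibble::tibble(region_id = c("d1", "d2"), direction = "increased")
  expect_equal(chip_da_overlap(units, da2, on_units)$pct_increased, 100)
  expect_error(chip_da_overlap(units[0, ], da2, on_units), "empty ChIP unit")
})

test_that("raising the fold-change cut never adds altered regions", {
  b <- simulate_dataset(small_params(42))
  n_altered <- vapply(c(0.5, 1, 2, 3), function(cut) {
    da <- call_da_regions(b$atac$counts, b$atac$design, b$atac$contrast,
                          thresholds(lfc_threshold = cut))
    sum(da$direction != "unchanged")
  }, 0)
  expect_true(all(diff(n_altered) <= 0))
})

test_that("altered regions unlinked to DEGs are counted as specified", {
  genes <- tibble::tibble(
    gene_id = c("deg1", "deg2", "nsg"), chrom = "c1",
    start = c(10000, 30000, 50000), end = c(14000, 34000, 54000),
    strand = "+", tss = c(10000, 30000, 50000)
  )
  degs <- deg_table(c("deg1", "deg2", "nsg"), c(2, -2, 0), c(0, 0, 1))
  # 2 regions on DEG promoters, 1 on the ns gene's body, 1 intergenic
  coords <- tibble::tibble(
    region_id = c("r1", "r2", "r3", "r4"), chrom = "c1",
    start = c(9000, 29000, 51000, 80000),
    end = c(9200, 29200, 51200, 80200), score = NA_real_
  )
  da <- tibble::tibble(region_id = coords$region_id, direction = "increased")
  expect_equal(da_expression_link(da, coords, genes, degs), 50)

  onlyig <- da[4, ]
  expect_equal(da_expression_link(onlyig, coords, genes, degs), 100)
  onprom <- da[1:2, ]
  expect_equal(da_expression_link(onprom, coords, genes, degs), 0)

  none <- tibble::tibble(region_id = "r1", direction = "unchanged")
  expect_error(da_expression_link(none, coords, genes, degs), "zero altered")
})
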