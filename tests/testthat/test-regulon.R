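mk_annotation <- function(prom_genes, body_genes) {
  structure(list(
    links = tibble::tibble(),
    peak_category = tibble::tibble(),
    gene_class = dplyr::bind_rows(
      tibble::tibble(gene_id = prom_genes, class = "promoter_bound"),
      tibble::tibble(gene_id = body_genes, class = "body_only_bound")
    ),
    promoter_window = c(upstream = 2000, downstream = 500)
  ), class = "peak_annotation")
}

test_that("binding mode controls which gene classes count as bound", {
  degs <- deg_table(c("a", "b", "c"), c(2, 2, -2), c(0, 0, 0))
  ann <- mk_annotation(prom_genes = "a", body_genes = "b")

  prom <- classify_degs(degs, ann, "promoter")
  expect_equal(prom$bound, c(TRUE, FALSE, FALSE)) # body-only gene unbound
  pb <- classify_degs(degs, ann, "promoter_or_body")
  expect_equal(pb$bound, c(TRUE, TRUE, FALSE))
  # c is absent from the annotation: counted unbound, not dropped
  expect_equal(nrow(prom), 3)

  expect_error(classify_degs(deg_table("x", 0, 1), ann), "empty DEG set")
})

test_that("promoter-mode bound genes are a subset of promoter-or-body-mode", {
  b <- simulate_dataset(small_params(31))
  d <- call_degs(b$rna$counts, b$rna$design, b$rna$contrast)
  ann <- annotate_peaks(b$peaks, b$genes)
  bp <- classify_degs(d, ann, "promoter")
  bpb <- classify_degs(d, ann, "promoter_or_body")
  expect_true(all(bp$gene_id[bp$bound] %in% bpb$gene_id[bpb$bound]))
  expect_equal(sort(bp$gene_id), sort(bpb$gene_id))
})

test_that("quadrants match an independent join of status and class streams", {
  degs <- deg_table(sprintf("g%d", 1:8),
                    c(2, 2, -2, -2, 2, -2, 2, -2),
                    rep(0, 8))
  ann <- mk_annotation(prom_genes = c("g1", "g3"), body_genes = c("g5", "g6"))
  part <- classify_degs(degs, ann, "promoter_or_body")
  # brute-force join
  bound_set <- c("g1", "g3", "g5", "g6")
  expected <- table(paste0(
    ifelse(degs$gene_id %in% bound_set, "bound_", "unbound_"), degs$status
  ))
  got <- table(part$quadrant)
  expect_equal(as.list(got), as.list(expected))
})

test_that("regulon statistics cover the degenerate extremes", {
  degs <- deg_table(c("a", "b"), c(2, -2), c(0, 0))
  all_bound <- classify_degs(degs, mk_annotation(c("a", "b"), character()), "promoter")
  expect_equal(regulon_stats(all_bound)$pct_bound_all, 100)
  none_bound <- classify_degs(degs, mk_annotation(character(), character()), "promoter")
  expect_equal(regulon_stats(none_bound)$pct_bound_all, 0)
})

test_that("planted promoter-bound up-regulated genes are recovered precisely", {
  b <- simulate_dataset(small_params(32))
  d <- call_degs(b$rna$counts, b$rna$design, b$rna$contrast)
  ann <- annotate_peaks(b$peaks, b$genes)
  part <- classify_degs(d, ann, "promoter")
  called_bound_up <- part$gene_id[part$quadrant == "bound_up"]
  truth_bound_up <- intersect(
    b$truth$deg_status$gene_id[b$truth$deg_status$status == "up"],
    b$truth$gene_class$gene_id[b$truth$gene_class$class == "promoter_bound"]
  )
  precision <- mean(called_bound_up %in% truth_bound_up)
  expect_gte(precision, 0.95)
})
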