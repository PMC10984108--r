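test_that("PWM validation rejects malformed matrices", {
  bad <- matrix(c(0.5, 0.5, 0.2, 0.1), nrow = 1)[rep(1, 4), ]
  expect_error(pwm("bad", bad), "does not sum to 1")
  short <- matrix(0.25, nrow = 3, ncol = 4)
  expect_error(pwm("short", short), "length")
  expect_error(scan_motifs(list(structure(list(
    tf_name = "bad", matrix = bad, background = rep(0.25, 4)
  ), class = "pwm")), c(r1 = "ACGTACGTACGT")), "sum to 1")
})

test_that("consensus scores at the maximum on the matching strand", {
  p <- pwm_from_consensus("TFX", "ACGGTTCAGT")
  hits <- scan_motifs(list(p), c(r1 = "ACGGTTCAGT"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  lo <- reguloncascade:::pwm_log_odds(p)
  expect_equal(hits$score, sum(apply(lo, 1, max)))

  rc <- reguloncascade:::revcomp("ACGGTTCAGT")
  hits_rc <- scan_motifs(list(p), c(r1 = rc))
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score) # strand symmetry
  expect_equal(hits_rc$offset, 0)
})

test_that("windows containing N are skipped", {
  p <- pwm_from_consensus("TFX", "ACGGTTCAGT")
  hits <- scan_motifs(list(p), c(r1 = "ACGGTNCAGT"))
  expect_equal(nrow(hits), 0)
})

test_that("planted consensus instances are recovered at the default threshold", {
  p <- pwm_from_consensus("TFP", "TTGACGTCAA")
  withr::with_seed(77, {
    seqs <- vapply(1:200, function(i) {
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    }, "")
    offsets <- sample.int(120 - 10 + 1, 200, replace = TRUE)
  })
  for (i in 1:200) substr(seqs[i], offsets[i], offsets[i] + 9) <- "TTGACGTCAA"
  names(seqs) <- sprintf("r%03d", 1:200)
  hits <- scan_motifs(list(p), seqs)
  recovered <- sum(vapply(1:200, function(i) {
    any(hits$region_id == names(seqs)[i] & hits$offset == offsets[i] - 1)
  }, TRUE))
  expect_gte(recovered / 200, 0.95)
})

test_that("the core-TF filter requires motif, DE status and binding", {
  degs <- deg_table(c("gA", "gB", "gC", "gD"), c(2, -2, 0, 2), c(0, 0, 1, 0))
  ann <- structure(list(gene_class = tibble::tibble(
    gene_id = c("gA", "gB", "gC"), class = "promoter_bound"
  )), class = "peak_annotation")
  part <- classify_degs(degs, ann, "promoter")
  tf_map <- tibble::tibble(
    tf_name = c("TFup", "TFdown", "TFns", "TFunbound"),
    gene_id = c("gA", "gB", "gC", "gD")
  )
  core <- suppressMessages(select_core_tfs(
    c("TFup", "TFdown", "TFns", "TFunbound", "TFnomap"), degs, part, tf_map
  ))
  expect_setequal(core$tf_name, c("TFup", "TFdown")) # ns and unbound excluded
  expect_equal(core$direction[core$tf_name == "TFup"], "up")
  expect_equal(attr(core, "n_unmapped"), 1)
})

test_that("coverage accounting is conserved, bounded and monotone in edges", {
  degs <- deg_table(sprintf("g%02d", 1:20),
                    rep(c(2, -2), 10), rep(0, 20))
  ann <- structure(list(gene_class = tibble::tibble(
    gene_id = sprintf("g%02d", 1:8), class = "promoter_bound"
  )), class = "peak_annotation")
  part <- classify_degs(degs, ann, "promoter")
  core <- tibble::tibble(tf_name = c("T1", "T2"), gene_id = c("g01", "g02"),
                         direction = c("up", "down"))

  empty <- tf_contribution(core, tibble::tibble(tf = character(), target = character()), part)
  expect_equal(empty$overall$pct_covered, 0)
  expect_true(all(empty$quadrants$covered == 0))

  full <- tf_contribution(core, tibble::tibble(tf = "T1", target = degs$gene_id), part)
  expect_equal(full$overall$pct_covered, 100)
  expect_true(all(full$quadrants$pct_covered == 100))
  expect_error(uncovered_stats(full, part), "no uncovered")

  withr::with_seed(88, {
    edges <- tibble::tibble(
      tf = sample(c("T1", "T2"), 30, TRUE),
      target = sample(degs$gene_id, 30, TRUE)
    )
  })
  prev <- empty
  for (k in c(5, 15, 30)) {
    cur <- tf_contribution(core, edges[1:k, ], part)
    expect_true(all(cur$quadrants$covered >= prev$quadrants$covered))
    expect_equal(sum(cur$quadrants$covered), cur$overall$n_covered)
    expect_true(all(cur$quadrants$covered <= cur$quadrants$size))
    expect_true(all(cur$per_tf$pct_of_degs <= cur$overall$pct_covered + 1e-12))
    prev <- cur
  }
})

test_that("uncovered-DEG binding fractions hit the degenerate extremes", {
  degs <- deg_table(c("a", "b", "c"), c(2, 2, -2), c(0, 0, 0))
  ann <- structure(list(gene_class = tibble::tibble(
    gene_id = "a", class = "promoter_bound"
  )), class = "peak_annotation")
  part <- classify_degs(degs, ann, "promoter")
  core <- tibble::tibble(tf_name = "T1", gene_id = "a", direction = "up")

  # uncovered = {b, c}, both unbound
  rep1 <- tf_contribution(core, tibble::tibble(tf = "T1", target = "a"), part)
  expect_equal(uncovered_stats(rep1, part), 100)
  # uncovered = {a} only, bound
  rep2 <- tf_contribution(core, tibble::tibble(tf = "T1", target = c("b", "c")), part)
  expect_equal(uncovered_stats(rep2, part), 0)
})

test_that("planted core TFs are recovered exactly on simulated data", {
  b <- simulate_dataset(small_params(51))
  d <- call_degs(b$rna$counts, b$rna$design, b$rna$contrast)
  part <- classify_degs(d, annotate_peaks(b$peaks, b$genes), "promoter_or_body")
  hits <- scan_motifs(b$pwms, b$sequences)
  core <- select_core_tfs(unique(hits$tf_name), d, part, b$tf_map)
  expect_setequal(core$tf_name, b$truth$core_tfs$tf_name)
  expect_equal(
    core$direction[order(core$tf_name)],
    b$truth$core_tfs$direction[order(b$truth$core_tfs$tf_name)]
  )
})
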