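test_that("the same seed reproduces the bundle and its files byte-for-byte", {
  p <- small_params(61)
  b1 <- simulate_dataset(p)
  b2 <- simulate_dataset(p)
  expect_identical(b1, b2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = sprintf("file %s", f))
  }
  expect_false(identical(b1, simulate_dataset(small_params(62))))
})

test_that("requested peak category splits are planted exactly", {
  b <- simulate_dataset(sim_params(
    seed = 63, n_genes = 300,
    peaks = list(n = 100, split = c(promoter = 0.5, body = 0.3, intergenic = 0.2))
  ))
  ann <- annotate_peaks(b$peaks, b$genes)
  s <- peak_summary(ann)
  expect_equal(s$n_promoter_peaks, 50)
  expect_equal(s$n_body_peaks, 30)
  expect_equal(s$n_intergenic_peaks, 20)
  # realized annotation equals the planted truth
  expect_equal(
    ann$peak_category$category,
    b$truth$peak_category$category
  )
})

test_that("planted DE genes are recovered at the default effect plan", {
  b <- simulate_dataset(sim_params(seed = 64, n_genes = 1000,
                                   de = list(n_up = 100, n_down = 100)))
  d <- call_degs(b$rna$counts, b$rna$design, b$rna$contrast)
  truth <- b$truth$deg_status
  planted <- truth$status != "ns"
  sensitivity <- mean(d$status[planted] == truth$status[planted])
  called <- d$status != "ns"
  precision <- mean(truth$status[called] == d$status[called])
  expect_gte(sensitivity, 0.9)
  expect_gte(precision, 0.9)
})

test_that("bundles round-trip through plain-text files losslessly", {
  b <- simulate_dataset(small_params(65))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_equal(back$genes, b$genes)
  expect_equal(back$peaks[, c("region_id", "chrom", "start", "end")],
               b$peaks[, c("region_id", "chrom", "start", "end")])
  expect_equal(back$rna$counts, b$rna$counts)
  expect_equal(back$rna$design, b$rna$design)
  expect_equal(back$sequences, b$sequences)
  expect_equal(back$network, b$network)
  expect_equal(names(back$pwms), names(b$pwms))
  expect_equal(back$pwms[[1]]$matrix, b$pwms[[1]]$matrix,
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(as.data.frame(back$truth$deg_status),
               as.data.frame(b$truth$deg_status))
})

test_that("infeasible plans fail before emitting anything", {
  expect_error(
    simulate_dataset(sim_params(seed = 66, n_genes = 60,
                                de = list(n_up = 5, n_down = 5),
                                peaks = list(n = 100))),
    "infeasible"
  )
  expect_error(sim_params(peaks = list(split = c(0.5, 0.2, 0.2))))
})
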