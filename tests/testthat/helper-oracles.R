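# Brute-force oracles, deliberately independent of the package's interval
# machinery: every overlap is computed by enumerating bases.

bf_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1)))
}

# per-peak category by scanning all promoters, then all bodies
bf_peak_categories <- function(peaks, genes, up = 2000, down = 500) {
  prom <- promoter_of(genes, up, down)
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    for (j in seq_len(nrow(genes))) {
      if (bf_overlap(p, prom[j, ]) > 0) return("promoter")
    }
    for (j in seq_len(nrow(genes))) {
      if (bf_overlap(p, genes[j, ]) > 0) return("body")
    }
    "intergenic"
  }, "")
}

bf_chip_labels <- function(units, da, da_coords) {
  coords <- merge(da_coords, da[, c("region_id", "direction")], by = "region_id")
  vapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    dirs <- vapply(seq_len(nrow(coords)), function(j) {
      if (bf_overlap(u, coords[j, ]) > 0) coords$direction[j] else "none"
    }, "")
    if ("increased" %in% dirs) "increased"
    else if ("decreased" %in% dirs) "decreased"
    else "unchanged"
  }, "")
}

random_layout <- function(seed, n_genes = 40, n_peaks = 120, span = 2e5) {
  withr::with_seed(seed, {
    gs <- sort(sample.int(span, n_genes))
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = sample(c("c1", "c2"), n_genes, replace = TRUE),
      start = gs,
      end = gs + sample(500:5000, n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
    ps <- sample.int(span, n_peaks)
    peaks <- tibble::tibble(
      region_id = sprintf("p%03d", seq_len(n_peaks)),
      chrom = sample(c("c1", "c2"), n_peaks, replace = TRUE),
      start = ps,
      end = ps + sample(50:800, n_peaks, replace = TRUE),
      score = NA_real_
    )
    list(genes = genes, peaks = peaks)
  })
}

# small parameter set so simulation-backed tests stay fast
small_params <- function(seed, ...) {
  sim_params(
    seed = seed, n_genes = 300,
    de = list(n_up = 30, n_down = 30),
    peaks = list(n = 100),
    accessibility = list(n_regions = 120),
    ...
  )
}
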