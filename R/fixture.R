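# Deterministic fixture marginals. The published count tables for the
# ZFP541 pachytene-spermatocyte study fix every accounting statistic:
#   peaks:   4956 promoter + 2494 body + 786 intergenic = 8236
#   genes:   3742 promoter-bound + 1851 body-only-bound = 5593 bound
#   DEGs:    2807 up + 4898 down = 7705
#            promoter-bound: 1077 up / 304 down
#            promoter-or-body-bound: 1563 up / 484 down
#   ATAC:    of the 5593 bound genes 3666 increased / 1009 decreased / 918 unchanged
#   network: 25 core TFs (17 up / 8 down); covered DEGs per quadrant
#            1472/1563, 422/484, 856/1244, 1946/4414 (the unique small-integer
#            reconstruction of the printed coverage percentages)
FIXTURE <- list(
  n_prom_genes = 3742, n_body_genes = 1851,
  n_prom_peaks = 4956, n_body_peaks = 2494, n_intergenic_peaks = 786,
  up_prom = 1077, down_prom = 304, up_body = 486, down_body = 180,
  unbound_up = 1244, unbound_down = 4414,
  n_unbound_ns = 300,
  acc_inc = 3666, acc_dec = 1009, acc_unch = 918,
  acc_extra_unchanged = 3500,
  n_tf_up = 17, n_tf_down = 8,
  covered = c(bound_up = 1472, bound_down = 422, unbound_up = 856, unbound_down = 1946),
  small_tf_targets = 3,
  gene_width = 4000, spacing = 10000, promoter_window = c(2000, 500),
  base_mean = 100, up_fold = 4, down_fold = 0.25
)

#' Deterministic fixture reproducing the published marginal counts
#'
#' Builds, without any randomness, a complete multi-omics bundle whose
#' marginal counts are planted to equal the published ZFP541 count tables:
#' 8236 binding peaks (4956 promoter / 2494 body / 786 intergenic) over 5593
#' bound genes (3742 promoter-bound / 1851 body-only), 2807 up- and 4898
#' down-regulated genes with 1077/304 promoter-bound and 1563/484
#' promoter-or-body-bound, gene-level accessibility labels 3666 increased /
#' 1009 decreased / 918 unchanged over the bound genes, and a 25-TF core set
#' (17 up, 8 down) whose network covers 1472/422/856/1946 DEGs per quadrant.
#' Every downstream accounting statistic is therefore exactly checkable.
#'
#' The bundle carries both derived tables (`degs`, a ready [deg_table()];
#' `da` direction labels) and consistent low-level files (constant-count
#' matrices, peak/region coordinates, sequences with planted motifs), so the
#' accounting can be recomputed either from the derived tables or from raw
#' inputs with identical results. The accessibility region set includes 3500
#' intergenic unchanged regions so that median-of-ratios normalisation of
#' the region counts is neutral and directions re-derive from raw counts.
#'
#' @return A `dataset_bundle` with extra elements `degs` and `da`.
#' @export
fixture_paper_marginals <- function() {
  f <- FIXTURE
  w <- f$gene_width; sp <- f$spacing
  up_win <- f$promoter_window[1]; down_win <- f$promoter_window[2]

  ## --- gene universe ----------------------------------------------------
  # order: promoter-bound (up | down | ns), body-only (up | down | ns),
  #        unbound DEGs (up | down), unbound ns
  n_bound <- f$n_prom_genes + f$n_body_genes
  n_genes <- n_bound + f$unbound_up + f$unbound_down + f$n_unbound_ns
  idx <- seq_len(n_genes)
  per_chrom <- 6000L
  chrom <- sprintf("chrS%d", (idx - 1) %/% per_chrom + 1)
  pos <- (idx - 1) %% per_chrom
  start <- 10000 + pos * sp
  genes <- tibble(
    gene_id = sprintf("G%05d", idx),
    chrom = chrom, start = start, end = start + w,
    strand = "+", tss = start
  )

  i_prom <- seq_len(f$n_prom_genes)
  i_body <- f$n_prom_genes + seq_len(f$n_body_genes)
  i_unbound_de <- n_bound + seq_len(f$unbound_up + f$unbound_down)
  status <- rep("ns", n_genes)
  status[seq_len(f$up_prom)] <- "up"
  status[f$up_prom + seq_len(f$down_prom)] <- "down"
  status[i_body[seq_len(f$up_body)]] <- "up"
  status[i_body[f$up_body + seq_len(f$down_body)]] <- "down"
  status[n_bound + seq_len(f$unbound_up)] <- "up"
  status[n_bound + f$unbound_up + seq_len(f$unbound_down)] <- "down"

  ## --- peaks ------------------------------------------------------------
  prom_peak1 <- tibble(gene = i_prom, start = genes$tss[i_prom] - 400)
  extra_prom <- f$n_prom_peaks - f$n_prom_genes
  prom_peak2 <- tibble(gene = seq_len(extra_prom), start = genes$tss[seq_len(extra_prom)] - 1400)
  body_peak1 <- tibble(gene = i_body, start = genes$start[i_body] + 1000)
  extra_body <- f$n_body_peaks - f$n_body_genes
  body_peak2 <- tibble(gene = i_body[seq_len(extra_body)],
                       start = genes$start[i_body[seq_len(extra_body)]] + 2000)
  ig_gene <- seq_len(f$n_intergenic_peaks)
  ig_peak <- tibble(gene = ig_gene, start = genes$start[ig_gene] - 5000)
  pk <- bind_rows(prom_peak1, prom_peak2, body_peak1, body_peak2, ig_peak)
  peaks <- tibble(
    region_id = sprintf("PK%05d", seq_len(nrow(pk))),
    chrom = genes$chrom[pk$gene], start = pk$start, end = pk$start + 200,
    score = 10
  )
  stopifnot(nrow(peaks) == f$n_prom_peaks + f$n_body_peaks + f$n_intergenic_peaks)

  ## --- RNA counts (constant within group; exactly re-derivable) ---------
  fold <- ifelse(status == "up", f$up_fold, ifelse(status == "down", f$down_fold, 1))
  rna_counts <- cbind(
    WT_1 = rep(f$base_mean, n_genes), WT_2 = rep(f$base_mean, n_genes),
    KO_1 = f$base_mean * fold, KO_2 = f$base_mean * fold
  )
  rownames(rna_counts) <- genes$gene_id
  design <- tibble(sample_id = colnames(rna_counts), group = c("WT", "WT", "KO", "KO"))
  lfc <- log2((f$base_mean * fold + 1) / (f$base_mean + 1))
  degs <- deg_table(genes$gene_id, lfc, ifelse(status == "ns", 1, 0))
  stopifnot(identical(degs$status, status))

  ## --- accessibility ----------------------------------------------------
  # gene-coupled regions: one per bound gene, inside its body
  i_bound <- seq_len(n_bound)
  acc_dir_gene <- rep(c("increased", "decreased", "unchanged"),
                      c(f$acc_inc, f$acc_dec, f$acc_unch))
  gene_da <- tibble(
    chrom = genes$chrom[i_bound],
    start = genes$start[i_bound] + 3000,
    direction = acc_dir_gene
  )
  # intergenic unchanged ballast keeps median-of-ratios factors at 1
  ig_da_gene <- f$n_intergenic_peaks + seq_len(f$acc_extra_unchanged)
  ig_da <- tibble(
    chrom = genes$chrom[ig_da_gene],
    start = genes$start[ig_da_gene] - 5000,
    direction = "unchanged"
  )
  da_all <- bind_rows(gene_da, ig_da)
  da_regions <- tibble(
    region_id = sprintf("DA%05d", seq_len(nrow(da_all))),
    chrom = da_all$chrom, start = da_all$start, end = da_all$start + 400,
    score = NA_real_
  )
  da <- tibble(region_id = da_regions$region_id, direction = da_all$direction)
  a_fold <- ifelse(da$direction == "increased", f$up_fold,
                   ifelse(da$direction == "decreased", f$down_fold, 1))
  atac_counts <- cbind(
    WT_a1 = rep(f$base_mean, nrow(da)), WT_a2 = rep(f$base_mean, nrow(da)),
    KO_a1 = f$base_mean * a_fold, KO_a2 = f$base_mean * a_fold
  )
  rownames(atac_counts) <- da$region_id
  a_design <- tibble(sample_id = colnames(atac_counts), group = c("WT", "WT", "KO", "KO"))

  ## --- motifs: 25 core TFs + 2 decoys ----------------------------------
  n_tf <- f$n_tf_up + f$n_tf_down
  tf_names <- sprintf("TF%02d", seq_len(n_tf + 2))
  consensus <- vapply(seq_along(tf_names), fixture_consensus, "")
  pwms <- setNames(purrr::map2(tf_names, consensus, pwm_from_consensus), tf_names)
  # TF genes: 17 promoter-bound up, 8 promoter-bound down, then decoys:
  # one promoter-bound ns gene and one unbound up gene
  tf_gene_idx <- c(
    seq_len(f$n_tf_up),
    f$up_prom + seq_len(f$n_tf_down),
    2000L,
    n_bound + 1L
  )
  tf_map <- tibble(tf_name = tf_names, gene_id = genes$gene_id[tf_gene_idx])
  # sequences for the first 30 increased regions; motif i planted in region i
  seq_ids <- da_regions$region_id[seq_len(30)]
  background <- strrep("ACGT", 100)
  sequences <- setNames(rep(background, 30), seq_ids)
  for (i in seq_along(tf_names)) {
    substr(sequences[[i]], 51, 60) <- consensus[i]
  }

  ## --- network ----------------------------------------------------------
  ord_bound_up <- c(seq_len(f$up_prom), i_body[seq_len(f$up_body)])
  ord_bound_down <- c(f$up_prom + seq_len(f$down_prom), i_body[f$up_body + seq_len(f$down_body)])
  ord_unbound_up <- n_bound + seq_len(f$unbound_up)
  ord_unbound_down <- n_bound + f$unbound_up + seq_len(f$unbound_down)
  covered_idx <- c(
    head(ord_bound_up, f$covered[["bound_up"]]),
    head(ord_bound_down, f$covered[["bound_down"]]),
    head(ord_unbound_up, f$covered[["unbound_up"]]),
    head(ord_unbound_down, f$covered[["unbound_down"]])
  )
  covered_ids <- genes$gene_id[covered_idx]
  big_tfs <- tf_names[seq_len(f$n_tf_up)]
  small_tfs <- tf_names[f$n_tf_up + seq_len(f$n_tf_down)]
  edges <- bind_rows(
    tibble(tf = rep_len(big_tfs, length(covered_ids)), target = covered_ids),
    tibble(
      tf = rep(small_tfs, each = f$small_tf_targets),
      target = covered_ids[seq_len(f$n_tf_down * f$small_tf_targets)]
    ),
    # decoy edges to genes that are not DEGs
    tibble(tf = big_tfs[1], target = genes$gene_id[n_genes - seq_len(50) + 1])
  )
  network <- distinct(edges, .data$tf, .data$target)

  gene_class_truth <- bind_rows(
    tibble(gene_id = genes$gene_id[i_prom], class = "promoter_bound"),
    tibble(gene_id = genes$gene_id[i_body], class = "body_only_bound")
  )
  peak_truth <- tibble(
    region_id = peaks$region_id,
    category = rep(c("promoter", "body", "intergenic"),
                   c(f$n_prom_peaks, f$n_body_peaks, f$n_intergenic_peaks))
  )

  structure(
    list(
      genes = genes,
      rna = list(counts = rna_counts, design = design, contrast = c("KO", "WT")),
      peaks = peaks,
      atac = list(regions = da_regions, counts = atac_counts, design = a_design,
                  contrast = c("KO", "WT")),
      sequences = sequences,
      pwms = pwms,
      tf_map = tf_map,
      network = network,
      degs = degs,
      da = da,
      truth = list(
        deg_status = tibble(gene_id = genes$gene_id, status = status),
        peak_category = peak_truth,
        gene_class = gene_class_truth,
        da_direction = da,
        core_tfs = tibble(
          tf_name = tf_names[seq_len(n_tf)],
          gene_id = genes$gene_id[tf_gene_idx[seq_len(n_tf)]],
          direction = rep(c("up", "down"), c(f$n_tf_up, f$n_tf_down))
        ),
        coverage = tibble(
          quadrant = names(f$covered),
          size = c(f$up_prom + f$up_body, f$down_prom + f$down_body,
                   f$unbound_up, f$unbound_down),
          covered = as.integer(f$covered)
        )
      ),
      params = NULL
    ),
    class = "dataset_bundle"
  )
}

# doubled base-4 digits of (i - 1): pairwise-distinct 10-mers containing
# adjacent repeated letters, so they can never occur in the fixture's
# ACGT-periodic background sequence (nor can their reverse complements)
fixture_consensus <- function(i) {
  d <- integer(5)
  x <- i - 1
  for (k in 5:1) {
    d[k] <- x %% 4
    x <- x %/% 4
  }
  paste(strrep(DNA_BASES[d + 1], 2), collapse = "")
}
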