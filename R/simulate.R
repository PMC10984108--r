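#' Simulation parameters for a synthetic multi-omics bundle
#'
#' Collects every knob of [simulate_dataset()] with defaults chosen as a
#' realistic small study: negative-binomial RNA counts (dispersion 0.05,
#' mean 200, 3 replicates per genotype) with planted |log2FC| = 2 genes,
#' binding peaks with a controllable promoter/body/intergenic split,
#' accessibility regions coupled to binding, planted PWM instances, and a
#' TF-target network planted to hit per-quadrant coverage fractions.
#'
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   bundle exactly.
#' @param n_genes Number of genes laid out on the synthetic chromosomes.
#' @param n_chromosomes Number of synthetic chromosomes.
#' @param gene_spacing Start-to-start distance between adjacent genes (bp).
#' @param gene_width_range Min/max gene widths (bp).
#' @param promoter_window `c(upstream, downstream)` promoter extents (bp).
#' @param de DE plan: `n_up`, `n_down`, `lfc`, `dispersion`, `mean`,
#'   `n_replicates`, `groups` (mutant first).
#' @param peaks Peak plan: `n`, `split` (promoter/body/intergenic fractions),
#'   `width`.
#' @param accessibility Accessibility plan: `n_regions`, `frac_increased`,
#'   `frac_decreased`, `coupling` (probability an altered region is placed on
#'   a binding peak), `width`, `mean`, `dispersion`, `n_replicates`, `lfc`.
#' @param motifs Motif plan: `n_tfs`, `n_core_up`, `n_core_down`,
#'   `motif_length`, `instances_per_tf`, `off_rate`.
#' @param network Network plan: `coverage` (named per-quadrant fractions),
#'   `extra_edges` (decoy edges to non-DEGs).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1,
                       n_genes = 2000,
                       n_chromosomes = 2,
                       gene_spacing = 10000,
                       gene_width_range = c(1000, 4000),
                       promoter_window = c(2000, 500),
                       de = list(),
                       peaks = list(),
                       accessibility = list(),
                       motifs = list(),
                       network = list()) {
  de <- utils::modifyList(list(
    n_up = 100, n_down = 100, lfc = 2, dispersion = 0.05, mean = 200,
    n_replicates = 3, groups = c("KO", "WT")
  ), de)
  peaks <- utils::modifyList(list(
    n = 200, split = c(promoter = 0.5, body = 0.3, intergenic = 0.2), width = 200
  ), peaks)
  accessibility <- utils::modifyList(list(
    n_regions = 300, frac_increased = 0.3, frac_decreased = 0.1, coupling = 0.8,
    width = 400, mean = 100, dispersion = 0.05, n_replicates = 3, lfc = 2
  ), accessibility)
  motifs <- utils::modifyList(list(
    n_tfs = 12, n_core_up = 5, n_core_down = 3, motif_length = 10,
    instances_per_tf = 5, off_rate = 0.001
  ), motifs)
  network <- utils::modifyList(list(
    coverage = c(bound_up = 0.9, bound_down = 0.85, unbound_up = 0.65, unbound_down = 0.45),
    extra_edges = 50
  ), network)
  p <- list(
    seed = seed, n_genes = n_genes, n_chromosomes = n_chromosomes,
    gene_spacing = gene_spacing, gene_width_range = gene_width_range,
    promoter_window = promoter_window, de = de, peaks = peaks,
    accessibility = accessibility, motifs = motifs, network = network
  )
  stopifnot(
    n_genes > 0, n_chromosomes > 0,
    de$n_up + de$n_down <= n_genes,
    abs(sum(peaks$split) - 1) < 1e-9,
    accessibility$frac_increased + accessibility$frac_decreased <= 1,
    all(network$coverage >= 0), all(network$coverage <= 1)
  )
  structure(p, class = "sim_params")
}

# draw an NB counts matrix, features x samples; `mu` is features x samples
draw_counts <- function(mu, dispersion) {
  counts <- if (dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate a seeded multi-omics dataset with planted ground truth
#'
#' Builds a complete bundle — gene annotation, RNA counts with design,
#' binding peaks, accessibility regions with counts, region sequences, PWMs,
#' TF name map, TF-target network — together with truth tables recording
#' every planted label, so recovery can be measured against a known answer.
#'
#' Genes are laid out non-overlapping on synthetic chromosomes with enough
#' spacing that promoter windows never collide. Peaks are placed inside
#' promoter windows, inside gene bodies clear of the promoter window, or in
#' intergenic gaps, to hit the requested category split exactly (promoter and
#' body peaks go to disjoint gene sets so the planted gene classes are
#' unambiguous). Altered accessibility regions are placed on binding peaks
#' with the coupling probability, otherwise in gaps. Motif instances are
#' planted into the sequences of increased regions at recorded offsets. The
#' network is planted to cover, per regulon quadrant, a round-half-up count
#' matching the requested coverage fractions, with edges distributed
#' round-robin over the core TFs.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `dataset_bundle`; see the `truth` element for the
#'   planted labels.
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, simulate_dataset_impl(params))
}

simulate_dataset_impl <- function(p) {
  up <- p$promoter_window[1]; down <- p$promoter_window[2]
  pk_w <- p$peaks$width
  min_body_room <- down + pk_w + 20
  stopifnot(p$gene_width_range[1] >= min_body_room)
  if (p$gene_spacing < p$gene_width_range[2] + 2 * up + 200) {
    abort("gene_spacing too small for the promoter window: promoters would collide")
  }

  ## --- gene layout ------------------------------------------------------
  n <- p$n_genes
  per_chrom <- ceiling(n / p$n_chromosomes)
  chrom_idx <- rep(seq_len(p$n_chromosomes), each = per_chrom)[seq_len(n)]
  pos_in_chrom <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
  width <- sample(seq(p$gene_width_range[1], p$gene_width_range[2]), n, replace = TRUE)
  start <- (up + 1000) + (pos_in_chrom - 1) * p$gene_spacing
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- tibble(
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = sprintf("chrS%d", chrom_idx),
    start = start,
    end = start + width,
    strand = strand
  ) |> mutate(tss = if_else(.data$strand == "-", .data$end - 1, .data$start))

  ## --- DE plan ----------------------------------------------------------
  de_genes <- sample(genes$gene_id, p$de$n_up + p$de$n_down)
  up_genes <- de_genes[seq_len(p$de$n_up)]
  down_genes <- setdiff(de_genes, up_genes)
  deg_truth <- tibble(gene_id = genes$gene_id) |>
    mutate(status = dplyr::case_when(
      .data$gene_id %in% up_genes ~ "up",
      .data$gene_id %in% down_genes ~ "down",
      TRUE ~ "ns"
    ))
  nrep <- p$de$n_replicates
  samples <- c(sprintf("WT_%d", seq_len(nrep)), sprintf("%s_%d", p$de$groups[1], seq_len(nrep)))
  design <- tibble(
    sample_id = samples,
    group = rep(c(p$de$groups[2], p$de$groups[1]), each = nrep)
  )
  lfc_signed <- ifelse(deg_truth$status == "up", p$de$lfc,
                       ifelse(deg_truth$status == "down", -p$de$lfc, 0))
  mu <- matrix(p$de$mean, nrow = n, ncol = 2 * nrep,
               dimnames = list(genes$gene_id, samples))
  mu[, design$group == p$de$groups[1]] <-
    mu[, design$group == p$de$groups[1]] * 2^lfc_signed
  rna_counts <- draw_counts(mu, p$de$dispersion)

  ## --- peaks ------------------------------------------------------------
  n_prom <- round_half_up(p$peaks$n * p$peaks$split[["promoter"]], 0)
  n_body <- round_half_up(p$peaks$n * p$peaks$split[["body"]], 0)
  n_int <- p$peaks$n - n_prom - n_body
  if (n_prom + n_body > n) abort("infeasible peak plan: more gene-linked peaks than genes")
  # core TF genes must be promoter-bound DEGs; reserve them first
  # (clamped to the planted DE genes actually available)
  core_up_genes <- head(up_genes, p$motifs$n_core_up)
  core_down_genes <- head(down_genes, p$motifs$n_core_down)
  n_core_up <- length(core_up_genes)
  n_core_down <- length(core_down_genes)
  reserved <- c(core_up_genes, core_down_genes)
  if (length(reserved) > n_prom) abort("infeasible plan: fewer promoter peaks than core TFs")
  prom_genes <- c(reserved, sample(setdiff(genes$gene_id, reserved), n_prom - length(reserved)))
  body_pool <- genes |>
    filter(!.data$gene_id %in% prom_genes, .data$end - .data$start >= min_body_room)
  if (nrow(body_pool) < n_body) abort("infeasible peak plan: not enough genes with body room")
  body_genes <- sample(body_pool$gene_id, n_body)

  place_promoter_peak <- function(g) {
    u <- sample(seq(pk_w + 100, up - 100), length(g$gene_id), replace = TRUE)
    s <- ifelse(g$strand == "+", g$tss - u, g$tss + u - pk_w)
    tibble(chrom = g$chrom, start = s, end = s + pk_w)
  }
  place_body_peak <- function(g) {
    lo <- ifelse(g$strand == "+", g$start + down + 10, g$start)
    hi <- ifelse(g$strand == "+", g$end - pk_w, g$end - down - 10 - pk_w)
    s <- lo + floor(runif(length(lo)) * (hi - lo + 1))
    tibble(chrom = g$chrom, start = s, end = s + pk_w)
  }
  gp <- genes[match(prom_genes, genes$gene_id), ]
  gb <- genes[match(body_genes, genes$gene_id), ]
  gap_margin <- up + 100
  gaps <- genes |>
    group_by(.data$chrom) |>
    summarise(gs = list(.data$end[-n()] + gap_margin),
              ge = list(.data$start[-1] - gap_margin), .groups = "drop") |>
    tidyr::unnest(c("gs", "ge")) |>
    filter(.data$ge - .data$gs >= pk_w + 10)
  place_intergenic <- function(k, w) {
    gi <- sample(nrow(gaps), k, replace = TRUE)
    s <- gaps$gs[gi] + floor(runif(k) * (gaps$ge[gi] - gaps$gs[gi] - w + 1))
    tibble(chrom = gaps$chrom[gi], start = s, end = s + w)
  }
  peak_coords <- bind_rows(
    place_promoter_peak(gp), place_body_peak(gb), place_intergenic(n_int, pk_w)
  )
  peaks <- tibble(
    region_id = sprintf("PK%05d", seq_len(nrow(peak_coords))),
    chrom = peak_coords$chrom, start = peak_coords$start, end = peak_coords$end,
    score = round_half_up(stats::rexp(nrow(peak_coords), 1 / 10), 3)
  )
  peak_truth <- tibble(
    region_id = peaks$region_id,
    category = rep(c("promoter", "body", "intergenic"), c(n_prom, n_body, n_int)),
    gene_id = c(prom_genes, body_genes, rep(NA_character_, n_int))
  )
  gene_class_truth <- bind_rows(
    tibble(gene_id = unique(prom_genes), class = "promoter_bound"),
    tibble(gene_id = unique(body_genes), class = "body_only_bound")
  )

  ## --- accessibility ----------------------------------------------------
  acc <- p$accessibility
  n_inc <- round_half_up(acc$n_regions * acc$frac_increased, 0)
  n_dec <- round_half_up(acc$n_regions * acc$frac_decreased, 0)
  n_unch <- acc$n_regions - n_inc - n_dec
  direction <- c(rep("increased", n_inc), rep("decreased", n_dec), rep("unchanged", n_unch))
  coupled <- runif(acc$n_regions) < acc$coupling & direction != "unchanged"
  k_c <- sum(coupled)
  pk_anchor <- sample(nrow(peaks), k_c, replace = TRUE)
  anchor_start <- pmax(0, peaks$start[pk_anchor] - floor(acc$width / 4))
  coupled_coords <- tibble(
    chrom = peaks$chrom[pk_anchor], start = anchor_start, end = anchor_start + acc$width
  )
  free_coords <- place_intergenic(acc$n_regions - k_c, acc$width)
  da_coords_raw <- bind_rows(coupled_coords, free_coords)
  ord <- order(c(which(coupled), which(!coupled))) # restore direction order
  da_coords_raw <- da_coords_raw[ord, ]
  da_regions <- tibble(
    region_id = sprintf("DA%05d", seq_len(acc$n_regions)),
    chrom = da_coords_raw$chrom, start = da_coords_raw$start, end = da_coords_raw$end,
    score = NA_real_
  )
  da_truth <- tibble(region_id = da_regions$region_id, direction = direction)
  nrep_a <- acc$n_replicates
  a_samples <- c(sprintf("WT_a%d", seq_len(nrep_a)),
                 sprintf("%s_a%d", p$de$groups[1], seq_len(nrep_a)))
  a_design <- tibble(
    sample_id = a_samples,
    group = rep(c(p$de$groups[2], p$de$groups[1]), each = nrep_a)
  )
  a_lfc <- ifelse(direction == "increased", acc$lfc,
                  ifelse(direction == "decreased", -acc$lfc, 0))
  mu_a <- matrix(acc$mean, nrow = acc$n_regions, ncol = 2 * nrep_a,
                 dimnames = list(da_regions$region_id, a_samples))
  mu_a[, a_design$group == p$de$groups[1]] <-
    mu_a[, a_design$group == p$de$groups[1]] * 2^a_lfc
  atac_counts <- draw_counts(mu_a, acc$dispersion)

  ## --- motifs and sequences --------------------------------------------
  mo <- p$motifs
  sequences <- setNames(random_dna(acc$n_regions, acc$width), da_regions$region_id)
  tf_names <- sprintf("TF%02d", seq_len(mo$n_tfs))
  consensus <- random_dna(mo$n_tfs, mo$motif_length)
  pwms <- setNames(
    purrr::map2(tf_names, consensus, pwm_from_consensus, off_rate = mo$off_rate),
    tf_names
  )
  inc_ids <- da_truth$region_id[da_truth$direction == "increased"]
  occupied <- setNames(vector("list", length(sequences)), names(sequences))
  planted <- list()
  for (i in seq_along(tf_names)) {
    for (k in seq_len(mo$instances_per_tf)) {
      placed <- FALSE
      for (try in 1:50) {
        rid <- sample(inc_ids, 1)
        o <- sample.int(nchar(sequences[[rid]]) - mo$motif_length + 1, 1)
        win <- c(o, o + mo$motif_length - 1)
        clash <- any(vapply(occupied[[rid]], function(x) win[1] <= x[2] && x[1] <= win[2], TRUE))
        if (!clash) {
          substr(sequences[[rid]], win[1], win[2]) <- consensus[i]
          occupied[[rid]] <- c(occupied[[rid]], list(win))
          planted[[length(planted) + 1]] <-
            tibble(tf_name = tf_names[i], region_id = rid, offset = o - 1)
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place all motif instances; increase region width/count")
    }
  }
  planted_motifs <- purrr::list_rbind(planted)

  ## --- TF name map ------------------------------------------------------
  core_tf_names <- tf_names[seq_len(n_core_up + n_core_down)]
  decoy_names <- setdiff(tf_names, core_tf_names)
  ns_unbound <- setdiff(genes$gene_id, c(de_genes, prom_genes, body_genes))
  decoy_gene <- sample(ns_unbound, length(decoy_names))
  tf_map <- bind_rows(
    tibble(tf_name = tf_names[seq_len(n_core_up)], gene_id = core_up_genes),
    tibble(tf_name = tf_names[n_core_up + seq_len(n_core_down)], gene_id = core_down_genes),
    tibble(tf_name = decoy_names, gene_id = decoy_gene)
  )
  core_truth <- tf_map |>
    filter(.data$tf_name %in% core_tf_names) |>
    left_join(deg_truth, by = "gene_id") |>
    rename(direction = "status")

  ## --- network planted to per-quadrant coverage -------------------------
  bound_genes <- c(prom_genes, body_genes)
  quad_truth <- deg_truth |>
    filter(.data$status != "ns") |>
    mutate(quadrant = paste0(if_else(.data$gene_id %in% bound_genes, "bound_", "unbound_"),
                             .data$status))
  cov <- p$network$coverage
  covered_ids <- purrr::map(names(cov), function(q) {
    ids <- quad_truth$gene_id[quad_truth$quadrant == q]
    head(sample(ids), round_half_up(length(ids) * cov[[q]], 0))
  }) |> unlist()
  coverage_truth <- quad_truth |>
    count(.data$quadrant, name = "size") |>
    left_join(
      tibble(gene_id = covered_ids) |>
        left_join(quad_truth, by = "gene_id") |>
        count(.data$quadrant, name = "covered"),
      by = "quadrant"
    ) |>
    mutate(covered = dplyr::coalesce(.data$covered, 0L))
  edges <- if (length(covered_ids) > 0 && length(core_tf_names) > 0) {
    tibble(
      tf = rep_len(core_tf_names, length(covered_ids)),
      target = covered_ids
    )
  } else {
    tibble(tf = character(), target = character())
  }
  if (p$network$extra_edges > 0 && length(ns_unbound) > 0) {
    edges <- bind_rows(edges, tibble(
      tf = sample(tf_names, p$network$extra_edges, replace = TRUE),
      target = sample(ns_unbound, p$network$extra_edges, replace = TRUE)
    ))
  }
  network <- distinct(edges, .data$tf, .data$target)

  structure(
    list(
      genes = genes,
      rna = list(counts = rna_counts, design = design, contrast = p$de$groups),
      peaks = peaks,
      atac = list(regions = da_regions, counts = atac_counts, design = a_design,
                  contrast = p$de$groups),
      sequences = sequences,
      pwms = pwms,
      tf_map = tf_map,
      network = network,
      truth = list(
        deg_status = deg_truth,
        peak_category = peak_truth,
        gene_class = gene_class_truth,
        da_direction = da_truth,
        planted_motifs = planted_motifs,
        core_tfs = core_truth,
        coverage = coverage_truth
      ),
      params = p
    ),
    class = "dataset_bundle"
  )
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(
    "<dataset_bundle> %d genes, %d peaks, %d accessibility regions, %d PWMs, %d network edges\n",
    nrow(x$genes), nrow(x$peaks), nrow(x$atac$regions), length(x$pwms), nrow(x$network)
  ))
  invisible(x)
}

#' Write / read a dataset bundle as plain-text files
#'
#' Serialises every component of a bundle through the package's standard
#' readers and writers: GTF annotation, narrowPeak-style BED peaks, TSV count
#' matrices and designs, FASTA region sequences, MEME motifs, TSV name map
#' and network, and JSON truth tables. `read_bundle()` round-trips the
#' result.
#'
#' @param bundle A `dataset_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir` (or the bundle, for `read_bundle`), invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_gene_annotation(bundle$genes, fp("genes.gtf"))
  write_regions(bundle$peaks, fp("chip_peaks.bed"))
  write_count_matrix(bundle$rna$counts, bundle$rna$design,
                     fp("rna_counts.tsv"), fp("rna_design.tsv"), "gene_id")
  write_regions(bundle$atac$regions, fp("atac_regions.bed"))
  write_count_matrix(bundle$atac$counts, bundle$atac$design,
                     fp("atac_counts.tsv"), fp("atac_design.tsv"), "region_id")
  write_region_sequences(bundle$sequences, fp("regions.fa"))
  write_meme(bundle$pwms, fp("motifs.meme"))
  readr::write_tsv(bundle$tf_map, fp("tf_map.tsv"), progress = FALSE)
  write_network(bundle$network, fp("network.tsv"))
  jsonlite::write_json(
    c(bundle$truth, list(contrast = bundle$rna$contrast)),
    fp("truth.json"), dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  rna <- read_count_matrix(fp("rna_counts.tsv"), fp("rna_design.tsv"))
  atac <- read_count_matrix(fp("atac_counts.tsv"), fp("atac_design.tsv"))
  truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  contrast <- truth$contrast
  truth$contrast <- NULL
  truth <- lapply(truth, as_tibble)
  structure(
    list(
      genes = read_gene_annotation(fp("genes.gtf")),
      rna = list(counts = rna$counts, design = rna$design, contrast = contrast),
      peaks = read_regions(fp("chip_peaks.bed")),
      atac = list(regions = read_regions(fp("atac_regions.bed")),
                  counts = atac$counts, design = atac$design, contrast = contrast),
      sequences = read_region_sequences(fp("regions.fa")),
      pwms = read_meme(fp("motifs.meme")),
      tf_map = readr::read_tsv(fp("tf_map.tsv"), show_col_types = FALSE, progress = FALSE),
      network = read_network(fp("network.tsv")),
      truth = truth,
      params = NULL
    ),
    class = "dataset_bundle"
  )
}
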