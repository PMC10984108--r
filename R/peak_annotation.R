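#' Annotate binding peaks against promoters and gene bodies
#'
#' Every peak overlapping (>= 1 bp, strand-blind) a gene's promoter window
#' yields a `promoter` link and every peak overlapping a gene's span yields a
#' `body` link; links are many-to-many in both directions. From the links,
#' peaks are categorised with promoter > body > intergenic precedence (a peak
#' with any promoter link is a promoter peak, otherwise a body peak if it has
#' any body link, otherwise intergenic) and genes are classed with
#' promoter_bound > body_only_bound precedence. The precedence makes both
#' tallies disjoint so they sum to the peak and gene totals.
#'
#' @param peaks Region tibble (see [read_regions()]).
#' @param genes Gene tibble (see [read_gene_annotation()]).
#' @param promoter_up,promoter_down Promoter window extents in bp passed to
#'   [promoter_of()].
#' @return A `peak_annotation` object: list with `links` (tibble `peak_id`,
#'   `gene_id`, `link_type`), `peak_category` (tibble `peak_id`, `category`
#'   covering every peak), `gene_class` (tibble `gene_id`, `class` covering
#'   every linked gene), and the promoter window used.
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 2000, promoter_down = 500) {
  stopifnot(!anyDuplicated(peaks$region_id), !anyDuplicated(genes$gene_id))
  px <- tibble(id = peaks$region_id, chrom = peaks$chrom,
               start = peaks$start, end = peaks$end)
  if (nrow(genes) > 0) {
    prom <- promoter_of(genes, promoter_up, promoter_down)
    prom_links <- overlap_join(
      px, tibble(id = prom$gene_id, chrom = prom$chrom, start = prom$start, end = prom$end),
      "peak_id", "gene_id"
    ) |> mutate(link_type = "promoter")
    body_links <- overlap_join(
      px, tibble(id = genes$gene_id, chrom = genes$chrom, start = genes$start, end = genes$end),
      "peak_id", "gene_id"
    ) |> mutate(link_type = "body")
    links <- bind_rows(prom_links, body_links) |>
      select("peak_id", "gene_id", "link_type") |>
      arrange(.data$peak_id, .data$gene_id, .data$link_type)
  } else {
    links <- tibble(peak_id = character(), gene_id = character(), link_type = character())
  }
  has_prom <- unique(links$peak_id[links$link_type == "promoter"])
  has_body <- unique(links$peak_id[links$link_type == "body"])
  peak_category <- tibble(peak_id = peaks$region_id) |>
    mutate(category = dplyr::case_when(
      .data$peak_id %in% has_prom ~ "promoter",
      .data$peak_id %in% has_body ~ "body",
      TRUE ~ "intergenic"
    ))
  g_prom <- unique(links$gene_id[links$link_type == "promoter"])
  g_body <- setdiff(unique(links$gene_id[links$link_type == "body"]), g_prom)
  gene_class <- bind_rows(
    tibble(gene_id = g_prom, class = "promoter_bound"),
    tibble(gene_id = g_body, class = "body_only_bound")
  ) |> arrange(.data$gene_id)
  structure(
    list(
      links = links,
      peak_category = peak_category,
      gene_class = gene_class,
      promoter_window = c(upstream = promoter_up, downstream = promoter_down)
    ),
    class = "peak_annotation"
  )
}

#' Summarise a peak annotation
#'
#' Counts and percentages of peaks on promoters, gene bodies and intergenic
#' space, and of genes bound at promoters vs bodies only. Percentages are
#' kept at full precision; rounding is a presentation concern.
#'
#' @param annotation A `peak_annotation` from [annotate_peaks()].
#' @return One-row tibble with `n_peaks`, `n_promoter_peaks`, `n_body_peaks`,
#'   `n_intergenic_peaks`, `n_promoter_genes`, `n_body_only_genes`,
#'   `pct_gene_associated`, `pct_intergenic`.
#' @export
peak_summary <- function(annotation) {
  pc <- annotation$peak_category
  if (nrow(pc) == 0) abort("empty peak set: percentages are undefined")
  n <- nrow(pc)
  n_prom <- sum(pc$category == "promoter")
  n_body <- sum(pc$category == "body")
  n_int <- sum(pc$category == "intergenic")
  gc <- annotation$gene_class
  tibble(
    n_peaks = n,
    n_promoter_peaks = n_prom,
    n_body_peaks = n_body,
    n_intergenic_peaks = n_int,
    n_promoter_genes = sum(gc$class == "promoter_bound"),
    n_body_only_genes = sum(gc$class == "body_only_bound"),
    pct_gene_associated = pct(n_prom + n_body, n),
    pct_intergenic = pct(n_int, n)
  )
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf(
    "<peak_annotation> %d links, %d peaks, %d bound genes (promoter window -%d/+%d)\n",
    nrow(x$links), nrow(x$peak_category), nrow(x$gene_class),
    x$promoter_window[["upstream"]], x$promoter_window[["downstream"]]
  ))
  invisible(x)
}

#' @method tidy peak_annotation
#' @export
tidy.peak_annotation <- function(x, ...) x$links

#' @method glance peak_annotation
#' @export
glance.peak_annotation <- function(x, ...) peak_summary(x)
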