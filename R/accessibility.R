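#' Call differential-accessibility regions
#'
#' Applies the package's differential engine ([call_degs()]) to a region x
#' sample accessibility count matrix and relabels the result in
#' accessibility vocabulary: `up` becomes `increased`, `down` becomes
#' `decreased`, `ns` becomes `unchanged`.
#'
#' @param region_counts Non-negative integer matrix, regions x samples, with
#'   region ids as rownames.
#' @param design Tibble with `sample_id`, `group`.
#' @param contrast `c(numerator_group, denominator_group)`.
#' @param th A [thresholds()] object; the same semantics as for expression.
#' @return Tibble with `region_id`, `log2fc`, `p_value`, `padj_bh`,
#'   `direction` in {increased, decreased, unchanged}.
#' @export
call_da_regions <- function(region_counts, design, contrast, th = thresholds()) {
  res <- call_degs(region_counts, design, contrast, th)
  tibble(
    region_id = res$gene_id,
    log2fc = res$log2fc,
    p_value = res$p_value,
    padj_bh = res$padj_bh,
    direction = dplyr::recode(res$status, up = "increased", down = "decreased", ns = "unchanged")
  )
}

da_directions <- function(da) {
  stopifnot(all(da$direction %in% c("increased", "decreased", "unchanged")))
  da
}

#' Overlap ChIP units with differential-accessibility regions
#'
#' Labels each ChIP unit — a binding peak, or a bound gene represented by its
#' promoter-plus-body span — by the accessibility change it overlaps:
#' `increased` if it overlaps at least one increased region, else `decreased`
#' if it overlaps at least one decreased region, else `unchanged`. The fixed
#' increased > decreased precedence makes the labels a partition of the
#' units.
#'
#' @param chip_units Region tibble of units (`region_id`, `chrom`, `start`,
#'   `end`); for gene-level accounting build it with [gene_units()].
#' @param da Differential-accessibility tibble from [call_da_regions()] (or
#'   any tibble with `region_id` and `direction`).
#' @param da_coords Region tibble giving coordinates for `da`'s region ids.
#' @return An `accessibility_summary`: one-row tibble with `n_chip_units`,
#'   `n_increased`, `n_decreased`, `n_unchanged`, `pct_increased`,
#'   `pct_decreased`, `pct_altered`, carrying the per-unit label tibble as
#'   attribute `labels`.
#' @export
chip_da_overlap <- function(chip_units, da, da_coords) {
  if (nrow(chip_units) == 0) abort("empty ChIP unit set")
  da <- da_directions(da)
  coords <- inner_join(da_coords, da[, c("region_id", "direction")], by = "region_id")
  hits <- overlap_join(
    tibble(id = chip_units$region_id, chrom = chip_units$chrom,
           start = chip_units$start, end = chip_units$end),
    tibble(id = coords$region_id, chrom = coords$chrom,
           start = coords$start, end = coords$end),
    "unit_id", "region_id"
  ) |> left_join(coords[, c("region_id", "direction")], by = "region_id")
  labels <- tibble(unit_id = chip_units$region_id) |>
    mutate(
      label = dplyr::case_when(
        .data$unit_id %in% hits$unit_id[hits$direction == "increased"] ~ "increased",
        .data$unit_id %in% hits$unit_id[hits$direction == "decreased"] ~ "decreased",
        TRUE ~ "unchanged"
      )
    )
  accessibility_summary(labels)
}

#' Summarise per-unit accessibility labels
#'
#' @param labels Tibble with `unit_id` and `label` in
#'   {increased, decreased, unchanged}.
#' @return An `accessibility_summary` one-row tibble (see
#'   [chip_da_overlap()]).
#' @export
accessibility_summary <- function(labels) {
  if (nrow(labels) == 0) abort("empty ChIP unit set")
  stopifnot(all(labels$label %in% c("increased", "decreased", "unchanged")))
  n <- nrow(labels)
  n_inc <- sum(labels$label == "increased")
  n_dec <- sum(labels$label == "decreased")
  out <- tibble(
    n_chip_units = n,
    n_increased = n_inc,
    n_decreased = n_dec,
    n_unchanged = n - n_inc - n_dec,
    pct_increased = pct(n_inc, n),
    pct_decreased = pct(n_dec, n),
    pct_altered = pct(n_inc + n_dec, n)
  )
  structure(out, labels = labels, class = c("accessibility_summary", class(out)))
}

#' Gene-level ChIP units
#'
#' Represents each bound gene as one interval spanning its promoter window
#' and its body, the unit used for gene-level ChIP x accessibility
#' accounting.
#'
#' @param genes Gene tibble; typically subset to the bound genes first.
#' @param promoter_up,promoter_down Promoter window extents in bp.
#' @return Region tibble (`region_id` = gene_id, `chrom`, `start`, `end`).
#' @export
gene_units <- function(genes, promoter_up = 2000, promoter_down = 500) {
  prom <- promoter_of(genes, promoter_up, promoter_down)
  tibble(
    region_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmin(genes$start, prom$start),
    end = pmax(genes$end, prom$end)
  )
}

#' Fraction of altered accessibility regions not linked to any DEG
#'
#' An altered (increased or decreased) region is "linked" when it overlaps
#' the promoter window or the body of a gene whose expression status is `up`
#' or `down`; the statistic is the percentage of altered regions that are
#' not linked — regions whose accessibility change has no expression
#' correlate or no gene at all.
#'
#' @param da Differential-accessibility tibble (`region_id`, `direction`).
#' @param da_coords Region tibble of coordinates for `da`.
#' @param genes Gene tibble.
#' @param degs A `deg_table`.
#' @param promoter_up,promoter_down Promoter window extents in bp.
#' @return Percentage (0-100) of altered regions unlinked to any DEG.
#' @export
da_expression_link <- function(da, da_coords, genes, degs,
                               promoter_up = 2000, promoter_down = 500) {
  da <- da_directions(da)
  altered_ids <- da$region_id[da$direction != "unchanged"]
  if (length(altered_ids) == 0) abort("zero altered regions")
  altered <- da_coords[da_coords$region_id %in% altered_ids, ]
  deg_ids <- degs$gene_id[degs$status %in% c("up", "down")]
  deg_genes <- genes[genes$gene_id %in% deg_ids, ]
  units <- gene_units(deg_genes, promoter_up, promoter_down)
  hits <- overlap_join(
    tibble(id = altered$region_id, chrom = altered$chrom,
           start = altered$start, end = altered$end),
    tibble(id = units$region_id, chrom = units$chrom,
           start = units$start, end = units$end),
    "region_id", "gene_id"
  )
  pct(sum(!altered$region_id %in% hits$region_id), nrow(altered))
}
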