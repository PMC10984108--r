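#' Partition DEGs by transcription-factor binding
#'
#' Splits the up- and down-regulated genes of a DEG table into four disjoint
#' quadrants by whether the gene carries a ChIP peak: `bound_up`,
#' `bound_down`, `unbound_up`, `unbound_down`. In `promoter` mode a gene is
#' bound only when its class is `promoter_bound`; in `promoter_or_body` mode
#' a `body_only_bound` gene also counts. Genes with status `ns` are excluded
#' entirely; DEGs absent from the annotation's gene universe are counted as
#' unbound (not dropped), so quadrant totals always sum to the DEG totals.
#'
#' @param degs A `deg_table` (see [call_degs()]).
#' @param annotation A `peak_annotation` (see [annotate_peaks()]).
#' @param mode `"promoter"` or `"promoter_or_body"`.
#' @return A `regulon_partition`: tibble with `gene_id`, `status`, `bound`,
#'   `quadrant`, one row per DEG, with the mode as an attribute.
#' @export
classify_degs <- function(degs, annotation, mode = c("promoter", "promoter_or_body")) {
  mode <- match.arg(mode)
  de <- degs[degs$status %in% c("up", "down"), c("gene_id", "status")]
  if (nrow(de) == 0) abort("empty DEG set")
  gc <- annotation$gene_class
  bound_classes <- if (mode == "promoter") "promoter_bound" else c("promoter_bound", "body_only_bound")
  bound_genes <- gc$gene_id[gc$class %in% bound_classes]
  out <- as_tibble(de) |>
    mutate(
      bound = .data$gene_id %in% bound_genes,
      quadrant = paste0(if_else(.data$bound, "bound_", "unbound_"), .data$status)
    )
  structure(out, mode = mode, class = c("regulon_partition", class(out)))
}

quadrant_sizes <- function(partition) {
  q <- c("bound_up", "bound_down", "unbound_up", "unbound_down")
  sizes <- table(factor(partition$quadrant, levels = q))
  setNames(as.integer(sizes), q)
}

#' Binding-fraction statistics of a regulon partition
#'
#' The headline direct-regulation accounting: what fraction of up-, down-
#' and all DEGs carry a binding peak under the partition's mode.
#'
#' @param partition A `regulon_partition` from [classify_degs()].
#' @return One-row tibble echoing the quadrant counts plus `pct_bound_up`,
#'   `pct_bound_down`, `pct_bound_all` at full precision.
#' @export
regulon_stats <- function(partition) {
  q <- quadrant_sizes(partition)
  n_up <- q[["bound_up"]] + q[["unbound_up"]]
  n_down <- q[["bound_down"]] + q[["unbound_down"]]
  if (n_up + n_down == 0) abort("empty DEG set")
  tibble(
    mode = attr(partition, "mode"),
    n_up = n_up,
    n_down = n_down,
    n_bound_up = q[["bound_up"]],
    n_bound_down = q[["bound_down"]],
    pct_bound_up = pct(q[["bound_up"]], n_up),
    pct_bound_down = pct(q[["bound_down"]], n_down),
    pct_bound_all = pct(q[["bound_up"]] + q[["bound_down"]], n_up + n_down)
  )
}

#' @method glance regulon_partition
#' @export
glance.regulon_partition <- function(x, ...) regulon_stats(x)
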