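#' Run the full integration pipeline on a dataset bundle
#'
#' Executes the stages in cascade order — differential expression, peak
#' annotation, regulon partition (both promoter and promoter-or-body modes),
#' differential accessibility, gene-level ChIP x accessibility overlap,
#' motif scan, core-TF selection, TF-target contribution, uncovered-DEG
#' accounting — and returns a consolidated report with every statistic at
#' full precision plus a 2-decimal presentation value.
#'
#' @param bundle A `dataset_bundle` from [simulate_dataset()],
#'   [fixture_paper_marginals()] or [read_bundle()].
#' @param th [thresholds()] used for both expression and accessibility.
#' @param promoter_up,promoter_down Promoter window extents in bp.
#' @param score_fraction Motif-scan threshold fraction (see [scan_motifs()]).
#' @param marginal_cutoff Per-TF significant-contribution cutoff in percent.
#' @param use_derived When `TRUE` (default) and the bundle carries
#'   precomputed `degs` / `da` tables, the accounting runs on those; when
#'   `FALSE` the statistical callers are re-run on the raw count matrices.
#' @return A list of class `cascade_report` with elements `degs`,
#'   `annotation`, `partition` (promoter-or-body mode), `stages` (named list
#'   of per-stage summaries) and `statistics` (flat named list of the
#'   headline percentages at full precision).
#' @export
run_pipeline <- function(bundle, th = thresholds(),
                         promoter_up = 2000, promoter_down = 500,
                         score_fraction = 0.8, marginal_cutoff = 1,
                         use_derived = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  degs <- stage("diffexpr", {
    if (use_derived && !is.null(bundle$degs)) bundle$degs
    else call_degs(bundle$rna$counts, bundle$rna$design, bundle$rna$contrast, th)
  })
  annotation <- stage("peak_annotation",
    annotate_peaks(bundle$peaks, bundle$genes, promoter_up, promoter_down))
  summary_peaks <- stage("peak_annotation", peak_summary(annotation))
  part_prom <- stage("regulon", classify_degs(degs, annotation, "promoter"))
  part_pb <- stage("regulon", classify_degs(degs, annotation, "promoter_or_body"))
  stats_prom <- regulon_stats(part_prom)
  stats_pb <- regulon_stats(part_pb)

  da <- stage("accessibility", {
    if (use_derived && !is.null(bundle$da)) bundle$da
    else call_da_regions(bundle$atac$counts, bundle$atac$design, bundle$atac$contrast, th)
  })
  bound_genes <- bundle$genes[bundle$genes$gene_id %in% annotation$gene_class$gene_id, ]
  acc_summary <- stage("accessibility", chip_da_overlap(
    gene_units(bound_genes, promoter_up, promoter_down), da, bundle$atac$regions))
  unlinked_pct <- stage("accessibility", da_expression_link(
    da, bundle$atac$regions, bundle$genes, degs, promoter_up, promoter_down))

  hits <- stage("motif_scan", scan_motifs(bundle$pwms, bundle$sequences, score_fraction))
  core <- stage("core_tfs", select_core_tfs(unique(hits$tf_name), degs, part_pb, bundle$tf_map))
  contribution <- stage("contribution", tf_contribution(core, bundle$network, part_pb, marginal_cutoff))
  uncovered_unbound <- stage("uncovered", uncovered_stats(contribution, part_pb))

  statistics <- list(
    pct_peaks_gene_associated = summary_peaks$pct_gene_associated,
    pct_peaks_intergenic = summary_peaks$pct_intergenic,
    pct_bound_up_promoter = stats_prom$pct_bound_up,
    pct_bound_down_promoter = stats_prom$pct_bound_down,
    pct_bound_all_promoter = stats_prom$pct_bound_all,
    pct_bound_up_promoter_or_body = stats_pb$pct_bound_up,
    pct_bound_down_promoter_or_body = stats_pb$pct_bound_down,
    pct_bound_all_promoter_or_body = stats_pb$pct_bound_all,
    pct_bound_genes_accessibility_increased = acc_summary$pct_increased,
    pct_bound_genes_accessibility_decreased = acc_summary$pct_decreased,
    pct_bound_genes_accessibility_altered = acc_summary$pct_altered,
    pct_altered_regions_unlinked = unlinked_pct,
    pct_degs_covered = contribution$overall$pct_covered,
    pct_covered_bound_up = contribution$quadrants$pct_covered[
      contribution$quadrants$quadrant == "bound_up"],
    pct_covered_bound_down = contribution$quadrants$pct_covered[
      contribution$quadrants$quadrant == "bound_down"],
    pct_covered_unbound_up = contribution$quadrants$pct_covered[
      contribution$quadrants$quadrant == "unbound_up"],
    pct_covered_unbound_down = contribution$quadrants$pct_covered[
      contribution$quadrants$quadrant == "unbound_down"],
    pct_uncovered_unbound = uncovered_unbound
  )

  structure(
    list(
      degs = degs,
      annotation = annotation,
      partition = part_pb,
      stages = list(
        peaks = summary_peaks,
        regulon_promoter = stats_prom,
        regulon_promoter_or_body = stats_pb,
        accessibility = acc_summary,
        core_tfs = core,
        contribution = contribution
      ),
      statistics = statistics,
      n_input = c(
        genes = nrow(bundle$genes), peaks = nrow(bundle$peaks),
        da_regions = nrow(bundle$atac$regions), degs = sum(degs$status != "ns"),
        network_edges = nrow(bundle$network)
      ),
      generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  s <- x$statistics
  for (k in names(s)) cat(sprintf("  %-42s %8.2f\n", k, round_half_up(s[[k]])))
  invisible(x)
}

#' Serialise a cascade report
#'
#' Writes the report's statistics and stage summaries as JSON (full
#' precision plus 2-decimal presentation values, half-up like printed
#' percentages), and optionally a Markdown summary table.
#'
#' @param report A `cascade_report` from [run_pipeline()].
#' @param json_path Output JSON path.
#' @param md_path Optional Markdown summary path.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  s <- report$statistics
  payload <- list(
    schema = "cascade_report/1",
    generated = report$generated,
    n_input = as.list(report$n_input),
    statistics = lapply(s, function(v) list(value = v, display = round_half_up(v))),
    quadrant_coverage = report$stages$contribution$quadrants,
    per_tf = report$stages$contribution$per_tf,
    core_tfs = report$stages$core_tfs
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(md_path)) {
    lines <- c(
      "# Cascade accounting report", "",
      sprintf("Generated: %s", report$generated), "",
      "| statistic | value (%) |", "|---|---|",
      sprintf("| %s | %.2f |", names(s), vapply(s, round_half_up, 0))
    )
    readr::write_lines(lines, md_path)
  }
  invisible(json_path)
}
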