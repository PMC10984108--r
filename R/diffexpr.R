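#' Significance thresholds for differential calls
#'
#' The defaults are the thresholds used throughout: raw p-value below 0.05
#' and absolute log2 fold change above 1. With `strict = TRUE` (default) the
#' comparisons are strict (`p < p_threshold`, `|lfc| > lfc_threshold`); with
#' `strict = FALSE` the fold-change comparison becomes `>=`, the alternative
#' reading sometimes printed in figure legends.
#'
#' @param p_threshold Significance level in (0, 1).
#' @param lfc_threshold Non-negative |log2 fold change| cut.
#' @param strict Logical; strict (`>`/`<`) vs inclusive (`>=`) fold-change
#'   comparison. The p-value comparison is always `<`.
#' @return A list of class `threshold_config`.
#' @examples
#' thresholds()
#' thresholds(lfc_threshold = 1, strict = FALSE)
#' @export
thresholds <- function(p_threshold = 0.05, lfc_threshold = 1, strict = TRUE) {
  stopifnot(p_threshold > 0, p_threshold < 1, lfc_threshold >= 0)
  structure(
    list(p_threshold = p_threshold, lfc_threshold = lfc_threshold, strict = strict),
    class = "threshold_config"
  )
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors in the median-of-ratios style: reference
#' genes are those with positive counts in every sample; each sample's factor
#' is the median over reference genes of the ratio between the observed count
#' and the gene's geometric mean across samples. Factors are scale-equivariant
#' (doubling a sample's counts doubles its factor).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named numeric vector of positive factors, one per sample.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(100, 200))
#' colnames(m) <- c("s1", "s2")
#' size_factors(m)
#' @export
size_factors <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    abort(paste(
      "no gene has positive counts in all samples;",
      "median-of-ratios needs at least one all-positive reference gene",
      "(pseudo-reference fallback is disabled)"
    ))
  }
  x <- counts[ref, , drop = FALSE]
  geomean <- exp(rowMeans(log(x)))
  factors <- apply(x / geomean, 2, median)
  setNames(factors, colnames(counts))
}

# Vectorised two-sided Welch t-test across matrix rows.
# Degenerate rows (zero variance in both groups) get p = 1 when the group
# means are equal and p = 0 when they differ (the limit of the statistic).
welch_rows <- function(x_a, x_b) {
  na <- ncol(x_a); nb <- ncol(x_b)
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  va <- apply(x_a, 1, stats::var); vb <- apply(x_b, 1, stats::var)
  se2 <- va / na + vb / nb
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  # means compared with a relative tolerance: normalisation can perturb
  # genuinely identical groups at the last float digit
  same <- abs(ma - mb) <= 1e-8 * pmax(1, abs(ma), abs(mb))
  p[degen] <- ifelse(same[degen], 1, 0)
  p
}

status_from <- function(log2fc, p_value, th) {
  lfc_pass <- if (th$strict) abs(log2fc) > th$lfc_threshold else abs(log2fc) >= th$lfc_threshold
  sig <- p_value < th$p_threshold & lfc_pass
  dplyr::case_when(sig & log2fc > 0 ~ "up", sig & log2fc < 0 ~ "down", TRUE ~ "ns")
}

#' Call differentially expressed genes
#'
#' A documented stand-in for heavier DE machinery: counts are normalised by
#' [size_factors()], the log2 fold change is computed on normalised group
#' means with a pseudocount of 1, and the p-value comes from a two-sided
#' Welch t-test on `log2(normalised count + 1)` across replicates. Status is
#' `up`/`down`/`ns` per the [thresholds()] semantics; raw p-values drive the
#' status, a Benjamini-Hochberg column is emitted for information only. A
#' gene with zero counts everywhere is `ns` with p = 1, never NaN.
#'
#' @param counts Non-negative integer matrix, genes x samples, ids as rownames.
#' @param design Tibble with `sample_id`, `group` covering all columns.
#' @param contrast Length-2 character vector `c(numerator_group,
#'   denominator_group)`, e.g. `c("KO", "WT")`: log2fc is mutant over control.
#' @param th A [thresholds()] object.
#' @return A `deg_table`: tibble with `gene_id`, `log2fc`, `p_value`,
#'   `padj_bh`, `status`, carrying the contrast and thresholds as attributes.
#' @export
call_degs <- function(counts, design, contrast, th = thresholds()) {
  validate_count_matrix(counts, design)
  stopifnot(length(contrast) == 2)
  groups <- setNames(design$group, design$sample_id)[colnames(counts)]
  for (g in contrast) {
    if (sum(groups == g) < 2) {
      abort(sprintf("group '%s' needs at least 2 samples, has %d", g, sum(groups == g)))
    }
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, groups == contrast[1], drop = FALSE]
  b <- norm[, groups == contrast[2], drop = FALSE]
  log2fc <- unname(log2((rowMeans(a) + 1) / (rowMeans(b) + 1)))
  p <- unname(welch_rows(log2(a + 1), log2(b + 1)))
  all_zero <- unname(rowSums(counts) == 0)
  p[all_zero] <- 1
  out <- tibble(
    gene_id = rownames(counts),
    log2fc = log2fc,
    p_value = p,
    padj_bh = stats::p.adjust(p, method = "BH"),
    status = status_from(log2fc, p, th)
  )
  new_deg_table(out, contrast = contrast, thresholds = th)
}

new_deg_table <- function(x, contrast = NULL, thresholds = NULL) {
  structure(
    as_tibble(x),
    contrast = contrast,
    thresholds = thresholds,
    class = c("deg_table", class(as_tibble(x)))
  )
}

#' Build a DEG table from precomputed statistics
#'
#' Used by fixtures and by callers that bring their own fold changes and
#' p-values; the status column is (re)derived from the thresholds so the
#' table is always internally consistent.
#'
#' @param gene_id,log2fc,p_value Per-gene vectors.
#' @param th A [thresholds()] object.
#' @return A `deg_table` (see [call_degs()]).
#' @export
deg_table <- function(gene_id, log2fc, p_value, th = thresholds()) {
  stopifnot(!anyDuplicated(gene_id))
  out <- tibble(
    gene_id = as.character(gene_id),
    log2fc = log2fc,
    p_value = p_value,
    padj_bh = stats::p.adjust(p_value, method = "BH"),
    status = status_from(log2fc, p_value, th)
  )
  new_deg_table(out, thresholds = th)
}

#' Shared and exclusive DEGs between two contrasts
#'
#' Partitions the union of the two tables' DEGs (status `up` or `down`) into
#' a-only, b-only and shared sets, the accounting behind cross-genotype Venn
#' comparisons. With `direction_aware = TRUE` a gene is shared only when its
#' status matches in both tables.
#'
#' @param a,b `deg_table`s.
#' @param direction_aware Logical; require matching direction for "shared".
#'   A gene that is a DEG in both tables with opposite directions then counts
#'   as exclusive to each.
#' @return List with character vectors `shared`, `a_only`, `b_only`.
#' @export
deg_overlap <- function(a, b, direction_aware = FALSE) {
  da <- a[a$status != "ns", c("gene_id", "status")]
  db <- b[b$status != "ns", c("gene_id", "status")]
  if (direction_aware) {
    shared <- dplyr::intersect(as_tibble(da), as_tibble(db))$gene_id
  } else {
    shared <- intersect(da$gene_id, db$gene_id)
  }
  list(
    shared = shared,
    a_only = setdiff(da$gene_id, shared),
    b_only = setdiff(db$gene_id, shared)
  )
}
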