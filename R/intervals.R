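#' Genomic interval utilities
#'
#' All coordinates in this package are 0-based half-open `[start, end)`;
#' readers convert from the external dialects (GTF is 1-based inclusive, BED
#' is already 0-based half-open). Chromosome names are opaque strings — no
#' "chr" prefix normalisation is attempted, so mixed namespaces simply never
#' overlap.
#'
#' @param chrom,start,end,strand Vectors describing intervals. `start < end`
#'   must hold element-wise and `start >= 0`.
#' @return `genomic_interval()` returns a tibble with columns `chrom`,
#'   `start`, `end`, `strand`, validated.
#' @examples
#' genomic_interval("chr1", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    abort(sprintf("%s with empty chromosome name", what))
  }
  if (any(x$start < 0)) {
    abort(sprintf("%s with negative start", what))
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s with start >= end (first offender: row %d, [%g, %g))",
      what, bad[1], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

#' Overlap width of two interval sets, element-wise
#'
#' Strand-blind overlap in base pairs:
#' `max(0, min(end) - max(start))` when chromosomes match, else 0.
#' Vectorised with the usual recycling rules.
#'
#' @param a,b Tibbles with `chrom`, `start`, `end` columns (e.g. from
#'   [genomic_interval()]), recycled against each other.
#' @return Integer-valued numeric vector of overlapped base pairs (never
#'   negative).
#' @examples
#' interval_overlap(genomic_interval("chr1", 0, 10), genomic_interval("chr1", 5, 15))
#' @export
interval_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  same <- a$chrom[ai] == b$chrom[bi]
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ifelse(same, ov, 0)
}

#' Strand-aware promoter window around the TSS
#'
#' For a `+` strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a `-` strand gene it is `[tss - downstream, tss + upstream)`. Windows
#' are clamped at coordinate 0. The default (2000 bp upstream, 500 bp
#' downstream) is a common ChIP-seq promoter convention; nothing downstream
#' hard-codes it.
#'
#' @param genes A gene tibble (see [read_gene_annotation()]) with `chrom`,
#'   `strand` and `tss` columns.
#' @param upstream,downstream Non-negative window extents in bp;
#'   `upstream + downstream` must be positive.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand` for the
#'   promoter windows.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 5000,
#'                     end = 9000, strand = "+", tss = 5000)
#' promoter_of(g)
#' @export
promoter_of <- function(genes, upstream = 2000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0, start),
    end = end,
    strand = genes$strand
  )
}

# Interval join via the IRanges/GenomicRanges machinery. `x` and `y` are
# tibbles with (id, chrom, start, end); returns one row per overlapping pair
# (>= 1 bp, strand-blind) with the two id columns and the overlap width.
overlap_join <- function(x, y, x_id = "x_id", y_id = "y_id") {
  if (nrow(x) == 0 || nrow(y) == 0) {
    out <- tibble(a = character(), b = character(), overlap = numeric())
    names(out) <- c(x_id, y_id, "overlap")
    return(out)
  }
  gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
  gy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1, y$end))
  # disjoint chromosome namespaces are legitimate (they simply never
  # overlap); silence the seqlevel warning findOverlaps emits for them
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gx, gy, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- tibble(
    a = x$id[qi],
    b = y$id[si],
    overlap = pmax(0, pmin(x$end[qi], y$end[si]) - pmax(x$start[qi], y$start[si]))
  )
  names(out) <- c(x_id, y_id, "overlap")
  out
}
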