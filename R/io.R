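#' Read a gene annotation from GTF
#'
#' Collapses all feature lines sharing a `gene_id` attribute into one gene
#' spanning their union, converting GTF 1-based inclusive coordinates to the
#' package's 0-based half-open convention. The TSS is the first transcribed
#' base: `start` on the `+` strand, `end - 1` on the `-` strand.
#'
#' @param path Path to a GTF file. Lines starting with `#` are skipped.
#' @return A gene tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, one row per gene, ordered by (chrom, start).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines("chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"g1\";", gtf)
#' read_gene_annotation(gtf)
#' @export
read_gene_annotation <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort("GTF file contains no feature lines")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                  lineno[which(nf < 9)[1]], nf[which(nf < 9)[1]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad) > 0) {
    abort(sprintf("malformed GTF line %d: bad coordinates '%s'..'%s'",
                  lineno[bad[1]], m[bad[1], 4], m[bad[1], 5]))
  }
  gid <- stringr::str_match(m[, 9], "gene_id[ =]+\"?([^\";]+)\"?")[, 2]
  bad <- which(is.na(gid))
  if (length(bad) > 0) {
    abort(sprintf("malformed GTF line %d: no gene_id attribute", lineno[bad[1]]))
  }
  feat <- tibble(
    gene_id = gid, chrom = m[, 1],
    start = start1 - 1, end = end1, strand = m[, 7]
  )
  chk <- feat |> distinct(.data$gene_id, .data$chrom) |> count(.data$gene_id)
  if (any(chk$n > 1)) {
    abort(sprintf("gene_id '%s' appears on more than one chromosome",
                  chk$gene_id[chk$n > 1][1]))
  }
  genes <- feat |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      .groups = "drop"
    ) |>
    mutate(tss = if_else(.data$strand == "-", .data$end - 1, .data$start)) |>
    arrange(.data$chrom, .data$start)
  validate_intervals(genes, "gene")
  genes
}

#' Write a gene tibble as a minimal GTF
#'
#' One `gene` feature line per gene, converting back to 1-based inclusive
#' coordinates.
#'
#' @param genes Gene tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- sprintf(
    "%s\treguloncascade\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, as.integer(genes$start + 1), as.integer(genes$end),
    genes$strand, genes$gene_id
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a region set from BED or narrowPeak
#'
#' BED coordinates are 0-based half-open and taken as-is. Region ids come
#' from column 4 when present (and not `"."`); otherwise an automatic
#' `"chrom:start-end"` id is used. Duplicate ids are made unique
#' deterministically by suffixing occurrences after the first with `.1`,
#' `.2`, ... in file order. For 10-column narrowPeak rows the score is the
#' signalValue column (7); for 5+-column BED it is column 5.
#'
#' @param path Path to a BED3/BED6 or ENCODE narrowPeak file.
#' @return A region tibble with columns `region_id`, `chrom`, `start`,
#'   `end`, `score` (NA when absent), in file order.
#' @export
read_regions <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 columns", lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: start/end '%s'..'%s' (need 0 <= start < end)",
                  lineno[bad[1]], fields[[bad[1]]][2], fields[[bad[1]]][3]))
  }
  name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", "")
  auto <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  id <- ifelse(is.na(name) | name == ".", auto, name)
  score <- rep(NA_real_, length(id))
  np <- nf >= 10
  score[np] <- suppressWarnings(as.numeric(vapply(fields[np], `[`, "", 7)))
  b5 <- !np & nf >= 5
  s5 <- suppressWarnings(as.numeric(vapply(fields[b5], `[`, "", 5)))
  score[b5] <- ifelse(is.nan(s5), NA_real_, s5)
  # deterministic de-duplication: 2nd, 3rd ... occurrences get .1, .2, ...
  occ <- stats::ave(seq_along(id), id, FUN = seq_along)
  id <- ifelse(occ > 1, paste0(id, ".", occ - 1), id)
  out <- tibble(region_id = id, chrom = chrom, start = start, end = end, score = score)
  validate_intervals(out, "region")
  out
}

#' Write a region tibble as BED
#'
#' Emits 5 tab-separated columns (chrom, start, end, id, score with `.` for
#' missing), newline-terminated. Reading the file back with [read_regions()]
#' reproduces ids and coordinates exactly.
#'
#' @param regions Region tibble (see [read_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  score <- regions$score %||% rep(NA_real_, nrow(regions))
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s",
    regions$chrom, as.integer(regions$start), as.integer(regions$end),
    regions$region_id,
    ifelse(is.na(score), ".", format(score, trim = TRUE, scientific = FALSE))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write a count matrix with its design
#'
#' The counts file is a TSV whose first column holds feature ids (genes or
#' accessibility regions) and whose header names the samples; the design file
#' is a two-column TSV `sample_id`, `group`.
#'
#' @param counts_path,design_path TSV paths.
#' @return `read_count_matrix()` returns a list with `counts` (integer matrix,
#'   feature ids as rownames), and `design` (tibble `sample_id`, `group`).
#' @export
read_count_matrix <- function(counts_path, design_path) {
  tab <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1]])
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  names(design)[1:2] <- c("sample_id", "group")
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  validate_count_matrix(mat, design)
  list(counts = mat, design = as_tibble(design))
}

#' @rdname read_count_matrix
#' @param counts Numeric matrix of non-negative counts, feature ids as rownames.
#' @param design Tibble with `sample_id`, `group`.
#' @param feature_col Name for the id column in the written TSV.
#' @export
write_count_matrix <- function(counts, design, counts_path, design_path,
                               feature_col = "feature_id") {
  tab <- as_tibble(counts)
  tab <- dplyr::bind_cols(tibble(!!feature_col := rownames(counts)), tab)
  readr::write_tsv(tab, counts_path, progress = FALSE)
  readr::write_tsv(design, design_path, progress = FALSE)
  invisible(counts_path)
}

validate_count_matrix <- function(counts, design) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers")
  }
  if (!setequal(colnames(counts), design$sample_id)) {
    abort("count matrix columns and design sample_ids do not match")
  }
  invisible(counts)
}

#' Read / write region sequences as FASTA
#'
#' Thin wrappers over Biostrings; sequences are returned as a plain named
#' character vector keyed by region id.
#'
#' @param path FASTA path.
#' @return Named character vector of DNA sequences.
#' @export
read_region_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_region_sequences
#' @param sequences Named character vector of DNA sequences.
#' @export
write_region_sequences <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write a TF-target edge list
#'
#' Two-column TSV (`tf`, `target`), one row per regulatory edge, in the style
#' of database exports such as GTRD. Duplicate edges are dropped on read.
#'
#' @param path TSV path.
#' @return Tibble with columns `tf`, `target`.
#' @export
read_network <- function(path) {
  net <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(net)[1:2] <- c("tf", "target")
  net |>
    mutate(tf = as.character(.data$tf), target = as.character(.data$target)) |>
    distinct(.data$tf, .data$target)
}

#' @rdname read_network
#' @param network Tibble with columns `tf`, `target`.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(network, path, progress = FALSE)
  invisible(path)
}
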