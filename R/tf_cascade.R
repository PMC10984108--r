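DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrices
#'
#' A PWM is a per-position base-probability model of a TF binding motif:
#' an L x 4 matrix (columns A, C, G, T) whose rows each sum to 1, plus a
#' background base distribution. Motifs must be at least 4 bp long.
#'
#' @param tf_name Transcription factor name.
#' @param matrix L x 4 numeric matrix of base probabilities, columns in
#'   A, C, G, T order, rows summing to 1 (tolerance 1e-9).
#' @param background Length-4 base probabilities summing to 1; uniform by
#'   default.
#' @return A validated list of class `pwm`.
#' @examples
#' pwm_from_consensus("TFX", "ACGTACGT")
#' @export
pwm <- function(tf_name, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  colnames(matrix) <- DNA_BASES
  x <- structure(
    list(tf_name = tf_name, matrix = matrix, background = setNames(background, DNA_BASES)),
    class = "pwm"
  )
  validate_pwm(x)
}

validate_pwm <- function(x) {
  m <- x$matrix
  if (ncol(m) != 4) abort(sprintf("PWM '%s': matrix must have 4 columns", x$tf_name))
  if (nrow(m) < 4) abort(sprintf("PWM '%s': motif length must be >= 4", x$tf_name))
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    abort(sprintf("PWM '%s': row %d does not sum to 1", x$tf_name,
                  which(abs(rowSums(m) - 1) > 1e-9)[1]))
  }
  if (abs(sum(x$background) - 1) > 1e-9) {
    abort(sprintf("PWM '%s': background does not sum to 1", x$tf_name))
  }
  x
}

#' @rdname pwm
#' @param consensus A DNA string over A/C/G/T; the matrix puts
#'   `1 - 3 * off_rate` on the consensus base and `off_rate` elsewhere.
#' @param off_rate Probability of each non-consensus base per position.
#' @export
pwm_from_consensus <- function(tf_name, consensus, off_rate = 0.001,
                               background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% DNA_BASES))
  m <- matrix(off_rate, nrow = length(bases), ncol = 4)
  m[cbind(seq_along(bases), match(bases, DNA_BASES))] <- 1 - 3 * off_rate
  pwm(tf_name, m, background)
}

#' @rdname pwm
#' @param x A `pwm`.
#' @return `pwm_consensus()` returns the modal base string.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 1, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, %d bp, consensus %s\n", x$tf_name, nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# log-odds matrix with a 1e-3 pseudo-probability floor per cell
pwm_log_odds <- function(p) {
  lo <- log(pmax(p$matrix, 1e-3))
  bg <- log(pmax(p$background, 1e-3))
  sweep(lo, 2, bg, "-")
}

#' Read and write motifs in minimal MEME text format
#'
#' Supports the subset of MEME format needed to exchange PWM sets: the
#' header, one optional `Background letter frequencies` line, and `MOTIF`
#' blocks with `letter-probability matrix` sections.
#'
#' @param path Path to a MEME-format motif file.
#' @return `read_meme()` returns a named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readr::read_lines(path))
  background <- rep(0.25, 4)
  bg_at <- which(startsWith(lines, "Background letter frequencies"))
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(lines[bg_at + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    background <- vals[!is.na(vals)][1:4]
  }
  starts <- which(startsWith(lines, "MOTIF"))
  pwms <- lapply(seq_along(starts), function(i) {
    name <- strsplit(lines[starts[i]], "\\s+")[[1]][2]
    block_end <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:block_end]
    hdr <- which(startsWith(block, "letter-probability matrix"))[1]
    if (is.na(hdr)) abort(sprintf("motif '%s': no letter-probability matrix", name))
    rows <- block[-seq_len(hdr)]
    rows <- rows[grepl("^[0-9.eE+ \t-]+$", rows) & nzchar(rows)]
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    pwm(name, m, background)
  })
  setNames(pwms, vapply(pwms, `[[`, "", "tf_name"))
}

#' @rdname read_meme
#' @param pwms Named list of [pwm()] objects (a shared background is taken
#'   from the first).
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    sprintf("A %g C %g G %g T %g", bg[1], bg[2], bg[3], bg[4]), ""
  )
  for (p in pwms) {
    out <- c(
      out,
      sprintf("MOTIF %s", p$tf_name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", nrow(p$matrix)),
      apply(p$matrix, 1, function(r) sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])),
      ""
    )
  }
  readr::write_lines(out, path)
  invisible(path)
}

scan_one_strand <- function(lo, codes) {
  L <- nrow(lo)
  n_win <- length(codes) - L + 1
  if (n_win < 1) return(numeric(0))
  score <- numeric(n_win)
  for (j in seq_len(L)) {
    score <- score + unname(lo[j, codes[j:(j + n_win - 1)]]) # NA marks N windows
  }
  score
}

#' Scan sequences with PWMs on both strands
#'
#' A single-threshold log-odds scanner: each window of each sequence is
#' scored as the summed log-odds of its bases (motif probability over
#' background, with a 1e-3 pseudo-probability floor per cell) and reported
#' as a hit when the score reaches `score_fraction` of the PWM's maximum
#' achievable score. Both strands are scanned; minus-strand hits score the
#' reverse complement and are reported at their forward-strand offset.
#' Windows containing `N` are skipped.
#'
#' @param pwms List of [pwm()] objects.
#' @param sequences Named character vector of DNA sequences (names are
#'   region ids).
#' @param score_fraction Hit threshold as a fraction of the maximum
#'   achievable log-odds score (default 0.8).
#' @return Tibble of motif hits: `tf_name`, `region_id`, `offset` (0-based
#'   on the forward strand), `strand`, `score`.
#' @export
scan_motifs <- function(pwms, sequences, score_fraction = 0.8) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  pwms <- lapply(pwms, validate_pwm)
  coded <- lapply(sequences, function(s) {
    match(strsplit(toupper(s), "")[[1]], DNA_BASES) # N and anything else -> NA
  })
  hits <- purrr::map(pwms, function(p) {
    lo <- pwm_log_odds(p)
    # minus strand == scanning with the reverse-complemented PWM
    lo_rc <- lo[rev(seq_len(nrow(lo))), rev(seq_len(4)), drop = FALSE]
    max_score <- sum(apply(lo, 1, max))
    thr <- score_fraction * max_score
    purrr::map(names(coded), function(rid) {
      codes <- coded[[rid]]
      fwd <- scan_one_strand(lo, codes)
      rev_ <- scan_one_strand(lo_rc, codes)
      keep_f <- which(!is.na(fwd) & fwd >= thr)
      keep_r <- which(!is.na(rev_) & rev_ >= thr)
      tibble(
        tf_name = p$tf_name,
        region_id = rid,
        offset = c(keep_f, keep_r) - 1,
        strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
        score = c(fwd[keep_f], rev_[keep_r])
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  hits
}

#' Select core transcription factors
#'
#' The cascade filter: a TF is core when (1) its motif was detected in
#' altered-accessibility regions, (2) its own gene is differentially
#' expressed, and (3) its own gene is bound in the partition's mode. The
#' TF's direction is its gene's expression status. TF names that cannot be
#' mapped to a gene id are skipped with a message and counted in the
#' `n_unmapped` attribute.
#'
#' @param motif_tfs Character vector of TF names with detected motifs
#'   (e.g. `unique(scan_motifs(...)$tf_name)`).
#' @param degs A `deg_table`.
#' @param partition A `regulon_partition` from [classify_degs()].
#' @param tf_map Tibble mapping `tf_name` to `gene_id`.
#' @return Tibble of core TFs: `tf_name`, `gene_id`, `direction`, with
#'   attribute `n_unmapped`.
#' @export
select_core_tfs <- function(motif_tfs, degs, partition, tf_map) {
  motif_tfs <- unique(motif_tfs)
  mapped <- tf_map[tf_map$tf_name %in% motif_tfs, c("tf_name", "gene_id")]
  n_unmapped <- length(setdiff(motif_tfs, tf_map$tf_name))
  if (n_unmapped > 0) {
    inform(sprintf("select_core_tfs: %d TF name(s) not in the name map, skipped", n_unmapped))
  }
  bound <- partition[partition$bound, c("gene_id", "status")]
  core <- inner_join(mapped, as_tibble(bound), by = "gene_id") |>
    rename(direction = "status") |>
    arrange(.data$tf_name)
  attr(core, "n_unmapped") <- n_unmapped
  core
}

#' TF-target contribution accounting
#'
#' Measures how much of the differential transcriptome a core TF set can
#' account for through a TF-target network: a DEG is covered when it is the
#' target of at least one core TF. Coverage is reported per regulon quadrant
#' and overall, plus each TF's marginal coverage (the fraction of all DEGs
#' that are its own targets) and whether it clears the
#' `significant contribution` cutoff.
#'
#' @param core_tfs Core TF tibble from [select_core_tfs()].
#' @param network Edge tibble (`tf`, `target`) as from [read_network()].
#' @param partition A `regulon_partition`.
#' @param marginal_cutoff A TF "contributes significantly" when its marginal
#'   coverage is at least this percentage of all DEGs (default 1).
#' @return A `tf_contribution` object: list with `quadrants` (per-quadrant
#'   size, covered count, pct), `overall` (one-row tibble), `per_tf`
#'   (marginal coverage tibble), and `covered` (covered gene ids).
#' @export
tf_contribution <- function(core_tfs, network, partition, marginal_cutoff = 1) {
  stopifnot(nrow(partition) > 0)
  edges <- network[network$tf %in% core_tfs$tf_name, ]
  covered <- unique(edges$target[edges$target %in% partition$gene_id])
  q_levels <- c("bound_up", "bound_down", "unbound_up", "unbound_down")
  quadrants <- as_tibble(partition) |>
    mutate(quadrant = factor(.data$quadrant, levels = q_levels)) |>
    group_by(.data$quadrant, .drop = FALSE) |>
    summarise(
      size = n(),
      covered = sum(.data$gene_id %in% !!covered),
      .groups = "drop"
    ) |>
    mutate(quadrant = as.character(.data$quadrant), pct_covered = pct(.data$covered, .data$size))
  n_deg <- nrow(partition)
  stopifnot(sum(quadrants$covered) == length(covered)) # conservation
  overall <- tibble(
    n_deg = n_deg,
    n_covered = length(covered),
    pct_covered = pct(length(covered), n_deg),
    n_core_tfs = nrow(core_tfs)
  )
  per_tf <- core_tfs |>
    select("tf_name", "direction") |>
    left_join(
      edges |>
        filter(.data$target %in% partition$gene_id) |>
        distinct(.data$tf, .data$target) |>
        count(.data$tf, name = "n_deg_targets"),
      by = c(tf_name = "tf")
    ) |>
    mutate(
      n_deg_targets = dplyr::coalesce(.data$n_deg_targets, 0L),
      pct_of_degs = pct(.data$n_deg_targets, n_deg),
      significant = .data$pct_of_degs >= marginal_cutoff
    ) |>
    arrange(dplyr::desc(.data$n_deg_targets))
  structure(
    list(quadrants = quadrants, overall = overall, per_tf = per_tf,
         covered = covered, marginal_cutoff = marginal_cutoff),
    class = "tf_contribution"
  )
}

#' @export
print.tf_contribution <- function(x, ...) {
  cat(sprintf(
    "<tf_contribution> %d core TFs cover %d / %d DEGs (%.2f%%)\n",
    x$overall$n_core_tfs, x$overall$n_covered, x$overall$n_deg, x$overall$pct_covered
  ))
  invisible(x)
}

#' @method tidy tf_contribution
#' @export
tidy.tf_contribution <- function(x, ...) x$per_tf

#' @method glance tf_contribution
#' @export
glance.tf_contribution <- function(x, ...) {
  wide <- x$quadrants |>
    select("quadrant", "pct_covered") |>
    tidyr::pivot_wider(names_from = "quadrant", values_from = "pct_covered",
                       names_prefix = "pct_covered_")
  dplyr::bind_cols(x$overall, wide)
}

#' Binding status of the uncovered DEGs
#'
#' Among DEGs not covered by any core TF, the percentage that are also not
#' bound — the closing statistic of the cascade argument: genes the TF layer
#' misses are mostly not direct targets either.
#'
#' @param report A `tf_contribution` from [tf_contribution()].
#' @param partition The `regulon_partition` the report was computed on.
#' @return Percentage (0-100) of uncovered DEGs that are unbound.
#' @export
uncovered_stats <- function(report, partition) {
  uncovered <- partition[!partition$gene_id %in% report$covered, ]
  if (nrow(uncovered) == 0) abort("no uncovered DEGs")
  pct(sum(!uncovered$bound), nrow(uncovered))
}
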