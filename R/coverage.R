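#' Coverage track constructor
#'
#' A coverage track is a tibble with one row per position of a locus window
#' (1-based, strictly increasing, zero-depth positions included) carrying
#' integer read depth, plus attributes identifying the locus and sample.
#'
#' @param chrom Chromosome name (recycled).
#' @param pos Genomic positions, strictly increasing.
#' @param depth Non-negative integer depths, same length as `pos`.
#' @param locus Locus label.
#' @param sample_id Sample identifier.
#' @param mean_depth_genomewide Optional genome-wide mean depth (x units).
#' @return A `vdj_coverage` tibble with columns `chrom`, `pos`, `depth`.
#' @export
coverage_track <- function(chrom, pos, depth, locus = NA_character_,
                           sample_id = NA_character_,
                           mean_depth_genomewide = NA_real_) {
  if (length(pos) != length(depth)) {
    stop("pos and depth must have equal length", call. = FALSE)
  }
  if (length(pos) > 1 && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(depth < 0)) stop("depth must be non-negative", call. = FALSE)
  out <- tibble::tibble(chrom = rep_len(chrom, length(pos)),
                        pos = as.numeric(pos), depth = as.numeric(depth))
  attr(out, "locus") <- locus
  attr(out, "sample_id") <- sample_id
  attr(out, "mean_depth_genomewide") <- mean_depth_genomewide
  class(out) <- c("vdj_coverage", class(out))
  out
}

#' Extract per-base coverage over a locus window from a BAM/CRAM file
#'
#' Computes read depth at every position of the locus span (positions with no
#' coverage reported as 0), filtering reads below `min_mapq` and bases below
#' `min_baseq`. Duplicate-marked and secondary/supplementary alignments are
#' excluded by default, mirroring standard depth semantics; defaults
#' `min_mapq = 0`, `min_baseq = 0` mirror plain `samtools depth`.
#'
#' If the locus chromosome is absent from the alignment header, the
#' chr-prefixed/stripped alternative is tried before failing.
#'
#' @param alignment_path Indexed BAM or CRAM file.
#' @param locus A `locus_definition`.
#' @param min_mapq,min_baseq Minimum mapping/base quality (inclusive).
#' @param include_duplicates Include duplicate-marked reads.
#' @param reference Reference FASTA, required for CRAM input.
#' @param sample_id Sample identifier stored on the track.
#' @return A `vdj_coverage` track spanning the full locus window.
#' @export
extract_coverage <- function(alignment_path, locus, min_mapq = 0,
                             min_baseq = 0, include_duplicates = FALSE,
                             reference = NULL, sample_id = NA_character_) {
  stopifnot(inherits(locus, "locus_definition"))
  is_cram <- grepl("\\.cram$", alignment_path, ignore.case = TRUE)
  if (is_cram && is.null(reference)) {
    stop("CRAM input requires a reference FASTA (argument 'reference')",
         call. = FALSE)
  }
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path, call. = FALSE)
  }
  bf <- Rsamtools::BamFile(alignment_path)
  hdr_seqs <- names(Rsamtools::scanBamHeader(bf)$targets)
  chrom <- locus$chrom
  if (!chrom %in% hdr_seqs) {
    alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom)
           else paste0("chr", chrom)
    if (alt %in% hdr_seqs) {
      chrom <- alt
    } else {
      stop("chromosome '", locus$chrom, "' (or '", alt, "') not present in ",
           alignment_path, call. = FALSE)
    }
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(locus$span_start,
                                                          locus$span_end))
  flags <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE,
    isUnmappedQuery = FALSE)
  p <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = FALSE,
    include_deletions = FALSE, include_insertions = FALSE)
  res <- Rsamtools::pileup(bf, scanBamParam = Rsamtools::ScanBamParam(
    flag = flags, which = which), pileupParam = p)

  pos <- seq(locus$span_start, locus$span_end)
  depth <- numeric(length(pos))
  if (nrow(res)) depth[res$pos - locus$span_start + 1] <- res$count
  coverage_track(locus$chrom, pos, depth, locus = locus$locus,
                 sample_id = sample_id)
}

#' Read / write coverage tables
#'
#' Coverage tracks are serialised as 3-column TSV (`chrom`, `pos`, `depth`);
#' gzip-compressed input is accepted transparently and `write_coverage_table`
#' gzips when `path` ends in `.gz`. Positions are 1-based and must be strictly
#' increasing; `write` then `read` is the identity on the table.
#'
#' @param path File path (plain or `.gz`).
#' @param locus,sample_id Metadata attached to the returned track.
#' @return `read_coverage_table` returns a `vdj_coverage` tibble;
#'   `write_coverage_table` returns `path` invisibly.
#' @export
read_coverage_table <- function(path, locus = NA_character_,
                                sample_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    depth = readr::col_double()), progress = FALSE)
  if (!all(c("chrom", "pos", "depth") %in% names(tab))) {
    stop("coverage table must have columns chrom, pos, depth", call. = FALSE)
  }
  if (anyNA(tab$pos) || anyNA(tab$depth)) {
    bad <- which(is.na(tab$pos) | is.na(tab$depth))[1]
    stop("malformed coverage row at line ", bad + 1, " of ", path,
         call. = FALSE)
  }
  if (nrow(tab) > 1 && any(diff(tab$pos) <= 0)) {
    bad <- which(diff(tab$pos) <= 0)[1] + 1
    stop("positions not strictly increasing at line ", bad + 1, " of ", path,
         call. = FALSE)
  }
  coverage_track(tab$chrom, tab$pos, tab$depth, locus = locus,
                 sample_id = sample_id)
}

#' @rdname read_coverage_table
#' @param track A `vdj_coverage` track.
#' @export
write_coverage_table <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "pos", "depth")], path, progress = FALSE)
  invisible(path)
}
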