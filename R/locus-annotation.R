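#' Load the genomic model of a V(D)J locus
#'
#' Builds a validated `locus_definition` for one of the four adaptive-immune
#' receptor loci (`TCRA`, `TCRB`, `TCRG`, `IGH`) on GRCh38: the ordered V/D/J
#' (and, for IGH, constant-gene) segment intervals, the locus window, its
#' orientation, the flanking baseline regions used for depth normalisation and
#' the nearby gene whose somatic copy-number call is used for local-CN
#' adjustment in tumours.
#'
#' All coordinates are 1-based inclusive (the `samtools depth` convention).
#' The packaged segment tables are approximate reconstructions of the GRCh38
#' gene models (locus windows are exact; individual segment placements are
#' representative). For analyses of real data, supply an exact IMGT-derived
#' table via `annotation_path`.
#'
#' Orientation is resolved at load time by mapping genomic coordinates onto an
#' abstract *deletion axis* that always runs V-region-first: for a
#' reverse-oriented locus (IGH, TCRG) axis position increases as the genomic
#' coordinate decreases. All downstream modelling is orientation-free.
#'
#' @param locus_name One of `"TCRA"`, `"TCRB"`, `"TCRG"`, `"IGH"`.
#' @param annotation_path Path to a segment annotation TSV with columns
#'   `name`, `kind` (`V`/`D`/`J`/`CONSTANT`), `chrom`, `start`, `end`,
#'   `switch_order` (CONSTANT rows only), or `"packaged"` (default) for the
#'   table shipped with the package.
#' @return A `locus_definition` object: a list with elements `locus`, `chrom`,
#'   `span_start`, `span_end`, `orientation`, `cn_proxy_gene`, `segments`
#'   (a tibble ordered along the deletion axis, with axis coordinates
#'   `axis_start`/`axis_end`), and `baseline_regions` (a tibble of genomic
#'   intervals outside any possible deletion).
#' @examples
#' tcra <- load_locus_definition("TCRA")
#' tcra$span_start
#' dplyr::count(tcra$segments, kind)
#' @export
load_locus_definition <- function(locus_name, annotation_path = "packaged") {
  idx <- utils::read.delim(
    system.file("extdata", "annotation", "loci.tsv", package = "vdjlens"),
    stringsAsFactors = FALSE)
  if (!locus_name %in% idx$locus) {
    stop("unknown locus '", locus_name, "'; expected one of ",
         paste(idx$locus, collapse = ", "), call. = FALSE)
  }
  row <- idx[idx$locus == locus_name, ]
  path <- if (identical(annotation_path, "packaged")) {
    system.file("extdata", "annotation", row$segment_file, package = "vdjlens")
  } else {
    annotation_path
  }
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  seg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(switch_order = "integer"))
  required <- c("name", "kind", "chrom", "start", "end", "switch_order")
  if (!all(required %in% names(seg))) {
    stop("annotation file ", path, " is missing columns: ",
         paste(setdiff(required, names(seg)), collapse = ", "), call. = FALSE)
  }
  seg <- tibble::as_tibble(seg)

  new_locus_definition(
    locus = row$locus, chrom = row$chrom,
    span_start = row$span_start, span_end = row$span_end,
    orientation = row$orientation, cn_proxy_gene = row$cn_proxy_gene,
    segments = seg)
}

#' Construct and validate a locus definition
#'
#' Lower-level constructor behind [load_locus_definition()], useful for toy
#' loci in simulations and tests. Checks every structural invariant of the
#' locus model and orders segments along the deletion axis.
#'
#' @param locus Locus label.
#' @param chrom Chromosome name.
#' @param span_start,span_end Full locus window (1-based inclusive).
#' @param orientation `"forward"` if the V-to-J deletion axis runs with
#'   increasing genomic coordinate, `"reverse"` otherwise.
#' @param segments Data frame with columns `name`, `kind`, `chrom`, `start`,
#'   `end` and (for CONSTANT rows) `switch_order`.
#' @param cn_proxy_gene Gene whose somatic CN call proxies local copy number.
#' @param baseline_margin Gap (bp) left between the outermost segment and the
#'   start of each flanking baseline region.
#' @return A validated `locus_definition`.
#' @export
new_locus_definition <- function(locus, chrom, span_start, span_end,
                                 orientation = c("forward", "reverse"),
                                 segments, cn_proxy_gene = NA_character_,
                                 baseline_margin = 1000L) {
  orientation <- match.arg(orientation)
  seg <- tibble::as_tibble(segments)
  if (!"switch_order" %in% names(seg)) seg$switch_order <- NA_integer_
  seg$start <- as.numeric(seg$start)
  seg$end <- as.numeric(seg$end)

  bad_kind <- setdiff(unique(seg$kind), c("V", "D", "J", "CONSTANT"))
  if (length(bad_kind)) {
    stop("unknown segment kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  if (any(seg$start > seg$end)) {
    stop("malformed segment(s) with start > end: ",
         paste(seg$name[seg$start > seg$end], collapse = ", "), call. = FALSE)
  }
  if (!all(seg$chrom == chrom)) {
    stop("all segments of ", locus, " must be on ", chrom, call. = FALSE)
  }
  if (any(seg$start < span_start | seg$end > span_end)) {
    out <- seg$name[seg$start < span_start | seg$end > span_end]
    stop("segment(s) outside locus span: ", paste(out, collapse = ", "),
         call. = FALSE)
  }
  has_so <- !is.na(seg$switch_order)
  if (any(has_so & seg$kind != "CONSTANT") ||
      any(!has_so & seg$kind == "CONSTANT")) {
    stop("switch_order must be present for CONSTANT segments and absent ",
         "otherwise", call. = FALSE)
  }

  # deletion-axis coordinates: axis 0 at the V-proximal end of the window
  ax <- function(x) if (orientation == "forward") x - span_start else span_end - x
  seg$axis_start <- pmin(ax(seg$start), ax(seg$end))
  seg$axis_end <- pmax(ax(seg$start), ax(seg$end))
  seg <- dplyr::arrange(seg, .data$axis_start)

  # same-kind intervals must not overlap
  for (k in unique(seg$kind)) {
    s <- seg[seg$kind == k, ]
    if (nrow(s) > 1 && any(s$axis_start[-1] <= s$axis_end[-nrow(s)])) {
      stop("overlapping ", k, " segments in ", locus, call. = FALSE)
    }
  }
  v <- seg[seg$kind == "V", ]
  j <- seg[seg$kind == "J", ]
  if (nrow(v) == 0 || nrow(j) == 0) {
    stop("locus must contain at least one V and one J segment", call. = FALSE)
  }
  if (max(v$axis_end) >= min(j$axis_start)) {
    stop("invalid segment ordering: every V segment must precede every J ",
         "segment on the deletion axis", call. = FALSE)
  }
  cst <- seg[seg$kind == "CONSTANT", ]
  if (nrow(cst) > 0 && min(cst$axis_start) <= max(j$axis_end)) {
    stop("all CONSTANT segments must follow all J segments on the deletion ",
         "axis", call. = FALSE)
  }

  # baseline = flanks of the window outside any possible deletion
  lo <- min(seg$start) - baseline_margin
  hi <- max(seg$end) + baseline_margin
  baseline <- tibble::tibble(
    start = c(span_start, hi),
    end = c(lo, span_end))
  baseline <- baseline[baseline$end - baseline$start >= 0, ]

  structure(
    list(locus = locus, chrom = chrom,
         span_start = as.numeric(span_start), span_end = as.numeric(span_end),
         orientation = orientation, cn_proxy_gene = cn_proxy_gene,
         segments = seg, baseline_regions = baseline),
    class = "locus_definition")
}

#' @export
print.locus_definition <- function(x, ...) {
  cat("<locus_definition> ", x$locus, "  ", x$chrom, ":", format(x$span_start,
      big.mark = ","), "-", format(x$span_end, big.mark = ","),
      " (", x$orientation, ")\n", sep = "")
  cat("  segments: ", paste(sprintf("%s=%d", names(table(x$segments$kind)),
                                    as.integer(table(x$segments$kind))),
                            collapse = ", "), "\n", sep = "")
  cat("  baseline regions: ", nrow(x$baseline_regions), "\n", sep = "")
  invisible(x)
}

#' Map genomic positions onto the deletion axis
#'
#' @param locus A `locus_definition`.
#' @param x Genomic positions (1-based).
#' @return Numeric axis positions (0 at the V-proximal window end).
#' @keywords internal
#' @export
deletion_axis <- function(locus, x) {
  if (locus$orientation == "forward") x - locus$span_start
  else locus$span_end - x
}

segments_of <- function(locus, kind) {
  locus$segments[locus$segments$kind == kind, ]
}

#' V(D)J deletion indicator
#'
#' Indicates whether a genomic position is excised by a given (V, J)
#' rearrangement: 1 iff the position lies strictly between the deletion-axis
#' end of the V segment and the deletion-axis start of the J segment,
#' respecting locus orientation.
#'
#' @param locus A `locus_definition`.
#' @param x A genomic position inside the locus span.
#' @param v,j Segment names (a V and a J segment of the locus).
#' @return 0 or 1.
#' @examples
#' tcra <- load_locus_definition("TCRA")
#' deletion_indicator(tcra, 22460000, "TRAV1-1", "TRAJ61")
#' @export
deletion_indicator <- function(locus, x, v, j) {
  stopifnot(inherits(locus, "locus_definition"))
  if (x < locus$span_start || x > locus$span_end) {
    stop("position ", x, " outside locus span", call. = FALSE)
  }
  vs <- segments_of(locus, "V")
  js <- segments_of(locus, "J")
  if (!v %in% vs$name) stop("'", v, "' is not a V segment of ", locus$locus,
                            call. = FALSE)
  if (!j %in% js$name) stop("'", j, "' is not a J segment of ", locus$locus,
                            call. = FALSE)
  ax <- deletion_axis(locus, x)
  v_end <- vs$axis_end[vs$name == v]
  j_start <- js$axis_start[js$name == j]
  as.integer(ax > v_end & ax < j_start)
}

#' Export locus segments as BED6
#'
#' Writes the segment annotation in BED6 (0-based half-open) for genome
#' browsers. The score column carries the switch order for constant genes.
#'
#' @param locus A `locus_definition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(locus, path) {
  seg <- locus$segments
  strand <- if (locus$orientation == "forward") "+" else "-"
  bed <- data.frame(
    chrom = seg$chrom, start = as.integer(seg$start) - 1L,
    end = as.integer(seg$end), name = seg$name,
    score = ifelse(is.na(seg$switch_order), 0L, seg$switch_order),
    strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
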