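#' Bin per-base coverage and annotate GC content
#'
#' Aggregates a per-base coverage track into fixed-width bins tiling the locus
#' window, computing the mean depth and the G+C fraction of each bin. Bins
#' whose footprint lies entirely inside a flanking baseline region are marked
#' `baseline`; bins overlapping the uncertainty zone around any segment edge
#' (+/- `boundary_margin` bp) are flagged `boundary` and later down-weighted.
#'
#' GC content comes either from a reference FASTA (`reference`, any file
#' readable by [Rsamtools::FaFile()]) or from a per-position numeric vector
#' `gc` aligned with the track rows (useful for simulated data). With neither,
#' a constant 0.5 is used and GC correction degenerates to the identity.
#'
#' @param track A `vdj_coverage` track.
#' @param locus A `locus_definition` (same chromosome as the track).
#' @param bin_size Bin width in bp (>= 50).
#' @param reference Optional reference FASTA path or [Rsamtools::FaFile()].
#' @param gc Optional per-position GC values (same length as `track`).
#' @param boundary_margin Half-width (bp) of the segment-edge uncertainty zone.
#' @return A `vdj_bins` tibble: `bin_start`, `bin_end`, `axis_mid`, `n_pos`,
#'   `raw_sum`, `depth`, `gc`, `baseline`, `boundary`.
#' @export
bin_coverage <- function(track, locus, bin_size = 500, reference = NULL,
                         gc = NULL, boundary_margin = 250) {
  stopifnot(inherits(locus, "locus_definition"))
  if (bin_size < 50) stop("bin_size must be >= 50 bp", call. = FALSE)
  if (!all(track$chrom %in% locus$chrom)) {
    stop("track chromosome does not match locus ", locus$locus, call. = FALSE)
  }
  keep <- track$pos >= locus$span_start & track$pos <= locus$span_end
  pos <- track$pos[keep]
  depth <- track$depth[keep]
  if (!length(pos)) stop("track has no positions inside the locus span",
                         call. = FALSE)

  gc_pos <- if (!is.null(gc)) {
    if (length(gc) != nrow(track)) {
      stop("gc must have one value per track position", call. = FALSE)
    }
    gc[keep]
  } else if (!is.null(reference)) {
    fa <- if (inherits(reference, "FaFile")) reference
          else Rsamtools::FaFile(reference)
    rng <- GenomicRanges::GRanges(locus$chrom,
                                  IRanges::IRanges(min(pos), max(pos)))
    seqs <- tryCatch(Rsamtools::getSeq(fa, rng), error = function(e)
      stop("cannot fetch ", locus$chrom, " from reference: ",
           conditionMessage(e), call. = FALSE))
    letters <- strsplit(as.character(seqs[[1]]), "")[[1]]
    as.numeric(letters %in% c("G", "C", "g", "c"))[pos - min(pos) + 1]
  } else {
    rep(0.5, length(pos))
  }

  idx <- floor((pos - locus$span_start) / bin_size)
  bin_start <- locus$span_start + idx * bin_size
  grp <- factor(idx, levels = sort(unique(idx)))
  n_pos <- as.numeric(tapply(depth, grp, length))
  raw_sum <- as.numeric(tapply(depth, grp, sum))
  gc_bin <- as.numeric(tapply(gc_pos, grp, mean))
  bs <- locus$span_start + as.numeric(levels(grp)) * bin_size
  be <- pmin(bs + bin_size - 1, locus$span_end)

  base <- rep(FALSE, length(bs))
  for (i in seq_len(nrow(locus$baseline_regions))) {
    base <- base | (bs >= locus$baseline_regions$start[i] &
                    be <= locus$baseline_regions$end[i])
  }
  edges <- c(locus$segments$start, locus$segments$end)
  boundary <- vapply(seq_along(bs), function(i) {
    any(edges >= bs[i] - boundary_margin & edges <= be[i] + boundary_margin)
  }, logical(1))

  out <- tibble::tibble(
    bin_start = bs, bin_end = be,
    axis_mid = deletion_axis(locus, (bs + be) / 2),
    n_pos = n_pos, raw_sum = raw_sum, depth = raw_sum / n_pos,
    gc = gc_bin, baseline = base, boundary = boundary)
  attr(out, "locus") <- locus$locus
  attr(out, "bin_size") <- bin_size
  attr(out, "sample_id") <- attr(track, "sample_id")
  class(out) <- c("vdj_bins", class(out))
  out
}

#' Fit a GC-bias model on baseline bins
#'
#' Fits a smooth local-regression (LOESS) trend of log2 depth on GC fraction
#' using baseline-region bins only, weighting by bin footprint. The trend is
#' evaluated on GC in [0.25, 0.75] and clamped outside. If the baseline GC
#' spread is degenerate (< 0.05) the identity model is returned with a
#' warning.
#'
#' @param bins A `vdj_bins` tibble from [bin_coverage()].
#' @param span LOESS span.
#' @return A `gc_model` object with elements `predict` (function of gc,
#'   returning the multiplicative depth correction on the log2 scale relative
#'   to the baseline mean), `residual_sd`, and `method`.
#' @export
fit_gc_model <- function(bins, span = 0.75) {
  bl <- bins[bins$baseline & bins$raw_sum > 0, ]
  if (nrow(bl) < 30) {
    stop("need >= 30 baseline bins with coverage to fit the GC model (got ",
         nrow(bl), ")", call. = FALSE)
  }
  identity_model <- function(msg) {
    warning(msg, call. = FALSE)
    structure(list(
      predict = function(gc) rep(0, length(gc)),
      residual_sd = NA_real_, method = "identity"), class = "gc_model")
  }
  if (diff(range(bl$gc)) < 0.05) {
    return(identity_model(
      "degenerate GC range on baseline bins; using identity GC model"))
  }
  y <- log2(bl$depth)
  fit <- stats::loess(y ~ gc, data = data.frame(y = y, gc = bl$gc),
                      span = span, degree = 2, weights = bl$n_pos,
                      control = stats::loess.control(surface = "direct"))
  ref <- stats::weighted.mean(stats::predict(fit, data.frame(gc = bl$gc)),
                              bl$n_pos)
  pred <- function(gc) {
    gcc <- pmin(pmax(gc, 0.25), 0.75)
    stats::predict(fit, data.frame(gc = gcc)) - ref
  }
  structure(list(predict = pred,
                 residual_sd = stats::sd(stats::residuals(fit)),
                 method = "loess"),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model> method:", x$method, " residual SD:",
      format(x$residual_sd, digits = 3), "\n")
  invisible(x)
}

#' Build a GC-corrected log2 read-depth-ratio profile
#'
#' Divides GC-corrected bin depths by the mean corrected depth over baseline
#' bins and takes log2, yielding the read depth ratio (RDR) profile that all
#' downstream fitting consumes. Zero-coverage bins are retained with a
#' pseudo-count of 0.5 reads. Each bin carries a weight proportional to its
#' expected read count if undeleted (baseline depth times footprint);
#' segment-boundary bins are down-weighted.
#'
#' @param bins A `vdj_bins` tibble.
#' @param gc_model A `gc_model` from [fit_gc_model()].
#' @param locus The `locus_definition` the bins were computed on.
#' @param boundary_downweight Multiplier applied to boundary-bin weights.
#' @param exclude Optional data frame of intervals (`start`, `end`) to drop
#'   (e.g. low-mappability regions).
#' @return A `vdj_ratio_profile` tibble: `bin_start`, `bin_end`, `axis_mid`,
#'   `gc`, `log2_rdr`, `weight`, `baseline`, `boundary`; attributes
#'   `baseline_depth`, `mean_depth`, `locus`, `bin_size`.
#' @export
to_ratio_profile <- function(bins, gc_model, locus,
                             boundary_downweight = 0.1, exclude = NULL) {
  stopifnot(inherits(bins, "vdj_bins"), inherits(gc_model, "gc_model"))
  b <- bins
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(exclude))) {
      drop <- drop | (b$bin_end >= exclude$start[i] &
                      b$bin_start <= exclude$end[i])
    }
    b <- b[!drop, ]
  }
  corr <- 2^(-gc_model$predict(b$gc))           # multiplicative, mean 1 on baseline
  depth_eff <- pmax(b$raw_sum, 0.5) / b$n_pos   # pseudo-count for empty bins
  cdepth <- depth_eff * corr
  bl <- b$baseline
  baseline_depth <- stats::weighted.mean(cdepth[bl], b$n_pos[bl])
  if (!is.finite(baseline_depth) || baseline_depth <= 0) {
    stop("baseline depth is not positive; cannot normalise", call. = FALSE)
  }
  if (sum(bl) < 5) {
    stop("need >= 5 usable baseline bins (got ", sum(bl), ")", call. = FALSE)
  }
  w <- baseline_depth * b$n_pos
  w[b$boundary] <- w[b$boundary] * boundary_downweight
  out <- tibble::tibble(
    bin_start = b$bin_start, bin_end = b$bin_end, axis_mid = b$axis_mid,
    gc = b$gc, log2_rdr = log2(cdepth / baseline_depth), weight = w,
    baseline = bl, boundary = b$boundary)
  attr(out, "locus") <- attr(bins, "locus")
  attr(out, "bin_size") <- attr(bins, "bin_size")
  attr(out, "sample_id") <- attr(bins, "sample_id")
  attr(out, "baseline_depth") <- baseline_depth
  attr(out, "mean_depth") <- stats::weighted.mean(b$depth, b$n_pos)
  class(out) <- c("vdj_ratio_profile", class(out))
  out
}

#' One-call normalisation: coverage track to RDR profile
#'
#' Convenience wrapper chaining [bin_coverage()], [fit_gc_model()] and
#' [to_ratio_profile()].
#'
#' @inheritParams bin_coverage
#' @inheritParams to_ratio_profile
#' @param gc_span LOESS span passed to [fit_gc_model()].
#' @return A `vdj_ratio_profile`.
#' @export
ratio_profile <- function(track, locus, bin_size = 500, reference = NULL,
                          gc = NULL, boundary_margin = 250, gc_span = 0.75,
                          boundary_downweight = 0.1, exclude = NULL) {
  bins <- bin_coverage(track, locus, bin_size = bin_size,
                       reference = reference, gc = gc,
                       boundary_margin = boundary_margin)
  gm <- if (is.null(reference) && is.null(gc)) {
    structure(list(predict = function(g) rep(0, length(g)),
                   residual_sd = NA_real_, method = "identity"),
              class = "gc_model")
  } else {
    fit_gc_model(bins, span = gc_span)
  }
  to_ratio_profile(bins, gm, locus, boundary_downweight = boundary_downweight,
                   exclude = exclude)
}

#' Serialise / load an RDR profile
#'
#' @param profile A `vdj_ratio_profile`.
#' @param path TSV output path.
#' @return `path` invisibly.
#' @export
write_ratio_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
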