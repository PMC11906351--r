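#' Segment usage distribution
#'
#' Validates a V- or J-segment usage vector as a labelled probability
#' simplex.
#'
#' @param probs Non-negative values summing to 1 (tolerance 1e-8).
#' @param labels Unique segment names (defaults to `names(probs)`).
#' @param source `"V"` or `"J"`.
#' @param locus Locus label.
#' @return A `segment_usage` object (named numeric vector with attributes).
#' @export
segment_usage <- function(probs, labels = names(probs), source = "V",
                          locus = NA_character_) {
  if (is.null(labels)) labels <- paste0("seg", seq_along(probs))
  if (anyDuplicated(labels)) stop("segment labels must be unique",
                                  call. = FALSE)
  if (length(labels) != length(probs)) {
    stop("labels and probs must have equal length", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("probs must be a probability simplex (non-negative, sum 1)",
         call. = FALSE)
  }
  structure(stats::setNames(as.numeric(probs), labels),
            source = source, locus = locus, class = "segment_usage")
}

as_usage <- function(x) {
  if (inherits(x, "segment_usage")) x else segment_usage(x)
}

#' Shannon diversity of a segment usage distribution
#'
#' `-sum(p_i * ln p_i)` in nats, with `0 * ln 0 := 0`.
#'
#' @param dist A `segment_usage` (or named simplex vector).
#' @return Shannon diversity in nats; 0 for a degenerate distribution and
#'   `ln K` for the uniform distribution over K segments.
#' @examples
#' shannon_diversity(rep(1 / 8, 8))  # log(8)
#' @export
shannon_diversity <- function(dist) {
  p <- as_usage(dist)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Jensen-Shannon divergence between two usage distributions
#'
#' `JSD(P, Q) = D(P || M)/2 + D(Q || M)/2` with `M = (P + Q)/2` and
#' Kullback-Leibler divergence in nats; symmetric, in `[0, ln 2]`.
#' Distributions over different label sets are aligned on the union with
#' zero fill when `zero_fill = TRUE`; zero-probability terms contribute 0 to
#' their own KL sum.
#'
#' @param p,q `segment_usage` objects or named simplex vectors.
#' @param zero_fill Align differing label sets on their union.
#' @return JSD in nats.
#' @export
jensen_shannon_divergence <- function(p, q, zero_fill = TRUE) {
  p <- as_usage(p); q <- as_usage(q)
  if (!setequal(names(p), names(q))) {
    if (!zero_fill) {
      stop("distributions have different label sets (set zero_fill = TRUE ",
           "to align on the union)", call. = FALSE)
    }
    labs <- union(names(p), names(q))
    p <- stats::setNames(ifelse(labs %in% names(p), p[labs], 0), labs)
    q <- stats::setNames(ifelse(labs %in% names(q), q[labs], 0), labs)
    p[is.na(p)] <- 0; q[is.na(q)] <- 0
  } else {
    q <- q[names(p)]
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Segments selected by the usage model
#'
#' A segment counts as selected when its fitted usage exceeds the threshold
#' (strictly greater than; default 0.001).
#'
#' @param dist A `segment_usage` (or named simplex vector).
#' @param threshold Strict lower bound on usage.
#' @return Character vector of selected segment names.
#' @export
selected_segments <- function(dist, threshold = 0.001) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  p <- as_usage(dist)
  names(p)[p > threshold]
}

#' Gate diversity metrics on a minimum lymphocyte fraction
#'
#' Segment-usage diversity is only meaningful when enough lymphocyte signal
#' is present; fits at or below `min_fraction` (strictly greater passes) are
#' gated out.
#'
#' @param fit A `vdj_fit`.
#' @param min_fraction Strict lower bound on the fitted fraction.
#' @return `TRUE` if the fit passes the gate.
#' @export
min_fraction_gate <- function(fit, min_fraction = 0.05) {
  stopifnot(inherits(fit, "vdj_fit"))
  fit$fraction > min_fraction
}

#' Diversity summary of a fit
#'
#' Shannon diversity of the fitted V and J usage, with the gate flag.
#'
#' @param fit A `vdj_fit`.
#' @param min_fraction Gate threshold (see [min_fraction_gate()]).
#' @return A one-row tibble: `locus`, `fraction`, `gated` (TRUE when the fit
#'   fails the gate), `shannon_v`, `shannon_j`, `n_selected_v`.
#' @export
diversity_summary <- function(fit, min_fraction = 0.05) {
  tibble::tibble(
    locus = fit$locus, fraction = fit$fraction,
    gated = !min_fraction_gate(fit, min_fraction),
    shannon_v = shannon_diversity(fit$v_usage),
    shannon_j = shannon_diversity(fit$j_usage),
    n_selected_v = length(selected_segments(fit$v_usage)))
}
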