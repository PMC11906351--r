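#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a V(D)J fit into a per-segment tibble
#'
#' @param x A `vdj_fit`.
#' @param ... Unused.
#' @return A tibble with one row per V/J segment: `locus`, `segment`,
#'   `kind`, `usage`, `selected` (strict 0.001 rule).
#' @export
tidy.vdj_fit <- function(x, ...) {
  tibble::tibble(
    locus = x$locus,
    segment = c(names(x$v_usage), names(x$j_usage)),
    kind = rep(c("V", "J"), c(length(x$v_usage), length(x$j_usage))),
    usage = unname(c(x$v_usage, x$j_usage)),
    selected = unname(c(x$v_usage, x$j_usage)) > 0.001)
}

#' One-row summary of a V(D)J fit
#'
#' @param x A `vdj_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `locus`, `fraction`, `ci_lower`, `ci_upper`,
#'   `objective`, `n_bins_used`, `converged`, `zero_fraction`, `shannon_v`.
#' @export
glance.vdj_fit <- function(x, ...) {
  tibble::tibble(
    locus = x$locus, fraction = x$fraction, ci_lower = x$ci_lower,
    ci_upper = x$ci_upper, objective = x$objective,
    n_bins_used = x$n_bins_used, converged = x$converged,
    zero_fraction = x$zero_fraction,
    shannon_v = shannon_diversity(x$v_usage))
}

#' Tidy a class-switch decomposition
#'
#' @param x A `class_switch_fit`.
#' @param ... Unused.
#' @return A tibble with one row per isotype class: `class`, `rank`,
#'   `proportion`, `b_fraction_class` (proportion times total B fraction).
#' @export
tidy.class_switch_fit <- function(x, ...) {
  cls <- isotype_classes()
  tibble::tibble(
    class = cls$class, rank = cls$rank,
    proportion = unname(x$isotype_props[cls$class]),
    b_fraction_class = x$b_fraction * unname(x$isotype_props[cls$class]))
}

#' One-row summary of a class-switch decomposition
#'
#' @param x A `class_switch_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the headline aggregates.
#' @export
glance.class_switch_fit <- function(x, ...) {
  tibble::tibble(
    b_fraction = x$b_fraction, igm_igd = unname(x$igm_igd),
    class_switched = unname(x$class_switched), igg = unname(x$igg),
    iga = unname(x$iga), ige = unname(x$ige), undefined = x$undefined)
}

#' Tidy germline CNV calls
#'
#' @param x A `germline_cnv_calls` object.
#' @param ... Unused.
#' @return The calls as a plain tibble with the `low_confidence` flag column.
#' @export
tidy.germline_cnv_calls <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$low_confidence <- attr(x, "low_confidence")
  out
}

#' Export a fit as JSON
#'
#' @param fit A `vdj_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    locus = fit$locus, fraction = fit$fraction,
    ci = c(fit$ci_lower, fit$ci_upper),
    v_usage = as.list(fit$v_usage), j_usage = as.list(fit$j_usage),
    qc = list(n_bins = fit$n_bins_used, objective = fit$objective,
              converged = fit$converged, zero_fraction = fit$zero_fraction)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
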