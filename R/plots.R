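#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RDR profile
#'
#' Binned log2 read-depth ratio along the genome, coloured by bin role
#' (baseline / boundary / model). Overlay a fitted deletion curve by passing
#' the matching `vdj_fit` and `locus_definition`.
#'
#' @param object A `vdj_ratio_profile`.
#' @param fit Optional `vdj_fit` to overlay as the expected RDR.
#' @param locus Required with `fit`: the `locus_definition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vdj_ratio_profile <- function(object, fit = NULL, locus = NULL,
                                       ...) {
  df <- tibble::as_tibble(object)
  df$role <- ifelse(df$baseline, "baseline",
                    ifelse(df$boundary, "boundary", "model"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start,
                                        y = .data$log2_rdr,
                                        colour = .data$role)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "genomic position", y = "log2 read depth ratio",
                  colour = NULL,
                  title = paste0(attr(object, "locus"), " RDR profile")) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(!is.null(locus))
    curve <- deletion_curve(locus, fit$v_usage, fit$j_usage)
    used <- pool_profile_bins(object, locus)
    exp_df <- tibble::tibble(
      bin_start = df$bin_start[used],
      expected = expected_log2_rdr(fit$fraction, curve, fit$ctx,
                                   df$axis_mid[used], a = fit$a))
    p <- p + ggplot2::geom_line(
      data = exp_df,
      ggplot2::aes(x = .data$bin_start, y = .data$expected),
      inherit.aes = FALSE, colour = "black", linewidth = 0.4)
  }
  p
}

#' Plot fitted segment usage
#'
#' Bar plot of the fitted V and J usage simplices.
#'
#' @param object A `vdj_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vdj_fit <- function(object, ...) {
  df <- tidy(object)
  df$segment <- factor(df$segment, levels = df$segment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$usage,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "usage",
                  title = sprintf("%s fraction %.3f", object$locus,
                                  object$fraction)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot a class-switch decomposition
#'
#' @param object A `class_switch_fit`.
#' @param ... Unused.
#' @return A ggplot of per-class B cell fractions.
#' @export
autoplot.class_switch_fit <- function(object, ...) {
  df <- tidy(object)
  df$class <- factor(df$class, levels = df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                   y = .data$b_fraction_class)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "B cell fraction",
                  title = sprintf("class switching (f_B = %.3f)",
                                  object$b_fraction)) +
    ggplot2::theme_minimal()
}
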