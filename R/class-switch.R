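#' Call germline copy-number variants over the IGH locus
#'
#' Common inherited CNVs across the IGH constant genes would masquerade as
#' class-switch deletions, so they are called from the matched germline
#' (blood) profile and masked before class-switch fitting. For each
#' constant-gene region and each V-segment block the caller assigns the
#' integer copy number minimising `|median RDR - log2(CN/2)|` over
#' `CN = 0..4` (CN 0 represented by `log2(0.05/2)` so deep deletions remain
#' callable) and records the margin to the runner-up in RDR units. Regions
#' with `CN != 2`, or margin below `margin_threshold`, are masked. Calls from
#' profiles whose baseline (undeleted flank) depth is below 10x, at integer
#' reporting resolution, carry a low-confidence flag.
#'
#' @param normal_profile A `vdj_ratio_profile` from the germline sample, or
#'   `NULL` (all regions unmasked, with a warning recorded).
#' @param locus The IGH `locus_definition` (any locus with segments works).
#' @param margin_threshold Minimum margin (RDR units) for a confident call.
#' @param cn_max Largest copy number considered.
#' @return A `germline_cnv_calls` tibble: `region`, `kind`, `cn`, `margin`,
#'   `masked`, `n_bins`; attributes `low_confidence` and `mean_depth`.
#' @export
call_germline_cnv <- function(normal_profile, locus, margin_threshold = 0.1,
                              cn_max = 4) {
  stopifnot(inherits(locus, "locus_definition"))
  regions <- locus$segments[locus$segments$kind %in% c("CONSTANT", "V"), ]
  if (is.null(normal_profile)) {
    warning("no germline profile supplied; all regions left unmasked",
            call. = FALSE)
    out <- tibble::tibble(region = regions$name, kind = regions$kind,
                          cn = NA_integer_, margin = NA_real_,
                          masked = FALSE, n_bins = 0L)
    attr(out, "low_confidence") <- TRUE
    attr(out, "mean_depth") <- NA_real_
    class(out) <- c("germline_cnv_calls", class(out))
    return(out)
  }
  stopifnot(inherits(normal_profile, "vdj_ratio_profile"))
  mean_depth <- attr(normal_profile, "baseline_depth")
  low_conf <- is.na(mean_depth) || round(mean_depth) < 10

  # V segments are narrow; widen each block to the midpoints towards its
  # neighbours so the whole V region is covered
  rr <- regions
  v_idx <- which(rr$kind == "V")
  if (length(v_idx) > 1) {
    vstart <- rr$start[v_idx]; vend <- rr$end[v_idx]
    o <- order(vstart)
    lo <- vstart[o]; hi <- vend[o]
    mid <- (lo[-1] + hi[-length(hi)]) / 2
    lo2 <- c(lo[1], ceiling(mid)); hi2 <- c(floor(mid), hi[length(hi)])
    rr$start[v_idx[o]] <- lo2; rr$end[v_idx[o]] <- hi2
  }

  ref_rdr <- log2(pmax(0:cn_max, 0.05) / 2)
  res <- lapply(seq_len(nrow(rr)), function(i) {
    sel <- normal_profile$bin_start <= rr$end[i] &
      normal_profile$bin_end >= rr$start[i] &
      is.finite(normal_profile$log2_rdr)
    if (!any(sel)) {
      return(tibble::tibble(region = rr$name[i], kind = rr$kind[i],
                            cn = NA_integer_, margin = NA_real_,
                            masked = TRUE, n_bins = 0L))
    }
    med <- stats::median(normal_profile$log2_rdr[sel])
    dist <- abs(med - ref_rdr)
    o <- order(dist)
    cn <- o[1] - 1L
    margin <- dist[o[2]] - dist[o[1]]
    tibble::tibble(region = rr$name[i], kind = rr$kind[i], cn = cn,
                   margin = margin,
                   masked = cn != 2L | margin < margin_threshold,
                   n_bins = sum(sel))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "low_confidence") <- low_conf
  attr(out, "mean_depth") <- mean_depth
  class(out) <- c("germline_cnv_calls", class(out))
  out
}

#' Class-switch survival of a constant gene
#'
#' The proportion of B cells whose class-switch recombination deleted
#' constant gene `g`: cells switched to a class of higher switch rank,
#' `S(g) = sum over classes c with rank(c) > rank(g) of pi_c`.
#'
#' @param props Isotype mixture over the eight switch classes (named by class
#'   or in switch order).
#' @param gene Constant-gene name (e.g. `"IGHG1"`).
#' @param locus An IGH `locus_definition` (supplies switch ranks); defaults to
#'   the packaged IGH model.
#' @return Survival S(g) in [0, 1].
#' @export
switch_survival <- function(props, gene,
                            locus = load_locus_definition("IGH")) {
  cls <- isotype_classes()
  props <- align_usage(props, cls$class, "isotype props")
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8) {
    stop("isotype props must lie on the simplex", call. = FALSE)
  }
  cst <- segments_of(locus, "CONSTANT")
  if (!gene %in% cst$name) stop("unknown constant gene: ", gene,
                                call. = FALSE)
  r <- cst$switch_order[cst$name == gene]
  sum(props[cls$rank > r])
}

#' Decompose the B cell fraction into isotype classes
#'
#' Conditional on the IGH V(D)J fit (total B cell fraction `f_B`), the RDR of
#' each inter-switch interval (every position between two consecutive switch
#' regions shares the survival of the enclosed constant gene) yields a
#' plug-in estimate of switch survival,
#' `s(g) = C_flank (1 - 2^RDR_g) / (a_cs f_B)` with `a_cs = 1` (class-switch
#' recombination deletes one allele). Survival is fitted non-increasing along
#' switch order by weighted isotonic regression; the isotype proportion of
#' each class is the decrement across its switch boundary, clipped to the
#' simplex. Bins overlapping masked (CNV) gene bodies are excluded; a rank
#' left with no usable bins inherits the fitted survival of its
#' switch-upstream neighbour, merging its class mass into the next class
#' downstream.
#'
#' If `f_B` is below `fb_threshold` the isotype steps are unidentifiable and
#' the decomposition is returned flagged undefined (no error).
#'
#' @param profile A `vdj_ratio_profile` over IGH.
#' @param vdj_fit The IGH `vdj_fit` (supplies `f_B`).
#' @param cnv Optional `germline_cnv_calls` for masking.
#' @param ctx A `purity_cn_context`.
#' @param a_cs Alleles deleted per class-switched cell (1).
#' @param fb_threshold B cell fraction below which isotypes are undefined.
#' @param survival_z Detection threshold: fitted survival below this many
#'   standard errors of its interval estimate is called zero.
#' @param locus The IGH `locus_definition` (defaults to the packaged model).
#' @return A `class_switch_fit`: `b_fraction`, `isotype_props` (length-8
#'   simplex or NA), aggregates `igm_igd`, `class_switched`, `igg`, `iga`,
#'   `ige`, the fitted `survival` table and QC flags.
#' @export
fit_class_switch <- function(profile, vdj_fit, cnv = NULL,
                             ctx = purity_cn_context(), a_cs = 1,
                             fb_threshold = 1e-3, survival_z = 2,
                             locus = load_locus_definition("IGH")) {
  stopifnot(inherits(profile, "vdj_ratio_profile"),
            inherits(vdj_fit, "vdj_fit"))
  f_b <- vdj_fit$fraction
  cls <- isotype_classes()
  cst <- segments_of(locus, "CONSTANT")

  undefined_fit <- function() {
    structure(list(
      b_fraction = f_b, isotype_props = stats::setNames(rep(NA_real_, 8),
                                                        cls$class),
      igm_igd = NA_real_, class_switched = NA_real_, igg = NA_real_,
      iga = NA_real_, ige = NA_real_, survival = NULL,
      undefined = TRUE, ige_low_confidence = TRUE), class = "class_switch_fit")
  }
  if (f_b < fb_threshold) return(undefined_fit())

  masked <- character(0)
  if (!is.null(cnv)) {
    masked <- cnv$region[cnv$masked & cnv$kind == "CONSTANT"]
  }
  if (nrow(cst) - length(intersect(masked, cst$name)) < 3) {
    stop("need >= 3 unmasked constant-gene regions", call. = FALSE)
  }

  # Every position between two consecutive switch regions shares the switch
  # survival of the enclosed gene, so each rank is estimated from the whole
  # inter-switch interval, not just the gene body. Rank r's region runs from
  # its gene's switch boundary (axis start) to the next gene's; rank 0 starts
  # just past the J cluster.
  cls_gene <- isotype_classes()
  b <- vapply(cls_gene$gene[-1], function(g) cst$axis_start[cst$name == g],
              numeric(1))                       # boundaries for ranks 1..7
  s_mu <- max(segments_of(locus, "J")$axis_end) + 500
  lo <- c(s_mu, b)
  hi <- c(b, cst$axis_end[cst$name == "IGHA2"])

  drop_bin <- rep(FALSE, nrow(profile))
  for (g in intersect(masked, cst$name)) {
    row <- cst[cst$name == g, ]
    drop_bin <- drop_bin | (profile$bin_start <= row$end &
                              profile$bin_end >= row$start)
  }
  usable <- is.finite(profile$log2_rdr) & profile$weight > 0 & !drop_bin

  by_rank <- dplyr::bind_rows(lapply(0:7, function(r) {
    sel <- usable & profile$axis_mid >= lo[r + 1] &
      profile$axis_mid < hi[r + 1]
    if (!any(sel)) return(NULL)
    s_bin <- ctx$c_flank * (1 - 2^profile$log2_rdr[sel]) / (a_cs * f_b)
    w <- profile$weight[sel]
    s_mean <- sum(w * s_bin) / sum(w)
    denom <- sum(w) - sum(w^2) / sum(w)
    s2 <- if (denom > 0) sum(w * (s_bin - s_mean)^2) / denom else 0
    tibble::tibble(rank = r, s_raw = s_mean, weight = sum(w),
                   s_se = sqrt(s2 * sum(w^2) / sum(w)^2))
  }))
  if (nrow(by_rank) < 3) {
    stop("too few constant-region intervals with usable bins", call. = FALSE)
  }
  s_fit <- pmin(pmax(pava(by_rank$s_raw, by_rank$weight,
                          increasing = FALSE), 0), 1)
  # detection threshold: the trailing run of ranks whose fitted survival is
  # indistinguishable from zero (below z standard errors) is called zero;
  # restricting to a suffix preserves monotonicity
  below <- s_fit < survival_z * by_rank$s_se
  k <- length(s_fit)
  while (k >= 1 && below[k]) { s_fit[k] <- 0; k <- k - 1 }

  # survival on the full rank ladder 0..7; masked ranks carry the
  # switch-upstream value forward
  s_all <- rep(NA_real_, 8)
  s_all[by_rank$rank + 1] <- s_fit
  for (k in seq_along(s_all)) {
    if (is.na(s_all[k])) s_all[k] <- if (k == 1) s_fit[1] else s_all[k - 1]
  }
  pi_hat <- c(1 - s_all[1], -diff(s_all))
  pi_hat <- normalise_simplex(pmax(pi_hat, 0))
  names(pi_hat) <- cls$class

  structure(list(
    b_fraction = f_b,
    isotype_props = pi_hat,
    igm_igd = f_b * pi_hat[["IgM/IgD"]],
    class_switched = f_b * (1 - pi_hat[["IgM/IgD"]]),
    igg = f_b * sum(pi_hat[c("IgG3", "IgG1", "IgG2", "IgG4")]),
    iga = f_b * sum(pi_hat[c("IgA1", "IgA2")]),
    ige = f_b * pi_hat[["IgE"]],
    survival = tibble::tibble(rank = 0:7, class = cls$class,
                              survival = s_all),
    undefined = FALSE, ige_low_confidence = TRUE),
    class = "class_switch_fit")
}

#' @export
print.class_switch_fit <- function(x, ...) {
  cat("<class_switch_fit>\n")
  cat(sprintf("  B cell fraction: %.4f\n", x$b_fraction))
  if (x$undefined) {
    cat("  isotype decomposition undefined (B fraction below threshold)\n")
  } else {
    cat(sprintf("  IgM/IgD %.4f | class-switched %.4f (IgG %.4f, IgA %.4f, IgE %.4f)\n",
                x$igm_igd, x$class_switched, x$igg, x$iga, x$ige))
  }
  invisible(x)
}
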