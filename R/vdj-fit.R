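#' Weighted isotonic regression (pool-adjacent-violators)
#'
#' Minimises sum(w * (y - yhat)^2) subject to yhat non-decreasing
#' (`increasing = TRUE`) or non-increasing.
#'
#' @param y Observed values.
#' @param w Positive weights.
#' @param increasing Direction of the monotonicity constraint.
#' @return Fitted values, same length as `y`.
#' @export
pava <- function(y, w = rep(1, length(y)), increasing = TRUE) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (!increasing) return(rev(pava(rev(y), rev(w), TRUE)))
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] >= val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

#' Tumour purity / local copy-number context
#'
#' Captures the cellular composition at a V(D)J locus in a (possibly tumour)
#' sample: tumour purity rho, local tumour copy number (from the somatic CN
#' call of the locus' proxy gene) and germline copy number (2 unless a
#' germline CNV is known). The flank copy number
#' `C_flank = rho * tumor_cn + (1 - rho) * germline_cn` is the expected copy
#' number of undeleted locus DNA and must be positive.
#'
#' @param purity Tumour purity rho (between 0 and 1); 0 for normal/blood samples.
#' @param tumor_cn Local somatic copy number at the locus (>= 0).
#' @param germline_cn Germline copy number (default 2).
#' @return A `purity_cn_context` list with `purity`, `tumor_cn`,
#'   `germline_cn`, `c_flank`.
#' @export
purity_cn_context <- function(purity = 0, tumor_cn = 2, germline_cn = 2) {
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]", call. = FALSE)
  if (tumor_cn < 0) stop("tumor_cn must be >= 0", call. = FALSE)
  c_flank <- purity * tumor_cn + (1 - purity) * germline_cn
  if (c_flank <= 0) {
    stop("flank copy number rho*n_t + (1-rho)*n_g must be positive",
         call. = FALSE)
  }
  structure(list(purity = purity, tumor_cn = tumor_cn,
                 germline_cn = germline_cn, c_flank = c_flank),
            class = "purity_cn_context")
}

#' Deletion curve of a V(D)J rearrangement mixture
#'
#' For V usage p and J usage q (independent by assumption), the probability
#' that a deletion-axis position x is excised in a rearranged cell is
#' `F(x) = PV(x) * QJ(x)`, where `PV(x)` sums usage of V segments whose
#' deletion-axis end precedes x and `QJ(x)` sums usage of J segments whose
#' deletion-axis start follows x. F is a piecewise-constant function:
#' non-decreasing through the V region, 1 between the last V and the first J,
#' non-increasing through the J region.
#'
#' @param locus A `locus_definition`.
#' @param v_usage,j_usage Named (or annotation-ordered) usage vectors on the
#'   simplex over the locus' V / J segments.
#' @return A `deletion_curve` object; call it on deletion-axis positions, or
#'   use `curve$eval(ax)`.
#' @export
deletion_curve <- function(locus, v_usage, j_usage) {
  vs <- segments_of(locus, "V")
  js <- segments_of(locus, "J")
  v_usage <- align_usage(v_usage, vs$name, "v_usage")
  j_usage <- align_usage(j_usage, js$name, "j_usage")
  for (u in list(v_usage, j_usage)) {
    if (any(u < 0) || abs(sum(u) - 1) > 1e-8) {
      stop("usage vectors must lie on the probability simplex", call. = FALSE)
    }
  }
  v_ends <- vs$axis_end
  j_starts <- js$axis_start
  cp <- cumsum(v_usage)
  cq <- cumsum(j_usage)
  cp <- unname(cp); cq <- unname(cq)
  eval_fun <- function(ax) {
    pv <- c(0, cp)[findInterval(ax, v_ends, left.open = TRUE) + 1]
    qj <- 1 - c(0, cq)[findInterval(ax, j_starts) + 1]
    unname(pv * qj)
  }
  structure(list(eval = eval_fun, v_usage = v_usage, j_usage = j_usage,
                 v_ends = v_ends, j_starts = j_starts, locus = locus$locus),
            class = "deletion_curve")
}

align_usage <- function(u, labels, what) {
  if (!is.null(names(u))) {
    missing <- setdiff(labels, names(u))
    if (length(missing)) {
      stop(what, " missing segments: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    u <- u[labels]
  } else if (length(u) != length(labels)) {
    stop(what, " must have one entry per segment", call. = FALSE)
  }
  stats::setNames(as.numeric(u), labels)
}

#' Expected log2 read-depth ratio under the deletion model
#'
#' Forward model for the RDR profile: a lymphocyte fraction `f` of cells has
#' both alleles (a = 2) of the interval excised with probability `F(x)`, so
#' the expected copy number at x is `CN(x) = C_flank - a * f * F(x)` and the
#' expected RDR is `log2(CN(x) / C_flank)`.
#'
#' @param f Lymphocyte fraction (of all cells) in the unit interval.
#' @param curve A `deletion_curve`.
#' @param ctx A `purity_cn_context`.
#' @param ax Deletion-axis position(s) (see [deletion_axis()]).
#' @param a Deleted alleles per rearranged cell (2 for V(D)J).
#' @return Expected log2 RDR at `ax`.
#' @export
expected_log2_rdr <- function(f, curve, ctx, ax, a = 2) {
  stopifnot(inherits(curve, "deletion_curve"),
            inherits(ctx, "purity_cn_context"))
  if (f < 0 || f > 1) stop("f must be in [0, 1]", call. = FALSE)
  cn <- ctx$c_flank - a * f * curve$eval(ax)
  if (any(cn <= 0)) {
    stop("expected copy number non-positive: f too large for this context",
         call. = FALSE)
  }
  log2(cn / ctx$c_flank)
}

# Variance of each pool's weighted mean, for usage moderation.
pool_mean_variance <- function(pooled) {
  ids <- sort(unique(pooled$pool_id))
  out <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    sel <- pooled$pool_id == ids[k]
    w <- pooled$w[sel]; d <- pooled$d[sel]
    if (length(d) < 2) { out[k] <- 0; next }
    dbar <- sum(w * d) / sum(w)
    denom <- sum(w) - sum(w^2) / sum(w)
    s2 <- if (denom > 0) sum(w * (d - dbar)^2) / denom else 0
    out[k] <- s2 * sum(w^2) / sum(w)^2
  }
  out
}

# Pool bins between consecutive segment boundaries on the deletion axis.
# Returns a list describing the pooling used by the two-stage fit.
pool_profile <- function(profile, locus, a = 2, ctx = purity_cn_context()) {
  vs <- segments_of(locus, "V")
  js <- segments_of(locus, "J")
  v_ends <- vs$axis_end
  j_starts <- js$axis_start
  n_v <- length(v_ends); n_j <- length(j_starts)

  keep <- is.finite(profile$log2_rdr) & profile$weight > 0
  # IGH: the constant region lies past the J cluster and is shaped by class
  # switching, not V(D)J deletion -- exclude it (flank beyond it is kept).
  cst <- segments_of(locus, "CONSTANT")
  if (nrow(cst) > 0) {
    cs_lo <- min(cst$axis_start) - 1000
    cs_hi <- max(cst$axis_end) + 1000
    keep <- keep & !(profile$axis_mid > cs_lo & profile$axis_mid < cs_hi)
  }
  p <- profile[keep, ]
  # plug-in estimate of f * F(x) per bin
  d <- ctx$c_flank * (1 - 2^p$log2_rdr) / a
  breaks <- c(v_ends, j_starts)
  pool_id <- findInterval(p$axis_mid, breaks)   # 0 .. n_v + n_j
  list(d = d, w = p$weight, pool_id = pool_id, n_v = n_v, n_j = n_j,
       n_bins = nrow(p), v_names = vs$name, j_names = js$name)
}

# Plateau-profiled shape-constrained fit on pooled values.
# Returns fraction, per-pool fitted values and usage estimates.
fit_plateau <- function(pooled, f_max) {
  n_v <- pooled$n_v; n_j <- pooled$n_j
  means <- tapply(pooled$d * pooled$w, pooled$pool_id, sum) /
    tapply(pooled$w, pooled$pool_id, sum)
  wsum <- tapply(pooled$w, pooled$pool_id, sum)
  ids <- as.integer(names(means))

  v_ids <- ids[ids < n_v]            # pools 0 .. n_v-1 (V side incl. pre-flank)
  i_ids <- ids[ids == n_v]           # interior plateau pool
  j_ids <- ids[ids > n_v]            # J side incl. post flank
  vy <- means[as.character(v_ids)]; vw <- wsum[as.character(v_ids)]
  jy <- means[as.character(j_ids)]; jw <- wsum[as.character(j_ids)]
  iy <- if (length(i_ids)) means[as.character(i_ids)] else NA_real_
  iw <- if (length(i_ids)) wsum[as.character(i_ids)] else 0

  vfit0 <- if (length(vy)) pava(vy, vw, increasing = TRUE) else numeric(0)
  jfit0 <- if (length(jy)) pava(jy, jw, increasing = FALSE) else numeric(0)

  obj <- function(m) {
    vf <- pmax(pmin(vfit0, m), 0)
    jf <- pmax(pmin(jfit0, m), 0)
    s <- 0
    if (length(vf)) s <- s + sum(vw * (vy - vf)^2)
    if (iw > 0) s <- s + iw * (iy - m)^2
    if (length(jf)) s <- s + sum(jw * (jy - jf)^2)
    s
  }
  opt <- stats::optimize(obj, c(0, f_max), tol = 1e-10)
  m <- opt$minimum
  for (cand in c(0, f_max)) if (obj(cand) < obj(m)) m <- cand

  vfit <- pmax(pmin(vfit0, m), 0)
  jfit <- pmax(pmin(jfit0, m), 0)

  # per-pool fitted values over the full pool index 0..n_v+n_j, carrying the
  # previous value through empty pools so increments telescope
  vals <- rep(NA_real_, n_v + n_j + 1)
  vals[v_ids + 1] <- vfit
  vals[n_v + 1] <- m
  vals[j_ids + 1] <- jfit
  for (k in seq_along(vals)) {
    if (is.na(vals[k])) vals[k] <- if (k == 1) 0 else vals[k - 1]
  }
  p_inc <- pmax(diff(vals[1:(n_v + 1)]), 0)
  q_dec <- pmax(-diff(vals[(n_v + 1):(n_v + n_j + 1)]), 0)
  list(fraction = m, vals = vals, p_inc = p_inc, q_dec = q_dec,
       objective_d = obj(m))
}

normalise_simplex <- function(u, floor = 1e-6) {
  u[u < floor] <- 0
  s <- sum(u)
  if (s <= 0) rep(1 / length(u), length(u)) else u / s
}

# Empirical-Bayes moderation of a usage estimate: shrink towards the uniform
# distribution by the fraction of the observed between-segment variance that
# is attributable to measurement noise. Noiseless data is left untouched.
eb_moderate_usage <- function(u, noise_var) {
  k <- length(u)
  if (k < 2) return(u)
  s2 <- stats::var(u)
  if (!is.finite(s2) || s2 <= 0) return(rep(1 / k, k))
  lambda <- max(0, 1 - mean(noise_var) / s2)
  lambda * u + (1 - lambda) / k
}

#' Fit lymphocyte fraction and segment usage from an RDR profile
#'
#' The core estimator. Each bin's RDR is transformed to
#' `d(x) = C_flank * (1 - 2^RDR) / a`, an unbiased plug-in for `f * F(x)`
#' under the deletion model; bins are pooled between consecutive segment
#' boundaries on the deletion axis; the pooled values are fitted by weighted
#' isotonic regression (pool-adjacent-violators) constrained non-decreasing
#' across the V region, tied to a common plateau over the V-J interior and
#' non-increasing across the J region. The plateau value is the lymphocyte
#' fraction estimate; V/J usage is read off the isotonic increments at each
#' segment boundary and renormalised to the simplex. A bootstrap over bins
#' (resampled within pools, fixed seed) gives a percentile confidence
#' interval for the fraction.
#'
#' Fractions below `zero_threshold` (default 1e-4) are reported as zero with
#' the `zero_fraction` flag and uniform usage vectors.
#'
#' @param profile A `vdj_ratio_profile`.
#' @param locus The matching `locus_definition`.
#' @param ctx A `purity_cn_context`; default is a pure normal sample.
#' @param a Deleted alleles per rearranged cell (2: both alleles).
#' @param boot_n Bootstrap resamples for the CI (0 disables).
#' @param boot_seed Seed for the bootstrap RNG.
#' @param zero_threshold Fraction below which the fit is flagged zero.
#' @param moderate_usage Apply empirical-Bayes moderation to the usage
#'   vectors: shrink towards uniform by the estimated share of
#'   between-segment variance due to measurement noise (no effect on
#'   noiseless data).
#' @return A `vdj_fit` object; see [tidy.vdj_fit()] and [glance.vdj_fit()].
#' @examples
#' locus <- load_locus_definition("TCRG")
#' truth <- sim_truth("TCRG", f = 0.15, depth = 30, seed = 42)
#' track <- simulate_coverage(truth, locus)
#' prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
#' fit <- fit_vdj(prof, locus, boot_n = 50)
#' fit$fraction
#' @export
fit_vdj <- function(profile, locus, ctx = purity_cn_context(), a = 2,
                    boot_n = 200, boot_seed = 1234, zero_threshold = 1e-4,
                    moderate_usage = TRUE) {
  stopifnot(inherits(profile, "vdj_ratio_profile"),
            inherits(locus, "locus_definition"),
            inherits(ctx, "purity_cn_context"))
  pooled <- pool_profile(profile, locus, a = a, ctx = ctx)
  if (pooled$n_bins < 20) {
    stop("need >= 20 usable bins to fit (got ", pooled$n_bins, ")",
         call. = FALSE)
  }
  f_max <- min(1, ctx$c_flank / a * 0.999)
  fit <- fit_plateau(pooled, f_max)
  f_hat <- min(max(fit$fraction, 0), 1)
  zero <- f_hat < zero_threshold

  if (zero) {
    p <- rep(1 / pooled$n_v, pooled$n_v)
    q <- rep(1 / pooled$n_j, pooled$n_j)
    f_hat <- 0
  } else {
    p <- normalise_simplex(fit$p_inc)
    q <- normalise_simplex(fit$q_dec)
    if (moderate_usage) {
      pv <- pool_mean_variance(pooled)
      var_of <- function(id) {
        v <- pv[as.character(id)]
        ifelse(is.na(v), 0, v)
      }
      sp <- sum(fit$p_inc); sq <- sum(fit$q_dec)
      if (sp > 0) {
        nv_inc <- (var_of(seq_len(pooled$n_v) - 1) +
                     var_of(seq_len(pooled$n_v))) / sp^2
        p <- normalise_simplex(eb_moderate_usage(p, nv_inc))
      }
      if (sq > 0) {
        nv_dec <- (var_of(pooled$n_v + seq_len(pooled$n_j) - 1) +
                     var_of(pooled$n_v + seq_len(pooled$n_j))) / sq^2
        q <- normalise_simplex(eb_moderate_usage(q, nv_dec))
      }
    }
  }
  names(p) <- pooled$v_names
  names(q) <- pooled$j_names

  # weighted RSS of the refit forward model on the RDR scale
  dfit_bin <- fit$vals[pooled$pool_id + 1]
  exp_rdr <- log2(pmax(ctx$c_flank - a * dfit_bin, 1e-9) / ctx$c_flank)
  used <- pool_profile_bins(profile, locus)
  objective <- sum(pooled$w * (profile$log2_rdr[used] - exp_rdr)^2)

  ci <- c(NA_real_, NA_real_)
  boot <- numeric(0)
  if (boot_n > 0) {
    boot <- boot_fraction(pooled, f_max, boot_n, boot_seed)
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    ci[1] <- min(ci[1], f_hat)
    ci[2] <- max(ci[2], f_hat)
  }

  structure(list(
    locus = locus$locus, fraction = f_hat, v_usage = p, j_usage = q,
    ci_lower = ci[1], ci_upper = ci[2], objective = objective,
    n_bins_used = pooled$n_bins, converged = TRUE, zero_fraction = zero,
    ctx = ctx, a = a, boot = boot,
    pool_fit = tibble::tibble(pool = seq_along(fit$vals) - 1,
                              fitted_d = fit$vals)),
    class = "vdj_fit")
}

# indices of profile bins used by pool_profile (same filtering)
pool_profile_bins <- function(profile, locus) {
  keep <- is.finite(profile$log2_rdr) & profile$weight > 0
  cst <- segments_of(locus, "CONSTANT")
  if (nrow(cst) > 0) {
    cs_lo <- min(cst$axis_start) - 1000
    cs_hi <- max(cst$axis_end) + 1000
    keep <- keep & !(profile$axis_mid > cs_lo & profile$axis_mid < cs_hi)
  }
  which(keep)
}

boot_fraction <- function(pooled, f_max, boot_n, boot_seed) {
  split_idx <- split(seq_along(pooled$d), pooled$pool_id)
  withr::with_seed(boot_seed, {
    vapply(seq_len(boot_n), function(b) {
      idx <- unlist(lapply(split_idx, function(ii) {
        if (length(ii) == 1) ii else sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      rp <- list(d = pooled$d[idx], w = pooled$w[idx],
                 pool_id = pooled$pool_id[idx], n_v = pooled$n_v,
                 n_j = pooled$n_j)
      min(max(fit_plateau(rp, f_max)$fraction, 0), 1)
    }, numeric(1))
  })
}

#' @export
print.vdj_fit <- function(x, ...) {
  cat("<vdj_fit> ", x$locus, "\n", sep = "")
  cat(sprintf("  fraction: %.4f", x$fraction))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  (95%% CI %.4f-%.4f)", x$ci_lower, x$ci_upper))
  }
  cat("\n")
  if (x$zero_fraction) cat("  flagged: zero fraction (usage undefined)\n")
  cat(sprintf("  bins used: %d  objective: %.3g\n", x$n_bins_used,
              x$objective))
  invisible(x)
}

#' Report the fitted fraction on a chosen denominator
#'
#' In a tumour sample the fitted fraction counts lymphocytes among *all*
#' cells. `denominator = "nontumor_cells"` rescales to the non-tumour
#' compartment, `f / (1 - rho)`.
#'
#' @param fit A converged `vdj_fit`.
#' @param ctx A `purity_cn_context` (defaults to the one used in the fit).
#' @param denominator `"all_cells"` or `"nontumor_cells"`.
#' @return A named numeric value; the name records the denominator.
#' @export
adjust_reported_fraction <- function(fit, ctx = fit$ctx,
                                     denominator = c("all_cells",
                                                     "nontumor_cells")) {
  denominator <- match.arg(denominator)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (denominator == "all_cells") {
    return(stats::setNames(fit$fraction, "all_cells"))
  }
  if (ctx$purity >= 1) {
    stop("nontumor_cells denominator undefined at purity 1", call. = FALSE)
  }
  stats::setNames(fit$fraction / (1 - ctx$purity), "nontumor_cells")
}
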