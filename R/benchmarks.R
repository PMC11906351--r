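#' Recovery benchmarks
#'
#' Reproducible end-to-end benchmarks used by the validation suite: they
#' simulate cohorts with known truth, run the full normalise-and-fit pipeline
#' on each sample, and return truth and estimate side by side. Samples are
#' processed one at a time so memory stays flat.
#'
#' `benchmark_vdj_recovery` simulates lymphocyte fractions uniform on
#' `f_range` at the first depth in `depths`, then binomially thins the same
#' track to each further depth, fitting at every depth.
#'
#' @param n Number of simulated samples.
#' @param locus_name Locus to simulate (default TCRA).
#' @param depths Vector of mean depths; the first is simulated, the rest are
#'   obtained by thinning.
#' @param f_range Uniform range for the true fraction.
#' @param seed Master seed.
#' @return A tibble with `sample`, `f_true`, `depth`, `f_hat`.
#' @export
benchmark_vdj_recovery <- function(n = 100, locus_name = "TCRA",
                                   depths = c(30, 5), f_range = c(0, 0.5),
                                   seed = 1L) {
  locus <- load_locus_definition(locus_name)
  pars <- withr::with_seed(seed, data.frame(
    f = stats::runif(n, f_range[1], f_range[2]),
    sim_seed = sample.int(2^30, n),
    thin_seed = sample.int(2^30, n)))
  rows <- vector("list", n * length(depths))
  for (i in seq_len(n)) {
    truth <- sim_truth(locus_name, f = pars$f[i], depth = depths[1],
                       seed = pars$sim_seed[i])
    track <- simulate_coverage(truth, locus)
    gc <- attr(track, "gc")
    for (d in seq_along(depths)) {
      tr_d <- if (d == 1) track
              else downsample_track(track, depths[d],
                                    seed = pars$thin_seed[i] + d)
      prof <- ratio_profile(tr_d, locus, gc = gc)
      fit <- fit_vdj(prof, locus, boot_n = 0)
      rows[[(i - 1) * length(depths) + d]] <- tibble::tibble(
        sample = i, f_true = pars$f[i], depth = depths[d],
        f_hat = fit$fraction)
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname benchmark_vdj_recovery
#' @details `benchmark_class_switch` simulates IGH samples with B fractions
#'   uniform on `f_range` and Dirichlet(1) isotype mixtures, and reports the
#'   true and estimated IgM/IgD, IgG and IgA aggregates.
#' @param depth Simulated mean depth.
#' @return For `benchmark_class_switch`: a tibble with per-sample true and
#'   estimated aggregates and an `order_ok` flag (class-switched versus
#'   non-switched ordering preserved).
#' @export
benchmark_class_switch <- function(n = 50, f_range = c(0.02, 0.2),
                                   depth = 30, seed = 1L) {
  locus <- load_locus_definition("IGH")
  cls <- isotype_classes()
  pars <- withr::with_seed(seed, list(
    f = stats::runif(n, f_range[1], f_range[2]),
    pi = lapply(seq_len(n), function(i) rdirichlet(rep(1, 8))),
    sim_seed = sample.int(2^30, n)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pi_t <- stats::setNames(pars$pi[[i]], cls$class)
    truth <- sim_truth("IGH", f = pars$f[i], isotype = pi_t, depth = depth,
                       seed = pars$sim_seed[i])
    track <- simulate_coverage(truth, locus)
    prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
    fit <- fit_vdj(prof, locus, boot_n = 0)
    cs <- fit_class_switch(prof, fit, locus = locus)
    igg_t <- pars$f[i] * sum(pi_t[c("IgG3", "IgG1", "IgG2", "IgG4")])
    iga_t <- pars$f[i] * sum(pi_t[c("IgA1", "IgA2")])
    igm_t <- pars$f[i] * pi_t[["IgM/IgD"]]
    sw_t <- pars$f[i] - igm_t
    rows[[i]] <- tibble::tibble(
      sample = i, f_b_true = pars$f[i], f_b_hat = fit$fraction,
      igm_true = igm_t, igm_hat = unname(cs$igm_igd),
      igg_true = igg_t, igg_hat = unname(cs$igg),
      iga_true = iga_t, iga_hat = unname(cs$iga),
      order_ok = (sw_t > igm_t) == (cs$class_switched > cs$igm_igd))
  }
  dplyr::bind_rows(rows)
}

#' @rdname benchmark_vdj_recovery
#' @details `benchmark_germline_cnv` simulates germline IGH samples carrying
#'   heterozygous or homozygous constant-region CNVs across a depth grid and
#'   scores the integer copy-number calls of every constant gene.
#' @param n_per Samples per depth.
#' @return For `benchmark_germline_cnv`: a tibble with one row per sample x
#'   constant gene: `depth`, `region`, `cn_true`, `cn_called`,
#'   `low_confidence`.
#' @export
benchmark_germline_cnv <- function(depths = c(2, 5, 10, 20, 30), n_per = 6,
                                   seed = 1L) {
  locus <- load_locus_definition("IGH")
  genes <- isotype_classes()$gene
  grid <- expand.grid(depth = depths, rep = seq_len(n_per))
  pars <- withr::with_seed(seed, lapply(seq_len(nrow(grid)), function(i) {
    gene <- sample(genes, 1)
    list(gene = gene, cn = sample(c(0L, 1L, 3L), 1),
         sim_seed = sample.int(2^30, 1))
  }))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cn_vec <- stats::setNames(pars[[i]]$cn, pars[[i]]$gene)
    truth <- sim_truth("IGH", f = 0.05, germline_cn = as.list(cn_vec),
                       depth = grid$depth[i], seed = pars[[i]]$sim_seed)
    track <- simulate_coverage(truth, locus)
    prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
    calls <- call_germline_cnv(prof, locus)
    cc <- calls[calls$kind == "CONSTANT", ]
    truth_cn <- ifelse(cc$region == pars[[i]]$gene, pars[[i]]$cn, 2L)
    rows[[i]] <- tibble::tibble(
      depth = grid$depth[i], region = cc$region, cn_true = truth_cn,
      cn_called = cc$cn, low_confidence = attr(calls, "low_confidence"))
  }
  dplyr::bind_rows(rows)
}

#' @rdname benchmark_vdj_recovery
#' @details `benchmark_purity_adjustment` simulates tumour mixtures over a
#'   purity and local-copy-number grid and reports the purity/CN-adjusted
#'   all-cells immune fraction against truth.
#' @param purities,tumor_cns Tumour purity and local CN grids.
#' @return For `benchmark_purity_adjustment`: a tibble with `purity`,
#'   `tumor_cn`, `f_true`, `f_hat`.
#' @export
benchmark_purity_adjustment <- function(purities = c(0.3, 0.6),
                                        tumor_cns = 1:4, n_per = 2,
                                        depth = 30, locus_name = "TCRA",
                                        seed = 1L) {
  locus <- load_locus_definition(locus_name)
  grid <- expand.grid(purity = purities, tumor_cn = tumor_cns,
                      rep = seq_len(n_per))
  pars <- withr::with_seed(seed, data.frame(
    f = stats::runif(nrow(grid), 0.02, 0.25),
    sim_seed = sample.int(2^30, nrow(grid))))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    truth <- sim_truth(locus_name, f = pars$f[i], purity = grid$purity[i],
                       tumor_cn = grid$tumor_cn[i], depth = depth,
                       seed = pars$sim_seed[i])
    track <- simulate_coverage(truth, locus)
    prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
    ctx <- purity_cn_context(grid$purity[i], grid$tumor_cn[i])
    fit <- fit_vdj(prof, locus, ctx, boot_n = 0)
    rows[[i]] <- tibble::tibble(
      purity = grid$purity[i], tumor_cn = grid$tumor_cn[i],
      f_true = pars$f[i],
      f_hat = unname(adjust_reported_fraction(fit, ctx, "all_cells")))
  }
  dplyr::bind_rows(rows)
}

#' Brute-force least-squares oracle for the segment-step model
#'
#' Exhaustive grid search over fraction and V/J usage simplices, evaluating
#' the weighted least-squares objective of the forward model directly. Only
#' feasible for toy loci; used to certify that the two-stage isotonic
#' estimator attains the global optimum.
#'
#' @param profile A `vdj_ratio_profile`.
#' @param locus The matching (small) `locus_definition`.
#' @param ctx A `purity_cn_context`.
#' @param f_grid Grid of candidate fractions.
#' @param simplex_step Resolution of the usage simplex grids.
#' @return A list with `objective` (best weighted RSS) and `par`.
#' @export
vdj_grid_oracle <- function(profile, locus, ctx = purity_cn_context(),
                            f_grid = seq(0, 0.5, by = 0.01),
                            simplex_step = 0.1) {
  n_v <- nrow(segments_of(locus, "V"))
  n_j <- nrow(segments_of(locus, "J"))
  p_grid <- simplex_lattice(n_v, simplex_step)
  q_grid <- simplex_lattice(n_j, simplex_step)
  used <- is.finite(profile$log2_rdr) & profile$weight > 0
  ax <- profile$axis_mid[used]
  rdr <- profile$log2_rdr[used]
  w <- profile$weight[used]
  best <- Inf; best_par <- NULL
  for (f in f_grid) {
    for (pi in seq_len(nrow(p_grid))) {
      for (qi in seq_len(nrow(q_grid))) {
        curve <- deletion_curve(locus, as.numeric(p_grid[pi, ]),
                                as.numeric(q_grid[qi, ]))
        expd <- log2(pmax(ctx$c_flank - 2 * f * curve$eval(ax), 1e-9) /
                       ctx$c_flank)
        obj <- sum(w * (rdr - expd)^2)
        if (obj < best) {
          best <- obj
          best_par <- list(f = f, p = as.numeric(p_grid[pi, ]),
                           q = as.numeric(q_grid[qi, ]))
        }
      }
    }
  }
  list(objective = best, par = best_par)
}

# regular lattice on the probability simplex
simplex_lattice <- function(k, step) {
  n <- round(1 / step)
  combos <- expand.grid(rep(list(0:n), k - 1))
  keep <- rowSums(combos) <= n
  combos <- as.matrix(combos[keep, , drop = FALSE])
  unname(cbind(combos, n - rowSums(combos)) * step)
}
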