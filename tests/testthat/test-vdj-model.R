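test_that("expected RDR matches closed forms", {
  locus <- toy_locus()
  curve <- deletion_curve(locus, c(0.5, 0.3, 0.2), c(0.6, 0.4))
  ctx0 <- purity_cn_context()
  interior <- deletion_axis(locus, 25000)   # F = 1 between last V and first J
  expect_equal(curve$eval(interior), 1)

  # f = 0: zero everywhere
  ax <- deletion_axis(locus, seq(2000, 58000, by = 1000))
  expect_equal(expected_log2_rdr(0, curve, ctx0, ax), rep(0, length(ax)))

  # no tumour, f = 0.5 at F = 1: log2(1 - 0.5) = -1
  expect_equal(expected_log2_rdr(0.5, curve, ctx0, interior), -1)

  # tumour context: C_flank = rho n_t + (1 - rho) n_g = 0.6*3 + 0.4*2 = 2.6;
  # f = 0.1, F = 1 -> log2((2.6 - 0.2)/2.6)
  ctx_t <- purity_cn_context(purity = 0.6, tumor_cn = 3)
  expect_equal(ctx_t$c_flank, 2.6)
  expect_equal(expected_log2_rdr(0.1, curve, ctx_t, interior),
               log2(2.4 / 2.6))

  # domain error when the implied copy number is non-positive
  ctx_small <- purity_cn_context(purity = 0.9, tumor_cn = 0.5)
  expect_error(expected_log2_rdr(0.4, curve, ctx_small, interior),
               "non-positive")
})

test_that("weighted PAVA solves monotone least squares", {
  # against stats::isoreg on unweighted data
  set.seed(2)
  y <- cumsum(rnorm(50)) / 10
  expect_equal(pava(y), stats::isoreg(y)$yf)
  # weighted: verify KKT via small perturbations of the fit
  w <- runif(50, 0.5, 2)
  fit <- pava(y, w)
  obj <- function(v) sum(w * (y - v)^2)
  expect_true(all(diff(fit) >= -1e-12))
  base <- obj(fit)
  for (k in c(10, 25, 40)) {
    v <- fit
    v[seq_len(k)] <- v[seq_len(k)] - 1e-4  # stays monotone
    expect_gte(obj(v), base - 1e-12)
  }
  # antitonic is the reversal
  expect_equal(pava(y, w, increasing = FALSE), rev(pava(rev(y), rev(w))))
})

test_that("two-stage estimator attains the grid-search optimum on a noiseless toy locus", {
  locus <- toy_locus(3, 2)
  p_true <- c(0.5, 0.3, 0.2); q_true <- c(0.6, 0.4)
  track <- noiseless_track(locus, f = 0.3, p_true, q_true)
  prof <- ratio_profile(track, locus, bin_size = 1000,
                        boundary_downweight = 0)
  fit <- fit_vdj(prof, locus, boot_n = 0)
  expect_equal(fit$fraction, 0.3, tolerance = 1e-4)
  expect_equal(unname(fit$v_usage), p_true, tolerance = 1e-3)
  expect_equal(unname(fit$j_usage), q_true, tolerance = 1e-3)

  oracle <- grid_search_objective(prof, locus, f_grid = seq(0.2, 0.4, 0.01),
                                  simplex_step = 0.1)
  expect_lte(fit$objective, oracle$objective + 1e-6)
})

test_that("a flat profile yields a flagged zero fraction", {
  locus <- toy_locus()
  pos <- seq(locus$span_start, locus$span_end)
  prof <- ratio_profile(coverage_track("chr1", pos, rep(30, length(pos))),
                        locus)
  fit <- fit_vdj(prof, locus, boot_n = 0)
  expect_lt(fit$fraction, 1e-4)
  expect_true(fit$zero_fraction)
  expect_equal(unname(fit$v_usage), rep(1 / 3, 3))
})

test_that("fractions are recovered from Poisson simulations", {
  locus <- load_locus_definition("TCRG")
  for (f in c(0.05, 0.2, 0.4)) {
    truth <- sim_truth("TCRG", f = f, depth = 30, seed = round(1000 * f))
    track <- simulate_coverage(truth, locus)
    prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
    fit <- fit_vdj(prof, locus, boot_n = 30)
    expect_lt(abs(fit$fraction - f), 0.02)
    # simplex + CI invariants
    expect_equal(sum(fit$v_usage), 1, tolerance = 1e-8)
    expect_equal(sum(fit$j_usage), 1, tolerance = 1e-8)
    expect_true(all(fit$v_usage >= 0) && all(fit$j_usage >= 0))
    expect_lte(fit$ci_lower, fit$fraction)
    expect_gte(fit$ci_upper, fit$fraction)
  }
})

test_that("fitted deletion plateau is monotone by construction", {
  locus <- load_locus_definition("TCRG")
  truth <- sim_truth("TCRG", f = 0.25, depth = 10, seed = 9)
  track <- simulate_coverage(truth, locus)
  prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
  fit <- fit_vdj(prof, locus, boot_n = 0)
  n_v <- nrow(locus$segments[locus$segments$kind == "V", ])
  vals <- fit$pool_fit$fitted_d
  expect_true(all(diff(vals[seq_len(n_v + 1)]) >= -1e-12))
  expect_true(all(diff(vals[(n_v + 1):length(vals)]) <= 1e-12))
  expect_true(all(vals >= 0) && all(vals <= fit$fraction + 1e-12))
})

test_that("purity/local-CN context recovers the all-cells fraction in tumours", {
  locus <- load_locus_definition("TCRA")
  truth <- sim_truth("TCRA", f = 0.1, purity = 0.6, tumor_cn = 3,
                     depth = 30, seed = 21)
  track <- simulate_coverage(truth, locus)
  prof <- ratio_profile(track, locus, gc = attr(track, "gc"))
  ctx <- purity_cn_context(purity = 0.6, tumor_cn = 3)
  fit <- fit_vdj(prof, locus, ctx, boot_n = 0)
  expect_lt(abs(adjust_reported_fraction(fit, ctx, "all_cells") - 0.1), 0.02)
})

test_that("reported-fraction denominators follow the purity arithmetic", {
  locus <- toy_locus()
  track <- noiseless_track(locus, 0.1, c(0.4, 0.3, 0.3), c(0.5, 0.5))
  prof <- ratio_profile(track, locus, bin_size = 1000,
                        boundary_downweight = 0)
  fit <- fit_vdj(prof, locus, boot_n = 0)

  # rho = 0: both denominators agree
  expect_equal(unname(adjust_reported_fraction(fit, denominator = "all_cells")),
               unname(adjust_reported_fraction(fit,
                                               denominator = "nontumor_cells")))
  # f = 0.1, rho = 0.5: non-tumour denominator doubles it
  ctx5 <- purity_cn_context(purity = 0.5)
  expect_equal(unname(adjust_reported_fraction(fit, ctx5, "nontumor_cells")),
               fit$fraction / 0.5)
  ctx1 <- purity_cn_context(purity = 1, tumor_cn = 2)
  expect_error(adjust_reported_fraction(fit, ctx1, "nontumor_cells"),
               "purity 1")
})
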