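blood_pi <- c(0.80, 0.04, 0.05, 0.04, 0.02, 0.01, 0.02, 0.02)

test_that("switch survival matches brute-force enumeration", {
  igh <- load_locus_definition("IGH")
  cls <- isotype_classes()

  # all IgM/IgD: nothing deleted
  pi0 <- c(1, rep(0, 7))
  for (g in cls$gene) expect_equal(switch_survival(pi0, g, igh), 0)

  # all IgA2: every upstream gene deleted, IGHA2 itself retained
  pi7 <- c(rep(0, 7), 1)
  for (g in setdiff(cls$gene, "IGHA2")) {
    expect_equal(switch_survival(pi7, g, igh), 1)
  }
  expect_equal(switch_survival(pi7, "IGHA2", igh), 0)
  expect_equal(switch_survival(pi7, "IGHD", igh), 1)  # shares rank 0 with IGHM

  # random mixtures against an independent enumeration oracle
  set.seed(12)
  for (rep in 1:5) {
    p <- rgamma(8, 1); p <- p / sum(p)
    for (g in c("IGHM", "IGHG1", "IGHG4", "IGHA2")) {
      r <- cls$rank[cls$gene == g]
      oracle <- sum(p[which(cls$rank > r)])
      expect_equal(switch_survival(p, g, igh), oracle)
    }
  }
  expect_error(switch_survival(pi0, "IGHZ9", igh), "unknown constant gene")
})

igh_profile <- function(truth, igh) {
  track <- simulate_coverage(truth, igh)
  ratio_profile(track, igh, gc = attr(track, "gc"))
}

test_that("germline CNV calls recover simulated constant-region CNVs", {
  igh <- load_locus_definition("IGH")

  # diploid at 30x: all constant genes CN 2, unmasked, confident
  prof <- igh_profile(sim_truth("IGH", f = 0.05, depth = 30, seed = 31), igh)
  calls <- call_germline_cnv(prof, igh)
  cc <- calls[calls$kind == "CONSTANT", ]
  expect_true(all(cc$cn == 2))
  expect_false(any(cc$masked))
  expect_false(attr(calls, "low_confidence"))

  # heterozygous IGHG4 deletion at 30x: CN 1 called and masked
  prof_del <- igh_profile(sim_truth("IGH", f = 0.05, depth = 30, seed = 32,
                                    germline_cn = c(IGHG4 = 1)), igh)
  calls_del <- call_germline_cnv(prof_del, igh)
  expect_equal(calls_del$cn[calls_del$region == "IGHG4"], 1L)
  expect_true(calls_del$masked[calls_del$region == "IGHG4"])
  expect_true(all(calls_del$cn[calls_del$kind == "CONSTANT" &
                                 calls_del$region != "IGHG4"] == 2))

  # homozygous deletion and duplication are representable too
  prof_multi <- igh_profile(sim_truth("IGH", f = 0.05, depth = 30, seed = 33,
                                      germline_cn = c(IGHG4 = 0, IGHA2 = 3)),
                            igh)
  calls_multi <- call_germline_cnv(prof_multi, igh)
  expect_equal(calls_multi$cn[calls_multi$region == "IGHG4"], 0L)
  expect_equal(calls_multi$cn[calls_multi$region == "IGHA2"], 3L)

  # the same deletion at 2x carries the low-confidence flag
  prof_low <- igh_profile(sim_truth("IGH", f = 0.05, depth = 2, seed = 34,
                                    germline_cn = c(IGHG4 = 1)), igh)
  calls_low <- call_germline_cnv(prof_low, igh)
  expect_true(attr(calls_low, "low_confidence"))

  # absent normal: unmasked with a warning
  expect_warning(calls_na <- call_germline_cnv(NULL, igh), "unmasked")
  expect_false(any(calls_na$masked))
})

test_that("class-switch decomposition recovers a blood-like isotype mixture", {
  igh <- load_locus_definition("IGH")
  truth <- sim_truth("IGH", f = 0.08, isotype = blood_pi, depth = 30,
                     seed = 41)
  prof <- igh_profile(truth, igh)
  fit <- fit_vdj(prof, igh, boot_n = 0)
  cs <- fit_class_switch(prof, fit, locus = igh)

  f_b <- 0.08
  expect_lt(abs(cs$igm_igd - f_b * 0.80), 0.02)
  expect_lt(abs(cs$igg - f_b * 0.12), 0.02)
  expect_lt(abs(cs$iga - f_b * 0.06), 0.02)
  # conservation and simplex invariants
  expect_equal(unname(cs$igm_igd + cs$class_switched), cs$b_fraction,
               tolerance = 1e-8)
  expect_equal(sum(cs$isotype_props), 1, tolerance = 1e-8)
  expect_true(all(cs$isotype_props >= 0))
  # fitted survival is monotone non-increasing along switch order
  expect_true(all(diff(cs$survival$survival) <= 1e-12))
})

test_that("switched-dominant samples keep their ordering and IgM-only samples stay unswitched", {
  igh <- load_locus_definition("IGH")
  # tumour-like enrichment of IgA/IgG switched B cells
  pi_sw <- c(0.15, 0.10, 0.25, 0.20, 0.10, 0.05, 0.02, 0.13)
  truth <- sim_truth("IGH", f = 0.10, isotype = pi_sw, depth = 30, seed = 42)
  prof <- igh_profile(truth, igh)
  cs <- fit_class_switch(prof, fit_vdj(prof, igh, boot_n = 0), locus = igh)
  expect_gt(cs$class_switched, cs$igm_igd)

  # all IgM/IgD: class-switched fraction at most 1% of f_B
  truth0 <- sim_truth("IGH", f = 0.10, isotype = c(1, rep(0, 7)), depth = 30,
                      seed = 43)
  prof0 <- igh_profile(truth0, igh)
  cs0 <- fit_class_switch(prof0, fit_vdj(prof0, igh, boot_n = 0), locus = igh)
  expect_lte(cs0$class_switched, 0.01 * cs0$b_fraction)
})

test_that("a vanishing B fraction flags the decomposition as undefined", {
  igh <- load_locus_definition("IGH")
  pos <- seq(igh$span_start, igh$span_end)
  flat <- coverage_track("chr14", pos, rep(30, length(pos)), locus = "IGH")
  prof <- ratio_profile(flat, igh)
  fit <- fit_vdj(prof, igh, boot_n = 0)
  expect_true(fit$zero_fraction)
  cs <- fit_class_switch(prof, fit, locus = igh)
  expect_true(cs$undefined)
  expect_true(all(is.na(cs$isotype_props)))

  # with Poisson noise at f = 0 the decomposition stays near-unswitched
  truth <- sim_truth("IGH", f = 0, depth = 30, seed = 44)
  prof_n <- igh_profile(truth, igh)
  fit_n <- fit_vdj(prof_n, igh, boot_n = 0)
  cs_n <- fit_class_switch(prof_n, fit_n, locus = igh)
  expect_lt(fit_n$fraction, 0.01)
  if (!cs_n$undefined) expect_lt(cs_n$class_switched, 0.005)
})

test_that("masking a CNV region only perturbs the adjacent isotype classes", {
  igh <- load_locus_definition("IGH")
  truth <- sim_truth("IGH", f = 0.10, isotype = blood_pi, depth = 30,
                     seed = 45)
  prof <- igh_profile(truth, igh)
  fit <- fit_vdj(prof, igh, boot_n = 0)
  cs_full <- fit_class_switch(prof, fit, locus = igh)

  # pretend IGHG2 (rank 4) sits on a germline CNV
  fake_cnv <- tibble::tibble(region = "IGHG2", kind = "CONSTANT", cn = 1L,
                             margin = 1, masked = TRUE, n_bins = 10L)
  class(fake_cnv) <- c("germline_cnv_calls", class(fake_cnv))
  cs_mask <- fit_class_switch(prof, fit, cnv = fake_cnv, locus = igh)
  delta <- abs(cs_mask$isotype_props - cs_full$isotype_props)
  step_at_masked <- cs_full$isotype_props[["IgG2"]]
  expect_true(all(delta[!names(delta) %in% c("IgG2", "IgG4")] <=
                    step_at_masked + 0.02))
})
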