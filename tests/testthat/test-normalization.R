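test_that("binning reproduces brute-force per-bin averages and GC extremes", {
  locus <- toy_locus()
  # constant depth: every full bin averages exactly 30
  flat <- coverage_track("chr1", 1:10000, rep(30, 10000))
  bins <- bin_coverage(flat, locus, bin_size = 1000)
  expect_equal(nrow(bins), 10)
  expect_true(all(bins$depth == 30))

  # random depths: means equal direct averaging oracle
  set.seed(11)
  d <- rpois(10000, 8)
  tr <- coverage_track("chr1", 1:10000, d)
  bins <- bin_coverage(tr, locus, bin_size = 500)
  oracle <- tapply(d, (0:9999) %/% 500, mean)
  expect_equal(bins$depth, as.vector(oracle))

  # GC extremes through a supplied per-position vector
  gc0 <- bin_coverage(tr, locus, bin_size = 500, gc = rep(0, 10000))
  expect_true(all(gc0$gc == 0))
  gc1 <- bin_coverage(tr, locus, bin_size = 500, gc = rep(1, 10000))
  expect_true(all(gc1$gc == 1))

  expect_error(bin_coverage(tr, locus, bin_size = 10), "bin_size")
  expect_error(bin_coverage(coverage_track("chr9", 1:10, rep(1, 10)), locus),
               "chromosome")
})

test_that("GC model is near-identity without bias and flattens a known bias", {
  locus <- toy_locus()
  pos <- seq(locus$span_start, locus$span_end)
  gc <- 0.5 + 0.2 * sin(2 * pi * pos / 20000)

  # no bias: correction within 0.02 on the log2 scale
  flat <- coverage_track("chr1", pos, rep(30, length(pos)))
  bins <- bin_coverage(flat, locus, gc = gc)
  gm <- fit_gc_model(bins)
  expect_lt(max(abs(gm$predict(seq(0.3, 0.7, by = 0.01)))), 0.02)

  # known bias exp(-4 (gc - 0.5)^2): corrected depths flat within 2%
  biased <- coverage_track("chr1", pos, 30 * exp(-4 * (gc - 0.5)^2))
  bins_b <- bin_coverage(biased, locus, gc = gc)
  gm_b <- fit_gc_model(bins_b)
  corrected <- bins_b$depth * 2^(-gm_b$predict(bins_b$gc))
  expect_lt(max(abs(corrected / mean(corrected) - 1)), 0.02)

  # too few baseline bins -> error per the pre-condition
  small <- bins[c(which(bins$baseline)[1:10], which(!bins$baseline)), ]
  class(small) <- class(bins)
  expect_error(fit_gc_model(small), ">= 30 baseline bins")

  # degenerate GC spread -> identity with a warning
  bins_c <- bin_coverage(flat, locus, gc = rep(0.5, length(pos)))
  expect_warning(gm_c <- fit_gc_model(bins_c), "degenerate GC range")
  expect_equal(gm_c$method, "identity")
  expect_equal(gm_c$predict(c(0.3, 0.6)), c(0, 0))
})

test_that("ratio profiles hit the closed-form RDR values", {
  locus <- toy_locus()
  pos <- seq(locus$span_start, locus$span_end)

  # flat 30x track: |log2 RDR| < 0.05 everywhere
  flat <- coverage_track("chr1", pos, rep(30, length(pos)))
  prof <- ratio_profile(flat, locus)
  expect_true(all(abs(prof$log2_rdr) < 0.05))
  expect_equal(attr(prof, "baseline_depth"), 30, tolerance = 1e-6)

  # interior at exactly half the baseline depth: log2 RDR = -1
  interior <- pos > 16000 & pos < 29000
  half <- coverage_track("chr1", pos, ifelse(interior, 15, 30))
  prof2 <- ratio_profile(half, locus)
  mid <- prof2$bin_start > 17000 & prof2$bin_end < 28000
  expect_equal(prof2$log2_rdr[mid], rep(-1, sum(mid)), tolerance = 0.02)
})

test_that("RDR is invariant under depth scaling and GC correction is idempotent", {
  locus <- toy_locus()
  pos <- seq(locus$span_start, locus$span_end)
  gc <- 0.5 + 0.15 * sin(2 * pi * pos / 15000)
  set.seed(4)
  base_depth <- rpois(length(pos), 30 * exp(-1 * (gc - 0.5)^2)) + 1

  prof1 <- ratio_profile(coverage_track("chr1", pos, base_depth), locus,
                         gc = gc)
  prof3 <- ratio_profile(coverage_track("chr1", pos, 3 * base_depth), locus,
                         gc = gc)
  expect_equal(prof1$log2_rdr, prof3$log2_rdr, tolerance = 1e-6)

  # idempotence: re-correcting corrected depths moves them < 1% RMS
  bins <- bin_coverage(coverage_track("chr1", pos, base_depth), locus,
                       gc = gc)
  gm <- fit_gc_model(bins)
  corrected <- bins$depth * 2^(-gm$predict(bins$gc))
  bins2 <- bins
  bins2$depth <- corrected
  bins2$raw_sum <- corrected * bins2$n_pos
  gm2 <- fit_gc_model(bins2)
  twice <- corrected * 2^(-gm2$predict(bins2$gc))
  rms_change <- sqrt(mean((log2(twice) - log2(corrected))^2))
  expect_lt(rms_change, 0.01)
})

test_that("profiles serialise to TSV", {
  locus <- toy_locus()
  pos <- seq(locus$span_start, locus$span_end)
  prof <- ratio_profile(coverage_track("chr1", pos, rep(20, length(pos))),
                        locus)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_profile(prof, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(prof))
  expect_equal(back$log2_rdr, prof$log2_rdr)
})

test_that("GC content can be computed from a reference FASTA", {
  locus <- toy_locus()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
               collapse = "")
  writeLines(c(">chr1", seq), fa)
  Rsamtools::indexFa(fa)
  tr <- coverage_track("chr1", 1:60000, rep(20, 60000))
  bins <- bin_coverage(tr, locus, reference = fa)
  gc1 <- mean(strsplit(substr(seq, 1, 500), "")[[1]] %in% c("G", "C"))
  expect_equal(bins$gc[1], gc1)
})
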