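test_that("packaged locus definitions load with the GRCh38 windows", {
  tcra <- load_locus_definition("TCRA")
  expect_s3_class(tcra, "locus_definition")
  expect_equal(tcra$chrom, "chr14")
  expect_equal(tcra$span_start, 21621904)
  expect_equal(tcra$span_end, 22752132)
  expect_equal(tcra$orientation, "forward")

  igh <- load_locus_definition("IGH")
  expect_equal(igh$span_start, 105566277)
  expect_equal(igh$span_end, 106879844)
  expect_equal(igh$orientation, "reverse")
  expect_true(all(c("V", "J", "CONSTANT") %in% igh$segments$kind))

  for (l in c("TCRB", "TCRG")) {
    def <- load_locus_definition(l)
    expect_true(all(def$segments$start >= def$span_start))
    expect_true(all(def$segments$end <= def$span_end))
  }
  expect_error(load_locus_definition("TCRD"), "unknown locus")
})

test_that("locus validation rejects malformed segment tables", {
  seg_ok <- data.frame(name = c("V1", "J1"), kind = c("V", "J"),
                       chrom = "chr1", start = c(100, 500),
                       end = c(150, 550))
  # J preceding V on the deletion axis
  seg_bad <- seg_ok
  seg_bad$start <- c(500, 100); seg_bad$end <- c(550, 150)
  expect_error(new_locus_definition("X", "chr1", 1, 1000, "forward", seg_bad),
               "V segment must precede")
  # overlapping same-kind segments
  seg_ov <- data.frame(name = c("V1", "V2", "J1"), kind = c("V", "V", "J"),
                       chrom = "chr1", start = c(100, 120, 500),
                       end = c(150, 170, 550))
  expect_error(new_locus_definition("X", "chr1", 1, 1000, "forward", seg_ov),
               "overlapping V")
  # segment outside the span
  expect_error(new_locus_definition("X", "chr1", 1, 520, "forward", seg_ok),
               "outside locus span")
  # start > end
  seg_rev <- seg_ok; seg_rev$end[1] <- 50
  expect_error(new_locus_definition("X", "chr1", 1, 1000, "forward", seg_rev),
               "start > end")
  # switch_order on a non-constant segment
  seg_so <- seg_ok; seg_so$switch_order <- c(1L, NA)
  expect_error(new_locus_definition("X", "chr1", 1, 1000, "forward", seg_so),
               "switch_order")
})

test_that("a user annotation file with broken ordering is rejected at load", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  bad <- data.frame(name = c("TRAV1", "TRAJ1"), kind = c("V", "J"),
                    chrom = "chr14",
                    start = c(22500000, 21700000),   # J before V
                    end = c(22500499, 21700059),
                    switch_order = c(NA, NA))
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_locus_definition("TCRA", tmp), "precede")
})

test_that("deletion indicator matches brute-force enumeration on a toy locus", {
  locus <- toy_locus(3, 2)
  seg <- locus$segments
  # probe placed after V2 (between V2 end and V3 start)
  x <- 12000
  got <- outer(paste0("TV", 1:3), paste0("TJ", 1:2),
               Vectorize(function(v, j) deletion_indicator(locus, x, v, j)))
  # independent enumeration from raw genomic intervals (forward locus)
  expected <- outer(1:3, 1:2, Vectorize(function(vi, ji) {
    v_end <- seg$end[seg$name == paste0("TV", vi)]
    j_start <- seg$start[seg$name == paste0("TJ", ji)]
    as.integer(x > v_end & x < j_start)
  }))
  expect_equal(got, expected)
  expect_equal(got, rbind(c(1, 1), c(1, 1), c(0, 0)))

  # never deleted upstream of every V end; always deleted in the interior
  expect_true(all(outer(paste0("TV", 1:3), paste0("TJ", 1:2),
    Vectorize(function(v, j) deletion_indicator(locus, 2000, v, j))) == 0))
  expect_true(all(outer(paste0("TV", 1:3), paste0("TJ", 1:2),
    Vectorize(function(v, j) deletion_indicator(locus, 25000, v, j))) == 1))

  expect_error(deletion_indicator(locus, 70000, "TV1", "TJ1"), "outside")
  expect_error(deletion_indicator(locus, 12000, "TJ1", "TJ2"), "not a V")
})

test_that("deletion set is contiguous and pair counts are monotone", {
  locus <- toy_locus(4, 3)
  xs <- seq(locus$span_start, locus$span_end, by = 250)
  vs <- paste0("TV", 1:4); js <- paste0("TJ", 1:3)
  for (v in vs) {
    for (j in js) {
      ind <- vapply(xs, function(x) deletion_indicator(locus, x, v, j),
                    integer(1))
      runs <- rle(ind)
      expect_lte(sum(runs$values == 1), 1)  # one contiguous deleted interval
    }
  }
  counts <- vapply(xs, function(x) {
    sum(outer(vs, js, Vectorize(function(v, j)
      deletion_indicator(locus, x, v, j))))
  }, numeric(1))
  v_region <- xs <= max(locus$segments$end[locus$segments$kind == "V"])
  j_region <- xs >= min(locus$segments$start[locus$segments$kind == "J"])
  expect_true(all(diff(counts[v_region]) >= 0))
  expect_true(all(diff(counts[j_region]) <= 0))
})

test_that("reverse-oriented loci map the deletion axis onto falling coordinates", {
  igh <- load_locus_definition("IGH")
  vs <- igh$segments[igh$segments$kind == "V", ]
  js <- igh$segments[igh$segments$kind == "J", ]
  # V segments sit at higher genomic coordinates than J segments
  expect_gt(min(vs$start), max(js$end))
  # a position genomically above all V segments is never deleted
  x_up <- max(vs$end) + 5000
  expect_equal(deletion_indicator(igh, x_up, vs$name[1], js$name[1]), 0L)
  # a position between the V and J clusters is deleted by every pair
  x_mid <- (min(vs$start) + max(js$end)) %/% 2
  expect_equal(deletion_indicator(igh, x_mid, vs$name[5], js$name[3]), 1L)
})

test_that("BED export writes 0-based half-open records", {
  locus <- toy_locus()
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(locus, tmp)
  bed <- read.delim(tmp, header = FALSE)
  expect_equal(nrow(bed), nrow(locus$segments))
  seg1 <- locus$segments[1, ]
  expect_equal(bed$V2[bed$V4 == seg1$name], seg1$start - 1)
  expect_equal(bed$V3[bed$V4 == seg1$name], seg1$end)
})
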