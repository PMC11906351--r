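# Shared fixtures: tiny loci and noiseless tracks built in code.

# Forward toy locus on chr1, 3 V / 2 J by default, with generous flanks so
# >= 30 baseline bins exist at 500 bp.
toy_locus <- function(n_v = 3, n_j = 2, chrom = "chr1") {
  v_starts <- 5000 + (seq_len(n_v) - 1) * 5000
  j_starts <- 30000 + (seq_len(n_j) - 1) * 5000
  seg <- data.frame(
    name = c(paste0("TV", seq_len(n_v)), paste0("TJ", seq_len(n_j))),
    kind = rep(c("V", "J"), c(n_v, n_j)),
    chrom = chrom,
    start = c(v_starts, j_starts),
    end = c(v_starts + 199, j_starts + 99))
  new_locus_definition("TOY", chrom, 1, 60000, "forward", seg)
}

# Noiseless coverage track: depth equals the expected Poisson rate exactly.
noiseless_track <- function(locus, f, v_usage, j_usage, depth = 30,
                            ctx = purity_cn_context()) {
  pos <- seq(locus$span_start, locus$span_end)
  curve <- deletion_curve(locus, v_usage, j_usage)
  cn <- ctx$c_flank - 2 * f * curve$eval(deletion_axis(locus, pos))
  coverage_track(locus$chrom, pos, depth * cn / ctx$c_flank,
                 locus = locus$locus, sample_id = "noiseless")
}

# Exhaustive weighted least-squares grid search over (f, p, q) for small
# loci: the independent oracle for the two-stage estimator.
grid_search_objective <- function(profile, locus, ctx = purity_cn_context(),
                                  f_grid = seq(0, 0.5, by = 0.01),
                                  simplex_step = 0.1) {
  n_v <- nrow(locus$segments[locus$segments$kind == "V", ])
  n_j <- nrow(locus$segments[locus$segments$kind == "J", ])
  p_grid <- simplex_grid(n_v, simplex_step)
  q_grid <- simplex_grid(n_j, simplex_step)
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
          best_par <- list(f = f, p = p_grid[pi, ], q = q_grid[qi, ])
        }
      }
    }
  }
  list(objective = best, par = best_par)
}

# All points of the unit simplex on a regular grid with the given step.
simplex_grid <- function(k, step) {
  n <- round(1 / step)
  combos <- expand.grid(rep(list(0:n), k - 1))
  keep <- rowSums(combos) <= n
  combos <- as.matrix(combos[keep, , drop = FALSE])
  cbind(combos, n - rowSums(combos)) * step
}

total_variation <- function(a, b) 0.5 * sum(abs(a - b))
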