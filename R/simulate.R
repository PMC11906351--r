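#' Ground truth for a simulated sample
#'
#' Bundles every generative parameter of a simulated WGS coverage track over a
#' V(D)J locus: lymphocyte fraction, V/J segment usage, isotype mixture (IGH),
#' germline copy-number variants over constant genes, tumour purity and local
#' copy number, nominal depth, GC-bias strength and the RNG seed. Defaults
#' describe a typical germline (blood) WGS sample: 30x depth, no tumour
#' content, uniform segment usage, diploid locus, mild GC bias.
#'
#' @param locus Locus label (`"TCRA"`, `"TCRB"`, `"TCRG"`, `"IGH"`).
#' @param f Lymphocyte fraction of all cells in the unit interval.
#' @param v_usage,j_usage Usage simplices (default uniform; may be named).
#' @param isotype IGH only: isotype mixture over the eight switch classes in
#'   switch order (`IgM/IgD`, `IgG3`, `IgG1`, `IgA1`, `IgG2`, `IgG4`, `IgE`,
#'   `IgA2`); default all IgM/IgD.
#' @param germline_cn Named integer vector of germline copy numbers for
#'   constant-gene regions that deviate from 2 (e.g. `c(IGHG4 = 1)`).
#' @param purity,tumor_cn Tumour purity and local somatic copy number.
#' @param depth Nominal flank depth (x units).
#' @param gc_bias_beta Strength of the multiplicative GC bias
#'   `exp(-beta * (gc - 0.5)^2)`; 0 disables.
#' @param overdispersion Negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson depth.
#' @param seed RNG seed used by [simulate_coverage()].
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(locus, f = 0.1, v_usage = NULL, j_usage = NULL,
                      isotype = NULL, germline_cn = NULL, purity = 0,
                      tumor_cn = 2, depth = 30, gc_bias_beta = 1,
                      overdispersion = Inf, seed = 1L) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (f > 1 - purity + 1e-12) {
    stop("lymphocyte fraction cannot exceed the non-tumour fraction",
         call. = FALSE)
  }
  if (!is.null(isotype)) {
    if (length(isotype) != 8 || any(isotype < 0) ||
        abs(sum(isotype) - 1) > 1e-8) {
      stop("isotype must be a length-8 simplex in switch order", call. = FALSE)
    }
    isotype <- stats::setNames(as.numeric(isotype), isotype_classes()$class)
  }
  structure(list(locus = locus, f = f, v_usage = v_usage, j_usage = j_usage,
                 isotype = isotype, germline_cn = germline_cn,
                 purity = purity, tumor_cn = tumor_cn, depth = depth,
                 gc_bias_beta = gc_bias_beta, overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' The eight IGH switch classes in switch order
#'
#' @return A tibble with columns `class`, `rank` and `gene` (constant genes;
#'   IgM and IgD share rank 0).
#' @export
isotype_classes <- function() {
  tibble::tibble(
    class = c("IgM/IgD", "IgG3", "IgG1", "IgA1", "IgG2", "IgG4", "IgE",
              "IgA2"),
    rank = 0:7,
    gene = c("IGHM", "IGHG3", "IGHG1", "IGHA1", "IGHG2", "IGHG4", "IGHE",
             "IGHA2"))
}

# Deterministic smooth GC landscape over the locus (sinusoid over the axis).
sim_gc_profile <- function(locus, pos) {
  period <- (locus$span_end - locus$span_start) / 8
  0.5 + 0.12 * sin(2 * pi * (pos - locus$span_start) / period)
}

# Expected copy number per position given the truth (orientation-free).
sim_expected_cn <- function(truth, locus, pos) {
  ax <- deletion_axis(locus, pos)
  vs <- segments_of(locus, "V")
  js <- segments_of(locus, "J")
  vu <- truth$v_usage %||% rep(1 / nrow(vs), nrow(vs))
  ju <- truth$j_usage %||% rep(1 / nrow(js), nrow(js))
  curve <- deletion_curve(locus, vu, ju)
  g <- rep(2, length(pos))
  cst <- segments_of(locus, "CONSTANT")
  if (!is.null(truth$germline_cn)) {
    for (gene in names(truth$germline_cn)) {
      row <- cst[cst$name == gene, ]
      if (!nrow(row)) stop("germline_cn names an unknown constant gene: ",
                           gene, call. = FALSE)
      g[pos >= row$start & pos <= row$end] <- truth$germline_cn[[gene]]
    }
  }
  s <- rep(0, length(pos))
  if (!is.null(truth$isotype) && nrow(cst) > 0) {
    cls <- isotype_classes()
    s_mu <- max(js$axis_end)  # CSR deletions begin just past the J cluster
    for (k in 2:nrow(cls)) {
      gene_start <- cst$axis_start[cst$name == cls$gene[k]]
      s <- s + truth$isotype[[cls$class[k]]] *
        as.numeric(ax > s_mu & ax < gene_start)
    }
  }
  cn <- truth$purity * truth$tumor_cn + (1 - truth$purity) * g -
    2 * truth$f * curve$eval(ax) - 1 * truth$f * s
  if (any(cn < 0)) stop("inconsistent truth: negative expected copy number",
                        call. = FALSE)
  cn
}

#' Simulate a WGS coverage track over a locus
#'
#' Draws per-base read depth `depth(x) ~ Poisson(D * CN(x)/C_flank * b(gc))`
#' where `CN(x)` composes V(D)J deletion (deletion curve of the true usage),
#' class-switch deletion over IGH constant genes, germline CNVs and the
#' tumour purity mixture, and `b(gc) = exp(-beta (gc - 0.5)^2)` is a mild
#' multiplicative GC bias over a smooth synthetic GC landscape. Deterministic
#' given `truth$seed`. With finite `overdispersion`, negative-binomial depth
#' (size = overdispersion) replaces Poisson.
#'
#' @param truth A `sim_truth`.
#' @param locus The matching `locus_definition`.
#' @param resolution `"base"` (per-base Poisson) or `"bin"` (per-bin totals,
#'   spread uniformly over the bin; identical at the bin level, faster).
#' @param bin_size Bin width for `resolution = "bin"`.
#' @return A `vdj_coverage` track with attributes `gc` (per-position GC) and
#'   `truth`.
#' @export
simulate_coverage <- function(truth, locus, resolution = c("base", "bin"),
                              bin_size = 500) {
  stopifnot(inherits(truth, "sim_truth"), inherits(locus, "locus_definition"))
  if (truth$locus != locus$locus) {
    stop("truth is for ", truth$locus, ", locus definition for ",
         locus$locus, call. = FALSE)
  }
  resolution <- match.arg(resolution)
  pos <- seq(locus$span_start, locus$span_end)
  gc <- sim_gc_profile(locus, pos)
  c_flank <- truth$purity * truth$tumor_cn + (1 - truth$purity) * 2
  rate <- truth$depth * sim_expected_cn(truth, locus, pos) / c_flank *
    exp(-truth$gc_bias_beta * (gc - 0.5)^2)

  depth <- withr::with_seed(truth$seed, {
    if (resolution == "base") {
      draw_depth(rate, truth$overdispersion)
    } else {
      idx <- floor((pos - locus$span_start) / bin_size)
      n <- tabulate(idx + 1)
      tot <- draw_depth(as.numeric(tapply(rate, idx, sum)),
                        truth$overdispersion)
      unlist(lapply(seq_along(tot), function(b) {
        base <- tot[b] %/% n[b]
        base + as.numeric(seq_len(n[b]) <= tot[b] %% n[b])
      }), use.names = FALSE)
    }
  })
  track <- coverage_track(locus$chrom, pos, depth, locus = locus$locus,
                          sample_id = paste0("sim_seed", truth$seed))
  attr(track, "gc") <- gc
  attr(track, "truth") <- truth
  track
}

draw_depth <- function(rate, overdispersion) {
  if (is.finite(overdispersion)) {
    stats::rnbinom(length(rate), size = overdispersion, mu = rate)
  } else {
    stats::rpois(length(rate), rate)
  }
}

#' Simulate a cohort of coverage tracks
#'
#' Draws `n` samples with independent truths from the given parameter ranges
#' and returns the tracks alongside a truth table. Fully reproducible: sample
#' seeds are derived from `seed`.
#'
#' @param n Number of samples.
#' @param locus A `locus_definition`.
#' @param f_range Range of the uniform lymphocyte-fraction draw.
#' @param depth Nominal depth for every sample.
#' @param usage `"uniform"` for uniform segment usage or `"dirichlet"` for a
#'   Dirichlet(1) draw per sample.
#' @param isotype_alpha IGH only: Dirichlet concentration (length 8) for
#'   isotype mixtures; `NULL` leaves isotypes at the all-IgM/IgD default.
#' @param purity,tumor_cn Passed to every truth.
#' @param seed Master seed.
#' @param out_dir If given, each track is written as
#'   `<out_dir>/<sample>.cov.tsv.gz` plus a `truth.tsv` table.
#' @return A list with `tracks` (list of `vdj_coverage`) and `truth` (tibble:
#'   `sample_id`, `f`, `depth`, `purity`, `tumor_cn`, `seed`).
#' @export
simulate_cohort <- function(n, locus, f_range = c(0, 0.5), depth = 30,
                            usage = c("uniform", "dirichlet"),
                            isotype_alpha = NULL, purity = 0, tumor_cn = 2,
                            seed = 1L, out_dir = NULL) {
  usage <- match.arg(usage)
  if (n == 0) {
    return(list(tracks = list(),
                truth = tibble::tibble(sample_id = character(), f = numeric(),
                                       depth = numeric(), purity = numeric(),
                                       tumor_cn = numeric(), seed = integer())))
  }
  pars <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      nv <- nrow(segments_of(locus, "V"))
      nj <- nrow(segments_of(locus, "J"))
      list(
        f = stats::runif(1, f_range[1], f_range[2]),
        v_usage = if (usage == "dirichlet") rdirichlet1(nv) else NULL,
        j_usage = if (usage == "dirichlet") rdirichlet1(nj) else NULL,
        isotype = if (!is.null(isotype_alpha)) rdirichlet(isotype_alpha)
                  else NULL,
        seed = sample.int(2^30, 1))
    })
  })
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- sim_truth(locus$locus, f = pars[[i]]$f, v_usage = pars[[i]]$v_usage,
                    j_usage = pars[[i]]$j_usage, isotype = pars[[i]]$isotype,
                    purity = purity, tumor_cn = tumor_cn, depth = depth,
                    seed = pars[[i]]$seed)
    tracks[[i]] <- simulate_coverage(tr, locus)
    attr(tracks[[i]], "sample_id") <- sprintf("sim%03d", i)
  }
  truth <- tibble::tibble(
    sample_id = sprintf("sim%03d", seq_len(n)),
    f = vapply(pars, `[[`, numeric(1), "f"),
    depth = depth, purity = purity, tumor_cn = tumor_cn,
    seed = vapply(pars, `[[`, integer(1), "seed"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_coverage_table(tracks[[i]], file.path(
        out_dir, paste0(truth$sample_id[i], ".cov.tsv.gz")))
    }
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  }
  list(tracks = tracks, truth = truth)
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}
rdirichlet1 <- function(k) rdirichlet(rep(1, k))

#' Downsample a coverage track by binomial thinning
#'
#' Each read at each position is kept independently with probability
#' `target_depth / current`, where `current` is the track's mean depth. This
#' makes thinning nested: thinning 30x to 5x is distributed as thinning 30x
#' to 10x to 5x.
#'
#' @param track A `vdj_coverage` track.
#' @param target_depth Target mean depth; if at or above the current mean the
#'   track is returned unchanged.
#' @param seed RNG seed.
#' @return A thinned `vdj_coverage` track (attributes preserved).
#' @export
downsample_track <- function(track, target_depth, seed = 1L) {
  current <- mean(track$depth)
  if (target_depth >= current) return(track)
  ratio <- target_depth / current
  depth <- withr::with_seed(seed,
    stats::rbinom(nrow(track), size = as.integer(track$depth), prob = ratio))
  out <- track
  out$depth <- as.numeric(depth)
  out
}

#' Write / read simulation truth
#'
#' JSON serialisation so every simulated track can travel with its generating
#' parameters; `read_sim_truth(write_sim_truth(x, p))` reproduces `x`.
#'
#' @param truth A `sim_truth`.
#' @param path JSON file path.
#' @return `write_sim_truth`: `path` invisibly; `read_sim_truth`: a
#'   `sim_truth`.
#' @export
write_sim_truth <- function(truth, path) {
  x <- unclass(truth)
  if (is.infinite(x$overdispersion)) x$overdispersion <- NULL  # Poisson default
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$overdispersion <- if (is.null(x$overdispersion)) Inf
                      else as.numeric(x$overdispersion)
  do.call(sim_truth, x[!vapply(x, is.null, logical(1))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
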