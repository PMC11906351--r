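#' Run the full per-sample analysis pipeline
#'
#' Orchestrates extract/normalise/fit/report for a set of samples and loci.
#' For each sample x locus the coverage is loaded (pre-extracted TSV or
#' BAM/CRAM), normalised to an RDR profile, fitted with [fit_vdj()], and for
#' IGH additionally decomposed with [call_germline_cnv()] (when a matched
#' germline coverage is given) and [fit_class_switch()]. Failures are
#' isolated per sample x locus and reported in the `status` column rather
#' than aborting the run.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{samples}{list of per-sample lists: `sample_id`; either
#'       `coverage` (named list locus -> coverage TSV) or `bam`
#'       (alignment path); optional `gc` (named list locus -> per-position
#'       GC TSV), `normal_coverage` (IGH germline coverage TSV for CNV
#'       calling), `tumor` (logical), `purity`, `local_cn` (named list
#'       locus -> somatic CN).}
#'     \item{loci}{character vector of loci to fit (default all four).}
#'     \item{annotation}{`"packaged"` or a directory of annotation TSVs.}
#'     \item{bin_size, boot_n, seed}{optional fitting parameters.}
#'     \item{reference}{reference FASTA (for BAM extraction / GC).}
#'   }
#' @param out_dir Optional directory for `report.json` and `report.tsv`.
#' @return A tibble with one row per sample x locus: `sample_id`, `locus`,
#'   `status`, `fraction`, `ci_lower`, `ci_upper`, `mean_depth`,
#'   `n_bins_used`, `zero_fraction`, `low_depth`, IGH class-switch aggregates
#'   (`igm_igd`, `class_switched`, `igg`, `iga`, `ige`), and a `fit` list
#'   column holding the full `vdj_fit` objects.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  loci_names <- config$loci %||% c("TCRA", "TCRB", "TCRG", "IGH")
  annotation <- config$annotation %||% "packaged"
  bin_size <- config$bin_size %||% 500
  boot_n <- config$boot_n %||% 200
  seed <- config$seed %||% 1234

  loci <- lapply(stats::setNames(loci_names, loci_names), function(l) {
    if (identical(annotation, "packaged")) load_locus_definition(l)
    else load_locus_definition(l, file.path(annotation, paste0(tolower(l),
                                                               "_segments.tsv")))
  })

  rows <- list()
  for (s in config$samples) {
    sid <- s$sample_id %||% stop("every sample needs a sample_id")
    if (isTRUE(s$tumor) && is.null(s$purity)) {
      stop("sample '", sid, "' is marked tumor but has no purity estimate",
           call. = FALSE)
    }
    for (ln in loci_names) {
      rows[[paste(sid, ln)]] <- run_sample_locus(
        s, loci[[ln]], config, bin_size = bin_size, boot_n = boot_n,
        seed = seed)
    }
  }
  report <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- dplyr::select(report, -dplyr::any_of(c("fit", "cs_fit")))
    readr::write_tsv(flat, file.path(out_dir, "report.tsv"), progress = FALSE)
    jsonlite::write_json(pipeline_json(report), file.path(out_dir,
                                                          "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}

run_sample_locus <- function(s, locus, config, bin_size, boot_n, seed) {
  sid <- s$sample_id
  base_row <- tibble::tibble(
    sample_id = sid, locus = locus$locus, status = "ok",
    fraction = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    mean_depth = NA_real_, n_bins_used = NA_integer_,
    zero_fraction = NA, low_depth = NA,
    igm_igd = NA_real_, class_switched = NA_real_, igg = NA_real_,
    iga = NA_real_, ige = NA_real_)
  tryCatch({
    track <- load_sample_track(s, locus, config)
    gc <- sample_gc(s, locus, track)
    prof <- ratio_profile(track, locus, bin_size = bin_size,
                          reference = if (is.null(gc)) config$reference,
                          gc = gc)
    ctx <- purity_cn_context(
      purity = s$purity %||% 0,
      tumor_cn = (s$local_cn[[locus$locus]] %||% 2))
    fit <- fit_vdj(prof, locus, ctx, boot_n = boot_n, boot_seed = seed)
    row <- base_row
    row$fraction <- fit$fraction
    row$ci_lower <- fit$ci_lower; row$ci_upper <- fit$ci_upper
    row$mean_depth <- attr(prof, "mean_depth")
    row$n_bins_used <- fit$n_bins_used
    row$zero_fraction <- fit$zero_fraction
    row$low_depth <- attr(prof, "mean_depth") < 5
    row$fit <- list(fit)
    if (locus$locus == "IGH") {
      cnv <- if (!is.null(s$normal_coverage)) {
        ntrack <- read_coverage_table(s$normal_coverage, locus = "IGH",
                                      sample_id = paste0(sid, "_normal"))
        nprof <- ratio_profile(ntrack, locus, bin_size = bin_size,
                               gc = sample_gc(s, locus, ntrack))
        call_germline_cnv(nprof, locus)
      } else NULL
      cs <- fit_class_switch(prof, fit, cnv = cnv, ctx = ctx, locus = locus)
      row$igm_igd <- unname(cs$igm_igd)
      row$class_switched <- unname(cs$class_switched)
      row$igg <- unname(cs$igg); row$iga <- unname(cs$iga)
      row$ige <- unname(cs$ige)
      row$cs_fit <- list(cs)
    }
    row
  }, error = function(e) {
    row <- base_row
    row$status <- paste0("error: ", conditionMessage(e))
    row
  })
}

load_sample_track <- function(s, locus, config) {
  if (!is.null(s$coverage)) {
    path <- s$coverage[[locus$locus]]
    if (is.null(path)) stop("no coverage file for locus ", locus$locus)
    read_coverage_table(path, locus = locus$locus, sample_id = s$sample_id)
  } else if (!is.null(s$bam)) {
    extract_coverage(s$bam, locus, reference = config$reference,
                     sample_id = s$sample_id)
  } else {
    stop("sample '", s$sample_id, "' has neither coverage tables nor a bam")
  }
}

sample_gc <- function(s, locus, track) {
  if (is.null(s$gc)) return(NULL)
  path <- s$gc[[locus$locus]]
  if (is.null(path)) return(NULL)
  gc_tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  gc_tab$gc[match(track$pos, gc_tab$pos)]
}

pipeline_json <- function(report) {
  lapply(seq_len(nrow(report)), function(i) {
    row <- report[i, ]
    out <- list(sample_id = row$sample_id, locus = row$locus,
                status = row$status, fraction = row$fraction,
                ci = c(row$ci_lower, row$ci_upper),
                qc = list(mean_depth = row$mean_depth,
                          n_bins = row$n_bins_used,
                          zero_fraction = row$zero_fraction,
                          low_depth = row$low_depth))
    if ("fit" %in% names(report) && length(report$fit) >= i &&
        !is.null(report$fit[[i]])) {
      out$v_usage <- as.list(report$fit[[i]]$v_usage)
      out$j_usage <- as.list(report$fit[[i]]$j_usage)
    }
    if (row$locus == "IGH" && !is.na(row$igm_igd)) {
      out$class_switch <- list(igm_igd = row$igm_igd,
                               class_switched = row$class_switched,
                               igg = row$igg, iga = row$iga, ige = row$ige)
    }
    out
  })
}
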