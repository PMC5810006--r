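#' Pipeline configuration
#'
#' Bundles every stage's tunables with defaults equal to the published
#' values where one is stated (filter thresholds, 10-SNP CNV window,
#' 50-SNP concordance window, 0.01/0.99 concordance verdict cutoffs)
#' and to package defaults elsewhere (CNV segment thresholds, LOH fit
#' settings).
#'
#' @param filter a [filter_config()].
#' @param cnv_window moving-average window in SNPs.
#' @param cnv_del_threshold,cnv_amp_threshold,cnv_min_snps segment-call
#'   settings.
#' @param loh_n_restarts,loh_min_coverage LOH fit settings.
#' @param concordance_window phase-test moving window in SNPs.
#' @param seed integer seed used for the LOH fit restarts (and for
#'   simulation when [run_pipeline()] is given parameters instead of
#'   files).
#' @param out_dir output directory for stage reports.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            cnv_window = 10,
                            cnv_del_threshold = -0.3,
                            cnv_amp_threshold = 0.3,
                            cnv_min_snps = 10,
                            loh_n_restarts = 8,
                            loh_min_coverage = 10,
                            concordance_window = 50,
                            seed = 1,
                            out_dir = ".") {
  stopifnot(inherits(filter, "filter_config"))
  if (cnv_window < 1 || cnv_min_snps < 1 || concordance_window < 1 ||
      loh_n_restarts < 1 || loh_min_coverage < 0) {
    stop("invalid pipeline configuration value", call. = FALSE)
  }
  if (cnv_del_threshold >= cnv_amp_threshold) {
    stop("cnv_del_threshold must be below cnv_amp_threshold",
         call. = FALSE)
  }
  structure(list(filter = filter, cnv_window = cnv_window,
                 cnv_del_threshold = cnv_del_threshold,
                 cnv_amp_threshold = cnv_amp_threshold,
                 cnv_min_snps = cnv_min_snps,
                 loh_n_restarts = loh_n_restarts,
                 loh_min_coverage = loh_min_coverage,
                 concordance_window = concordance_window,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys are the
#' arguments of [pipeline_config()] plus the filter thresholds
#' (`max_germline_vaf`, `min_tumor_alt_reads`, `min_coverage`,
#' `min_exomewide_vaf`, `min_strand_reads`, `max_germline_alt`).
#'
#' @param path config file path.
#' @param overrides named list applied after the file (CLI flags win).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
      }
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  for (k in names(overrides)) vals[[k]] <- overrides[[k]]
  filter_keys <- names(formals(filter_config))
  pipe_keys <- setdiff(names(formals(pipeline_config)), "filter")
  fargs <- list(); pargs <- list()
  for (k in names(vals)) {
    v <- vals[[k]]
    if (k %in% filter_keys) {
      fargs[[k]] <- as.numeric(v)
    } else if (k %in% pipe_keys) {
      pargs[[k]] <- if (k == "out_dir") as.character(v) else as.numeric(v)
    } else {
      stop(sprintf("unknown configuration key: '%s'", k), call. = FALSE)
    }
  }
  pargs$filter <- do.call(filter_config, fargs)
  do.call(pipeline_config, pargs)
}

#' Run the full paired-lesion pipeline
#'
#' Stages, in order: somatic filtering of primary and metastasis
#' variants; log2 CNV track + smoothing + segment calls (primary and
#' metastasis vs germline); Beta-Normal LOH mixture fit per
#' compartment; windowed phase-concordance between primary and
#' metastasis; family-enrichment 2x2 summary of the filtered calls.
#' Every stage's output is written as TSV/JSON under `config$out_dir`
#' with a run manifest recording configuration, seed and package
#' version. Reports are byte-stable for a fixed configuration and
#' seed; the timestamp lives only in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param case a `simulated_case`, or a list with the same elements
#'   read from files (`germline`, `primary`, `metastasis` SNP tables;
#'   `primary_variants`, `metastasis_variants` variant tables).
#' @param family_genes gene family tested in the enrichment stage.
#' @return (invisibly) list of per-stage results plus `manifest`.
#' @export
run_pipeline <- function(config, case, family_genes = akap_genes()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()

  results$filter <- stage("filter", {
    lapply(c(primary = "primary_variants", metastasis = "metastasis_variants"),
           function(el) {
             v <- filter_somatic(case[[el]], config$filter)
             cbind(case[[el]], v)
           })
  })
  write_variant_stage <- function(df, f) {
    write.table(df, out(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_variant_stage(results$filter$primary, "filter_primary.tsv")
  write_variant_stage(results$filter$metastasis, "filter_metastasis.tsv")

  results$cnv <- stage("cnv", {
    lapply(list(primary = case$primary, metastasis = case$metastasis),
           function(tum) {
             tr <- moving_average(log2_ratio_track(tum, case$germline),
                                  window = config$cnv_window)
             segs <- call_segments(tr, config$cnv_del_threshold,
                                   config$cnv_amp_threshold,
                                   config$cnv_min_snps)
             list(track = tr, segments = segs)
           })
  })
  write_variant_stage(results$cnv$primary$segments, "cnv_primary_segments.tsv")
  write_variant_stage(results$cnv$metastasis$segments,
                      "cnv_metastasis_segments.tsv")

  results$loh <- stage("loh_fit", {
    lapply(list(primary = case$primary, metastasis = case$metastasis),
           function(tum) {
             m <- major_allele_frequencies(case$germline, tum,
                                           config$loh_min_coverage)
             fit_loh_mixture(m, n_restarts = config$loh_n_restarts,
                             seed = config$seed)
           })
  })
  fit_json <- lapply(results$loh, function(f) f[setdiff(names(f), "restarts")])
  jsonlite::write_json(fit_json, out("loh_fit.json"), auto_unbox = TRUE,
                       digits = NA)

  results$concordance <- stage("phase_test", {
    ma <- major_allele_frequencies(case$germline, case$primary,
                                   config$loh_min_coverage)
    mb <- major_allele_frequencies(case$germline, case$metastasis,
                                   config$loh_min_coverage)
    windowed_concordance(ma, mb, window = config$concordance_window)
  })
  write_variant_stage(results$concordance, "phase_concordance.tsv")

  results$enrichment <- stage("enrich", {
    kept <- rbind(
      results$filter$primary[results$filter$primary$kept, , drop = FALSE],
      results$filter$metastasis[results$filter$metastasis$kept, ,
                                drop = FALSE])
    tab <- matrix(c(
      sum(kept$compartment == "metastasis" & kept$gene %in% family_genes),
      sum(kept$compartment == "primary" & kept$gene %in% family_genes),
      sum(kept$compartment == "metastasis" & !kept$gene %in% family_genes),
      sum(kept$compartment == "primary" & !kept$gene %in% family_genes)),
      nrow = 2,
      dimnames = list(c("metastasis", "primary"),
                      c("family", "non_family")))
    fisher_family_enrichment(tab)
  })
  jsonlite::write_json(
    list(table = results$enrichment$table,
         p_two_sided = results$enrichment$p_two_sided,
         odds_ratio = results$enrichment$odds_ratio),
    out("enrichment.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  manifest <- list(
    package = "pairedmet",
    version = as.character(utils::packageVersion("pairedmet")),
    seed = config$seed,
    config = config[setdiff(names(config), "filter")],
    filter = unclass(config$filter),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
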