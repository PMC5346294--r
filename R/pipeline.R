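#' Assemble and validate a pipeline run configuration
#'
#' Inputs are either a pair of per-population VCFs (with panels) or an
#' allele-count TSV. All analysis parameters used downstream are fixed here
#' so a run is fully described by its config.
#'
#' @param count_table Path to an allele-count TSV (alternative to VCFs).
#' @param vcf1,vcf2 Paths to the two population VCFs.
#' @param panel1,panel2 [population_panel()] objects (required with VCFs;
#'   defaults label the count-table populations pop1/pop2).
#' @param bed_paths Named character vector of BED3 category files; names are
#'   category labels.
#' @param scheme A [maf_bin_scheme()].
#' @param fold_scheme A [fold_class_scheme()].
#' @param min_mac Pooled minor-allele-count floor (default 5).
#' @param enrich_bin Bin label scanned for category enrichment.
#' @param baseline Baseline mode for [category_enrichment_scan()].
#' @param conf_level Confidence level for intervals.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the summary (the analysis itself is
#'   deterministic; the seed governs any simulation step feeding it).
#' @return An object of class `run_config`.
#' @export
run_config <- function(count_table = NULL, vcf1 = NULL, vcf2 = NULL,
                       panel1 = population_panel("pop1", 1L),
                       panel2 = population_panel("pop2", 1L),
                       bed_paths = character(0),
                       scheme = maf_bin_scheme(),
                       fold_scheme = fold_class_scheme(),
                       min_mac = 5L, enrich_bin = NULL,
                       baseline = "complement", conf_level = 0.95,
                       out_dir = ".", seed = 1L) {
  if (is.null(count_table) && (is.null(vcf1) || is.null(vcf2)))
    stop("provide either count_table or both vcf1 and vcf2")
  for (pth in c(count_table, vcf1, vcf2, unname(bed_paths)))
    if (!file.exists(pth)) stop("input file not found: ", pth)
  if (length(bed_paths) && is.null(names(bed_paths)))
    names(bed_paths) <- tools::file_path_sans_ext(basename(bed_paths))
  if (is.null(enrich_bin))
    enrich_bin <- scheme$labels[min(3L, length(scheme$labels))]
  structure(list(count_table = count_table, vcf1 = vcf1, vcf2 = vcf2,
                 panel1 = panel1, panel2 = panel2, bed_paths = bed_paths,
                 scheme = scheme, fold_scheme = fold_scheme,
                 min_mac = as.integer(min_mac), enrich_bin = enrich_bin,
                 baseline = baseline, conf_level = conf_level,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full two-population comparison pipeline
#'
#' Reads the variant inputs, applies the pooled MAC filter, attaches BED
#' category annotations, and writes the frequency-spectrum table, the
#' per-category enrichment scan of the configured bin, fold-enrichment
#' summaries in both directions, and a JSON run summary with record counts
#' at each stage. Output is deterministic given inputs and config.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory tables and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) message("[isoenrich] ", sprintf(...))
  records <- if (!is.null(config$count_table)) {
    log_msg("reading count table %s", config$count_table)
    read_count_table(config$count_table)
  } else {
    log_msg("reading VCF pair %s / %s", config$vcf1, config$vcf2)
    read_vcf_pair(config$vcf1, config$vcf2, config$panel1, config$panel2)
  }
  n_read <- nrow(records)
  log_msg("%d biallelic SNV records read", n_read)
  records <- filter_mac(records, config$min_mac)
  n_mac <- nrow(records)
  log_msg("%d records pass pooled MAC >= %d", n_mac, config$min_mac)
  if (!n_mac) stop("run_pipeline: no records left after the MAC filter")
  anns <- lapply(seq_along(config$bed_paths), function(i)
    read_bed_category(config$bed_paths[[i]], names(config$bed_paths)[i]))
  if (length(anns)) records <- annotate_categories(records, anns)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  spec_tab <- spectrum_table(records, config$scheme)
  paths$spectrum <- write_tsv(spec_tab, file.path(config$out_dir, "spectrum.tsv"))

  enrich_tab <- NULL
  if (length(category_labels(records))) {
    enrich_tab <- category_enrichment_scan(
      records, config$scheme, config$enrich_bin,
      baseline = config$baseline, conf_level = config$conf_level)
    paths$enrichment <- write_tsv(enrich_tab,
                                  file.path(config$out_dir, "enrichment.tsv"))
  } else log_msg("no categories supplied; enrichment scan skipped")

  fold_tab <- rbind(fold_summary(records, config$fold_scheme, 1),
                    fold_summary(records, config$fold_scheme, 2))
  paths$fold <- write_tsv(fold_tab, file.path(config$out_dir, "fold.tsv"))

  summary <- list(
    n_records_read = n_read, n_records_mac_pass = n_mac,
    min_mac = config$min_mac, enrich_bin = config$enrich_bin,
    baseline = config$baseline, seed = config$seed,
    populations = c(config$panel1$label, config$panel2$label),
    categories = as.list(category_labels(records)))
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  log_msg("outputs written to %s", config$out_dir)
  invisible(list(records = records, spectrum = spec_tab,
                 enrichment = enrich_tab, fold = fold_tab, paths = paths))
}
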