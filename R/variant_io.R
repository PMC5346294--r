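#' Describe a population sequencing panel
#'
#' A panel is a set of diploid individuals sequenced from one population; its
#' size fixes the total allele number (`2 * n_samples`) used when a variant is
#' absent from that panel's VCF but covered by the joint call set.
#'
#' @param label Population name, e.g. `"FIN"`.
#' @param n_samples Number of diploid individuals in the panel.
#' @return An object of class `population_panel`.
#' @export
population_panel <- function(label, n_samples) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples <= 0L)
    stop("n_samples must be a positive integer")
  structure(list(label = label, n_samples = n_samples),
            class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  cat(sprintf("<population_panel> %s: %d diploid samples\n", x$label, x$n_samples))
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

## Chromosome labels treated as non-autosomal and excluded from analysis.
NON_AUTOSOMES <- c("X", "Y", "MT", "M", "chrX", "chrY", "chrM", "chrMT")

empty_records <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), ac1 = integer(), an1 = integer(),
             ac2 = integer(), an2 = integer(), stringsAsFactors = FALSE)
}

#' Validate an allele-count record table
#'
#' Checks the invariants every downstream analysis relies on: counts within
#' `[0, an]`, even and positive allele numbers (diploid samples), single-base
#' ref/alt that differ.
#'
#' @param records A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ac1`, `an1`, `ac2`, `an2` and optionally a list column `categories`.
#' @param context String used to prefix error messages (e.g. a file name).
#' @return The validated table, invisibly, with integer count columns and a
#'   `categories` list column guaranteed present.
#' @export
validate_records <- function(records, context = "records") {
  needed <- c("chrom", "pos", "ref", "alt", "ac1", "an1", "ac2", "an2")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop(context, ": missing columns: ", paste(missing_cols, collapse = ", "))
  for (cc in c("pos", "ac1", "an1", "ac2", "an2"))
    records[[cc]] <- as.integer(records[[cc]])
  bad_line <- function(ok, what) {
    if (!all(ok))
      stop(context, ": ", what, " at row ", which(!ok)[1L])
  }
  bad_line(records$an1 > 0L & records$an2 > 0L, "total allele number must be > 0")
  bad_line(records$an1 %% 2L == 0L & records$an2 %% 2L == 0L,
           "odd total allele number (samples are diploid)")
  bad_line(records$ac1 >= 0L & records$ac1 <= records$an1 &
             records$ac2 >= 0L & records$ac2 <= records$an2,
           "allele count outside [0, an]")
  bad_line(records$ref %in% BASES & records$alt %in% BASES,
           "ref/alt must be a single A/C/G/T base")
  bad_line(records$ref != records$alt, "ref equals alt")
  if (is.null(records$categories))
    records$categories <- replicate(nrow(records), character(0), simplify = FALSE)
  invisible(records)
}

## Tally alt-allele counts from a vcfR object: one row per biallelic SNV
## (multi-allelic records split, non-SNV alt alleles dropped). Missing
## genotype calls reduce `an` by one per missing allele.
vcf_allele_counts <- function(vcf, path) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("no genotype (GT) data in ", path)
  fmt <- gt[, 1]
  if (any(substr(fmt, 1, 2) != "GT"))
    stop("GT must be the first FORMAT field in ", path)
  gtm <- gt[, -1, drop = FALSE]
  ## keep the GT part only; vcfR renders fully missing genotypes as NA
  gtm[] <- sub(":.*$", "", gtm)
  gtm[is.na(gtm)] <- "./."
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alleles <- unlist(strsplit(gsub("\\|", "/", gtm[i, ]), "/", fixed = TRUE))
    called <- alleles[alleles != "."]
    an <- length(called)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[i, "REF"]
    keep <- which(nchar(alts) == 1L & alts %in% BASES & nchar(ref) == 1L &
                    ref %in% BASES)
    if (!length(keep)) next
    out[[i]] <- data.frame(
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]), ref = ref,
      alt = alts[keep],
      ac = vapply(keep, function(k) sum(called == as.character(k)), integer(1)),
      an = an, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

#' Read a pair of per-population VCF files into one allele-count table
#'
#' Both files are assumed to come from a joint call over the union of sites,
#' so a biallelic SNV present in one file but absent from the other gets an
#' alt-allele count of 0 with the absent panel's full allele number
#' (`2 * n_samples`); `strict = TRUE` errors instead. Multi-allelic records
#' are split into per-alt biallelic records; indels and non-autosomal
#' chromosomes are dropped (a message reports how many). Missing genotypes
#' (`./.`) reduce the total allele number rather than being counted as
#' reference.
#'
#' @param vcf_path_1,vcf_path_2 Paths to the two VCF files (plain or gzip).
#' @param panel1,panel2 [population_panel()] objects describing each file.
#' @param strict Error when a site is present in only one file.
#' @return A record table (see [validate_records()]), keyed by
#'   (chrom, pos, ref, alt).
#' @export
read_vcf_pair <- function(vcf_path_1, vcf_path_2, panel1, panel2,
                          strict = FALSE) {
  stopifnot(inherits(panel1, "population_panel"),
            inherits(panel2, "population_panel"))
  t1 <- vcf_allele_counts(vcfR::read.vcfR(vcf_path_1, verbose = FALSE), vcf_path_1)
  t2 <- vcf_allele_counts(vcfR::read.vcfR(vcf_path_2, verbose = FALSE), vcf_path_2)
  if (is.null(t1) || is.null(t2) || !nrow(t1) || !nrow(t2))
    stop("no biallelic SNVs found in one of the input VCFs")

  ## ref consistency at shared positions
  p1 <- unique(t1[c("chrom", "pos", "ref")])
  p2 <- unique(t2[c("chrom", "pos", "ref")])
  shared <- merge(p1, p2, by = c("chrom", "pos"))
  bad <- shared$ref.x != shared$ref.y
  if (any(bad))
    stop("inconsistent REF allele at ", shared$chrom[bad][1L], ":",
         shared$pos[bad][1L], " (", shared$ref.x[bad][1L], " vs ",
         shared$ref.y[bad][1L], ")")

  m <- merge(t1, t2, by = c("chrom", "pos", "ref", "alt"), all = TRUE,
             suffixes = c("1", "2"))
  only1 <- is.na(m$ac2)
  only2 <- is.na(m$ac1)
  if (strict && any(only1 | only2))
    stop(sum(only1 | only2), " site(s) present in only one VCF (strict mode)")
  m$ac2[only1] <- 0L
  m$an2[only1] <- 2L * panel2$n_samples
  m$ac1[only2] <- 0L
  m$an1[only2] <- 2L * panel1$n_samples

  auto <- !(m$chrom %in% NON_AUTOSOMES)
  if (any(!auto))
    message("dropped ", sum(!auto), " non-autosomal record(s)")
  m <- m[auto, , drop = FALSE]
  m <- m[order(m$chrom, m$pos, m$alt), , drop = FALSE]
  rownames(m) <- NULL
  validate_records(m, context = "read_vcf_pair")
}

#' Read an allele-count table from TSV
#'
#' Expected header: `chrom, pos, ref, alt, ac1, an1, ac2, an2`.
#'
#' @param tsv_path Path to the tab-separated file.
#' @return A validated record table.
#' @export
read_count_table <- function(tsv_path) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "ac1", "an1", "ac2", "an2")
  if (!identical(names(df)[seq_along(needed)], needed))
    stop(tsv_path, ": header must be ", paste(needed, collapse = ","))
  df$chrom <- as.character(df$chrom)
  validate_records(df, context = tsv_path)
}

#' Write an allele-count table to TSV
#'
#' @param records A record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(records, path) {
  records <- validate_records(records)
  write.table(records[c("chrom", "pos", "ref", "alt",
                        "ac1", "an1", "ac2", "an2")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter on pooled minor allele count
#'
#' Retains variants whose minor allele count in the pooled two-population
#' sample, `min(ac1 + ac2, (an1 + an2) - (ac1 + ac2))`, is at least
#' `min_mac`. This mirrors joint-call quality control in which only sites
#' with several minor-allele copies across the full data set are released;
#' downstream per-population analyses then use each population's own counts.
#'
#' @param records A record table.
#' @param min_mac Minimum pooled minor allele count (default 5).
#' @return The filtered table; counts are never altered, only membership.
#' @export
filter_mac <- function(records, min_mac = 5L) {
  stopifnot(min_mac >= 0)
  records <- validate_records(records)
  pooled_ac <- records$ac1 + records$ac2
  pooled_an <- records$an1 + records$an2
  keep <- pmin(pooled_ac, pooled_an - pooled_ac) >= min_mac
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a functional category from genomic intervals
#'
#' @param label Category name.
#' @param intervals Data frame with columns `chrom`, `start`, `end` holding
#'   0-based half-open intervals (the BED convention). Overlap is allowed;
#'   membership is the union.
#' @return An object of class `category_annotation`.
#' @export
category_annotation <- function(label, intervals) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("category '", label, "': start must be < end (0-based half-open)")
  structure(list(label = label,
                 intervals = intervals[c("chrom", "start", "end")]),
            class = "category_annotation")
}

#' Read a BED3 file as a category annotation
#'
#' @param path Path to a BED file (first three columns used).
#' @param label Category label; defaults to the file name without extension.
#' @return A [category_annotation()].
#' @export
read_bed_category <- function(path, label = NULL) {
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  nf <- count.fields(path, sep = "\t", comment.char = "#")
  if (any(nf < 3L))
    stop(path, ": malformed BED line ", which(nf < 3L)[1L],
         " (fewer than 3 fields)")
  gr <- rtracklayer::import(path, format = "BED")
  category_annotation(label, data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # back to 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE))
}

#' Attach category memberships to variants
#'
#' A variant at 1-based position `p` belongs to a category iff `p - 1` falls
#' in `[start, end)` of any of its 0-based half-open intervals. Variants may
#' belong to several categories; the `categories` list column is replaced.
#'
#' @param records A record table.
#' @param annotations List of [category_annotation()] objects.
#' @return The record table with the `categories` list column populated.
#' @export
annotate_categories <- function(records, annotations) {
  records <- validate_records(records)
  if (inherits(annotations, "category_annotation"))
    annotations <- list(annotations)
  cats <- replicate(nrow(records), character(0), simplify = FALSE)
  if (nrow(records)) {
    vr <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, records$pos))
    for (ann in annotations) {
      iv <- ann$intervals
      if (!nrow(iv)) next
      gr <- GenomicRanges::GRanges(iv$chrom,
                                   IRanges::IRanges(iv$start + 1L, iv$end))
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(vr, gr, ignore.strand = TRUE)))
      for (i in hit) cats[[i]] <- c(cats[[i]], ann$label)
    }
  }
  records$categories <- lapply(cats, unique)
  records
}

## logical membership vector for one category label
has_category <- function(records, label) {
  vapply(records$categories, function(x) label %in% x, logical(1))
}

#' All category labels present in a record table
#'
#' @param records An annotated record table.
#' @return Character vector of distinct labels, in order of first appearance.
#' @export
category_labels <- function(records) {
  unique(unlist(records$categories))
}
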