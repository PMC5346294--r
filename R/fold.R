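#' Define fold-enrichment classes
#'
#' Default classes 2--5x, 5--10x, 10--50x, >=50x; each class is half-open
#' `[a, b)` on the fold ratio, the last open-ended.
#'
#' @param breakpoints Strictly increasing fold thresholds, all > 1.
#' @param labels One label per class; generated when `NULL`.
#' @return An object of class `fold_class_scheme`.
#' @export
fold_class_scheme <- function(breakpoints = c(2, 5, 10, 50), labels = NULL) {
  stopifnot(length(breakpoints) >= 1, all(diff(breakpoints) > 0),
            all(breakpoints > 1))
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))
  if (is.null(labels)) {
    k <- length(breakpoints)
    labels <- c(if (k > 1)
      sprintf("%s-%sx", fmt(breakpoints[-k]), fmt(breakpoints[-1L])),
      sprintf(">=%sx", fmt(breakpoints[k])))
  }
  stopifnot(length(labels) == length(breakpoints))
  structure(list(breakpoints = breakpoints, labels = labels),
            class = "fold_class_scheme")
}

## Frequency, in each population, of the *pooled-sample* minor allele, so the
## fold ratio compares the same physical allele in both populations. Folding
## per population would make the ratio ill-defined for alleles near 0.5.
pooled_minor_freqs <- function(records) {
  pooled_ac <- records$ac1 + records$ac2
  pooled_an <- records$an1 + records$an2
  alt_is_minor <- pooled_ac <= pooled_an - pooled_ac
  f1 <- ifelse(alt_is_minor, records$ac1, records$an1 - records$ac1) / records$an1
  f2 <- ifelse(alt_is_minor, records$ac2, records$an2 - records$ac2) / records$an2
  list(f1 = f1, f2 = f2)
}

#' Per-variant MAF fold ratio between populations
#'
#' Computes, for each variant, the ratio of the pooled-sample minor allele's
#' frequency in the numerator population to its frequency in the denominator
#' population. When the allele is absent from the denominator panel, its
#' frequency is replaced by the single-copy pseudo-frequency
#' `1 / (2 * n_samples)` -- the smallest frequency the panel could have
#' observed -- and the variant is flagged. A variant in which the allele is
#' absent from the *numerator* population has no defined enrichment and
#' raises an error; drop those variants first (see [fold_summary()]).
#'
#' @param records A record table.
#' @param numerator_pop 1 or 2: population whose frequency is the numerator.
#' @return Data frame with columns `fold` and `absent_in_denominator`.
#' @export
fold_ratio <- function(records, numerator_pop = 1) {
  stopifnot(numerator_pop %in% c(1, 2))
  records <- validate_records(records)
  fr <- pooled_minor_freqs(records)
  num <- if (numerator_pop == 1) fr$f1 else fr$f2
  den <- if (numerator_pop == 1) fr$f2 else fr$f1
  den_an <- if (numerator_pop == 1) records$an2 else records$an1
  if (any(num == 0))
    stop("minor allele absent from the numerator population at row ",
         which(num == 0)[1L], "; enrichment is undefined there")
  absent <- den == 0
  den[absent] <- 1 / den_an[absent]   # an = 2 * n_samples
  data.frame(fold = num / den, absent_in_denominator = absent)
}

#' Fold ratio from minor allele frequencies
#'
#' The frequency-level form of [fold_ratio()], for worked examples quoted as
#' MAFs rather than counts. An allele absent from the denominator panel
#' (`maf_den = 0`) is assigned the single-copy pseudo-frequency
#' `1 / (2 * n_den_samples)`, the smallest nonzero frequency that panel
#' could have observed.
#'
#' @param maf_num Minor allele frequency in the numerator population (> 0).
#' @param maf_den Minor allele frequency of the same allele in the
#'   denominator population (0 allowed).
#' @param n_den_samples Diploid sample count of the denominator panel,
#'   required when `maf_den` is 0.
#' @return Numeric fold ratio(s).
#' @export
fold_from_freqs <- function(maf_num, maf_den, n_den_samples = NULL) {
  stopifnot(all(maf_num > 0), all(maf_den >= 0))
  absent <- maf_den == 0
  if (any(absent)) {
    if (is.null(n_den_samples))
      stop("n_den_samples is required when the allele is absent from the ",
           "denominator panel")
    maf_den[absent] <- 1 / (2 * n_den_samples)
  }
  maf_num / maf_den
}

#' Tabulate fold-enrichment classes per category
#'
#' Classifies every variant carried by the numerator population (pooled
#' minor allele present there) by its MAF fold ratio and counts variants per
#' fold class, genome-wide and per category. Percentages are taken against
#' the category's total variant count in the numerator population, so the
#' genome-wide ">=2x" percentages are directly comparable between the two
#' run directions.
#'
#' @param records A MAC-filtered, annotated record table.
#' @param scheme A [fold_class_scheme()].
#' @param numerator_pop 1 or 2.
#' @param categories Category labels; defaults to all present. The
#'   genome-wide row set (category `"genome-wide"`) is always included.
#' @return Data frame with columns `numerator_pop`, `category`,
#'   `fold_class`, `count`, `total`, `percent`.
#' @export
fold_summary <- function(records, scheme = fold_class_scheme(),
                         numerator_pop = 1, categories = NULL) {
  records <- validate_records(records)
  if (is.null(categories)) categories <- category_labels(records)
  fr <- pooled_minor_freqs(records)
  num <- if (numerator_pop == 1) fr$f1 else fr$f2
  present <- num > 0
  recs <- records[present, , drop = FALSE]
  folds <- fold_ratio(recs, numerator_pop)$fold
  cls <- fold_class(folds, scheme)
  one_block <- function(label, sel) {
    total <- sum(sel)
    counts <- vapply(scheme$labels,
                     function(l) sum(sel & !is.na(cls) & cls == l), integer(1))
    data.frame(numerator_pop = numerator_pop, category = label,
               fold_class = scheme$labels, count = counts, total = total,
               percent = if (total > 0) 100 * counts / total else 0,
               stringsAsFactors = FALSE)
  }
  blocks <- list(one_block("genome-wide", rep(TRUE, nrow(recs))))
  for (lab in categories)
    blocks <- c(blocks, list(one_block(lab, has_category(recs, lab))))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Classify fold ratios into scheme classes
#'
#' @param fold Numeric fold ratios.
#' @param scheme A [fold_class_scheme()].
#' @return Character vector of class labels; NA below the first breakpoint.
#' @export
fold_class <- function(fold, scheme = fold_class_scheme()) {
  idx <- findInterval(fold, scheme$breakpoints)
  out <- rep(NA_character_, length(fold))
  out[idx >= 1] <- scheme$labels[idx[idx >= 1]]
  out
}

#' Fold-class summary from pre-tabulated counts
#'
#' Builds the same summary shape as [fold_summary()] from already-counted
#' per-class totals (e.g. a published table), with the fraction of variants
#' at or above each breakpoint.
#'
#' @param counts Per-class variant counts, in scheme order.
#' @param total Total variant count in the numerator population.
#' @param scheme A [fold_class_scheme()].
#' @return Data frame with `fold_class`, `count`, `percent`, and
#'   `percent_at_least` (cumulative from the class upward).
#' @export
fold_summary_from_counts <- function(counts, total,
                                     scheme = fold_class_scheme()) {
  stopifnot(length(counts) == length(scheme$labels), total > 0,
            all(counts >= 0), sum(counts) <= total)
  data.frame(fold_class = scheme$labels, count = counts,
             percent = 100 * counts / total,
             percent_at_least = 100 * rev(cumsum(rev(counts))) / total,
             stringsAsFactors = FALSE)
}
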