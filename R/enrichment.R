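#' Delta-method enrichment ratio of two variant counts
#'
#' Given `F` variants observed in population 1 and `B` in population 2 for
#' some category, models `F` as binomial in `M = F + B` trials with success
#' probability `s` (the proportion of the category's variants contributed by
#' population 1). The enrichment ratio is `u = s / (1 - s)`, estimated by
#' `u_hat = F / B`; a first-order Taylor (delta-method) expansion gives
#' `var log(u_hat) = 1 / (M * s_hat * (1 - s_hat))`, from which a normal
#' confidence interval on the log scale is formed. A two-sided binomial test
#' of `F` successes in `M` trials against 0.5 tests departure from equal
#' counts.
#'
#' @param F,B Nonnegative variant counts with `F + B > 0`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param haldane Add 0.5 to both counts when either is zero, instead of
#'   returning a flagged result with undefined ratio/CI.
#' @return A one-row data frame of class `enrichment_result` with columns
#'   `F`, `B`, `M`, `s_hat`, `u_hat`, `se_log_u`, `ci_low`, `ci_high`,
#'   `p_binomial`, `flagged`.
#' @export
enrichment_ratio <- function(F, B, conf_level = 0.95, haldane = FALSE) {
  stopifnot(length(F) == 1, length(B) == 1, F >= 0, B >= 0, F + B > 0,
            conf_level > 0, conf_level < 1)
  ## the binomial test always uses the observed integer counts
  p_binomial <- binom.test(round(F), round(F + B), p = 0.5)$p.value
  flagged <- FALSE
  if (F == 0 || B == 0) {
    if (haldane) {
      F <- F + 0.5
      B <- B + 0.5
      flagged <- TRUE
    } else {
      out <- data.frame(F = F, B = B, M = F + B, s_hat = F / (F + B),
                        u_hat = ifelse(B > 0, F / B, Inf),
                        se_log_u = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_binomial = p_binomial,
                        flagged = TRUE)
      class(out) <- c("enrichment_result", class(out))
      return(out)
    }
  }
  M <- F + B
  s_hat <- F / M
  u_hat <- F / B
  se_log_u <- sqrt(1 / (M * s_hat * (1 - s_hat)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(F = F, B = B, M = M, s_hat = s_hat, u_hat = u_hat,
                    se_log_u = se_log_u,
                    ci_low = exp(log(u_hat) - z * se_log_u),
                    ci_high = exp(log(u_hat) + z * se_log_u),
                    p_binomial = p_binomial, flagged = flagged)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Test whether two categories have different enrichment ratios
#'
#' For counts `(F1, B1)` and `(F2, B2)` in two variant categories, tests
#' `u1 = u2` via `log(u1_hat) - log(u2_hat)`, which under the null has
#' variance approximately `(1/M1 + 1/M2) / (s_hat * (1 - s_hat))` with the
#' pooled `s_hat = (F1 + F2) / (M1 + M2)`. For moderate counts the p-value
#' essentially matches the standard two-sample proportion test.
#'
#' @param F1,B1,F2,B2 Positive counts (see `haldane` for zeros).
#' @param haldane Add 0.5 to all four counts when any is zero.
#' @param conf_level Confidence level passed to the per-category
#'   [enrichment_ratio()] results.
#' @return A list of class `category_comparison` with elements `result1`,
#'   `result2`, `z`, `p`, `pooled_s`.
#' @export
compare_categories <- function(F1, B1, F2, B2, haldane = FALSE,
                               conf_level = 0.95) {
  counts <- c(F1, B1, F2, B2)
  stopifnot(all(counts >= 0), F1 + B1 > 0, F2 + B2 > 0)
  if (any(counts == 0)) {
    if (!haldane)
      stop("zero count in compare_categories; set haldane = TRUE to add ",
           "0.5 to all four counts")
    F1 <- F1 + 0.5; B1 <- B1 + 0.5; F2 <- F2 + 0.5; B2 <- B2 + 0.5
  }
  M1 <- F1 + B1
  M2 <- F2 + B2
  pooled_s <- (F1 + F2) / (M1 + M2)
  se <- sqrt((1 / M1 + 1 / M2) / (pooled_s * (1 - pooled_s)))
  z <- (log(F1 / B1) - log(F2 / B2)) / se
  structure(list(result1 = enrichment_ratio(F1, B1, conf_level, haldane),
                 result2 = enrichment_ratio(F2, B2, conf_level, haldane),
                 z = z, p = 2 * pnorm(-abs(z)), pooled_s = pooled_s),
            class = "category_comparison")
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf("<category_comparison> u1=%.4g u2=%.4g z=%.3f p=%.3g\n",
              x$result1$u_hat, x$result2$u_hat, x$z, x$p))
  invisible(x)
}

#' Scan functional categories for enrichment in one MAF bin
#'
#' For each category, `F` is the number of its variants whose population-1
#' folded MAF falls in `maf_bin`, and `B` the number using population-2's
#' MAF (bin membership is assessed per population, matching per-population
#' spectrum columns). Each category is compared against a baseline: its
#' complement within the bin (`"complement"`, disjoint counts) or all
#' variants in the bin (`"all"`).
#'
#' @param records An annotated, MAC-filtered record table.
#' @param scheme A [maf_bin_scheme()].
#' @param maf_bin A bin label of `scheme`.
#' @param categories Category labels to scan; defaults to all present.
#' @param baseline `"complement"` or `"all"`.
#' @param conf_level Confidence level for per-category intervals.
#' @param numerator_pop Population whose counts form `F` (default 1).
#' @return Data frame, one row per category, sorted by decreasing category
#'   size: `category`, `maf_bin`, `F`, `B`, `u_hat`, `ci_low`, `ci_high`,
#'   `baseline_F`, `baseline_B`, `z`, `p`, `bonferroni`, `flagged`.
#' @export
category_enrichment_scan <- function(records, scheme = maf_bin_scheme(),
                                     maf_bin = "2-5%",
                                     categories = NULL,
                                     baseline = c("complement", "all"),
                                     conf_level = 0.95,
                                     numerator_pop = 1) {
  baseline <- match.arg(baseline)
  records <- validate_records(records)
  if (!maf_bin %in% scheme$labels)
    stop("maf_bin '", maf_bin, "' is not a label of the binning scheme")
  if (is.null(categories)) categories <- category_labels(records)
  if (!length(categories)) stop("no categories to scan")
  den_pop <- if (numerator_pop == 1) 2 else 1
  in_bin_f <- population_bins(records, numerator_pop, scheme) == maf_bin
  in_bin_b <- population_bins(records, den_pop, scheme) == maf_bin
  rows <- lapply(categories, function(lab) {
    memb <- has_category(records, lab)
    F <- sum(in_bin_f & memb)
    B <- sum(in_bin_b & memb)
    if (baseline == "complement") {
      F0 <- sum(in_bin_f & !memb)
      B0 <- sum(in_bin_b & !memb)
    } else {
      F0 <- sum(in_bin_f)
      B0 <- sum(in_bin_b)
    }
    if (F + B == 0 || F == 0 || B == 0 || F0 == 0 || B0 == 0) {
      er <- if (F + B > 0) enrichment_ratio(F, B, conf_level) else NULL
      return(data.frame(category = lab, maf_bin = maf_bin, F = F, B = B,
                        u_hat = if (is.null(er)) NA_real_ else er$u_hat,
                        ci_low = if (is.null(er)) NA_real_ else er$ci_low,
                        ci_high = if (is.null(er)) NA_real_ else er$ci_high,
                        baseline_F = F0, baseline_B = B0,
                        z = NA_real_, p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    cmp <- compare_categories(F, B, F0, B0, conf_level = conf_level)
    data.frame(category = lab, maf_bin = maf_bin, F = F, B = B,
               u_hat = cmp$result1$u_hat, ci_low = cmp$result1$ci_low,
               ci_high = cmp$result1$ci_high,
               baseline_F = F0, baseline_B = B0,
               z = cmp$z, p = cmp$p, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-(out$F + out$B)), , drop = FALSE]
  out$bonferroni <- pmin(1, out$p * sum(!out$flagged))
  rownames(out) <- NULL
  out
}
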