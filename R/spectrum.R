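#' Folded minor allele frequency
#'
#' The frequency of the less common allele, `min(ac, an - ac) / an`, in
#' `[0, 0.5]`. "Folded" means no ancestral/derived polarity is assumed:
#' the value is invariant under `ac -> an - ac`.
#'
#' @param ac Alt-allele count(s).
#' @param an Total allele number(s); must be positive.
#' @return Numeric vector of folded frequencies.
#' @export
maf <- function(ac, an) {
  if (any(an <= 0)) stop("total allele number must be > 0")
  if (any(ac < 0 | ac > an)) stop("allele count outside [0, an]")
  pmin(ac, an - ac) / an
}

#' Per-population folded MAF of a record table
#'
#' @param records A record table.
#' @param population 1 or 2.
#' @return Numeric vector of MAFs for the chosen population.
#' @export
record_maf <- function(records, population) {
  stopifnot(population %in% c(1, 2))
  if (population == 1) maf(records$ac1, records$an1) else maf(records$ac2, records$an2)
}

record_mac <- function(records, population) {
  if (population == 1) pmin(records$ac1, records$an1 - records$ac1)
  else pmin(records$ac2, records$an2 - records$ac2)
}

#' Define a minor allele frequency binning scheme
#'
#' The default reproduces the four-bin scheme used for bottleneck/isolate
#' frequency-spectrum comparisons: a rare bin from `mac_floor` copies up to
#' 0.5%, then 0.5--2%, 2--5%, and a common bin above 5%. Interior bins are
#' lower-inclusive, upper-exclusive; a MAF exactly at the last edge falls in
#' the top bin.
#'
#' @param edges Strictly increasing MAF breakpoints in (0, 0.5].
#' @param labels One label per bin (`length(edges) + 1`); generated when `NULL`.
#' @param mac_floor Minimum minor allele count defining the lowest bin's
#'   lower boundary.
#' @return An object of class `maf_bin_scheme`.
#' @export
maf_bin_scheme <- function(edges = c(0.005, 0.02, 0.05), labels = NULL,
                           mac_floor = 5L) {
  stopifnot(length(edges) >= 1, all(diff(edges) > 0),
            all(edges > 0), all(edges <= 0.5), mac_floor >= 1)
  pct <- function(x) sub("\\.?0+$", "", sprintf("%.3f", 100 * x))
  if (is.null(labels)) {
    labels <- character(length(edges) + 1L)
    labels[1L] <- sprintf("%d copies-%s%%", as.integer(mac_floor), pct(edges[1L]))
    if (length(edges) > 1L)
      labels[seq(2L, length(edges))] <-
        sprintf("%s-%s%%", pct(edges[-length(edges)]), pct(edges[-1L]))
    labels[length(labels)] <- sprintf(">%s%%", pct(edges[length(edges)]))
  }
  stopifnot(length(labels) == length(edges) + 1L)
  structure(list(edges = edges, labels = labels,
                 mac_floor = as.integer(mac_floor)),
            class = "maf_bin_scheme")
}

#' @export
print.maf_bin_scheme <- function(x, ...) {
  cat("<maf_bin_scheme>", paste(x$labels, collapse = " | "),
      sprintf("(mac_floor=%d)\n", x$mac_floor))
  invisible(x)
}

#' Assign variants to MAF bins
#'
#' Monomorphic variants (MAF 0) get the label `"monomorphic"`; variants
#' below the first edge whose minor allele count is under the scheme's
#' `mac_floor` get `"filtered"`. All other variants fall in exactly one bin:
#' `[edge_i, edge_{i+1})` for interior bins, `>= last edge` for the top bin.
#'
#' @param maf_value Folded MAF value(s).
#' @param mac_value Minor allele count(s), same length.
#' @param scheme A [maf_bin_scheme()].
#' @return Character vector of bin labels.
#' @export
assign_bin <- function(maf_value, mac_value, scheme = maf_bin_scheme()) {
  stopifnot(inherits(scheme, "maf_bin_scheme"))
  idx <- findInterval(maf_value, scheme$edges, left.open = FALSE) + 1L
  out <- scheme$labels[idx]
  low <- maf_value < scheme$edges[1L]
  out[low & mac_value < scheme$mac_floor] <- "filtered"
  out[maf_value == 0] <- "monomorphic"
  out
}

## per-population bin labels with the within-population polymorphism floor:
## any variant with at least one minor-allele copy below the first edge
## counts in the lowest bin (the pooled MAC filter governs inclusion).
population_bins <- function(records, population, scheme) {
  within_pop <- scheme
  within_pop$mac_floor <- 1L
  assign_bin(record_maf(records, population),
             record_mac(records, population), within_pop)
}

#' Frequency-spectrum summary of two populations
#'
#' For each MAF bin, counts the variants each population holds in that bin
#' (using each population's own folded MAF) and the percentage of them that
#' are also polymorphic (minor allele count >= 1) in the other population.
#' This is the standard "spectrum plus sharing" table used to show
#' rare-variant depletion and low-frequency excess after a bottleneck.
#'
#' @param records A MAC-filtered record table.
#' @param scheme A [maf_bin_scheme()].
#' @return Data frame with columns `bin`, `count_pop1`, `count_pop2`,
#'   `pct_shared_1in2`, `pct_shared_2in1`.
#' @export
spectrum_table <- function(records, scheme = maf_bin_scheme()) {
  records <- validate_records(records)
  if (!nrow(records)) stop("spectrum_table: empty record table")
  b1 <- population_bins(records, 1, scheme)
  b2 <- population_bins(records, 2, scheme)
  poly1 <- record_mac(records, 1) >= 1L
  poly2 <- record_mac(records, 2) >= 1L
  out <- data.frame(bin = scheme$labels, stringsAsFactors = FALSE)
  out$count_pop1 <- vapply(scheme$labels, function(l) sum(b1 == l), integer(1))
  out$count_pop2 <- vapply(scheme$labels, function(l) sum(b2 == l), integer(1))
  out$pct_shared_1in2 <- vapply(scheme$labels, function(l) {
    in_bin <- b1 == l
    if (!any(in_bin)) return(NA_real_)
    100 * mean(poly2[in_bin])
  }, numeric(1))
  out$pct_shared_2in1 <- vapply(scheme$labels, function(l) {
    in_bin <- b2 == l
    if (!any(in_bin)) return(NA_real_)
    100 * mean(poly1[in_bin])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Ratio of population-1 to population-2 variant counts along a MAF grid
#'
#' Counts, per grid interval, the variants each population holds at a folded
#' MAF in that interval (polymorphic variants only) and forms the
#' pop1/pop2 count ratio -- the curve used to visualise how a bottleneck
#' depletes the rare end of the spectrum and inflates the low-frequency
#' range.
#'
#' @param records A record table.
#' @param grid Strictly increasing MAF breakpoints; interval `i` is
#'   `[grid[i], grid[i+1])`, the last interval closed above.
#' @return Data frame with `lower`, `upper`, `count_pop1`, `count_pop2`,
#'   `ratio` (NA when undefined), `undefined` (TRUE when `count_pop2` is 0).
#' @export
ratio_curve <- function(records, grid) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0))
  records <- validate_records(records)
  m1 <- record_maf(records, 1)
  m2 <- record_maf(records, 2)
  k <- length(grid) - 1L
  count_in <- function(m, i) {
    if (i < k) sum(m >= grid[i] & m < grid[i + 1L] & m > 0)
    else sum(m >= grid[i] & m <= grid[i + 1L] & m > 0)
  }
  n1 <- vapply(seq_len(k), function(i) count_in(m1, i), numeric(1))
  n2 <- vapply(seq_len(k), function(i) count_in(m2, i), numeric(1))
  data.frame(lower = grid[-length(grid)], upper = grid[-1L],
             count_pop1 = n1, count_pop2 = n2,
             ratio = ifelse(n2 > 0, n1 / n2, NA_real_),
             undefined = n2 == 0)
}
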