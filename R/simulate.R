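#' Two-population split demography with a bottleneck
#'
#' Describes an ancestral population that splits `t_split` generations ago
#' into population A, of constant diploid size `pop_a_size`, and population
#' B, which is founded at `bottleneck_size` diploids and grows exponentially
#' at rate `growth_rate` per generation for the first `t_growth` generations
#' after the founding, then stays at the size reached. The defaults give a
#' founder event (5000 -> 1000) followed by exponential recovery to the
#' ancestral size over the whole branch, a scaled-down rendition of an
#' isolate founded by a fraction of its source population that later
#' expanded -- enough extra drift to deplete rare variation and shift
#' surviving rare alleles into the low-frequency range without erasing the
#' low-frequency bin altogether.
#'
#' @param n_anc Ancestral diploid population size.
#' @param t_split Generations since the populations split.
#' @param pop_a_size Constant diploid size of population A.
#' @param bottleneck_size Diploid size of population B at the split.
#' @param growth_rate Per-generation exponential growth rate of population B
#'   during the growth phase; default recovers `n_anc` from
#'   `bottleneck_size` over `t_growth` generations.
#' @param t_growth Generations of growth at the start of the B branch
#'   (`t_growth <= t_split`).
#' @param seed RNG seed used by [simulate_sites()].
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(n_anc = 5000, t_split = 100, pop_a_size = 5000,
                             bottleneck_size = 1000,
                             growth_rate = log(n_anc / bottleneck_size) / t_growth,
                             t_growth = 100, seed = 1L) {
  m <- list(n_anc = n_anc, t_split = t_split, pop_a_size = pop_a_size,
            bottleneck_size = bottleneck_size, growth_rate = growth_rate,
            t_growth = t_growth, seed = as.integer(seed))
  stopifnot(m$n_anc >= 2, m$pop_a_size >= 2, m$bottleneck_size >= 2,
            m$t_split >= m$t_growth, m$t_growth >= 0, m$growth_rate >= 0)
  structure(m, class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf(paste0("<demography_model> anc %d | split %d gen ago | ",
                     "A: %d | B: %d growing at %.4f/gen for last %d gen ",
                     "(final %d) | seed %d\n"),
              x$n_anc, x$t_split, x$pop_a_size, x$bottleneck_size,
              x$growth_rate, x$t_growth,
              utils::tail(branch_b_sizes(x), 1L), x$seed))
  invisible(x)
}

## diploid size of population B at each generation 1..t_split after the
## split: exponential growth from the founding size, then constant
branch_b_sizes <- function(model) {
  grown <- if (model$t_growth > 0)
    pmax(2, round(model$bottleneck_size *
                    exp(model$growth_rate * seq_len(model$t_growth))))
  else integer(0)
  final <- if (length(grown)) grown[length(grown)] else model$bottleneck_size
  c(grown, rep(final, model$t_split - model$t_growth))
}

#' Specify a simulated variant category
#'
#' @param label Category name.
#' @param fraction_of_sites Proportion of simulated sites in the category.
#' @param sel_coeff Purifying selection coefficient `s` in `[0, 1)`, applied
#'   deterministically each generation as `f <- f (1 - s) / (1 - f s)`
#'   before drift.
#' @return An object of class `category_spec`.
#' @export
category_spec <- function(label, fraction_of_sites, sel_coeff = 0) {
  stopifnot(is.character(label), length(label) == 1L,
            fraction_of_sites >= 0, fraction_of_sites <= 1,
            sel_coeff >= 0, sel_coeff < 1)
  structure(list(label = label, fraction_of_sites = fraction_of_sites,
                 sel_coeff = sel_coeff), class = "category_spec")
}

## one branch: deterministic selection then binomial drift, vectorised
## across sites; sizes is the per-generation diploid size trajectory
drift_branch <- function(f, s, sizes) {
  for (N in sizes) {
    f <- f * (1 - s) / (1 - f * s)
    f <- rbinom(length(f), 2L * N, f) / (2L * N)
  }
  f
}

#' Simulate two population samples under a bottleneck demography
#'
#' Per site, an ancestral derived-allele frequency is drawn from a density
#' proportional to `1/x` on `[1/(2 n_anc), 0.5]` (the neutral shape of the
#' low-frequency end of the spectrum, truncated for folded-spectrum
#' symmetry), then propagated independently down the two branches by
#' per-generation binomial Wright-Fisher resampling of `2N` chromosomes,
#' with the branch's size trajectory and deterministic purifying selection
#' applied before each drift step. Final diploid samples are drawn
#' binomially from each branch's final frequency. Sites monomorphic in both
#' samples are dropped. Sites are independent (no linkage), which matches
#' the per-site statistics this package computes.
#'
#' @param model A [demography_model()].
#' @param n_sites Number of sites to simulate before the both-monomorphic
#'   drop.
#' @param categories List of [category_spec()]; site category labels are
#'   assigned by their fractions (remaining sites are uncategorised).
#' @param n_sample_a,n_sample_b Diploid sample sizes drawn from populations
#'   A and B (population 1 and 2 of the output records).
#' @return A record table with `categories` populated and positions placed
#'   uniformly on a synthetic contig `"sim1"`.
#' @export
simulate_sites <- function(model, n_sites = 200000L, categories = list(),
                           n_sample_a = 1463L, n_sample_b = 1463L) {
  stopifnot(inherits(model, "demography_model"), n_sites >= 1)
  if (inherits(categories, "category_spec")) categories <- list(categories)
  fracs <- vapply(categories, `[[`, numeric(1), "fraction_of_sites")
  if (sum(fracs) > 1) stop("category fractions sum to more than 1")
  b_sizes <- branch_b_sizes(model)
  if (n_sample_a > model$pop_a_size)
    stop("n_sample_a exceeds population A size")
  if (n_sample_b > b_sizes[length(b_sizes)])
    stop("n_sample_b exceeds population B's final size")

  set.seed(model$seed)
  x0 <- 1 / (2 * model$n_anc)
  f_anc <- x0 * (0.5 / x0)^runif(n_sites)          # inverse-CDF of 1/x density

  labels <- vapply(categories, `[[`, character(1), "label")
  sels <- vapply(categories, `[[`, numeric(1), "sel_coeff")
  cat_idx <- sample.int(length(categories) + 1L, n_sites, replace = TRUE,
                        prob = c(fracs, 1 - sum(fracs)))
  s_site <- c(sels, 0)[cat_idx]

  f_a <- drift_branch(f_anc, s_site, rep(model$pop_a_size, model$t_split))
  f_b <- drift_branch(f_anc, s_site, b_sizes)

  an1 <- 2L * as.integer(n_sample_a)
  an2 <- 2L * as.integer(n_sample_b)
  ac1 <- rbinom(n_sites, an1, f_a)
  ac2 <- rbinom(n_sites, an2, f_b)

  keep <- !((ac1 == 0L & ac2 == 0L) | (ac1 == an1 & ac2 == an2))
  contig_len <- 10L * n_sites
  pos <- sort(sample.int(contig_len, sum(keep)))
  ref <- sample(BASES, sum(keep), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))

  rec <- data.frame(chrom = "sim1", pos = pos, ref = ref, alt = alt,
                    ac1 = ac1[keep], an1 = an1, ac2 = ac2[keep], an2 = an2,
                    stringsAsFactors = FALSE)
  kept_cat <- cat_idx[keep]
  rec$categories <- lapply(kept_cat, function(i)
    if (i <= length(labels)) labels[i] else character(0))
  rownames(rec) <- NULL
  validate_records(rec)
}

## deterministic genotype layout consistent with an allele count:
## floor(ac/2) hom-alt individuals, one het if ac is odd, rest hom-ref
genotype_column <- function(ac, n_samples) {
  n_hom <- ac %/% 2L
  gt <- rep("0|0", n_samples)
  if (n_hom > 0) gt[seq_len(n_hom)] <- "1|1"
  if (ac %% 2L == 1L) gt[n_hom + 1L] <- "1|0"
  gt
}

write_vcf <- function(records, ac, an, path, panel, contig_len) {
  n <- panel$n_samples
  stopifnot(all(an == 2L * n))
  samples <- sprintf("%s%04d", panel$label, seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", records$chrom[1L], contig_len),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gts <- vapply(records$ac_out, function(a)
    paste(genotype_column(a, n), collapse = "\t"), character(1))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", ".", "GT", gts, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated record table as analysis-ready fixture files
#'
#' Emits, under `out_dir`: one VCF per population (genotypes laid out
#' deterministically consistent with the allele counts, so the pair
#' round-trips through [read_vcf_pair()] to the same counts), one BED3 file
#' per category, the allele-count TSV, and a JSON manifest with the model
#' parameters.
#'
#' @param records A record table from [simulate_sites()].
#' @param out_dir Output directory (created if needed).
#' @param panel1,panel2 [population_panel()] objects; sample counts must
#'   match the record table's allele numbers.
#' @param model Optional [demography_model()] recorded in the manifest.
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(records, out_dir, panel1, panel2, model = NULL) {
  records <- validate_records(records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contig_len <- max(records$pos) + 1L
  p <- list(vcf1 = file.path(out_dir, paste0(panel1$label, ".vcf")),
            vcf2 = file.path(out_dir, paste0(panel2$label, ".vcf")),
            counts = file.path(out_dir, "counts.tsv"),
            manifest = file.path(out_dir, "manifest.json"))
  r1 <- records; r1$ac_out <- records$ac1
  r2 <- records; r2$ac_out <- records$ac2
  write_vcf(r1, records$ac1, records$an1, p$vcf1, panel1, contig_len)
  write_vcf(r2, records$ac2, records$an2, p$vcf2, panel2, contig_len)
  write_count_table(records, p$counts)
  for (lab in category_labels(records)) {
    bed <- file.path(out_dir, paste0(lab, ".bed"))
    memb <- records[has_category(records, lab), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d", memb$chrom, memb$pos - 1L, memb$pos), bed)
    p[[paste0("bed_", lab)]] <- bed
  }
  manifest <- list(panel1 = unclass(panel1), panel2 = unclass(panel2),
                   n_records = nrow(records))
  if (!is.null(model)) manifest$model <- unclass(model)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Check that a simulated demography shows the expected bottleneck signatures
#'
#' Runs [simulate_sites()] over several seeds and asserts, on the pooled
#' MAC-filtered table, that population B (the bottlenecked branch) shows
#' (i) fewer rare variants (MAF below the scheme's first edge) than
#' population A, (ii) a proportional excess of low-frequency variants --
#' the share of B's variants falling in the scheme's third bin (2--5%
#' under the default scheme), relative to A's share, is above 1 -- and
#' (iii), when a category under purifying selection is simulated, a
#' category enrichment z (population B as numerator) above the median z of
#' the neutral categories. Signature (ii) is deliberately the *relative*
#' bin share, the form in which a founder effect enriches the low-frequency
#' spectrum: the bottleneck branch carries fewer variants overall, but a
#' larger fraction of them sit at low frequency.
#'
#' @param model A [demography_model()] with a genuine bottleneck.
#' @param n_sites Sites per seed.
#' @param scheme A [maf_bin_scheme()].
#' @param seeds Integer seeds; the model's own seed is replaced per run.
#' @param categories List of [category_spec()]; the default plants one
#'   selected category among neutral ones.
#' @param n_sample_a,n_sample_b Diploid sample sizes.
#' @param min_mac Pooled MAC filter applied before the checks.
#' @return A list of class `bottleneck_check` with per-seed measurements and
#'   logical `pass_*` components.
#' @export
bottleneck_expectation_check <- function(model = demography_model(),
                                         n_sites = 200000L,
                                         scheme = maf_bin_scheme(),
                                         seeds = 1:3,
                                         categories = default_sim_categories(),
                                         n_sample_a = 1463L,
                                         n_sample_b = 1463L,
                                         min_mac = 5L) {
  sel_labels <- vapply(categories, `[[`, character(1), "label")
  sel_s <- vapply(categories, `[[`, numeric(1), "sel_coeff")
  selected <- sel_labels[sel_s > 0]
  low_bin <- scheme$labels[1L]
  mid_bin <- scheme$labels[min(3L, length(scheme$labels))]
  per_seed <- lapply(seeds, function(sd) {
    m <- model
    m$seed <- as.integer(sd)
    rec <- simulate_sites(m, n_sites, categories, n_sample_a, n_sample_b)
    rec <- filter_mac(rec, min_mac)
    spec <- spectrum_table(rec, scheme)
    rare_a <- spec$count_pop1[spec$bin == low_bin]
    rare_b <- spec$count_pop2[spec$bin == low_bin]
    tot_a <- sum(record_mac(rec, 1) >= 1L)
    tot_b <- sum(record_mac(rec, 2) >= 1L)
    mid_ratio <- (spec$count_pop2[spec$bin == mid_bin] / tot_b) /
      (spec$count_pop1[spec$bin == mid_bin] / tot_a)
    z_sel <- NA_real_
    z_neutral_median <- NA_real_
    if (length(selected)) {
      scan <- category_enrichment_scan(rec, scheme, mid_bin,
                                       categories = sel_labels,
                                       numerator_pop = 2)
      z_sel <- scan$z[scan$category %in% selected][1L]
      z_neutral_median <- median(scan$z[!scan$category %in% selected],
                                 na.rm = TRUE)
    }
    list(seed = sd, rare_a = rare_a, rare_b = rare_b, mid_ratio = mid_ratio,
         z_sel = z_sel, z_neutral_median = z_neutral_median)
  })
  rare_ok <- vapply(per_seed, function(x) x$rare_b < x$rare_a, logical(1))
  mid_ok <- vapply(per_seed, function(x) x$mid_ratio > 1, logical(1))
  sel_ok <- if (length(selected))
    vapply(per_seed, function(x) isTRUE(x$z_sel > x$z_neutral_median),
           logical(1))
  else NA
  bottlenecked <- model$bottleneck_size < model$pop_a_size
  structure(list(per_seed = per_seed,
                 pass_rare_depletion = all(rare_ok),
                 pass_low_freq_excess = all(mid_ok),
                 pass_selection_detected = if (length(selected)) all(sel_ok) else NA,
                 bottleneck_modelled = bottlenecked),
            class = "bottleneck_check")
}

#' Default simulated category set
#'
#' One loss-of-function-like category under strong purifying selection plus
#' three neutral categories, used by [bottleneck_expectation_check()].
#'
#' @param sel_coeff Selection coefficient of the LoF-like category.
#' @return List of [category_spec()].
#' @export
default_sim_categories <- function(sel_coeff = 0.035) {
  list(category_spec("lof_like", 0.08, sel_coeff = sel_coeff),
       category_spec("neutral_a", 0.05),
       category_spec("neutral_b", 0.05),
       category_spec("neutral_c", 0.05))
}

#' @export
print.bottleneck_check <- function(x, ...) {
  verdict <- function(ok) if (isTRUE(ok)) "PASS" else if (isFALSE(ok)) "FAIL" else "n/a"
  if (!x$bottleneck_modelled)
    cat("no bottleneck detected: model has bottleneck_size >= pop_a_size\n")
  cat("rare-variant depletion in B: ", verdict(x$pass_rare_depletion), "\n",
      "low-frequency excess in B:   ", verdict(x$pass_low_freq_excess), "\n",
      "selected category detected:  ", verdict(x$pass_selection_detected), "\n",
      sep = "")
  for (s in x$per_seed)
    cat(sprintf("  seed %d: rare A=%d B=%d | low-freq share ratio B/A=%.3f | z_sel=%.2f z_neutral=%.2f\n",
                s$seed, s$rare_a, s$rare_b, s$mid_ratio, s$z_sel,
                s$z_neutral_median))
  invisible(x)
}
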