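test_that("fold ratio compares the pooled minor allele across populations", {
  ## PCSK9-like counts: 113/2926 vs 59/2926 gives the published 1.92x
  rec <- validate_records(data.frame(
    chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    ac1 = 113L, an1 = 2926L, ac2 = 59L, an2 = 2926L))
  fr <- fold_ratio(rec, 1)
  expect_equal(round(fr$fold, 2), 1.92)
  expect_false(fr$absent_in_denominator)

  ## identical frequencies -> 1
  rec$ac2 <- 113L
  expect_equal(fold_ratio(rec, 1)$fold, 1)

  ## the alt allele can be the pooled *major* allele: fold then uses ref
  rec2 <- validate_records(data.frame(
    chrom = "chr1", pos = 200L, ref = "A", alt = "G",
    ac1 = 1900L, an1 = 2000L, ac2 = 1800L, an2 = 2000L))
  expect_equal(fold_ratio(rec2, 1)$fold, (100 / 2000) / (200 / 2000))

  expect_error(fold_ratio(validate_records(data.frame(
    chrom = "chr1", pos = 1L, ref = "A", alt = "G",
    ac1 = 0L, an1 = 100L, ac2 = 5L, an2 = 100L)), 1), "numerator")
})

test_that("absent denominator uses the single-copy pseudo-frequency", {
  ## an AGA-like variant: 28 copies in 2926 alleles, absent in the other panel
  rec <- validate_records(data.frame(
    chrom = "chr4", pos = 500L, ref = "G", alt = "C",
    ac1 = 28L, an1 = 2926L, ac2 = 0L, an2 = 2926L))
  fr <- fold_ratio(rec, 1)
  expect_true(fr$absent_in_denominator)
  expect_equal(fr$fold, 28)   # (28/2926) / (1/2926)

  ## the frequency-level form reproduces the published rounded value
  expect_equal(round(fold_from_freqs(0.0096, 0, n_den_samples = 1463)), 28)
  expect_error(fold_from_freqs(0.01, 0), "n_den_samples")
})

test_that("fold classes are half-open and fold duality holds on shared variants", {
  sch <- fold_class_scheme()
  expect_equal(fold_class(c(1.9, 2, 4.99, 5, 10, 49.9, 50, 1000), sch),
               c(NA, "2-5x", "2-5x", "5-10x", "10-50x", "10-50x",
                 ">=50x", ">=50x"))

  rec <- random_records(800, seed = 17)
  ## keep variants whose pooled minor allele is present in both populations
  pooled_alt_minor <- (rec$ac1 + rec$ac2) <=
    (rec$an1 + rec$an2) - (rec$ac1 + rec$ac2)
  g1 <- ifelse(pooled_alt_minor, rec$ac1, rec$an1 - rec$ac1)
  g2 <- ifelse(pooled_alt_minor, rec$ac2, rec$an2 - rec$ac2)
  shared <- rec[g1 > 0 & g2 > 0, ]
  f1 <- fold_ratio(shared, 1)
  f2 <- fold_ratio(shared, 2)
  expect_false(any(f1$absent_in_denominator | f2$absent_in_denominator))
  expect_equal(f1$fold, 1 / f2$fold)
})

test_that("fold summary equals a brute-force scan on hand-set variants", {
  an <- 1000L
  ac1 <- c(400L, 30L, 100L, 250L, 20L, 8L, 3L, 55L, 5L, 120L)
  ac2 <- c(100L, 10L, 2L, 5L, 0L, 4L, 150L, 55L, 480L, 1L)
  rec <- validate_records(data.frame(
    chrom = "chr1", pos = seq(100L, by = 100L, length.out = 10L),
    ref = "A", alt = "G", ac1 = ac1, an1 = an, ac2 = ac2, an2 = an))
  rec$categories <- c(replicate(5, "setA", simplify = FALSE),
                      replicate(5, character(0), simplify = FALSE))
  sch <- fold_class_scheme()
  got <- fold_summary(rec, sch, numerator_pop = 1)

  ## brute force: pooled minor allele frequency in each population
  pooled_minor_is_alt <- (ac1 + ac2) <= (2 * an - ac1 - ac2)
  g1 <- ifelse(pooled_minor_is_alt, ac1, an - ac1) / an
  g2 <- ifelse(pooled_minor_is_alt, ac2, an - ac2) / an
  present <- g1 > 0
  fold <- g1[present] / ifelse(g2[present] > 0, g2[present], 1 / an)
  cls <- cut(fold, c(sch$breakpoints, Inf), right = FALSE,
             labels = sch$labels)
  gw <- got[got$category == "genome-wide", ]
  expect_equal(gw$count, as.integer(table(cls)[sch$labels]),
               ignore_attr = TRUE)
  expect_equal(gw$total, rep(sum(present), nrow(gw)))
  expect_equal(gw$percent, 100 * gw$count / sum(present))

  inA <- vapply(rec$categories[present], function(x) "setA" %in% x, logical(1))
  catA <- got[got$category == "setA", ]
  expect_equal(catA$count, as.integer(table(cls[inA])[sch$labels]),
               ignore_attr = TRUE)
  expect_equal(catA$total, rep(sum(inA), nrow(catA)))
})

test_that("no enrichment beyond 2x yields empty classes", {
  rec <- validate_records(data.frame(
    chrom = "chr1", pos = 1:20 * 50L, ref = "A", alt = "G",
    ac1 = rep(60L, 20), an1 = 1000L, ac2 = rep(50L, 20), an2 = 1000L))
  got <- fold_summary(rec, numerator_pop = 1)
  expect_equal(sum(got$count), 0L)
  expect_equal(sum(got$percent), 0)
})

test_that("summary from published-style counts recovers cumulative fractions", {
  s <- fold_summary_from_counts(c(100, 50, 30, 20), total = 1000)
  expect_equal(s$percent_at_least, c(20, 10, 5, 2))
  expect_equal(s$percent, c(10, 5, 3, 2))
  expect_error(fold_summary_from_counts(c(600, 600, 0, 0), total = 1000))
})
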