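test_that("enrichment ratio obeys its algebraic identities", {
  r <- enrichment_ratio(200, 100)
  expect_equal(r$u_hat, r$s_hat / (1 - r$s_hat))
  expect_equal(r$M, r$F + r$B)
  expect_true(r$ci_low < r$u_hat && r$u_hat < r$ci_high)

  ## var log u at s = 0.5 is exactly 4/M
  r2 <- enrichment_ratio(100, 100)
  expect_equal(r2$se_log_u^2, 4 / 200)
  expect_equal(r2$u_hat, 1)
  expect_equal(r2$p_binomial, 1)
  expect_equal(log(r2$ci_high), -log(r2$ci_low))   # symmetric on log scale

  ## swapping populations inverts u and reflects the CI on the log scale
  a <- enrichment_ratio(150, 60)
  b <- enrichment_ratio(60, 150)
  expect_equal(b$u_hat, 1 / a$u_hat)
  expect_equal(b$ci_low, 1 / a$ci_high)
  expect_equal(b$ci_high, 1 / a$ci_low)
  expect_equal(b$p_binomial, a$p_binomial)

  ## requested confidence level is honoured (not a hard-coded 1.96)
  r90 <- enrichment_ratio(150, 60, conf_level = 0.90)
  expect_lt(r90$ci_high, a$ci_high)
  expect_gt(r90$ci_low, a$ci_low)
})

test_that("zero counts are flagged, with an explicit Haldane escape hatch", {
  r <- enrichment_ratio(0, 25)
  expect_true(r$flagged)
  expect_true(is.na(r$ci_low))
  expect_lt(r$p_binomial, 1e-6)

  rh <- enrichment_ratio(0, 25, haldane = TRUE)
  expect_true(rh$flagged)
  expect_equal(rh$u_hat, 0.5 / 25.5)
  expect_false(is.na(rh$ci_low))

  expect_error(compare_categories(0, 10, 5, 5), "haldane")
  expect_silent(compare_categories(0, 10, 5, 5, haldane = TRUE))
})

test_that("delta-method CI matches a parametric bootstrap at small counts", {
  r <- enrichment_ratio(30, 10)
  set.seed(42)
  Fs <- rbinom(1e5, 40, 0.75)
  u <- Fs / (40 - Fs)
  u <- u[is.finite(u) & u > 0]
  boot <- quantile(u, c(0.025, 0.975), names = FALSE)
  ## the bootstrap distribution is discrete at M=40 (support gaps of ~0.2 on
  ## the log scale near the upper quantile), so agreement is asserted to
  ## within that granularity
  expect_lt(abs(log(boot[1]) - log(r$ci_low)), 0.25)
  expect_lt(abs(log(boot[2]) - log(r$ci_high)), 0.25)
  expect_lt(abs(sd(log(u)) - r$se_log_u) / r$se_log_u, 0.1)
})

test_that("two-category test is antisymmetric and null at equal ratios", {
  eq <- compare_categories(200, 100, 400, 200)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  ab <- compare_categories(150, 120, 5000, 4800)
  ba <- compare_categories(5000, 4800, 150, 120)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$pooled_s, (150 + 5000) / (150 + 120 + 5000 + 4800))
})

test_that("delta-method p agrees with the two-sample proportion test", {
  cases <- list(c(150, 120, 5000, 4800),
                c(60, 40, 55, 45),
                c(52000, 48000, 50500, 49500))
  for (cc in cases) {
    p_delta <- compare_categories(cc[1], cc[2], cc[3], cc[4])$p
    p_prop <- prop.test(c(cc[1], cc[3]), c(cc[1] + cc[2], cc[3] + cc[4]),
                        correct = FALSE)$p.value
    expect_lt(abs(p_delta - p_prop) / p_prop, 0.10)
  }
  ## agreement tightens as the counts grow (effect scaled as 1/sqrt(M) so
  ## the p-value stays in a comparable moderate range at every size)
  rel_err <- vapply(c(1e2, 1e3, 1e5), function(M) {
    F1 <- round(M * (0.5 + 0.8 / sqrt(M))); B1 <- M - F1
    F2 <- 5 * M; B2 <- 5 * M
    pd <- compare_categories(F1, B1, F2, B2)$p
    pp <- prop.test(c(F1, F2), c(M, 10 * M), correct = FALSE)$p.value
    abs(pd - pp) / pp
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
})

test_that("category scan counts per-population bin membership correctly", {
  rec <- random_records(4000, seed = 21, an1 = 400L, an2 = 400L)
  rec <- filter_mac(rec, 5L)
  ## deterministic category: first half of the table
  rec$categories <- lapply(seq_len(nrow(rec)), function(i)
    if (i <= nrow(rec) / 2) "half" else character(0))
  sch <- maf_bin_scheme()
  scan <- category_enrichment_scan(rec, sch, ">5%")
  memb <- vapply(rec$categories, function(x) "half" %in% x, logical(1))
  b1 <- assign_bin(record_maf(rec, 1), pmin(rec$ac1, rec$an1 - rec$ac1),
                   maf_bin_scheme(mac_floor = 1))
  b2 <- assign_bin(record_maf(rec, 2), pmin(rec$ac2, rec$an2 - rec$ac2),
                   maf_bin_scheme(mac_floor = 1))
  expect_equal(scan$F[scan$category == "half"], sum(memb & b1 == ">5%"))
  expect_equal(scan$B[scan$category == "half"], sum(memb & b2 == ">5%"))
  expect_equal(scan$baseline_F[scan$category == "half"],
               sum(!memb & b1 == ">5%"))

  ## a category covering every variant equals the "all" baseline exactly
  rec$categories <- replicate(nrow(rec), "everything", simplify = FALSE)
  scan_all <- category_enrichment_scan(rec, sch, ">5%", baseline = "all")
  expect_equal(scan_all$z, 0)
  expect_equal(scan_all$p, 1)
})

test_that("two-category test holds its nominal type-I error rate", {
  set.seed(31)
  n_rep <- 1000
  rejected <- vapply(seq_len(n_rep), function(i) {
    F1 <- rbinom(1, 500, 0.5)
    F2 <- rbinom(1, 5000, 0.5)
    if (F1 == 0 || F1 == 500 || F2 == 0 || F2 == 5000) return(FALSE)
    compare_categories(F1, 500 - F1, F2, 5000 - F2)$p < 0.05
  }, logical(1))
  rate <- mean(rejected)
  tol <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), tol)
})
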