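test_that("count table round-trips and invariant violations name the row", {
  rec <- toy_records()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(rec, path)
  back <- read_count_table(path)
  expect_equal(back[1:8], rec[1:8])

  bad <- rec
  bad$ac1[2] <- 11L   # ac > an
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad[1:8], path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(path2), "row 2")

  odd <- rec
  odd$an2[3] <- 9L
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(odd[1:8], path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(path3), "diploid")
})

test_that("VCF pair merging splits alts, fills absent sites, tracks missingness", {
  fx <- write_toy_vcf_pair(withr::local_tempdir())
  rec <- read_vcf_pair(fx$vcf1, fx$vcf2, fx$panel1, fx$panel2)

  expect_equal(nrow(rec), 4L)   # TA alt dropped, union of sites kept
  expect_equal(sum(rec$ac1 > 0 & rec$ac2 > 0), 2L)

  r100 <- rec[rec$pos == 100, ]
  expect_equal(c(r100$ac1, r100$an1, r100$ac2, r100$an2), c(3L, 6L, 1L, 4L))

  ## multi-allelic site: only the SNV alt survives, an counts all called alleles
  r400 <- rec[rec$pos == 400, ]
  expect_equal(c(r400$ref, r400$alt), c("T", "C"))
  expect_equal(c(r400$ac1, r400$an1), c(2L, 6L))
  ## absent from pop2: zero count with the panel's full allele number
  expect_equal(c(r400$ac2, r400$an2), c(0L, 4L))

  ## ./. reduces an by two alleles
  r300 <- rec[rec$pos == 300, ]
  expect_equal(c(r300$ac2, r300$an2), c(1L, 2L))

  expect_error(read_vcf_pair(fx$vcf1, fx$vcf2, fx$panel1, fx$panel2,
                             strict = TRUE), "strict")
})

test_that("conflicting REF at a shared position is reported with the site", {
  fx <- write_toy_vcf_pair(withr::local_tempdir())
  lines <- readLines(fx$vcf2)
  lines <- sub("chr1\t100\t.\tA\tG", "chr1\t100\t.\tT\tG", lines,
               fixed = TRUE)
  writeLines(lines, fx$vcf2)
  expect_error(read_vcf_pair(fx$vcf1, fx$vcf2, fx$panel1, fx$panel2),
               "chr1:100")
})

test_that("pooled MAC filter matches a brute-force scan and preserves counts", {
  rec <- random_records(500, seed = 7)
  for (min_mac in c(0L, 1L, 5L, 20L)) {
    got <- filter_mac(rec, min_mac)
    keep <- vapply(seq_len(nrow(rec)), function(i) {
      ac <- rec$ac1[i] + rec$ac2[i]
      an <- rec$an1[i] + rec$an2[i]
      min(ac, an - ac) >= min_mac
    }, logical(1))
    want <- rec[keep, ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
  expect_equal(filter_mac(rec, 0L), rec)          # identity at floor 0

  ## the published floor: 4 pooled copies in ~5852 alleles is removed
  one <- toy_records()[1, ]
  one$ac1 <- 2L; one$an1 <- 2926L; one$ac2 <- 2L; one$an2 <- 2926L
  expect_equal(nrow(filter_mac(validate_records(one), 5L)), 0L)
})

test_that("annotation follows BED half-open coordinates exactly", {
  rec <- toy_records()   # positions 100..500
  ann <- list(
    category_annotation("right_edge", data.frame(chrom = "chr1", start = 99, end = 100)),
    category_annotation("left_edge", data.frame(chrom = "chr1", start = 100, end = 200)),
    category_annotation("before", data.frame(chrom = "chr1", start = 0, end = 99)))
  got <- annotate_categories(rec, ann)
  cats_100 <- got$categories[[which(got$pos == 100)]]
  expect_true("right_edge" %in% cats_100)    # interval (99,100) covers pos 100
  expect_false("left_edge" %in% cats_100)    # (100,200) starts after pos 100
  expect_false("before" %in% cats_100)       # (0,99) ends before it
  cats_101_plus <- got$categories[[which(got$pos == 200)]]
  expect_true("left_edge" %in% cats_101_plus)  # pos 200 -> 0-based 199 in [100,200)
})

test_that("annotation equals an all-pairs check and ignores ordering", {
  rec <- random_records(1000, seed = 11)
  set.seed(12)
  anns <- lapply(1:5, function(k) {
    starts <- sample.int(10000, 10)
    category_annotation(paste0("cat", k),
                        data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                                   start = starts,
                                   end = starts + sample.int(500, 10)))
  })
  got <- annotate_categories(rec, anns)
  brute <- lapply(seq_len(nrow(rec)), function(i) {
    hits <- vapply(anns, function(a) {
      iv <- a$intervals
      any(iv$chrom == rec$chrom[i] &
            rec$pos[i] - 1L >= iv$start & rec$pos[i] - 1L < iv$end)
    }, logical(1))
    vapply(anns, `[[`, character(1), "label")[hits]
  })
  expect_equal(lapply(got$categories, sort), lapply(brute, sort))

  ## shuffled records and shuffled interval lists give the same memberships
  perm <- sample(nrow(rec))
  got2 <- annotate_categories(rec[perm, ], rev(anns))
  expect_equal(lapply(got2$categories, sort),
               lapply(got$categories[perm], sort))
})

test_that("malformed BED lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50"), path)
  expect_error(read_bed_category(path), "line 2")
})
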