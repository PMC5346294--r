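## In-code fixtures shared across test files. Everything is generated at
## test time; nothing binary is stored in the repository.

## small hand-built record table: positions/counts chosen to exercise MAF
## folding, bin boundaries and category membership
toy_records <- function() {
  validate_records(data.frame(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "C"),
    ac1 = c(3L, 8L, 0L, 5L, 50L),
    an1 = c(10L, 10L, 10L, 10L, 100L),
    ac2 = c(2L, 2L, 4L, 0L, 40L),
    an2 = c(10L, 10L, 10L, 10L, 100L),
    stringsAsFactors = FALSE))
}

## random but valid record table for property-style tests
random_records <- function(n, seed, an1 = 200L, an2 = 300L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  validate_records(data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(10 * n, n),
    ref = ref, alt = alt,
    ac1 = sample(0:an1, n, replace = TRUE),
    an1 = an1,
    ac2 = sample(0:an2, n, replace = TRUE),
    an2 = an2,
    stringsAsFactors = FALSE))
}

## two 3-variant toy VCFs sharing two sites; pop1 has 3 samples, pop2 has 2.
## site chr1:300 carries a missing genotype in pop2; chr1:400 is
## multi-allelic in pop1 with one non-SNV alt allele.
write_toy_vcf_pair <- function(dir) {
  hdr <- function(samples) c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  v1 <- file.path(dir, "pop1.vcf")
  v2 <- file.path(dir, "pop2.vcf")
  writeLines(c(hdr(c("s1", "s2", "s3")),
               "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
               "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
               "chr1\t400\t.\tT\tC,TA\t.\tPASS\t.\tGT\t1/2\t0/1\t0/0"), v1)
  writeLines(c(hdr(c("u1", "u2")),
               "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
               "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t0|0",
               "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1"), v2)
  list(vcf1 = v1, vcf2 = v2,
       panel1 = population_panel("P1", 3L), panel2 = population_panel("P2", 2L))
}
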