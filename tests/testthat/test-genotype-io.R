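test_that("PLINK triple round-trips bit-for-bit, including missing calls", {
  set.seed(11)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 3 * 5, replace = TRUE), 3, 5)
  g[1, 2] <- NA
  cohort <- make_cohort(g, samples = tibble::tibble(
    id = c("a", "b", "c"), sex = c("F", "M", "F")))
  prefix <- file.path(withr::local_tempdir(), "fix")
  write_plink(cohort, prefix)
  back <- read_plink(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                     paste0(prefix, ".fam"))
  expect_identical(unname(back$genotypes), unname(cohort$genotypes))
  expect_equal(back$variants$pos_bp, cohort$variants$pos_bp)
  expect_equal(back$samples$id, cohort$samples$id)

  # larger random cohort round-trip property
  g2 <- matrix(sample(c(0L, 1L, 2L, NA), 17 * 40, replace = TRUE,
                      prob = c(0.4, 0.3, 0.25, 0.05)), 17, 40)
  c2 <- make_cohort(g2)
  write_plink(c2, paste0(prefix, "2"))
  b2 <- read_plink(paste0(prefix, "2.bed"), paste0(prefix, "2.bim"),
                   paste0(prefix, "2.fam"))
  expect_identical(unname(b2$genotypes), unname(g2))
})

test_that("a hand-encoded .bed byte decodes to the documented 2-bit codes", {
  # 4 samples, 1 SNP. Codes (LSB pair first): sample1 = 00 (hom allele-1,
  # genotype 0), sample2 = 01 (missing), sample3 = 10 (het), sample4 = 11
  # (hom allele-2, genotype 2)  -> byte 0b11100100 = 0xE4.
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE4)), file.path(dir, "h.bed"))
  writeLines("1\trs1\t0\t1000\tA\tB", file.path(dir, "h.bim"))
  writeLines(sprintf("f%d\ts%d\t0\t0\t1\t-9", 1:4, 1:4),
             file.path(dir, "h.fam"))
  ch <- read_plink(file.path(dir, "h.bed"), file.path(dir, "h.bim"),
                   file.path(dir, "h.fam"))
  expect_identical(unname(ch$genotypes[, 1]), c(0L, NA, 1L, 2L))
})

test_that("malformed inputs are rejected with informative errors", {
  g <- matrix(0L, 3, 5)
  cohort <- make_cohort(g)
  prefix <- file.path(withr::local_tempdir(), "bad")
  write_plink(cohort, prefix)
  # fam claims 4 samples but bed is sized for 3
  writeLines(sprintf("f%d\ts%d\t0\t0\t1\t-9", 1:5, 1:5),
             paste0(prefix, ".fam"))
  expect_error(read_plink(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                          paste0(prefix, ".fam")),
               "size mismatch")
  expect_error(read_plink("nope.bed", paste0(prefix, ".bim"),
                          paste0(prefix, ".fam")),
               "not found")
  # covariate ids not matching fam ids
  write_plink(cohort, prefix)
  cov <- data.frame(id = c("id1", "id2", "wrong"), sex = "F",
                    region = "EUR", birth_year = 2000)
  expect_error(read_plink(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                          paste0(prefix, ".fam"), covariate_table = cov),
               "id3")
})

test_that("variant_stats counts alleles over non-missing calls only", {
  g <- rbind(c(0L, 2L, 0L), c(0L, 2L, 1L), c(1L, 2L, NA))
  st <- variant_stats(make_cohort(g))
  # SNP1: allele-b count 1 of 6 -> maf 1/6, minor is allele_b
  expect_equal(st$maf[1], 1 / 6)
  expect_equal(st$minor_allele[1], "B")
  # SNP2 monomorphic for allele_b -> maf 0, minor is allele_a
  expect_equal(st$maf[2], 0)
  expect_equal(st$minor_allele[2], "A")
  # SNP3: one missing -> call rate 2/3, maf over 4 alleles = 1/4
  expect_equal(st$call_rate[3], 2 / 3)
  expect_equal(st$maf[3], 0.25)
  # a 0.5 tie resolves toward allele_a
  st2 <- variant_stats(make_cohort(matrix(c(0L, 2L), 2, 1)))
  expect_equal(st2$minor_allele, "A")
})

test_that("maf is invariant under an allele-label swap", {
  set.seed(7)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 30, replace = TRUE), 20, 30)
  ch <- make_cohort(g)
  swapped <- make_cohort(2L - g)
  expect_equal(variant_stats(ch)$maf, variant_stats(swapped)$maf)
})

test_that("filter_variants enforces thresholds, is idempotent, reports", {
  set.seed(3)
  n <- 200
  g <- matrix(1L, n, 10)
  g[, 1:7] <- sample(c(0L, 1L, 2L), n * 7, replace = TRUE)
  g[, 8] <- 0L; g[1, 8] <- 2L; g[2, 8] <- 2L  # maf = 2/200 = 0.01 (kept)
  g[, 9] <- 0L; g[1, 9] <- 2L                 # maf = 0.005 (below 0.01)
  g[, 10] <- 0L                               # monomorphic
  g[1:20, 7] <- NA                            # call rate 0.9
  ch <- make_cohort(g)
  filtered <- filter_variants(ch)
  expect_equal(ncol(filtered$genotypes), 7)
  rep <- attr(filtered, "filter_report")
  expect_equal(rep$n[rep$criterion == "retained"], 7)
  expect_equal(rep$n[rep$criterion == "call_rate"], 1)
  expect_equal(rep$n[rep$criterion == "maf"], 2)

  twice <- filter_variants(filtered)
  expect_identical(twice$genotypes, filtered$genotypes)

  # thresholds 0,0 keep everything polymorphic or not
  all_kept <- filter_variants(ch, min_call_rate = 0, min_maf = 0,
                              autosomes_only = FALSE)
  expect_equal(ncol(all_kept$genotypes), 10)

  # non-autosomal chromosome label removed under autosomes_only
  chx <- make_cohort(g[, 1:2], chrom = c(1L, 1L))
  chx$variants$chrom <- c("1", "X")
  fx <- filter_variants(chx, min_call_rate = 0, min_maf = 0)
  expect_equal(fx$variants$chrom, "1")

  expect_error(filter_variants(make_cohort(matrix(NA_integer_, 5, 2))),
               "empty panel")
})

test_that("phased VCF input round-trips haplotypes and rejects unphased GT", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "p.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t250\trs2\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|0"), vcf)
  ch <- read_phased_vcf(vcf)
  expect_equal(unname(ch$genotypes), rbind(c(1L, 1L), c(2L, 0L)))
  expect_equal(ch$haplotypes$h1[1, ], c(0L, 1L))
  expect_equal(ch$haplotypes$h2[1, ], c(1L, 0L))
  expect_equal(ch$variants$allele_b, c("G", "T"))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_phased_vcf(vcf), "unphased")
})

test_that("race ages derive from start dates when explicit ages are absent", {
  records <- tibble::tibble(id = c("a", "b"),
                            start_date = c("2004-07-01", "2006-03-01"),
                            birth_year = c(2000L, 2000L))
  ph <- assign_race_status(records, c("a", "b"))
  expect_equal(ph$raced, c(1L, 0L))   # 4.5 vs 6.2 years old
})
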