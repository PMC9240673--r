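# PLINK 1 binary triple (.bed/.bim/.fam), SNP-major layout.
# 2-bit codes per byte (least-significant pair = first sample):
#   00 = homozygous allele-1 (.bim col 5)  -> genotype 0
#   01 = missing                           -> NA
#   10 = heterozygous                      -> 1
#   11 = homozygous allele-2 (.bim col 6)  -> 2
# Genotypes count copies of allele_b (= .bim allele-2).

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
.plink_decode_lut <- c(0L, NA_integer_, 1L, 2L)

#' Read a PLINK 1 binary genotype triple
#'
#' Reads SNP-major `.bed`/`.bim`/`.fam` files into a [roh_cohort()].
#' `.bim` allele-1 maps to `allele_a` and allele-2 to `allele_b`; genotype
#' values count copies of `allele_b`. An optional covariate table (data frame
#' or TSV path with columns `id`, `sex`, `region`, `birth_year`) is joined by
#' sample id; ids present in one source but not the other are an error.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files.
#' @param covariate_table Optional data frame or TSV path keyed by `id`.
#' @return A [roh_cohort()].
#' @export
read_plink <- function(bed_path, bim_path, fam_path, covariate_table = NULL) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "pos_bp", "allele_a", "allele_b")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], PLINK_MAGIC)) {
    abort("not a SNP-major PLINK 1 .bed file (bad magic bytes)")
  }
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m) {
    abort(sprintf(
      ".bed size mismatch: expected %d data bytes for %d samples x %d SNPs, found %d",
      bytes_per_snp * m, n, m, length(body)))
  }
  b <- as.integer(body)
  dim(b) <- c(bytes_per_snp, m)
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = m)
  codes[seq(1, by = 4, length.out = bytes_per_snp), ] <- b %% 4L
  codes[seq(2, by = 4, length.out = bytes_per_snp), ] <- (b %/% 4L) %% 4L
  codes[seq(3, by = 4, length.out = bytes_per_snp), ] <- (b %/% 16L) %% 4L
  codes[seq(4, by = 4, length.out = bytes_per_snp), ] <- (b %/% 64L) %% 4L
  geno <- matrix(.plink_decode_lut[codes[seq_len(n), , drop = FALSE] + 1L],
                 nrow = n, ncol = m)

  chrom_num <- suppressWarnings(as.integer(bim$chrom))
  variants <- tibble(
    chrom = ifelse(is.na(chrom_num), bim$chrom, chrom_num),
    pos_bp = bim$pos_bp, snp_id = bim$snp_id,
    allele_a = bim$allele_a, allele_b = bim$allele_b
  )
  if (all(!is.na(chrom_num))) variants$chrom <- chrom_num

  samples <- tibble(id = fam[[2]])
  if (!is.null(covariate_table)) {
    cov <- if (is.character(covariate_table)) {
      utils::read.table(covariate_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else as.data.frame(covariate_table)
    if (!"id" %in% names(cov)) abort("covariate table must have an `id` column")
    cov$id <- as.character(cov$id)
    missing_cov <- setdiff(samples$id, cov$id)
    extra_cov <- setdiff(cov$id, samples$id)
    if (length(missing_cov) > 0 || length(extra_cov) > 0) {
      abort(paste0(
        "covariate ids do not match .fam ids",
        if (length(missing_cov) > 0)
          paste0("; missing covariates for: ",
                 paste(head(missing_cov, 5), collapse = ", ")),
        if (length(extra_cov) > 0)
          paste0("; covariate rows without genotypes: ",
                 paste(head(extra_cov, 5), collapse = ", "))))
    }
    samples <- dplyr::left_join(samples, as_tibble(cov), by = "id")
  }
  roh_cohort(geno, variants, samples)
}

#' Write a cohort as a PLINK 1 binary triple
#'
#' @param cohort A [roh_cohort()].
#' @param prefix Output path prefix; writes `<prefix>.bed`, `.bim`, `.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "roh_cohort"))
  g <- cohort$genotypes
  n <- nrow(g); m <- ncol(g)
  v <- cohort$variants
  utils::write.table(
    data.frame(v$chrom, v$snp_id, 0, v$pos_bp, v$allele_a, v$allele_b),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  s <- cohort$samples
  sex_code <- if ("sex" %in% names(s)) ifelse(s$sex == "M", 1L, 2L) else 0L
  utils::write.table(
    data.frame(s$id, s$id, 0, 0, sex_code, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  # genotype -> 2-bit code: 0 -> 00, NA -> 01, 1 -> 10, 2 -> 11
  code_lut <- c(0L, 2L, 3L)
  codes <- matrix(1L, nrow = 4 * ceiling(n / 4), ncol = m)
  gc_ <- g
  codes[seq_len(n), ] <- ifelse(is.na(gc_), 1L, code_lut[gc_ + 1L])
  codes[seq_len(nrow(codes)) > n, ] <- 0L  # pad bits are zero
  bytes_per_snp <- ceiling(n / 4)
  i1 <- seq(1, by = 4, length.out = bytes_per_snp)
  body <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] +
    64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(body), con)
  invisible(prefix)
}

#' Read a covariate or race-record TSV
#'
#' Thin readers for the two delimited side tables: covariates
#' (`id`, `sex`, `region`, `birth_year`) and race records
#' (`id`, `age_at_first_start`, optionally `n_races`).
#'
#' @param path TSV path with a header row.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = c(id = "character")))
}

#' @rdname read_covariates
#' @export
read_race_records <- function(path) read_covariates(path)
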