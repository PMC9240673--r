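#' Read a phased VCF into a cohort
#'
#' Reads diploid biallelic genotypes with phased GT fields (`0|1` style)
#' into a [roh_cohort()] carrying both haplotypes, for the haplotype
#' screen. REF maps to `allele_a`, ALT to `allele_b`; any unphased
#' separator (`/`) is an error -- no phasing is attempted here.
#'
#' @param path VCF path (plain or bgzipped).
#' @param covariate_table Optional covariates joined by sample id (see
#'   [read_plink()]).
#' @return A phased [roh_cohort()].
#' @export
read_phased_vcf <- function(path, covariate_table = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)) {
    abort("VCF contains unphased genotypes ('/'); phased input required")
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_num <- function(x) {
    out <- suppressWarnings(matrix(as.integer(x), nrow = nrow(gt)))
    out
  }
  h1 <- t(to_num(a1)); h2 <- t(to_num(a2))
  geno <- h1 + h2
  chrom_num <- suppressWarnings(as.integer(fix[, "CHROM"]))
  variants <- tibble(
    chrom = if (all(!is.na(chrom_num))) chrom_num else fix[, "CHROM"],
    pos_bp = as.integer(fix[, "POS"]),
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    allele_a = fix[, "REF"], allele_b = fix[, "ALT"])
  samples <- tibble(id = colnames(gt))
  if (!is.null(covariate_table)) {
    cov <- if (is.character(covariate_table)) {
      read_covariates(covariate_table)
    } else as_tibble(covariate_table)
    samples <- dplyr::left_join(samples, cov, by = "id")
  }
  # haplotype matrices must be complete for the screen; missing sites are
  # tolerated in the genotype matrix only
  complete <- !anyNA(h1) && !anyNA(h2)
  roh_cohort(geno, variants, samples,
             haplotypes = if (complete) list(h1 = h1, h2 = h2) else NULL)
}
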