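#' Genotype cohort container
#'
#' Bundles a diploid biallelic genotype matrix with its variant map, sample
#' table and (optionally) phased haplotypes. Genotypes are coded as the count
#' of `allele_b` (0 = homozygous `allele_a`, 1 = heterozygous, 2 = homozygous
#' `allele_b`, `NA` = missing). Phased haplotypes, when present, are two
#' samples x variants 0/1 matrices whose sum reproduces the genotype matrix.
#'
#' @param genotypes Integer matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`. Row names are ignored; sample order follows `samples`.
#' @param variants Data frame with columns `chrom` (integer autosome id, or a
#'   character label for non-autosomes), `pos_bp` (1-based position),
#'   `snp_id`, `allele_a`, `allele_b`. Positions must be strictly increasing
#'   within each chromosome.
#' @param samples Data frame with at least a column `id`; typically also
#'   `sex` (`"F"`/`"M"`), `region` (`"EUR"`/`"ANZ"`) and `birth_year`.
#' @param haplotypes Optional list of two 0/1 matrices (`h1`, `h2`) with the
#'   same dimensions as `genotypes` and `h1 + h2 == genotypes` wherever the
#'   genotype is not missing.
#'
#' @return An object of class `roh_cohort`.
#' @export
roh_cohort <- function(genotypes, variants, samples, haplotypes = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)

  required <- c("chrom", "pos_bp", "snp_id", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("variants is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"id" %in% names(samples)) abort("samples must have an `id` column")
  if (nrow(genotypes) != nrow(samples)) {
    abort(sprintf("genotype matrix has %d rows but samples has %d",
                  nrow(genotypes), nrow(samples)))
  }
  if (ncol(genotypes) != nrow(variants)) {
    abort(sprintf("genotype matrix has %d columns but variants has %d rows",
                  ncol(genotypes), nrow(variants)))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotypes must be 0, 1, 2 or NA")
  }
  if (any(variants$allele_a == variants$allele_b)) {
    abort("allele_a and allele_b must differ for every variant")
  }
  pos_ok <- variants |>
    dplyr::mutate(.i = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_bp) > 0) || dplyr::n() == 1)
  if (!all(pos_ok$ok)) {
    abort("positions must be strictly increasing within each chromosome")
  }
  if (!is.null(haplotypes)) {
    stopifnot(is.list(haplotypes), length(haplotypes) == 2)
    h1 <- haplotypes[[1]]; h2 <- haplotypes[[2]]
    if (!all(dim(h1) == dim(genotypes)) || !all(dim(h2) == dim(genotypes))) {
      abort("haplotype matrices must match genotype dimensions")
    }
    obs <- !is.na(genotypes)
    if (!all((h1 + h2)[obs] == genotypes[obs])) {
      abort("haplotypes are inconsistent with genotypes (h1 + h2 != g)")
    }
    haplotypes <- list(h1 = h1, h2 = h2)
  }
  structure(
    list(genotypes = genotypes, variants = variants, samples = samples,
         haplotypes = haplotypes),
    class = "roh_cohort"
  )
}

#' @export
print.roh_cohort <- function(x, ...) {
  cat(sprintf("<roh_cohort> %d samples x %d variants on %d chromosome(s)%s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$variants$chrom)),
              if (is.null(x$haplotypes)) "" else ", phased"))
  invisible(x)
}

#' @export
dim.roh_cohort <- function(x) dim(x$genotypes)

#' Subset a cohort by variant index
#'
#' @param cohort A [roh_cohort()].
#' @param keep Logical or integer index over variants.
#' @return A `roh_cohort` restricted to the selected variants.
#' @export
subset_variants <- function(cohort, keep) {
  stopifnot(inherits(cohort, "roh_cohort"))
  hap <- cohort$haplotypes
  if (!is.null(hap)) {
    hap <- list(h1 = hap$h1[, keep, drop = FALSE],
                h2 = hap$h2[, keep, drop = FALSE])
  }
  roh_cohort(cohort$genotypes[, keep, drop = FALSE],
             cohort$variants[keep, , drop = FALSE],
             cohort$samples, hap)
}

#' Per-variant call rate and minor allele frequency
#'
#' Call rate is the fraction of samples with a non-missing genotype; minor
#' allele frequency is computed over non-missing calls. A variant where both
#' alleles are at frequency 0.5 reports `allele_a` as the minor allele.
#'
#' @param cohort A [roh_cohort()].
#' @return A tibble with one row per variant: `snp_id`, `chrom`, `pos_bp`,
#'   `call_rate`, `maf`, `minor_allele` (the allele string), and
#'   `minor_is_b` (logical; `NA` when every call is missing).
#' @export
variant_stats <- function(cohort) {
  stopifnot(inherits(cohort, "roh_cohort"))
  g <- cohort$genotypes
  n <- nrow(g)
  n_obs <- n - colSums(is.na(g))
  count_b <- colSums(g, na.rm = TRUE)
  freq_b <- ifelse(n_obs > 0, count_b / (2 * n_obs), NA_real_)
  # ties at 0.5 resolve toward allele_a as the minor allele
  minor_is_b <- ifelse(is.na(freq_b), NA, freq_b < 0.5)
  maf <- pmin(freq_b, 1 - freq_b)
  tibble(
    snp_id = cohort$variants$snp_id,
    chrom = cohort$variants$chrom,
    pos_bp = cohort$variants$pos_bp,
    call_rate = n_obs / n,
    maf = maf,
    minor_is_b = minor_is_b,
    minor_allele = ifelse(is.na(minor_is_b), NA_character_,
                          ifelse(minor_is_b, cohort$variants$allele_b,
                                 cohort$variants$allele_a))
  )
}

#' Filter variants on call rate, MAF and autosome membership
#'
#' Applies the standard post-genotyping panel filters: minimum call rate,
#' minimum minor allele frequency, and (optionally) autosomes only. A
#' chromosome is treated as autosomal when its label parses as a positive
#' integer. Variants with every call missing are always removed.
#'
#' @param cohort A [roh_cohort()].
#' @param min_call_rate Minimum call rate (default 0.99).
#' @param min_maf Minimum minor allele frequency (default 0.01); the filter
#'   keeps variants with `maf >= min_maf`.
#' @param autosomes_only Drop variants whose chromosome label is not a
#'   positive integer (default `TRUE`).
#' @return The filtered `roh_cohort`, with an attribute `filter_report`
#'   (tibble of counts removed per criterion; a variant failing several
#'   criteria is counted under each).
#' @export
filter_variants <- function(cohort, min_call_rate = 0.99, min_maf = 0.01,
                            autosomes_only = TRUE) {
  stats <- variant_stats(cohort)
  chrom_num <- suppressWarnings(as.integer(as.character(stats$chrom)))
  is_autosome <- !is.na(chrom_num) & chrom_num > 0
  fail_all_missing <- stats$call_rate == 0
  fail_call <- !fail_all_missing & stats$call_rate < min_call_rate
  fail_maf <- !fail_all_missing & stats$maf < min_maf
  fail_auto <- autosomes_only & !is_autosome
  keep <- !(fail_all_missing | fail_call | fail_maf | fail_auto)
  if (!any(keep)) abort("no variants survive filtering: empty panel")
  report <- tibble(
    criterion = c("all_missing", "call_rate", "maf", "non_autosomal",
                  "retained"),
    n = c(sum(fail_all_missing), sum(fail_call), sum(fail_maf),
          sum(fail_auto), sum(keep))
  )
  out <- subset_variants(cohort, keep)
  attr(out, "filter_report") <- report
  out
}
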