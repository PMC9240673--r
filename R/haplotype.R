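#' Extract phased haplotypes around a focal SNP
#'
#' Restricts both haplotypes of every sample to the SNPs within
#' `flank_bp` of the focal SNP on its chromosome. Requires a phased
#' cohort; no internal phasing is attempted.
#'
#' @param cohort A phased [roh_cohort()].
#' @param focal_snp A `snp_id` present in the cohort's variant map.
#' @param flank_bp Flank on each side of the focal SNP (default 500000,
#'   i.e. a 1 Mb window).
#' @return A list of class `hap_window`: `focal_snp`, `chrom`, `pos_bp`,
#'   `positions`, `n_positions`, and `haplotypes` (tibble with
#'   `sample_id`, `hap` (1 or 2) and the allele `string`).
#' @export
extract_window <- function(cohort, focal_snp, flank_bp = 500000) {
  stopifnot(inherits(cohort, "roh_cohort"))
  if (is.null(cohort$haplotypes)) {
    abort("cohort is unphased: haplotype extraction requires phased input")
  }
  hit <- which(cohort$variants$snp_id == focal_snp)
  if (length(hit) != 1) abort(paste0("focal SNP not found: ", focal_snp))
  ch <- cohort$variants$chrom[hit]
  pos <- cohort$variants$pos_bp[hit]
  on_chrom <- cohort$variants$chrom == ch
  win <- which(on_chrom & cohort$variants$pos_bp >= pos - flank_bp &
                 cohort$variants$pos_bp <= pos + flank_bp)
  chrom_range <- range(cohort$variants$pos_bp[on_chrom])
  if (pos - flank_bp < chrom_range[1] || pos + flank_bp > chrom_range[2]) {
    warn("window truncated at the chromosome edge; haplotypes are asymmetric")
  }
  str_of <- function(h) {
    apply(h[, win, drop = FALSE], 1, paste, collapse = "")
  }
  ids <- cohort$samples$id
  haps <- dplyr::bind_rows(
    tibble(sample_id = ids, hap = 1L, string = str_of(cohort$haplotypes$h1)),
    tibble(sample_id = ids, hap = 2L, string = str_of(cohort$haplotypes$h2)))
  structure(list(focal_snp = focal_snp, chrom = ch, pos_bp = pos,
                 positions = cohort$variants$pos_bp[win],
                 n_positions = length(win), haplotypes = haps),
            class = "hap_window")
}

.hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Consensus haplotype among ROH-homozygote carriers
#'
#' Identifies the modal haplotype (ties broken lexicographically) among the
#' haplotypes of the ROH + homozygous individuals, the fraction of those
#' individuals homozygous for it, the mean Hamming mismatch of their
#' non-identical haplotypes, and exact-copy carrier status for every
#' sample (a carrier holds at least one exact copy of the consensus).
#'
#' @param window A [extract_window()] result.
#' @param roh_aa_sample_ids Ids of samples homozygous for the focal minor
#'   allele inside a ROH.
#' @return A list of class `consensus_report`: `consensus`,
#'   `fraction_homozygous_identical`, `mean_mismatch`, `hap_frequency`
#'   (exact copies over all 2n haplotypes), and `carriers` (tibble with
#'   `sample_id`, `n_copies`, `carrier`, `near_miss` for <= 2 mismatches).
#' @export
consensus_analysis <- function(window, roh_aa_sample_ids) {
  stopifnot(inherits(window, "hap_window"))
  if (length(roh_aa_sample_ids) == 0) {
    abort("no ROH + homozygous individuals: consensus undefined")
  }
  haps <- window$haplotypes
  aa <- haps[haps$sample_id %in% roh_aa_sample_ids, ]
  tab <- table(aa$string)
  top <- names(tab)[tab == max(tab)]
  consensus <- sort(top)[1]

  by_sample <- aa |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(both = all(.data$string == consensus), .groups = "drop")
  frac_hom <- mean(by_sample$both)

  mism <- vapply(aa$string[aa$string != consensus], .hamming, numeric(1),
                 b = consensus)
  mean_mismatch <- if (length(mism) > 0) mean(mism) else 0

  carriers <- haps |>
    dplyr::mutate(
      exact = .data$string == consensus,
      dist = purrr::map_dbl(.data$string, .hamming, b = consensus)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_copies = sum(.data$exact),
                     min_dist = min(.data$dist), .groups = "drop") |>
    dplyr::mutate(carrier = .data$n_copies >= 1,
                  near_miss = !.data$carrier & .data$min_dist <= 2)

  structure(list(
    consensus = consensus,
    fraction_homozygous_identical = frac_hom,
    mean_mismatch = mean_mismatch,
    hap_frequency = sum(haps$string == consensus) / nrow(haps),
    carriers = carriers), class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<consensus_report> %d-SNP consensus at frequency %.3f;\n",
    "  %.1f%% of focal homozygotes identical, mean mismatch %.2f\n"),
    nchar(x$consensus), x$hap_frequency,
    100 * x$fraction_homozygous_identical, x$mean_mismatch))
  invisible(x)
}

#' Haplotype-frequency enrichment between two groups
#'
#' Compares chromosome-level (2 per individual) consensus-copy counts
#' between two groups with a two-sided Fisher exact test.
#'
#' @param n_copies Integer vector of consensus copies per sample (0/1/2).
#' @param group Factor or character vector with exactly two levels.
#' @return Tibble with one row per group (`group`, `n_chromosomes`,
#'   `n_copies`, `frequency`) plus an `enrichment_p` attribute; also
#'   returned as column `p_value` (same value on both rows).
#' @export
group_enrichment <- function(n_copies, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) abort("exactly two groups required")
  counts <- tapply(n_copies, group, sum)
  totals <- 2 * tabulate(group, nbins = 2)
  if (any(totals == 0)) abort("a group has zero chromosomes")
  tab <- rbind(counts, totals - counts)
  p <- fisher.test(tab)$p.value
  out <- tibble(group = levels(group), n_chromosomes = totals,
                n_copies = as.integer(counts),
                frequency = as.numeric(counts / totals), p_value = p)
  attr(out, "enrichment_p") <- p
  out
}

#' Hardy-Weinberg projection of homozygote and carrier counts
#'
#' Expected counts among `n_individuals` under random mating at haplotype
#' frequency `q`: `round(q^2 n)` homozygotes and `round(2 q (1-q) n)`
#' carriers.
#'
#' @param q Haplotype frequency in `[0, 1]`.
#' @param n_individuals Population size.
#' @return Named numeric vector `c(homozygotes, carriers)`.
#' @export
hwe_expected_counts <- function(q, n_individuals) {
  stopifnot(q >= 0, q <= 1, n_individuals >= 0)
  c(homozygotes = round(q^2 * n_individuals),
    carriers = round(2 * q * (1 - q) * n_individuals))
}
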