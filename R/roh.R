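#' Sliding-window ROH caller parameters
#'
#' Parameter set for the run-of-homozygosity caller, following the
#' PLINK 1.9 `--homozyg` conventions. Defaults correspond to
#' `--homozyg-window-snp 30 --homozyg-snp 30 --homozyg-kb 300
#' --homozyg-gap 150 --homozyg-density 100 --homozyg-window-missing 1
#' --homozyg-window-het 1` with the tool's default window hit threshold
#' of 0.05.
#'
#' @param window_snp Sliding window size in SNPs.
#' @param min_snp Minimum SNPs in an emitted segment.
#' @param min_kb Minimum segment length in kb.
#' @param max_gap_kb Maximum gap between adjacent SNPs inside a segment (kb);
#'   larger gaps split the run and both halves are re-tested.
#' @param density_kb_per_snp Maximum average kb per SNP in a segment.
#' @param window_missing Maximum missing calls tolerated per window.
#' @param window_het Maximum heterozygous calls tolerated per window.
#' @param window_threshold Minimum fraction of homozygous windows among
#'   windows containing a SNP for that SNP to be flagged.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 30L, min_snp = 30L, min_kb = 300,
                       max_gap_kb = 150, density_kb_per_snp = 100,
                       window_missing = 1L, window_het = 1L,
                       window_threshold = 0.05) {
  p <- list(window_snp = as.integer(window_snp), min_snp = as.integer(min_snp),
            min_kb = min_kb, max_gap_kb = max_gap_kb,
            density_kb_per_snp = density_kb_per_snp,
            window_missing = as.integer(window_missing),
            window_het = as.integer(window_het),
            window_threshold = window_threshold)
  if (any(unlist(p) <= 0)) abort("all ROH parameters must be positive")
  if (p$window_threshold > 1) abort("window_threshold must be in (0, 1]")
  class(p) <- "roh_params"
  p
}

#' Flag SNPs lying in predominantly homozygous windows (one sample)
#'
#' For each SNP, every window of `window_snp` consecutive SNPs on the same
#' chromosome that contains it is classified as homozygous if it holds at
#' most `window_het` heterozygous and at most `window_missing` missing
#' calls. The SNP is flagged when the fraction of homozygous windows among
#' its containing windows reaches `window_threshold`. Chromosomes with fewer
#' SNPs than the window size use a single truncated window.
#'
#' @param genotypes Integer vector of one sample's genotypes (0/1/2/NA),
#'   aligned to `variants`.
#' @param variants Variant map tibble (`chrom`, `pos_bp`, ...) in panel order.
#' @param params A [roh_params()].
#' @return Logical vector, one flag per SNP.
#' @export
flag_candidate_snps <- function(genotypes, variants, params = roh_params()) {
  stopifnot(length(genotypes) == nrow(variants))
  flags <- logical(length(genotypes))
  for (idx in split(seq_along(genotypes), variants$chrom)) {
    flags[idx] <- roh_flags_cpp(as.integer(genotypes[idx]),
                                params$window_snp, params$window_het,
                                params$window_missing,
                                params$window_threshold)
  }
  flags
}

# Segment tests + end-trimming for one candidate run (indices into one
# chromosome's SNPs). Returns NULL or c(start_i, end_i).
.trim_run <- function(run, het_or_mis) {
  while (length(run) > 0 && het_or_mis[run[1]]) run <- run[-1]
  while (length(run) > 0 && het_or_mis[run[length(run)]]) run <- run[-length(run)]
  run
}

#' Call ROH segments for one sample from flagged SNPs
#'
#' Maximal runs of flagged SNPs become candidate segments; runs are split
#' wherever two adjacent SNPs are more than `max_gap_kb` apart, leading and
#' trailing heterozygous or missing SNPs are trimmed, and each piece is
#' emitted only if it has at least `min_snp` SNPs, spans at least `min_kb`,
#' and averages at most `density_kb_per_snp` kb per SNP.
#'
#' @param flags Logical vector from [flag_candidate_snps()].
#' @param genotypes The same sample's genotype vector.
#' @param variants Variant map tibble.
#' @param params A [roh_params()].
#' @param sample_id Sample id recorded in the output.
#' @return Tibble of segments: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp` (= `end_bp - start_bp + 1`).
#' @export
call_roh <- function(flags, genotypes, variants, params = roh_params(),
                     sample_id = "sample") {
  out <- list()
  for (idx in split(seq_len(nrow(variants)), variants$chrom)) {
    f <- flags[idx]
    if (!any(f)) next
    g <- genotypes[idx]
    pos <- variants$pos_bp[idx]
    chrom <- variants$chrom[idx[1]]
    het_or_mis <- is.na(g) | g == 1L
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      # split at gaps exceeding max_gap_kb between adjacent genotyped SNPs
      gaps <- diff(pos[run])
      cut_after <- which(gaps > params$max_gap_kb * 1000)
      piece_id <- cumsum(c(1L, as.integer(seq_along(gaps) %in% cut_after)))
      for (piece in split(run, piece_id)) {
        piece <- .trim_run(piece, het_or_mis)
        if (length(piece) < params$min_snp) next
        len_bp <- pos[piece[length(piece)]] - pos[piece[1]] + 1
        if (len_bp < params$min_kb * 1000) next
        if ((len_bp / 1000) / length(piece) > params$density_kb_per_snp) next
        out[[length(out) + 1L]] <- tibble(
          sample_id = sample_id, chrom = chrom,
          start_bp = pos[piece[1]], end_bp = pos[piece[length(piece)]],
          n_snps = length(piece), length_bp = len_bp)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(sample_id = character(), chrom = integer(),
                  start_bp = numeric(), end_bp = numeric(),
                  n_snps = integer(), length_bp = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start_bp)
}

#' Call ROH for every sample in a cohort
#'
#' @param cohort A [roh_cohort()].
#' @param params A [roh_params()].
#' @return Tibble of ROH segments across all samples (see [call_roh()]).
#' @export
detect_roh <- function(cohort, params = roh_params()) {
  stopifnot(inherits(cohort, "roh_cohort"))
  ids <- cohort$samples$id
  segs <- purrr::map(split(seq_len(nrow(cohort$variants)),
                           cohort$variants$chrom), function(idx) {
    res <- roh_call_chrom_cpp(
      cohort$genotypes[, idx, drop = FALSE],
      as.numeric(cohort$variants$pos_bp[idx]),
      params$window_snp, params$min_snp, params$min_kb, params$max_gap_kb,
      params$density_kb_per_snp, params$window_missing, params$window_het,
      params$window_threshold)
    tibble(sample_id = ids[res$sample],
           chrom = cohort$variants$chrom[idx[1]],
           start_bp = res$start_bp, end_bp = res$end_bp,
           n_snps = res$n_snps,
           length_bp = res$end_bp - res$start_bp + 1)
  })
  dplyr::bind_rows(segs) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start_bp)
}

#' ROH-based inbreeding coefficients
#'
#' F_ROH is the summed ROH length divided by the total autosomal length
#' covered by `chrom_lengths` (2281 Mb for the horse autosomes at full
#' scale). The short/long partition splits segments at `long_mb`
#' (segments of exactly `long_mb` count as long), so
#' `f_roh == f_roh_short + f_roh_long` exactly.
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param sample_ids Character vector of all sample ids (samples with no
#'   segments get zero coefficients).
#' @param chrom_lengths Tibble with `chrom` and `length_bp`.
#' @param long_mb Length threshold (Mb) separating short from long ROH.
#' @return Tibble: `sample_id`, `f_roh`, `f_roh_short`, `f_roh_long`.
#' @export
compute_inbreeding <- function(segments, sample_ids, chrom_lengths,
                               long_mb = 5) {
  total_bp <- sum(chrom_lengths$length_bp)
  len_lut <- setNames(chrom_lengths$length_bp, as.character(chrom_lengths$chrom))
  if (nrow(segments) > 0) {
    seg_chrom_len <- len_lut[as.character(segments$chrom)]
    if (any(is.na(seg_chrom_len)) || any(segments$end_bp > seg_chrom_len) ||
        any(segments$start_bp < 1)) {
      abort("segment outside chromosome bounds (or unknown chromosome)")
    }
  }
  base <- tibble(sample_id = sample_ids)
  sums <- segments |>
    dplyr::mutate(long = .data$length_bp >= long_mb * 1e6) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      short_bp = sum(.data$length_bp[!.data$long]),
      long_bp = sum(.data$length_bp[.data$long]), .groups = "drop")
  base |>
    dplyr::left_join(sums, by = "sample_id") |>
    tidyr::replace_na(list(short_bp = 0, long_bp = 0)) |>
    dplyr::mutate(
      f_roh_short = .data$short_bp / total_bp,
      f_roh_long = .data$long_bp / total_bp,
      f_roh = .data$f_roh_short + .data$f_roh_long) |>
    dplyr::select("sample_id", "f_roh", "f_roh_short", "f_roh_long")
}

#' Leave-one-chromosome-out inbreeding coefficients
#'
#' For each sample and chromosome, F_ROHmod is the summed length of ROH on
#' all other chromosomes divided by the genome length excluding that
#' chromosome, so local ROH effects at a focal SNP can be separated from
#' genome-wide inbreeding.
#'
#' @inheritParams compute_inbreeding
#' @return Long tibble: `sample_id`, `chrom`, `f_roh_mod`.
#' @export
froh_mod <- function(segments, sample_ids, chrom_lengths) {
  total_bp <- sum(chrom_lengths$length_bp)
  per_chrom <- segments |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::summarise(bp = sum(.data$length_bp), .groups = "drop")
  grid <- tidyr::expand_grid(sample_id = sample_ids,
                             chrom = chrom_lengths$chrom)
  totals <- per_chrom |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$bp), .groups = "drop")
  grid |>
    dplyr::left_join(per_chrom, by = c("sample_id", "chrom")) |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::left_join(dplyr::rename(chrom_lengths, chrom_bp = "length_bp"),
                     by = "chrom") |>
    tidyr::replace_na(list(bp = 0, total = 0)) |>
    dplyr::mutate(f_roh_mod = (.data$total - .data$bp) /
                    (total_bp - .data$chrom_bp)) |>
    dplyr::select("sample_id", "chrom", "f_roh_mod")
}

#' Expected generations to the common ancestor of a ROH
#'
#' Under a uniform recombination map with 1 Mb equivalent to 1 cM, a ROH of
#' expected length `L` cM traces back to a common ancestor haplotype
#' approximately `g = 100 / (2 L)` generations ago; a 5 Mb ROH therefore
#' points to an ancestor about 10 generations back.
#'
#' @param length_mb Segment length in Mb (> 0).
#' @return Generations to the common ancestor.
#' @export
generations_to_ancestor <- function(length_mb) {
  if (any(length_mb <= 0)) abort("length_mb must be positive")
  100 / (2 * length_mb)
}

#' Per-SNP ROH frequency across a cohort
#'
#' The fraction of samples whose ROH overlap each SNP position: the ROH
#' landscape, exposing hotspots and coldspots of homozygosity.
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param variants Variant map tibble.
#' @param n_samples Number of samples in the cohort.
#' @return Tibble: `snp_id`, `chrom`, `pos_bp`, `roh_freq`.
#' @export
roh_landscape <- function(segments, variants, n_samples) {
  counts <- numeric(nrow(variants))
  for (idx in split(seq_len(nrow(variants)), variants$chrom)) {
    segs <- segments[segments$chrom == variants$chrom[idx[1]], ]
    if (nrow(segs) == 0) next
    pos <- variants$pos_bp[idx]
    lo <- findInterval(segs$start_bp - 1L, pos) + 1L  # first SNP >= start
    hi <- findInterval(segs$end_bp, pos)              # last SNP <= end
    keep <- lo <= hi
    delta <- numeric(length(idx) + 1L)
    for (k in which(keep)) {
      delta[lo[k]] <- delta[lo[k]] + 1
      delta[hi[k] + 1L] <- delta[hi[k] + 1L] - 1
    }
    counts[idx] <- cumsum(delta[seq_along(idx)])
  }
  tibble(snp_id = variants$snp_id, chrom = variants$chrom,
         pos_bp = variants$pos_bp, roh_freq = counts / n_samples)
}

#' Mean inbreeding by birth year
#'
#' @param inbreeding Tibble from [compute_inbreeding()].
#' @param samples Sample table with `id` and `birth_year`.
#' @return Tibble: `birth_year`, `n`, `mean_f_roh`.
#' @export
froh_by_year <- function(inbreeding, samples) {
  inbreeding |>
    dplyr::inner_join(dplyr::select(samples, sample_id = "id", "birth_year"),
                      by = "sample_id") |>
    dplyr::group_by(.data$birth_year) |>
    dplyr::summarise(n = dplyr::n(), mean_f_roh = mean(.data$f_roh),
                     .groups = "drop")
}
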