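# Shared fixture builders and independent oracles.

# Small cohort with explicit genotypes; one chromosome unless chrom given.
make_cohort <- function(geno, pos = NULL, chrom = NULL, samples = NULL,
                        haplotypes = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep(1L, m)
  variants <- tibble::tibble(
    chrom = chrom, pos_bp = pos,
    snp_id = sprintf("s%d", seq_len(m)), allele_a = "A", allele_b = "B")
  if (is.null(samples)) {
    samples <- tibble::tibble(id = sprintf("id%d", seq_len(nrow(geno))))
  }
  rohdepress::roh_cohort(geno, variants, samples, haplotypes)
}

# ---- independent brute-force ROH oracle ----------------------------------
# Deliberately naive: explicit loops over every window and every run, no
# shared code with the package implementation.

oracle_flags_one_chrom <- function(g, params) {
  L <- length(g)
  w <- min(params$window_snp, L)
  n_win <- L - w + 1
  win_ok <- logical(n_win)
  for (j in seq_len(n_win)) {
    n_het <- 0; n_mis <- 0
    for (k in j:(j + w - 1)) {
      if (is.na(g[k])) n_mis <- n_mis + 1
      else if (g[k] == 1) n_het <- n_het + 1
    }
    win_ok[j] <- n_het <= params$window_het && n_mis <= params$window_missing
  }
  flags <- logical(L)
  for (i in seq_len(L)) {
    hits <- 0; tot <- 0
    for (j in seq_len(n_win)) {
      if (j <= i && i <= j + w - 1) {
        tot <- tot + 1
        if (win_ok[j]) hits <- hits + 1
      }
    }
    flags[i] <- hits / tot >= params$window_threshold
  }
  flags
}

oracle_segments_one_chrom <- function(g, pos, params, chrom = 1L,
                                      sample_id = "sample") {
  flags <- oracle_flags_one_chrom(g, params)
  out <- list()
  emit <- function(idx) {
    # trim het/missing ends
    while (length(idx) > 0 && (is.na(g[idx[1]]) || g[idx[1]] == 1)) {
      idx <- idx[-1]
    }
    while (length(idx) > 0) {
      last <- idx[length(idx)]
      if (is.na(g[last]) || g[last] == 1) idx <- idx[-length(idx)] else break
    }
    if (length(idx) < params$min_snp) return()
    len <- pos[idx[length(idx)]] - pos[idx[1]] + 1
    if (len < params$min_kb * 1000) return()
    if ((len / 1000) / length(idx) > params$density_kb_per_snp) return()
    out[[length(out) + 1]] <<- data.frame(
      sample_id = sample_id, chrom = chrom, start_bp = pos[idx[1]],
      end_bp = pos[idx[length(idx)]], n_snps = length(idx), length_bp = len)
  }
  i <- 1
  while (i <= length(g)) {
    if (!flags[i]) { i <- i + 1; next }
    j <- i
    while (j < length(g) && flags[j + 1]) j <- j + 1
    run <- i:j
    # split at big gaps
    piece <- run[1]
    for (k in seq_along(run)[-1]) {
      if (pos[run[k]] - pos[run[k - 1]] > params$max_gap_kb * 1000) {
        emit(piece)
        piece <- run[k]
      } else piece <- c(piece, run[k])
    }
    emit(piece)
    i <- j + 1
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric()))
  }
  do.call(rbind, out)
}

# Random single-sample genotype instance for oracle comparisons.
random_roh_instance <- function(n_snp, p_het = 0.1, p_mis = 0.03,
                                mean_gap = 20000) {
  pos <- cumsum(1 + stats::rgeom(n_snp, 1 / mean_gap))
  g <- sample(c(0L, 2L), n_snp, replace = TRUE)
  g[stats::runif(n_snp) < p_het] <- 1L
  g[stats::runif(n_snp) < p_mis] <- NA
  list(g = g, pos = pos)
}

# Tiny simulation config for fast tests.
tiny_config <- function(...) {
  rohdepress::sim_config(
    n_founders = 60, n_generations = 3, n_samples_out = 90,
    n_chrom = 3, chrom_length_mb = 40, snp_density_per_mb = 15,
    risk_locus = list(chrom = 2, pos_frac = 0.5,
                      haplotype_length_kb = 1000, q = 0.15),
    seed = 42L, ...)
}
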