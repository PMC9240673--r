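#' Principal components of the genomic relationship matrix
#'
#' Standardizes each SNP to `(x - 2p) / sqrt(2p(1-p))` (missing calls set
#' to 0 after centring), forms the variance-standardized additive
#' relationship matrix `G = Z Z' / m`, and returns its top eigenvectors.
#'
#' @param cohort A filtered [roh_cohort()] (monomorphic SNPs are skipped).
#' @param k Number of components (default 10).
#' @return List with `pcs` (n x k matrix, columns `PC1..PCk`),
#'   `eigenvalues`, and `m` (SNPs used).
#' @export
grm_pca <- function(cohort, k = 10) {
  g <- cohort$genotypes
  n <- nrow(g)
  if (k >= n) abort("k must be smaller than the number of samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) abort("no polymorphic SNPs for the relationship matrix")
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(g, 2, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  if (ncol(Z) < nrow(Z)) {
    # thin panels: left singular vectors of Z are the eigenvectors of
    # G = ZZ'/m, at O(n m^2) instead of O(n^3)
    if (k > ncol(Z)) abort("k exceeds the rank of the relationship matrix")
    sv <- svd(Z, nu = k, nv = 0)
    pcs <- sv$u
    evals <- sv$d^2 / ncol(Z)
  } else {
    G <- tcrossprod(Z) / ncol(Z)
    eg <- eigen(G, symmetric = TRUE)
    pcs <- eg$vectors[, seq_len(k), drop = FALSE]
    evals <- eg$values
  }
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- cohort$samples$id
  list(pcs = pcs, eigenvalues = evals, m = ncol(Z))
}

#' Allele-specific ROH indicators at one SNP for one sample
#'
#' Returns `(1, 0)` when a ROH of the sample overlaps the SNP position and
#' the genotype is homozygous for the minor allele, `(0, 1)` for
#' homozygous major inside a ROH, and `(0, 0)` otherwise -- including a
#' heterozygous or missing call inside a ROH (legal, since the caller's
#' windows tolerate one heterozygote).
#'
#' @param segments This sample's ROH segments (tibble with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param chrom,pos_bp SNP coordinates.
#' @param genotype 0/1/2/NA count of `allele_b`.
#' @param minor_is_b Is `allele_b` the (panel-wide) minor allele?
#' @return Integer vector `c(ind_a, ind_b)`.
#' @export
encode_roh_predictors <- function(segments, chrom, pos_bp, genotype,
                                  minor_is_b) {
  in_roh <- any(segments$chrom == chrom & segments$start_bp <= pos_bp &
                  segments$end_bp >= pos_bp)
  if (!in_roh || is.na(genotype) || genotype == 1L) return(c(0L, 0L))
  hom_minor <- genotype == (if (minor_is_b) 2L else 0L)
  if (hom_minor) c(1L, 0L) else c(0L, 1L)
}

# n x m matrix of ROH states: 0 = not in ROH (or het/missing in ROH),
# 1 = in ROH and homozygous minor, 2 = in ROH and homozygous major.
roh_state_matrix <- function(segments, cohort, minor_is_b) {
  g <- cohort$genotypes
  n <- nrow(g); m <- ncol(g)
  covered <- matrix(FALSE, n, m)
  row_of <- setNames(seq_len(n), cohort$samples$id)
  for (idx in split(seq_len(m), cohort$variants$chrom)) {
    ch <- cohort$variants$chrom[idx[1]]
    segs <- segments[segments$chrom == ch, ]
    if (nrow(segs) == 0) next
    pos <- cohort$variants$pos_bp[idx]
    lo <- findInterval(segs$start_bp - 1L, pos) + 1L
    hi <- findInterval(segs$end_bp, pos)
    rows <- row_of[segs$sample_id]
    for (s in which(lo <= hi)) {
      covered[rows[s], idx[lo[s]]:idx[hi[s]]] <- TRUE
    }
  }
  hom_minor_code <- rep(ifelse(minor_is_b, 2L, 0L), each = n)
  hom_major_code <- 2L - hom_minor_code
  state <- matrix(0L, n, m)
  state[covered & !is.na(g) & g == hom_minor_code] <- 1L
  state[covered & !is.na(g) & g == hom_major_code] <- 2L
  state
}

#' Genome-wide allele-specific ROH association scan
#'
#' At every SNP, fits a binomial logit model of the raced outcome on two
#' ROH-status indicators (ROH overlapping the SNP with the minor or the
#' major allele homozygous), the additive 0/1/2 dosage, the
#' leave-focal-chromosome-out inbreeding coefficient F_ROHmod, region, sex,
#' principal components, and birth year as a fixed factor (the scan fast
#' mode). Effects and Wald p-values are extracted for both ROH indicators;
#' indicators backed by fewer than `min_count` individuals have their
#' p-value set missing.
#'
#' @param cohort A filtered [roh_cohort()] whose samples carry `sex`,
#'   `region` and `birth_year`.
#' @param segments ROH segments from [detect_roh()].
#' @param froh_mod_tbl Leave-one-chromosome-out coefficients from
#'   [froh_mod()].
#' @param phenotypes Tibble with `sample_id` and `raced`.
#' @param pcs Matrix of principal components from [grm_pca()] (or `NULL`
#'   for none).
#' @param min_count Minimum individuals in a ROH state for its p-value to
#'   be reported (default 5).
#' @return Tibble with one row per SNP: coordinates, `beta_roh_a`, `se_a`,
#'   `p_a`, `beta_roh_b`, `se_b`, `p_b`, `beta_add`, `n_roh_a`, `n_roh_b`,
#'   `converged`.
#' @export
gwas_scan <- function(cohort, segments, froh_mod_tbl, phenotypes,
                      pcs = NULL, min_count = 5) {
  samples <- cohort$samples
  phen <- phenotypes[match(samples$id, phenotypes$sample_id), ]
  if (any(is.na(phen$raced))) abort("phenotypes missing for some samples")
  y <- as.numeric(phen$raced)

  vs <- variant_stats(cohort)
  minor_is_b <- ifelse(is.na(vs$minor_is_b), TRUE, vs$minor_is_b)
  state <- roh_state_matrix(segments, cohort, minor_is_b)

  g <- cohort$genotypes
  dosage <- g
  storage.mode(dosage) <- "double"
  if (anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    na_idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[na_idx] <- mu[na_idx[, 2]]
  }

  base_df <- data.frame(
    region = factor(samples$region,
                    levels = union("ANZ", sort(unique(samples$region)))),
    sex = factor(samples$sex, levels = union("F", sort(unique(samples$sex)))),
    birth_year = factor(samples$birth_year))
  form <- ~ region + sex + birth_year
  if (!is.null(pcs)) {
    base_df <- cbind(base_df, as.data.frame(pcs))
    form <- as.formula(paste("~ region + sex + birth_year +",
                             paste(colnames(pcs), collapse = " + ")))
  }
  Xcov <- model.matrix(form, base_df)

  fm_wide <- froh_mod_tbl |>
    tidyr::pivot_wider(names_from = "chrom", values_from = "f_roh_mod")
  fm_wide <- fm_wide[match(samples$id, fm_wide$sample_id), ]

  out <- vector("list", 0)
  for (ch in unique(cohort$variants$chrom)) {
    idx <- which(cohort$variants$chrom == ch)
    Xbase <- cbind(Xcov, f_roh_mod = fm_wide[[as.character(ch)]])
    null_fit <- suppressWarnings(
      glm.fit(Xbase, y, family = binomial("logit")))
    res <- logistic_scan_cpp(Xbase, y, null_fit$coefficients,
                             state[, idx, drop = FALSE],
                             dosage[, idx, drop = FALSE])
    out[[length(out) + 1]] <- tibble(
      snp_id = cohort$variants$snp_id[idx],
      chrom = ch, pos_bp = cohort$variants$pos_bp[idx],
      beta_roh_a = res$beta_a, se_a = res$se_a,
      p_a = 2 * pnorm(-abs(res$beta_a / res$se_a)),
      beta_roh_b = res$beta_b, se_b = res$se_b,
      p_b = 2 * pnorm(-abs(res$beta_b / res$se_b)),
      beta_add = res$beta_add, se_add = res$se_add,
      p_add = 2 * pnorm(-abs(res$beta_add / res$se_add)),
      n_roh_a = res$n_a, n_roh_b = res$n_b,
      converged = res$converged)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      p_a = ifelse(.data$n_roh_a < min_count, NA_real_, .data$p_a),
      p_b = ifelse(.data$n_roh_b < min_count, NA_real_, .data$p_b))
}

#' Re-fit candidate scan hits with the full mixed model
#'
#' The genome-wide scan runs in fast mode (birth year as a fixed factor,
#' warm-started IRLS). Candidate hits -- rows whose ROH p-value falls below
#' `threshold` -- are re-fitted here with the full binomial mixed model
#' (birth-year random intercept, adaptive Gauss-Hermite quadrature) and
#' their effects and p-values replaced by the accurate fit.
#'
#' @inheritParams gwas_scan
#' @param scan Result of [gwas_scan()].
#' @param threshold Candidate threshold (e.g. from
#'   [significance_threshold()]).
#' @param quadrature_points Nodes for the refit (default 15).
#' @return `scan` with candidate rows updated and a logical `refined`
#'   column.
#' @export
refine_hits <- function(cohort, segments, froh_mod_tbl, phenotypes, scan,
                        threshold, pcs = NULL, quadrature_points = 15) {
  cand <- which((!is.na(scan$p_a) & scan$p_a < threshold) |
                  (!is.na(scan$p_b) & scan$p_b < threshold))
  scan$refined <- FALSE
  if (length(cand) == 0) return(scan)
  samples <- cohort$samples
  phen <- phenotypes[match(samples$id, phenotypes$sample_id), ]
  vs <- variant_stats(cohort)
  minor_is_b <- ifelse(is.na(vs$minor_is_b), TRUE, vs$minor_is_b)
  for (j in cand) {
    row_of <- match(scan$snp_id[j], cohort$variants$snp_id)
    ind <- t(vapply(seq_len(nrow(samples)), function(i) {
      segs_i <- segments[segments$sample_id == samples$id[i], ]
      encode_roh_predictors(segs_i, scan$chrom[j], scan$pos_bp[j],
                            cohort$genotypes[i, row_of],
                            minor_is_b[row_of])
    }, integer(2)))
    fm_j <- froh_mod_tbl[froh_mod_tbl$chrom == scan$chrom[j], ]
    df <- data.frame(
      raced = phen$raced, roh_a = ind[, 1], roh_b = ind[, 2],
      add = cohort$genotypes[, row_of],
      f_roh_mod = fm_j$f_roh_mod[match(samples$id, fm_j$sample_id)],
      region = factor(samples$region,
                      levels = union("ANZ", sort(unique(samples$region)))),
      sex = factor(samples$sex,
                   levels = union("F", sort(unique(samples$sex)))),
      birth_year = samples$birth_year)
    if (!is.null(pcs)) df <- cbind(df, as.data.frame(pcs))
    rhs <- c("roh_a", "roh_b", "add", "f_roh_mod", "region", "sex",
             if (!is.null(pcs)) colnames(pcs))
    keep <- vapply(rhs, function(v) {
      x <- df[[v]]
      length(unique(x[!is.na(x)])) > 1
    }, logical(1))
    form <- as.formula(paste("raced ~", paste(rhs[keep], collapse = " + ")))
    fit <- tryCatch(
      fit_binomial_glmm(df, form, group = "birth_year",
                        quadrature_points = quadrature_points),
      error = function(e) NULL)
    if (is.null(fit)) next
    if ("roh_a" %in% names(fit$beta)) {
      scan$beta_roh_a[j] <- fit$beta[["roh_a"]]
      scan$se_a[j] <- fit$se[["roh_a"]]
      scan$p_a[j] <- fit$p[["roh_a"]]
    }
    if ("roh_b" %in% names(fit$beta)) {
      scan$beta_roh_b[j] <- fit$beta[["roh_b"]]
      scan$se_b[j] <- fit$se[["roh_b"]]
      scan$p_b[j] <- fit$p[["roh_b"]]
    }
    scan$converged[j] <- fit$converged
    scan$refined[j] <- TRUE
  }
  scan
}

#' Effective number of independent tests (simpleM)
#'
#' Partitions each chromosome's SNPs into consecutive blocks, computes the
#' SNP-SNP composite (dosage) correlation matrix per block, and counts the
#' smallest number of top eigenvalues explaining `var_explained` of the
#' total variance; the effective test count is the sum over blocks.
#' Constant SNP columns are dropped with a warning; missing dosages are
#' mean-imputed within SNP.
#'
#' @param cohort A [roh_cohort()].
#' @param var_explained Fraction of variance the retained eigenvalues must
#'   reach (default 0.995).
#' @param block_size SNPs per block (default 1000).
#' @return Integer effective number of tests.
#' @export
simple_m <- function(cohort, var_explained = 0.995, block_size = 1000) {
  g <- cohort$genotypes
  if (ncol(g) < 2) abort("need at least 2 SNPs")
  m_eff <- 0L
  n_const <- 0L
  for (idx in split(seq_len(ncol(g)), cohort$variants$chrom)) {
    blocks <- split(idx, ceiling(seq_along(idx) / block_size))
    for (bl in blocks) {
      x <- g[, bl, drop = FALSE]
      storage.mode(x) <- "double"
      if (anyNA(x)) {
        mu <- colMeans(x, na.rm = TRUE)
        na_idx <- which(is.na(x), arr.ind = TRUE)
        x[na_idx] <- mu[na_idx[, 2]]
      }
      v <- apply(x, 2, stats::var)
      if (any(v == 0)) {
        n_const <- n_const + sum(v == 0)
        x <- x[, v > 0, drop = FALSE]
      }
      if (ncol(x) == 0) next
      if (ncol(x) == 1) { m_eff <- m_eff + 1L; next }
      ev <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      k <- which(cumsum(ev) >= var_explained * sum(ev))[1]
      m_eff <- m_eff + k
    }
  }
  if (n_const > 0) {
    warn(sprintf("%d constant SNP column(s) dropped from simpleM", n_const))
  }
  as.integer(m_eff)
}

#' Genome-wide significance threshold from the effective test count
#'
#' Bonferroni threshold `alpha / (tests_per_model * m_eff)`; with the
#' published 90,900 effective tests and two ROH tests per model this is
#' 2.75e-7.
#'
#' @param m_eff Effective number of independent tests.
#' @param tests_per_model Tests per fitted model (default 2: both ROH
#'   indicators).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test significance threshold.
#' @export
significance_threshold <- function(m_eff, tests_per_model = 2, alpha = 0.05) {
  if (m_eff < 1) abort("m_eff must be >= 1")
  alpha / (tests_per_model * m_eff)
}
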