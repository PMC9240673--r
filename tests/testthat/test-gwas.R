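test_that("ROH predictor coding follows the allele-specific rule", {
  segs <- tibble::tibble(chrom = 1L, start_bp = 1e6, end_bp = 2e6)
  # homozygous minor inside ROH (minor = allele_b, genotype 2)
  expect_equal(encode_roh_predictors(segs, 1L, 1.5e6, 2L, TRUE), c(1L, 0L))
  # homozygous major outside any ROH
  expect_equal(encode_roh_predictors(segs, 1L, 3e6, 0L, TRUE), c(0L, 0L))
  # heterozygous inside ROH is coded (0, 0)
  expect_equal(encode_roh_predictors(segs, 1L, 1.5e6, 1L, TRUE), c(0L, 0L))
  # homozygous major inside ROH
  expect_equal(encode_roh_predictors(segs, 1L, 1.5e6, 0L, TRUE), c(0L, 1L))
  # minor allele is allele_a: genotype 0 is homozygous minor
  expect_equal(encode_roh_predictors(segs, 1L, 1.5e6, 0L, FALSE), c(1L, 0L))
})

test_that("the state matrix agrees with per-SNP encoding and is exclusive", {
  s <- simulate_cohort(tiny_config())
  segs <- detect_roh(s$cohort)
  vs <- variant_stats(s$cohort)
  state <- rohdepress:::roh_state_matrix(segs, s$cohort, vs$minor_is_b)
  expect_true(all(state %in% 0:2))
  set.seed(5)
  for (k in 1:40) {
    i <- sample(nrow(state), 1); j <- sample(ncol(state), 1)
    ss <- segs[segs$sample_id == s$cohort$samples$id[i], ]
    want <- encode_roh_predictors(ss, s$cohort$variants$chrom[j],
                                  s$cohort$variants$pos_bp[j],
                                  s$cohort$genotypes[i, j],
                                  vs$minor_is_b[j])
    got <- c(state[i, j] == 1L, state[i, j] == 2L)
    expect_equal(as.integer(got), want)
  }
})

test_that("GRM principal components behave as the algebra dictates", {
  # single SNP at p = 0.5: standardized scores are -1.414, 0, 1.414 and
  # the leading eigenvector is proportional to them
  ch <- make_cohort(matrix(c(0L, 1L, 2L), 3, 1))
  res <- grm_pca(ch, k = 1)
  expect_equal(unname(abs(res$pcs[, 1])), c(0.7071068, 0, 0.7071068),
               tolerance = 1e-6)
  expect_equal(sum(res$eigenvalues), 4, tolerance = 1e-8)

  # duplicated individuals get identical PC rows
  set.seed(9)
  g <- matrix(sample(c(0L, 1L, 2L), 20 * 50, replace = TRUE), 20, 50)
  g[2, ] <- g[1, ]
  res2 <- grm_pca(make_cohort(g), k = 3)
  expect_equal(res2$pcs[1, ], res2$pcs[2, ], tolerance = 1e-8)

  expect_error(grm_pca(make_cohort(g), k = 20), "smaller")

  # two diverged subpopulations separate on PC1
  set.seed(10)
  n <- 60; m <- 300
  p1 <- runif(m, 0.1, 0.9)
  p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-0.4, 0.4), m, TRUE)))
  g1 <- sapply(p1, function(p) rbinom(n / 2, 2, p))
  g2 <- sapply(p2, function(p) rbinom(n / 2, 2, p))
  pop <- rep(c(0, 1), each = n / 2)
  res3 <- grm_pca(make_cohort(rbind(g1, g2)), k = 2)
  expect_gt(abs(cor(res3$pcs[, 1], pop)), 0.9)
})

test_that("simpleM counts effective tests from the LD eigenvalues", {
  # 10 perfectly correlated SNPs contribute a single effective test
  set.seed(12)
  base <- sample(c(0L, 1L, 2L), 50, replace = TRUE)
  ch <- make_cohort(matrix(base, 50, 10))
  expect_equal(simple_m(ch), 1L)

  # independent SNPs stay close to the panel size
  g <- matrix(rbinom(400 * 100, 2, 0.5), 400, 100)
  expect_gte(simple_m(make_cohort(g)), 95)

  # duplicating every SNP leaves the effective count unchanged
  ch1 <- make_cohort(g)
  gdup <- g[, rep(seq_len(ncol(g)), each = 2)]
  ch2 <- make_cohort(gdup)
  expect_equal(simple_m(ch2), simple_m(ch1))

  # constant column dropped with a warning
  gc <- cbind(g[, 1:5], 1L)
  expect_warning(simple_m(make_cohort(gc)), "constant")

  expect_error(simple_m(make_cohort(matrix(1L, 5, 1))), "2 SNPs")
})

test_that("the significance threshold is exact rational arithmetic", {
  expect_equal(significance_threshold(1, 1), 0.05)
  expect_equal(significance_threshold(100, 2), 2.5e-4)
  expect_error(significance_threshold(0), ">= 1")
})

test_that("the compiled scan reproduces stats::glm per SNP", {
  cfg <- tiny_config()
  s <- simulate_cohort(cfg)
  segs <- detect_roh(s$cohort)
  cl <- tibble::tibble(chrom = 1:cfg$n_chrom,
                       length_bp = round(cfg$chrom_length_mb * 1e6))
  fm <- froh_mod(segs, s$cohort$samples$id, cl)
  pca <- grm_pca(s$cohort, k = 2)
  scan <- gwas_scan(s$cohort, segs, fm, s$phenotypes, pcs = pca$pcs,
                    min_count = 1)
  expect_equal(nrow(scan), ncol(s$cohort$genotypes))
  expect_true(all(scan$n_roh_a + scan$n_roh_b <= nrow(s$cohort$samples)))

  vs <- variant_stats(s$cohort)
  state <- rohdepress:::roh_state_matrix(segs, s$cohort, vs$minor_is_b)
  df0 <- data.frame(
    raced = s$phenotypes$raced,
    region = factor(s$cohort$samples$region, levels = c("ANZ", "EUR")),
    sex = factor(s$cohort$samples$sex, levels = c("F", "M")),
    birth_year = factor(s$cohort$samples$birth_year),
    PC1 = pca$pcs[, 1], PC2 = pca$pcs[, 2])
  checked <- 0
  set.seed(31)
  for (j in sample(which(scan$converged & scan$n_roh_a >= 3 &
                           scan$n_roh_b >= 3), 5)) {
    df <- df0
    df$f_roh_mod <- fm$f_roh_mod[fm$chrom == scan$chrom[j]][
      match(s$cohort$samples$id,
            fm$sample_id[fm$chrom == scan$chrom[j]])]
    df$roh_a <- as.integer(state[, j] == 1L)
    df$roh_b <- as.integer(state[, j] == 2L)
    df$add <- s$cohort$genotypes[, j]
    ref <- glm(raced ~ region + sex + birth_year + PC1 + PC2 + f_roh_mod +
                 roh_a + roh_b + add, data = df, family = binomial())
    sm <- summary(ref)$coefficients
    expect_equal(scan$beta_roh_a[j], sm["roh_a", 1], tolerance = 1e-4)
    expect_equal(scan$se_a[j], sm["roh_a", 2], tolerance = 1e-3)
    expect_equal(scan$beta_roh_b[j], sm["roh_b", 1], tolerance = 1e-4)
    expect_equal(scan$beta_add[j], sm["add", 1], tolerance = 1e-4)
    checked <- checked + 1
  }
  expect_equal(checked, 5)
})

test_that("min_count suppresses p-values for rare ROH states", {
  cfg <- tiny_config()
  s <- simulate_cohort(cfg)
  segs <- detect_roh(s$cohort)
  cl <- tibble::tibble(chrom = 1:cfg$n_chrom,
                       length_bp = round(cfg$chrom_length_mb * 1e6))
  fm <- froh_mod(segs, s$cohort$samples$id, cl)
  scan <- gwas_scan(s$cohort, segs, fm, s$phenotypes, pcs = NULL,
                    min_count = 5)
  rare <- scan$n_roh_a < 5
  expect_true(all(is.na(scan$p_a[rare])))
  expect_true(any(!is.na(scan$p_a[!rare])))
})

test_that("a purely additive signal loads on the additive term, not ROH", {
  cfg <- tiny_config()
  cfg$n_samples_out <- 400
  cfg$n_generations <- 4
  cfg$seed <- 77
  set.seed(cfg$seed)
  f <- simulate_founders(cfg)
  bred <- breed_generations(f, cfg)
  co <- bred$cohort
  segs <- detect_roh(co)
  j <- f$risk$focal_idx + sum(co$variants$chrom < f$risk$chrom)
  dose <- co$genotypes[, j]
  set.seed(78)
  raced <- rbinom(nrow(co$samples), 1, plogis(1.5 - 1.2 * dose))
  phen <- tibble::tibble(sample_id = co$samples$id, raced = raced)
  cl <- tibble::tibble(chrom = 1:cfg$n_chrom,
                       length_bp = round(cfg$chrom_length_mb * 1e6))
  fm <- froh_mod(segs, co$samples$id, cl)
  scan <- gwas_scan(co, segs, fm, phen, pcs = NULL)
  row <- scan[j, ]
  # the additive term carries the signal; the ROH indicators stay null
  expect_lt(row$p_add, 0.01)
  expect_lt(row$beta_add, 0)
  expect_true(is.na(row$p_a) || row$p_a > 0.01)
  expect_true(is.na(row$p_b) || row$p_b > 0.01)
})
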