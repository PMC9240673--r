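#' Simulation configuration for a synthetic inbred cohort
#'
#' Parameters for the pedigree-based cohort generator. Founder haplotypes
#' are mosaics over a small pool of ancestral haplotypes, which bakes in
#' "old" background homozygosity (short ROH and realistic LD); the explicit
#' pedigree phase with kinship-weighted mate choice then creates recent
#' common ancestors and hence long ROH. A large-effect recessive risk
#' haplotype is embedded as an exact allele string among founder
#' haplotypes. Phenotypes (raced 0/1 and race counts) are generated from a
#' logit model on the true (pedigree) autozygous fraction, the
#' risk-homozygote indicator, sex, region and a birth-year random effect.
#'
#' Defaults give 2000 output samples on 31 chromosomes totalling 2281 Mb at
#' 15 SNPs/Mb (~34 K SNPs), a called F_ROH distribution centred near 0.28
#' spanning roughly 0.18-0.40, the risk haplotype at founder frequency
#' 0.101 with homozygote log odds -1.82, and a genome-wide inbreeding
#' effect of -5.75 on the logit scale.
#'
#' @param n_founders Number of founder individuals.
#' @param n_generations Number of bred generations; each contributes
#'   `n_samples_out / n_generations` output samples and one birth-year
#'   level.
#' @param n_samples_out Total output samples across bred generations.
#' @param n_chrom Number of autosomes.
#' @param chrom_length_mb Length of each chromosome in Mb.
#' @param snp_density_per_mb SNPs per Mb.
#' @param n_ancestral_haplotypes Size of the ancestral haplotype pool the
#'   founders are mosaics of (controls background homozygosity, roughly
#'   1/pool size).
#' @param ancestral_segment_mb Mean mosaic segment length in the founders
#'   (Mb); smaller values mean older background inbreeding.
#' @param mate_kinship_weight Exponential tilt on pairwise pedigree kinship
#'   in sire choice: weight `exp(w * kinship)`. 0 = random mating.
#' @param risk_locus List with `chrom`, `pos_frac` (position along the
#'   chromosome), `haplotype_length_kb` and `q` (founder haplotype
#'   frequency).
#' @param beta0,beta_froh,beta_riskhom,beta_sex,beta_region Logit-scale
#'   coefficients of the phenotype model (sex effect is M vs F, region
#'   effect EUR vs ANZ).
#' @param sigma_birth_year SD of the birth-year random intercept.
#' @param count_mu,count_theta Negative-binomial mean and size for race
#'   counts among raced samples.
#' @param beta_count_froh Log-scale F_ROH effect on race counts (default 0).
#' @param prob_eur,prob_male Covariate assignment probabilities.
#' @param allele_freq_range Range of the uniform per-SNP ancestral allele
#'   frequency distribution.
#' @param recomb_rate_cM_per_mb Uniform recombination rate (1 cM/Mb).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 250,
                       n_generations = 5,
                       n_samples_out = 2000,
                       n_chrom = 31,
                       chrom_length_mb = 2281 / 31,
                       snp_density_per_mb = 15,
                       n_ancestral_haplotypes = 3,
                       ancestral_segment_mb = 3,
                       mate_kinship_weight = 5,
                       risk_locus = list(chrom = 14, pos_frac = 0.5,
                                         haplotype_length_kb = 1000,
                                         q = 0.101),
                       beta0 = 3.5, beta_froh = -5.75, beta_riskhom = -1.82,
                       beta_sex = -0.1, beta_region = -0.8,
                       sigma_birth_year = 0.3,
                       count_mu = 16, count_theta = 3,
                       beta_count_froh = 0,
                       prob_eur = 0.595, prob_male = 0.5,
                       allele_freq_range = c(0.05, 0.95),
                       recomb_rate_cM_per_mb = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_chrom < 1 || cfg$chrom_length_mb <= 0) {
    abort("chromosome count and length must be positive")
  }
  if (cfg$mate_kinship_weight < 0) abort("mate_kinship_weight must be >= 0")
  q <- cfg$risk_locus$q
  if (q < 0 || q > 1) abort("risk haplotype frequency must be in [0,1]")
  if (cfg$risk_locus$chrom > cfg$n_chrom) {
    cfg$risk_locus$chrom <- 1L
  }
  if (q > 0 && round(q * 2 * cfg$n_founders) < 1) {
    abort("risk frequency q too low for the founder count (q * 2n < 0.5)")
  }
  class(cfg) <- "sim_config"
  cfg
}

# ---- ancestry bookkeeping -------------------------------------------------
# A haplotype's ancestry on one chromosome is a contiguous partition of
# (0, L] into segments, stored as list(e = segment end positions (last = L),
# id = founder-haplotype id per segment).

.splice_anc <- function(a1, a2, xo, first_a, L) {
  bounds <- c(xo, L)
  e <- id <- vector("list", length(bounds))
  lo <- 0
  for (k in seq_along(bounds)) {
    hi <- bounds[k]
    src <- if ((k %% 2 == 1) == first_a) a1 else a2
    i1 <- findInterval(lo, src$e) + 1L            # first segment with end > lo
    i2 <- findInterval(hi, src$e, left.open = TRUE) + 1L  # first end >= hi
    ee <- src$e[i1:i2]
    ee[length(ee)] <- hi
    e[[k]] <- ee
    id[[k]] <- src$id[i1:i2]
    lo <- hi
  }
  list(e = unlist(e), id = unlist(id))
}

# Intersection of two ancestries: intervals where founder ids agree.
.autozygous_segments <- function(a1, a2) {
  ends <- sort(unique(c(a1$e, a2$e)))
  id1 <- a1$id[findInterval(ends, a1$e, left.open = TRUE) + 1L]
  id2 <- a2$id[findInterval(ends, a2$e, left.open = TRUE) + 1L]
  same <- id1 == id2
  if (!any(same)) return(matrix(numeric(0), ncol = 2))
  starts <- c(0, ends[-length(ends)])
  r <- rle(same)
  hi_i <- cumsum(r$lengths)
  lo_i <- hi_i - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[lo_i[keep]], end = ends[hi_i[keep]])
}

# One gamete from a parent's haplotype pair on one chromosome.
.gamete <- function(hapA, hapB, ancA, ancB, pos, L_bp, xo_mean) {
  n_xo <- rpois(1, xo_mean)
  first_a <- runif(1) < 0.5
  if (n_xo == 0) {
    if (first_a) return(list(hap = hapA, anc = ancA))
    return(list(hap = hapB, anc = ancB))
  }
  xo <- sort(runif(n_xo, 0, L_bp))
  seg <- findInterval(pos, xo)
  use_a <- (seg %% 2 == 0) == first_a
  hap <- hapB
  hap[use_a] <- hapA[use_a]
  list(hap = hap, anc = .splice_anc(ancA, ancB, xo, first_a, L_bp))
}

#' Simulate founder haplotypes
#'
#' Draws a pool of ancestral haplotypes with per-SNP allele frequencies
#' uniform on `allele_freq_range`, builds each founder haplotype as a
#' mosaic over that pool with exponential segment lengths, and embeds the
#' risk haplotype string in `round(q * 2 n_founders)` founder haplotypes.
#'
#' Uses the current RNG state; seed via [simulate_cohort()] or `set.seed()`.
#'
#' @param config A [sim_config()].
#' @return A list with the variant `map`, per-chromosome haplotype matrices
#'   (`alleles`, SNPs x haplotypes), pedigree-level `anc`estry, the `risk`
#'   locus description (window SNP indices and embedded string) and
#'   `risk_carrier` flags per founder haplotype.
#' @export
simulate_founders <- function(config) {
  n_hap <- 2L * config$n_founders
  L_bp <- round(config$chrom_length_mb * 1e6)
  n_snp <- round(config$chrom_length_mb * config$snp_density_per_mb)
  A <- config$n_ancestral_haplotypes

  spacing <- L_bp / n_snp
  map <- list(); alleles <- list(); anc <- list()
  for (c_ in seq_len(config$n_chrom)) {
    # jittered regular grid: array-like spacing, gaps bounded by 2x spacing
    pos <- as.integer(round((seq_len(n_snp) - runif(n_snp)) * spacing))
    pos <- pmax(pos, seq_len(n_snp))
    bad <- which(diff(pos) <= 0)
    while (length(bad) > 0) {
      pos[bad + 1L] <- pos[bad] + 1L
      bad <- which(diff(pos) <= 0)
    }
    map[[c_]] <- tibble(
      chrom = c_, pos_bp = pos,
      snp_id = sprintf("snp%d_%d", c_, seq_len(n_snp)),
      allele_a = "A", allele_b = "B")
    p_b <- runif(n_snp, config$allele_freq_range[1], config$allele_freq_range[2])
    pool <- matrix(rbinom(n_snp * A, 1L, p_b), nrow = n_snp, ncol = A)
    # array ascertainment: panel SNPs are polymorphic in the population,
    # so redraw pool rows that came out monomorphic
    mono <- which(rowSums(pool) %in% c(0L, A))
    while (length(mono) > 0) {
      pool[mono, ] <- rbinom(length(mono) * A, 1L, p_b[mono])
      mono <- mono[rowSums(pool[mono, , drop = FALSE]) %in% c(0L, A)]
    }
    hm <- matrix(0L, nrow = n_snp, ncol = n_hap)
    for (h in seq_len(n_hap)) {
      # mosaic breakpoints: Poisson process, mean segment ancestral_segment_mb
      n_bp <- rpois(1, config$chrom_length_mb / config$ancestral_segment_mb)
      cuts <- sort(runif(n_bp, 0, L_bp))
      seg_of_snp <- findInterval(pos, cuts) + 1L
      src <- sample.int(A, n_bp + 1L, replace = TRUE)
      hm[, h] <- pool[cbind(seq_len(n_snp), src[seg_of_snp])]
    }
    alleles[[c_]] <- hm
    anc[[c_]] <- lapply(seq_len(n_hap), function(h) list(e = L_bp, id = h))
  }

  # embed the risk haplotype as an exact allele string
  rl <- config$risk_locus
  risk <- NULL
  risk_carrier <- logical(n_hap)
  if (rl$q > 0) {
    rc <- rl$chrom
    pos <- map[[rc]]$pos_bp
    centre <- round(rl$pos_frac * L_bp)
    half <- rl$haplotype_length_kb * 1000 / 2
    win <- which(pos >= centre - half & pos <= centre + half)
    if (length(win) < 2) abort("risk window contains fewer than 2 SNPs")
    string <- rbinom(length(win), 1L,
                     runif(length(win), config$allele_freq_range[1],
                           config$allele_freq_range[2]))
    carriers <- sample.int(n_hap, round(rl$q * n_hap))
    alleles[[rc]][win, carriers] <- string
    risk_carrier[carriers] <- TRUE
    focal <- win[which.min(abs(pos[win] - centre))]
    # the central SNP tags the risk haplotype: its alternate allele is
    # exclusive to carrier haplotypes (frequency ~ q), as for a rare
    # haplotype-tagging GWAS hit
    string[which(win == focal)] <- 1L
    alleles[[rc]][focal, ] <- 0L
    alleles[[rc]][focal, carriers] <- 1L
    risk <- list(chrom = rc, window_idx = win, string = string,
                 focal_idx = focal, focal_pos = pos[focal],
                 centre_bp = centre)
  }
  list(map = dplyr::bind_rows(map), map_by_chrom = map, alleles = alleles,
       anc = anc, risk = risk, risk_carrier = risk_carrier,
       L_bp = L_bp, n_snp_per_chrom = n_snp)
}

#' Breed a cohort from founder haplotypes
#'
#' Each generation draws dams uniformly and sires with probability
#' proportional to `exp(mate_kinship_weight * kinship(dam, sire))` (pedigree
#' kinship, tracked exactly), then forms offspring by meiosis with
#' `Poisson(length_cM / 100)` crossovers per chromosome at uniform
#' positions. All bred generations are emitted as the cohort
#' (`n_samples_out / n_generations` samples each); `birth_year` identifies
#' the generation.
#'
#' @param founders Output of [simulate_founders()].
#' @param config A [sim_config()].
#' @return A list: `cohort` (a phased [roh_cohort()]), `truth` (list with
#'   per-sample autozygous `segments` from pedigree transmission,
#'   `f_ibd` pedigree autozygous fraction, `risk_hom` indicator,
#'   `pedigree`, and the embedded `risk` description).
#' @export
breed_generations <- function(founders, config) {
  n_chrom <- config$n_chrom
  L_bp <- founders$L_bp
  xo_mean <- config$chrom_length_mb * config$recomb_rate_cM_per_mb / 100
  per_gen <- ceiling(config$n_samples_out / config$n_generations)

  par_alleles <- founders$alleles
  par_anc <- founders$anc
  n_par <- config$n_founders
  K <- matrix(0, n_par, n_par); diag(K) <- 0.5
  par_sex <- sample(c("F", "M"), n_par, replace = TRUE)
  par_global_id <- sprintf("F%04d", seq_len(n_par))

  out <- list(); pedigree <- list()
  sample_counter <- 0L
  for (gen in seq_len(config$n_generations)) {
    n_off <- if (gen == config$n_generations) {
      config$n_samples_out - sample_counter
    } else per_gen
    females <- which(par_sex == "F"); males <- which(par_sex == "M")
    if (length(females) == 0 || length(males) == 0) {
      abort("population collapse: a generation lacks one sex entirely")
    }
    dams <- sample(females, n_off, replace = TRUE)
    sires <- integer(n_off)
    w <- config$mate_kinship_weight
    for (i in seq_len(n_off)) {
      wt <- exp(w * (2 * K[dams[i], males]))  # kinship -> relationship scale
      sires[i] <- if (length(males) == 1) males else
        sample(males, 1, prob = wt)
    }

    off_alleles <- lapply(seq_len(n_chrom), function(c_) {
      matrix(0L, nrow = founders$n_snp_per_chrom, ncol = 2L * n_off)
    })
    off_anc <- lapply(seq_len(n_chrom), function(c_) vector("list", 2L * n_off))
    for (c_ in seq_len(n_chrom)) {
      pa <- par_alleles[[c_]]; pn <- par_anc[[c_]]
      pos <- founders$map_by_chrom[[c_]]$pos_bp
      oa <- off_alleles[[c_]]; on_ <- off_anc[[c_]]
      for (i in seq_len(n_off)) {
        d <- dams[i]; s <- sires[i]
        g1 <- .gamete(pa[, 2L * d - 1L], pa[, 2L * d],
                      pn[[2L * d - 1L]], pn[[2L * d]], pos, L_bp, xo_mean)
        g2 <- .gamete(pa[, 2L * s - 1L], pa[, 2L * s],
                      pn[[2L * s - 1L]], pn[[2L * s]], pos, L_bp, xo_mean)
        oa[, 2L * i - 1L] <- g1$hap; oa[, 2L * i] <- g2$hap
        on_[[2L * i - 1L]] <- g1$anc; on_[[2L * i]] <- g2$anc
      }
      off_alleles[[c_]] <- oa; off_anc[[c_]] <- on_
    }

    ids <- sprintf("G%dS%04d", gen, seq_len(n_off) + sample_counter)
    pedigree[[gen]] <- tibble(id = ids, dam = par_global_id[dams],
                              sire = par_global_id[sires],
                              generation = gen)
    out[[gen]] <- list(ids = ids, alleles = off_alleles, anc = off_anc,
                       generation = gen,
                       sex = sample(c("F", "M"), n_off, replace = TRUE,
                                    prob = c(1 - config$prob_male,
                                             config$prob_male)))
    sample_counter <- sample_counter + n_off

    # kinship of the offspring generation (tabular method)
    Kd <- K[dams, dams, drop = FALSE]; Ks <- K[sires, sires, drop = FALSE]
    Kds <- K[dams, sires, drop = FALSE]; Ksd <- K[sires, dams, drop = FALSE]
    Knew <- 0.25 * (Kd + Ks + Kds + Ksd)
    diag(Knew) <- 0.5 * (1 + K[cbind(dams, sires)])
    K <- Knew
    par_alleles <- off_alleles; par_anc <- off_anc
    par_sex <- out[[gen]]$sex; par_global_id <- ids
  }

  # assemble cohort across bred generations
  all_ids <- unlist(lapply(out, `[[`, "ids"))
  n <- length(all_ids)
  m <- nrow(founders$map)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  col_off <- 0L
  for (c_ in seq_len(n_chrom)) {
    nc <- founders$n_snp_per_chrom
    row_off <- 0L
    for (gen in seq_along(out)) {
      a <- out[[gen]]$alleles[[c_]]
      ng <- ncol(a) / 2L
      h1[row_off + seq_len(ng), col_off + seq_len(nc)] <-
        t(a[, seq(1, 2 * ng, by = 2), drop = FALSE])
      h2[row_off + seq_len(ng), col_off + seq_len(nc)] <-
        t(a[, seq(2, 2 * ng, by = 2), drop = FALSE])
      row_off <- row_off + ng
    }
    col_off <- col_off + nc
  }

  samples <- tibble(
    id = all_ids,
    sex = unlist(lapply(out, `[[`, "sex")),
    region = sample(c("ANZ", "EUR"), n, replace = TRUE,
                    prob = c(1 - config$prob_eur, config$prob_eur)),
    birth_year = 2000L + unlist(lapply(out, function(g) {
      rep(g$generation, length(g$ids))
    })))

  cohort <- roh_cohort(h1 + h2, founders$map, samples,
                       haplotypes = list(h1 = h1, h2 = h2))

  # truth: pedigree-IBD autozygous segments per sample
  seg_list <- list()
  f_ibd <- numeric(n)
  row_i <- 0L
  for (gen in seq_along(out)) {
    on_ <- out[[gen]]$anc
    for (i in seq_along(out[[gen]]$ids)) {
      row_i <- row_i + 1L
      tot <- 0
      for (c_ in seq_len(n_chrom)) {
        az <- .autozygous_segments(on_[[c_]][[2L * i - 1L]],
                                   on_[[c_]][[2L * i]])
        if (nrow(az) > 0) {
          tot <- tot + sum(az[, 2] - az[, 1])
          seg_list[[length(seg_list) + 1L]] <- tibble(
            sample_id = out[[gen]]$ids[i], chrom = c_,
            start_bp = az[, 1], end_bp = az[, 2])
        }
      }
      f_ibd[row_i] <- tot / (n_chrom * L_bp)
    }
  }
  truth_segments <- if (length(seg_list) > 0) {
    dplyr::bind_rows(seg_list) |>
      dplyr::mutate(length_bp = .data$end_bp - .data$start_bp)
  } else {
    tibble(sample_id = character(), chrom = integer(), start_bp = numeric(),
           end_bp = numeric(), length_bp = numeric())
  }

  risk_hom <- rep(0L, n)
  if (!is.null(founders$risk)) {
    rk <- founders$risk
    chrom_cols <- which(founders$map$chrom == rk$chrom)[rk$window_idx]
    m1 <- h1[, chrom_cols, drop = FALSE]
    m2 <- h2[, chrom_cols, drop = FALSE]
    hit1 <- rowSums(m1 != rep(rk$string, each = n)) == 0
    hit2 <- rowSums(m2 != rep(rk$string, each = n)) == 0
    risk_hom <- as.integer(hit1 & hit2)
    attr(risk_hom, "n_copies") <- as.integer(hit1) + as.integer(hit2)
  }

  list(cohort = cohort,
       truth = list(segments = truth_segments, f_ibd = f_ibd,
                    risk_hom = risk_hom,
                    pedigree = dplyr::bind_rows(pedigree),
                    risk = founders$risk))
}

#' Simulate raced/unraced phenotypes and race counts
#'
#' `raced ~ Bernoulli(logit^-1(beta0 + beta_froh * F + beta_riskhom * hom +
#' beta_sex * male + beta_region * eur + alpha_year))` with
#' `alpha ~ N(0, sigma_birth_year^2)`; race counts for raced samples are
#' negative binomial.
#'
#' @param samples Sample table with `id`, `sex`, `region`, `birth_year`.
#' @param f_true Per-sample true autozygous fraction used in the linear
#'   predictor.
#' @param risk_hom Per-sample 0/1 risk-homozygote indicator.
#' @param config A [sim_config()].
#' @return Tibble: `sample_id`, `raced`, `n_races`, `eta` (linear
#'   predictor), `p_raced`.
#' @export
simulate_phenotypes <- function(samples, f_true, risk_hom, config) {
  n <- nrow(samples)
  years <- sort(unique(samples$birth_year))
  alpha <- setNames(rnorm(length(years), 0, config$sigma_birth_year),
                    as.character(years))
  eta <- config$beta0 + config$beta_froh * f_true +
    config$beta_riskhom * risk_hom +
    config$beta_sex * (samples$sex == "M") +
    config$beta_region * (samples$region == "EUR") +
    alpha[as.character(samples$birth_year)]
  raced <- rbinom(n, 1L, plogis(eta))
  mu <- exp(log(config$count_mu) + config$beta_count_froh * f_true)
  n_races <- ifelse(raced == 1L,
                    pmax(1L, rnbinom(n, size = config$count_theta, mu = mu)),
                    NA_integer_)
  tibble(sample_id = samples$id, raced = raced, n_races = n_races,
         eta = unname(eta), p_raced = plogis(unname(eta)))
}

#' Simulate a complete cohort: genotypes, truth and phenotypes
#'
#' Seeds the RNG from `config$seed`, runs [simulate_founders()],
#' [breed_generations()] and [simulate_phenotypes()], and returns all
#' pieces. Identical configs give byte-identical results.
#'
#' @param config A [sim_config()].
#' @return List: `cohort`, `truth`, `phenotypes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  founders <- simulate_founders(config)
  bred <- breed_generations(founders, config)
  phen <- simulate_phenotypes(bred$cohort$samples, bred$truth$f_ibd,
                              bred$truth$risk_hom, config)
  list(cohort = bred$cohort, truth = bred$truth, phenotypes = phen,
       config = config)
}

#' Simulate phenotype-level data from the racing GLMM
#'
#' Draws covariates and outcomes directly from the binomial mixed model
#' (no genotypes), for calibration studies of the model-fitting stage.
#' F_ROH is drawn as `0.18 + 0.22 * Beta(2, 2.4)` (mean 0.28, range
#' 0.18-0.40, matching the cohort-level inbreeding distribution).
#'
#' @param n Number of samples.
#' @param n_years Number of birth-year levels (default 38).
#' @param beta0,beta_froh,beta_sex,beta_region Logit-scale coefficients.
#' @param sigma_birth_year Random-intercept SD.
#' @return Tibble with `sample_id`, `f_roh`, `sex`, `region`, `birth_year`,
#'   `raced`.
#' @export
simulate_glmm_cohort <- function(n = 5000, n_years = 38,
                                 beta0 = 3.5, beta_froh = -5.75,
                                 beta_sex = -0.1, beta_region = -0.8,
                                 sigma_birth_year = 0.3) {
  f_roh <- 0.18 + 0.22 * stats::rbeta(n, 2, 2.4)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  region <- sample(c("ANZ", "EUR"), n, replace = TRUE, prob = c(0.405, 0.595))
  birth_year <- sample.int(n_years, n, replace = TRUE)
  alpha <- rnorm(n_years, 0, sigma_birth_year)
  eta <- beta0 + beta_froh * f_roh + beta_sex * (sex == "M") +
    beta_region * (region == "EUR") + alpha[birth_year]
  tibble(sample_id = sprintf("s%05d", seq_len(n)), f_roh = f_roh,
         sex = sex, region = region, birth_year = birth_year,
         raced = rbinom(n, 1L, plogis(eta)))
}
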