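# End-to-end pipeline: simulate -> roh -> fit -> gwas -> haplotype, with
# per-stage caching keyed on the config hash and seed, and a YAML manifest.

.config_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

.stage_seed <- function(seed, stage) {
  # stated fan-out rule: top seed + a fixed per-stage offset
  offsets <- c(simulate = 101L, roh = 202L, fit = 303L, gwas = 404L,
               haplotype = 505L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Run one cached stage: recompute unless the cache exists and every
# recorded output file still matches its checksum.
.run_stage <- function(name, out_dir, manifest_old, compute, write_outputs) {
  cache <- file.path(out_dir, "cache", paste0(name, ".rds"))
  old <- manifest_old$stages[[name]]
  if (!is.null(old) && file.exists(cache)) {
    files <- names(old$checksums)
    ok <- length(files) > 0 &&
      all(file.exists(files)) &&
      identical(unname(tools::md5sum(files)), unname(unlist(old$checksums)))
    if (ok) {
      return(list(value = readRDS(cache), skipped = TRUE,
                  seconds = 0, checksums = old$checksums))
    }
  }
  t0 <- proc.time()[["elapsed"]]
  value <- compute()
  files <- write_outputs(value)
  saveRDS(value, cache)
  cs <- as.list(tools::md5sum(files))
  list(value = value, skipped = FALSE,
       seconds = round(proc.time()[["elapsed"]] - t0, 2), checksums = cs)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate, ROH calling, depression-model fitting, the ROH-status
#' GWAS and the haplotype screen in order, writing each stage's tables
#' under `out_dir` and a run manifest (config hash, per-stage seeds,
#' timings, output checksums, package version) to
#' `out_dir/manifest.yaml`. Stages whose cached outputs still match their
#' recorded checksums are skipped on re-runs; a corrupted output file
#' triggers re-execution of its stage.
#'
#' @param config A [sim_config()] (or a YAML path holding its fields).
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed, fanned out to per-stage seeds.
#' @param roh_pars A [roh_params()].
#' @param n_pcs Principal components for the scan.
#' @return The manifest (list), invisibly; stage results are attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1L,
                         roh_pars = roh_params(), n_pcs = 10) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  dir.create(file.path(out_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  manifest_old <- if (file.exists(manifest_path)) {
    yaml::read_yaml(manifest_path)
  } else list(stages = list())
  cfg_hash <- .config_hash(c(unclass(config), top_seed = seed))
  if (!identical(manifest_old$config_hash, cfg_hash)) {
    manifest_old <- list(stages = list())  # config changed: no reuse
  }
  manifest <- list(config_hash = cfg_hash, seed = as.integer(seed),
                   package_version = as.character(
                     utils::packageVersion("rohdepress")),
                   stages = list())

  config$seed <- .stage_seed(seed, "simulate")
  sim <- .run_stage("simulate", out_dir, manifest_old,
    compute = function() simulate_cohort(config),
    write_outputs = function(s) {
      prefix <- file.path(out_dir, "cohort")
      write_plink(s$cohort, prefix)
      c(paste0(prefix, c(".bed", ".bim", ".fam")),
        .write_tsv(s$cohort$samples, file.path(out_dir, "covariates.tsv")),
        .write_tsv(dplyr::select(s$phenotypes, id = "sample_id", "raced",
                                 "n_races"),
                   file.path(out_dir, "race_records.tsv")),
        .write_tsv(s$truth$segments, file.path(out_dir,
                                               "truth_segments.tsv")),
        { yaml::write_yaml(unclass(s$config),
                           file.path(out_dir, "config_echo.yaml"))
          file.path(out_dir, "config_echo.yaml") })
    })
  manifest$stages$simulate <- sim[c("skipped", "seconds", "checksums")]
  s <- sim$value
  chrom_lengths <- tibble(
    chrom = seq_len(config$n_chrom),
    length_bp = round(config$chrom_length_mb * 1e6))

  roh <- .run_stage("roh", out_dir, manifest_old,
    compute = function() {
      segments <- detect_roh(s$cohort, roh_pars)
      list(segments = segments,
           inbreeding = compute_inbreeding(segments, s$cohort$samples$id,
                                           chrom_lengths),
           froh_mod = froh_mod(segments, s$cohort$samples$id, chrom_lengths),
           landscape = roh_landscape(segments, s$cohort$variants,
                                     nrow(s$cohort$samples)))
    },
    write_outputs = function(r) {
      c(.write_tsv(dplyr::mutate(r$segments, kb = .data$length_bp / 1000),
                   file.path(out_dir, "roh_segments.tsv")),
        .write_tsv(r$inbreeding, file.path(out_dir, "inbreeding.tsv")),
        .write_tsv(r$froh_mod, file.path(out_dir, "froh_mod.tsv")),
        .write_tsv(r$landscape, file.path(out_dir, "roh_landscape.tsv")))
    })
  manifest$stages$roh <- roh[c("skipped", "seconds", "checksums")]
  r <- roh$value

  fit_seed <- .stage_seed(seed, "fit")
  fits <- .run_stage("fit", out_dir, manifest_old,
    compute = function() {
      set.seed(fit_seed)
      phen <- dplyr::select(s$phenotypes, "sample_id", "raced", "n_races")
      cov <- s$cohort$samples
      main <- fit_froh_model(phen, r$inbreeding, cov)
      grid <- seq(min(r$inbreeding$f_roh), max(r$inbreeding$f_roh),
                  length.out = 25)
      list(froh = main, shortlong = fit_short_long_model(phen, r$inbreeding,
                                                         cov),
           predictions = prediction_table(main, grid))
    },
    write_outputs = function(f) {
      c(.write_tsv(tidy(f$froh), file.path(out_dir, "fit_froh.tsv")),
        .write_tsv(tidy(f$shortlong),
                   file.path(out_dir, "fit_shortlong.tsv")),
        .write_tsv(f$predictions, file.path(out_dir, "predictions.tsv")))
    })
  manifest$stages$fit <- fits[c("skipped", "seconds", "checksums")]

  gwas_seed <- .stage_seed(seed, "gwas")
  gw <- .run_stage("gwas", out_dir, manifest_old,
    compute = function() {
      set.seed(gwas_seed)
      pca <- grm_pca(s$cohort, k = n_pcs)
      scan <- gwas_scan(s$cohort, r$segments, r$froh_mod,
                        s$phenotypes, pcs = pca$pcs)
      m_eff <- simple_m(s$cohort)
      threshold <- significance_threshold(m_eff)
      scan <- refine_hits(s$cohort, r$segments, r$froh_mod, s$phenotypes,
                          scan, threshold, pcs = pca$pcs)
      list(scan = scan, m_eff = m_eff, threshold = threshold)
    },
    write_outputs = function(g) {
      yaml::write_yaml(list(m_eff = g$m_eff, threshold = g$threshold),
                       file.path(out_dir, "simplem.yaml"))
      c(.write_tsv(g$scan, file.path(out_dir, "gwas.tsv")),
        file.path(out_dir, "simplem.yaml"))
    })
  manifest$stages$gwas <- gw[c("skipped", "seconds", "checksums")]

  hap <- .run_stage("haplotype", out_dir, manifest_old,
    compute = function() {
      scan <- gw$value$scan
      p_pick <- pmin(scan$p_a, scan$p_b, na.rm = TRUE)
      top <- if (any(is.finite(p_pick))) {
        scan$snp_id[which.min(p_pick)]
      } else {
        scan$snp_id[which.max(scan$n_roh_a + scan$n_roh_b)]
      }
      win <- extract_window(s$cohort, top)
      state <- roh_state_matrix(
        r$segments, subset_variants(s$cohort,
                                    s$cohort$variants$snp_id == top),
        minor_is_b = variant_stats(s$cohort)$minor_is_b[
          s$cohort$variants$snp_id == top])
      aa_ids <- s$cohort$samples$id[state[, 1] == 1L]
      cr <- if (length(aa_ids) > 0) consensus_analysis(win, aa_ids) else NULL
      list(top_snp = top, report = cr)
    },
    write_outputs = function(h) {
      if (is.null(h$report)) {
        yaml::write_yaml(list(top_snp = h$top_snp, note = "no ROH+AA samples"),
                         file.path(out_dir, "consensus.yaml"))
        return(file.path(out_dir, "consensus.yaml"))
      }
      yaml::write_yaml(list(
        top_snp = h$top_snp, consensus = h$report$consensus,
        fraction_homozygous_identical =
          h$report$fraction_homozygous_identical,
        mean_mismatch = h$report$mean_mismatch,
        hap_frequency = h$report$hap_frequency),
        file.path(out_dir, "consensus.yaml"))
      c(.write_tsv(h$report$carriers, file.path(out_dir, "carriers.tsv")),
        file.path(out_dir, "consensus.yaml"))
    })
  manifest$stages$haplotype <- hap[c("skipped", "seconds", "checksums")]

  yaml::write_yaml(manifest, manifest_path)
  attr(manifest, "results") <- list(
    sim = s, roh = r, fits = fits$value, gwas = gw$value,
    haplotype = hap$value)
  invisible(manifest)
}
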