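#' Run the full crop-weed hybrid analysis pipeline
#'
#' Orchestrates the stages end to end with seeded reproducibility:
#' simulate (or read) genotypes, filter variants, discover AIMs, compute
#' supervised ancestry and generation estimates, infer local-ancestry
#' tracks and the genome-bias table, run the dual FST comparison and pi
#' scans, build the focal-gene haplotype network, and (if injury data are
#' supplied) tabulate resistance phenotypes. Every stage writes TSVs into
#' `out_dir` and the run manifest records parameters, per-stage child seeds
#' and md5 digests of all outputs, so a rerun with the same seed is
#' byte-identical.
#'
#' @param config list with entries: either `sim` (a [sim_config()]) or
#'   `vcf` + `panels` paths; optional `maf_min`, `hwe_p_min`,
#'   `min_freq_diff`, `hmm` (list `eps`, `rho`), `window_bp`, `step_bp`,
#'   `focal_regions` (data.frame `name`, `chrom`, `start`, `end`),
#'   `haplonet_region`, `injury` (path or data.frame), `seed`.
#' @param out_dir output directory (created).
#' @return list with the stage objects and `manifest` (data.frame of
#'   outputs and digests), invisibly writing everything under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  outputs <- character(0)

  # stage 1: genotypes
  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- stage_seeds[1]
    sim <- simulate_cohort(cfg, out_dir = out_dir)
    outputs <- c(outputs, file.path(out_dir, c("cohort.vcf",
                                               "truth_segments.tsv",
                                               "lineage_truth.tsv")))
    gm <- genotype_matrix(rbind(sim$panels$crop$geno, sim$panels$weed$geno,
                                sim$gm$geno),
                          sim$gm$sites,
                          c(sim$panels$crop$sample_ids,
                            sim$panels$weed$sample_ids, sim$gm$sample_ids))
    panels <- data.frame(
      sample_id = gm$sample_ids,
      panel = rep(c("crop", "weed", "contemporary"),
                  c(length(sim$panels$crop$sample_ids),
                    length(sim$panels$weed$sample_ids),
                    length(sim$gm$sample_ids))))
  } else {
    sim <- NULL
    gm <- read_vcf(config$vcf)
    panels <- if (is.character(config$panels))
      read_panels(config$panels, gm) else config$panels
  }

  # stage 2: variant filters
  gm_f <- filter_variants(gm,
                          maf_min = config$maf_min %||% 0.05,
                          hwe_p_min = config$hwe_p_min %||% 1e-7)
  outputs <- c(outputs, write_vcf(gm_f, file.path(out_dir, "filtered.vcf")))

  # stage 3: AIMs between the two ancestral panels (unfiltered genotypes:
  # fixed differences are monomorphic within panels and would fail MAF)
  crop_gm <- subset_gm(gm, panels$sample_id[panels$panel == "crop"])
  weed_gm <- subset_gm(gm, panels$sample_id[panels$panel == "weed"])
  aims <- identify_aims(crop_gm, weed_gm,
                        min_freq_diff = config$min_freq_diff %||% 1.0)
  outputs <- c(outputs, wt(as.data.frame(aims), "aims.tsv"))

  # stage 4: ancestry coefficients + generations since hybridization
  contemp <- panels$sample_id[panels$panel == "contemporary"]
  cgm <- subset_gm(gm, contemp)
  anc <- supervised_ancestry(cgm, aims, pop_names = c("crop", "weed"))
  gens <- do.call(rbind, lapply(contemp, function(s) {
    h <- aim_heterozygosity(cgm, s, aims)
    e <- estimate_generations(h$fraction, h$n_called)
    data.frame(sample_id = s, n_het = h$n_het, n_called = h$n_called,
               het_fraction = h$fraction, g_hat = e$g_hat,
               g_lo = e$ci[1], g_hi = e$ci[2], censored = e$censored)
  }))
  outputs <- c(outputs, wt(anc, "ancestry_coefficients.tsv"),
               wt(gens, "generation_estimates.tsv"))

  # stage 5: local ancestry tracks and genome bias
  hmm <- utils::modifyList(list(eps = 0.01, rho = 1e-7), config$hmm %||% list())
  tracks <- lapply(stats::setNames(contemp, contemp), function(s)
    infer_tracks(cgm, s, aims, eps = hmm$eps, rho = hmm$rho))
  bias <- genome_bias(tracks, stats::setNames(rep("contemporary",
                                                  length(contemp)), contemp))
  segs <- do.call(rbind, lapply(contemp, function(s)
    cbind(sample = s, tracks[[s]]$haplotypes)))
  outputs <- c(outputs, wt(segs, "ancestry_tracks.tsv"),
               wt(cbind(chromosome = rownames(bias), bias), "genome_bias.tsv"))

  # stage 6: divergence scans
  win <- config$window_bp %||% 500000
  stp <- config$step_bp %||% 250000
  dual <- dual_comparison(gm_f, panels, "contemporary", "crop", "weed",
                          window_bp = win, step_bp = stp,
                          focal_regions = config$focal_regions)
  pi_t <- pi_windows(gm_f, panels, "contemporary", win, stp)
  outputs <- c(outputs, wt(dual$windows, "fst_windows.tsv"),
               wt(pi_t, "pi_windows.tsv"))
  if (!is.null(dual$focal))
    outputs <- c(outputs, wt(dual$focal, "focal_windows.tsv"))

  # stage 7: focal-gene haplotype network
  net <- NULL
  if (!is.null(config$haplonet_region)) {
    haps <- extract_haplotypes(gm, config$haplonet_region)
    if (nrow(haps$haplotypes) >= 2) {
      net <- median_joining(haps)
      if (!is.null(config$cds_map)) net <- annotate_steps(net, config$cds_map)
      outputs <- c(outputs,
                   write_network_tsv(net, file.path(out_dir, "haplonet")))
    }
  }

  # stage 8: resistance phenotypes
  resist <- NULL
  if (!is.null(config$injury)) {
    inj <- if (is.character(config$injury))
      read_injury_tsv(config$injury) else config$injury
    resist <- tabulate_resistance(inj)
    outputs <- c(outputs,
                 wt(cbind(Resistance = rownames(resist$table), resist$table),
                    "resistance_table.tsv"))
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  params <- data.frame(
    key = c("seed", "maf_min", "hwe_p_min", "window_bp", "step_bp",
            "hmm_eps", "hmm_rho",
            paste0("stage_seed_", seq_along(stage_seeds))),
    value = c(seed, config$maf_min %||% 0.05, config$hwe_p_min %||% 1e-7,
              win, stp, hmm$eps, hmm$rho, stage_seeds))
  utils::write.table(rbind(params,
                           data.frame(key = paste0("md5_", manifest$file),
                                      value = manifest$md5)),
                     file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(gm = gm, gm_filtered = gm_f, panels = panels, aims = aims,
                 ancestry = anc, generations = gens, tracks = tracks,
                 bias = bias, dual = dual, pi = pi_t, network = net,
                 resistance = resist, manifest = manifest, sim = sim))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
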