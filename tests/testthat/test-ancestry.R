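test_that("HMM decoding is exact on degenerate tracks", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6, g = 0,
                    n_lineages = 2, seed = 41)
  co <- simulate_cohort(cfg)
  aims <- identify_aims(co$panels$crop, co$panels$weed)
  # F1: dosage 1 everywhere
  tr <- infer_tracks(co$gm, "W01", aims)
  expect_true(all(tr$calls$dosage == 1L))
  # pure weed sample: one weed/weed segment per chromosome
  trw <- infer_tracks(co$panels$weed, "weed01", aims)
  expect_true(all(trw$calls$dosage == 0L))
  expect_equal(nrow(trw$segments), 2L)
  expect_true(all(trw$haplotypes$ancestry == "weed"))
})

test_that("posterior dosage probabilities sum to one at every AIM", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6, g = 4,
                    n_lineages = 2, seed = 43)
  co <- simulate_cohort(cfg)
  aims <- identify_aims(co$panels$crop, co$panels$weed)
  tr <- infer_tracks(co$gm, "W02", aims)
  expect_equal(tr$calls$post0 + tr$calls$post1 + tr$calls$post2,
               rep(1, nrow(tr$calls)))
})

test_that("decoding recovers simulated ancestry truth at >= 99% of AIMs", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length_bp = 2e6,
                    aim_density = 15, neutral_snp_density = 0, g = 4,
                    n_lineages = 10, seed = 47)
  co <- simulate_cohort(cfg)
  aims <- identify_aims(co$panels$crop, co$panels$weed)
  acc <- vapply(seq_len(10), function(i) {
    tr <- infer_tracks(co$gm, co$gm$sample_ids[i], aims, eps = 1e-3)
    mean(tr$calls$dosage == co$dosage[i, co$panels$is_aim])
  }, numeric(1))
  expect_gte(mean(acc), 0.99)
})

test_that("decoding accuracy degrades with emission error and generations", {
  accuracy_at <- function(g, eps, seed) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
                      aim_density = 15, neutral_snp_density = 0, g = g,
                      n_lineages = 12, seed = seed)
    co <- simulate_cohort(cfg)
    aims <- identify_aims(co$panels$crop, co$panels$weed)
    idx <- which(co$panels$is_aim)
    mean(vapply(seq_len(12), function(i) {
      g_obs <- co$gm$geno[i, idx]
      # flip alleles at rate eps to emulate genotyping error
      if (eps > 0) {
        flip <- which(stats::runif(length(g_obs)) < 2 * eps)
        g_obs[flip] <- sample(0:2, length(flip), replace = TRUE)
        gm2 <- co$gm
        gm2$geno[i, idx] <- g_obs
      } else gm2 <- co$gm
      tr <- infer_tracks(gm2, co$gm$sample_ids[i], aims, eps = max(eps, 1e-3))
      mean(tr$calls$dosage == co$dosage[i, idx])
    }, numeric(1)))
  }
  set.seed(97)
  acc_clean <- accuracy_at(2, 0, 61)
  acc_noisy <- accuracy_at(2, 0.1, 61)
  acc_old <- accuracy_at(8, 0, 61)
  expect_gte(acc_clean, acc_noisy)       # more error, no better accuracy
  expect_gte(acc_clean, acc_old - 0.02)  # more breakpoints, no better
})

test_that("genome bias is exact on pure panels and averages like Table rows", {
  cfg <- sim_config(n_chromosomes = 3, chrom_length_bp = 2e6, g = 0,
                    n_lineages = 2, seed = 53)
  co <- simulate_cohort(cfg)
  aims <- identify_aims(co$panels$crop, co$panels$weed)
  tc <- lapply(stats::setNames(co$panels$crop$sample_ids[1:2],
                               co$panels$crop$sample_ids[1:2]),
               function(s) infer_tracks(co$panels$crop, s, aims))
  tw <- lapply(stats::setNames(co$panels$weed$sample_ids[1:2],
                               co$panels$weed$sample_ids[1:2]),
               function(s) infer_tracks(co$panels$weed, s, aims))
  b <- genome_bias(c(tc, tw),
                   c(crop01 = "crop", crop02 = "crop",
                     weed01 = "weed", weed02 = "weed"))
  expect_true(all(b[, "crop"] == 0))
  expect_true(all(b[, "weed"] == 1))
  # Average row is the unweighted mean of the chromosome rows
  m <- matrix(c(0.6, 0.8, 0.7, 0.5, 0.9, 0.4), 3,
              dimnames = list(paste0("chr", 1:3), c("g1", "g2")))
  bt <- bias_table(m)
  expect_equal(unlist(bt["Average", ]), colMeans(m))
  expect_error(bias_table(m * 2), "outside")
})

test_that("focal blocks are labelled by agreement of overlapping calls", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e6,
                    aim_density = 10, g = 0, n_lineages = 1, seed = 59)
  co <- simulate_cohort(cfg)
  aims <- identify_aims(co$panels$crop, co$panels$weed)
  trw <- infer_tracks(co$panels$weed, "weed01", aims)
  all_w <- focal_block(trw, list(chrom = "chr1", start = 1, end = 2e6))
  expect_equal(all_w$label, "weed")
  none <- focal_block(trw, list(chrom = "chr1", start = 1, end = 2))
  expect_equal(none$label, "no-marker")
  f1 <- focal_block(infer_tracks(co$gm, "W01", aims),
                    list(chrom = "chr1", start = 1, end = 2e6))
  expect_equal(f1$label, "mixed")
  expect_equal(f1$mean_dosage, 1)
})
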