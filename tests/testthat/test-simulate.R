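test_that("ancestral panels are inbred, fully diverged at AIMs, and seeded", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6, g = 0,
                    n_lineages = 2, seed = 9)
  set.seed(cfg$seed)
  p1 <- make_ancestral_panels(cfg)
  expect_true(all(p1$crop$geno %in% c(0L, 2L)))   # no heterozygotes
  expect_true(all(p1$weed$geno %in% c(0L, 2L)))
  # AIM sites: frequency difference exactly 1
  fa <- colMeans(p1$crop$geno[, p1$is_aim]) / 2
  fb <- colMeans(p1$weed$geno[, p1$is_aim]) / 2
  expect_equal(abs(fa - fb), rep(1, sum(p1$is_aim)))
  set.seed(cfg$seed)
  p2 <- make_ancestral_panels(cfg)
  expect_identical(p1$crop$geno, p2$crop$geno)
  expect_identical(p1$weed$geno, p2$weed$geno)
})

test_that("expected heterozygosity halves each selfing generation", {
  expect_equal(expected_het_after_selfing(0), 1)
  expect_equal(expected_het_after_selfing(1), 0.5)
  expect_equal(expected_het_after_selfing(5), 0.03125)
  expect_error(expected_het_after_selfing(-1), "non-negative")
})

test_that("the F1 is heterozygous at every AIM with dosage 1", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6, g = 0,
                    n_lineages = 4, seed = 21)
  co <- simulate_cohort(cfg)
  expect_true(all(co$dosage == 1L))
  expect_true(all(co$gm$geno[, co$panels$is_aim] == 1L))
})

test_that("selfing without recombination segregates whole chromosomes 1:2:1", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length_bp = 1e6,
                    aim_density = 8, neutral_snp_density = 0,
                    recomb_rate = 0, g = 1, n_lineages = 60, seed = 13)
  co <- simulate_cohort(cfg)
  states <- integer(0)
  for (i in seq_len(cfg$n_lineages)) for (ch in unique(co$gm$sites$chrom)) {
    d <- co$dosage[i, co$gm$sites$chrom == ch]
    expect_equal(length(unique(d)), 1L)  # chromosome-uniform dosage
    states <- c(states, d[1])
  }
  frac_het <- mean(states == 1L)
  se <- sqrt(0.5 * 0.5 / length(states))
  expect_lt(abs(frac_het - 0.5), 4 * se)
})

test_that("truth segments tile chromosomes and genotypes match ancestry", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6, g = 3,
                    n_lineages = 8, seed = 31)
  co <- simulate_cohort(cfg)
  L <- cfg$chrom_length_bp[1]
  for (i in seq_len(8)) {
    tr <- co$truth[[i]]
    for (ch in 1:2) for (h in 1:2) {
      hp <- tr$haps[[ch]][[h]]
      expect_equal(hp$ends[length(hp$ends)], L)      # reaches chromosome end
      expect_true(all(diff(hp$ends) > 0))            # contiguous tiling
      if (length(hp$labels) > 1)                     # merged runs
        expect_true(all(diff(hp$labels) != 0))
    }
    # at AIMs the crop allele is ref, so alt dosage = 2 - crop dosage
    expect_equal(co$gm$geno[i, co$panels$is_aim],
                 2L - co$dosage[i, co$panels$is_aim])
  }
})

test_that("cohort AIM heterozygosity matches the selfing decay law", {
  cfg <- sim_config(n_chromosomes = 6, chrom_length_bp = 2e6,
                    aim_density = 10, neutral_snp_density = 0, g = 2,
                    n_lineages = 60, seed = 17)
  co <- simulate_cohort(cfg)
  het <- rowMeans(co$dosage[, co$panels$is_aim] == 1L)
  mc_se <- stats::sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 0.25), 3 * mc_se)
})

test_that("strong selection at a site keeps the crop allele segregating", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                    aim_density = 10, neutral_snp_density = 0,
                    g = 5, n_lineages = 120,
                    selection_site = list(chrom = "chr1", pos = 5e5, s = 19),
                    seed = 23)
  co <- simulate_cohort(cfg)
  sel_aim <- which.min(abs(co$gm$sites$pos - 5e5))
  carry <- mean(co$dosage[, sel_aim] >= 1L)
  expect_gt(carry, 0.95)
  # impossible selection must fail loudly, not hang
  p <- co$panels
  bad <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                    aim_density = 10, neutral_snp_density = 0, g = 1,
                    n_lineages = 1, background_penalty = 0.9, seed = 1)
  set.seed(1)
  expect_error(
    simulate_lineage(p$crop$geno[1, ] / 2, p$weed$geno[1, ] / 2, bad,
                     p$crop$sites, p$is_aim, max_tries = 50L),
    "selection too strong")
})

test_that("identical seeds give byte-identical simulated VCF output", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6, g = 2,
                    n_lineages = 5, seed = 77)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))
  expect_identical(unname(tools::md5sum(file.path(d1, "truth_segments.tsv"))),
                   unname(tools::md5sum(file.path(d2, "truth_segments.tsv"))))
})
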