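test_that("site FST components behave at fixation and under equality", {
  fixed <- wc_fst_components(c(10, 0, 0), c(0, 0, 10))
  expect_equal(fixed$fst, 1)
  same <- wc_fst_components(c(4, 4, 2), c(4, 4, 2))
  expect_lte(same$a, 0)
  expect_lte(same$fst, 0)
  expect_error(wc_fst_components(c(1, 0, 0), c(5, 5, 0)), ">= 2")
  # monomorphic overall: zero total, NaN ratio
  mono <- wc_fst_components(c(5, 0, 0), c(7, 0, 0))
  expect_true(is.nan(mono$fst))
})

test_that("site components match the independent Weir-Cockerham transcription", {
  # the worked all-homozygote example: p = 0.8 vs 0.2, n = 10 each
  ex <- wc_fst_components(c(8, 0, 2), c(2, 0, 8))
  or <- wc_oracle(list(c(8, 0, 2), c(2, 0, 8)))
  expect_equal(ex$a, or$a, tolerance = 1e-12)
  expect_equal(ex$abc, or$abc, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    cA <- as.vector(stats::rmultinom(1, sample(2:40, 1), stats::runif(3)))
    cB <- as.vector(stats::rmultinom(1, sample(2:40, 1), stats::runif(3)))
    w <- wc_fst_components(cA, cB)
    o <- wc_oracle(list(cA, cB))
    expect_equal(w$a, o$a, tolerance = 1e-12)
    expect_equal(w$abc, o$abc, tolerance = 1e-12)
  }
})

test_that("windowed FST is a bounded ratio of sums matching single sites", {
  gm <- genotype_matrix(
    rbind(a1 = c(0L, 0L), a2 = c(0L, 1L), b1 = c(2L, 2L), b2 = c(2L, 1L)),
    data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 200L),
               ref = "A", alt = "C"),
    c("a1", "a2", "b1", "b2"))
  pa <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                   panel = c("A", "A", "B", "B"))
  w <- fst_windows(gm, pa, "A", "B", window_bp = 1000, step_bp = 1000)
  s1 <- wc_fst_components(c(2, 0, 0), c(0, 0, 2))
  s2 <- wc_fst_components(c(1, 1, 0), c(0, 1, 1))
  expect_equal(w$value[w$chrom == "chr1"], s1$fst)
  expect_equal(w$value[w$chrom == "chr2"], s2$fst)
  # ratio-of-sums never exceeds 1 on simulated data
  co <- simulate_cohort(sim_config(n_chromosomes = 1, chrom_length_bp = 2e6,
                                   aim_density = 10, g = 3, n_lineages = 12,
                                   seed = 67))
  cb <- combine_cohort(co)
  ws <- fst_windows(cb$gm, cb$panels, "contemporary", "weed",
                    window_bp = 5e5, step_bp = 2.5e5)
  expect_true(all(ws$value[!is.nan(ws$value)] <= 1))
  expect_error(fst_windows(gm, pa, "A", "B", window_bp = 0), "positive")
})

test_that("site pi counts allele pair differences and ignores labels", {
  # 2 diploids AA and aa: 4 differing pairs of 6
  gm <- genotype_matrix(rbind(s1 = 0L, s2 = 2L),
                        data.frame(chrom = "chr1", pos = 10L,
                                   ref = "A", alt = "C"), c("s1", "s2"))
  pa <- data.frame(sample_id = c("s1", "s2"), panel = "p")
  w <- pi_windows(gm, pa, "p", window_bp = 100, step_bp = 100)
  expect_equal(w$value, 4 / 6)
  # allele-label swap leaves pi unchanged
  gm2 <- gm; gm2$geno <- 2L - gm$geno
  expect_equal(pi_windows(gm2, pa, "p", 100, 100)$value, w$value)
  # monomorphic site contributes zero
  gm3 <- genotype_matrix(rbind(s1 = 0L, s2 = 0L), gm$sites, c("s1", "s2"))
  expect_equal(pi_windows(gm3, pa, "p", 100, 100)$value, 0)
  # frequency-0.5 site in large n approaches 1/2
  n <- 200
  gm4 <- genotype_matrix(matrix(rep(c(0L, 2L), n / 2), ncol = 1),
                         gm$sites, sprintf("x%03d", 1:n))
  pa4 <- data.frame(sample_id = gm4$sample_ids, panel = "p")
  expect_equal(pi_windows(gm4, pa4, "p", 100, 100)$value, 0.5,
               tolerance = 0.01)
})

test_that("label permutation drives genome-average windowed FST to zero", {
  co <- simulate_cohort(sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
                                   aim_density = 10, neutral_snp_density = 10,
                                   g = 4, n_lineages = 24, seed = 71))
  cb <- combine_cohort(co)
  contemp <- cb$panels$sample_id[cb$panels$panel == "contemporary"]
  set.seed(71)
  halves <- sample(rep(c("g1", "g2"), each = 12))
  pa <- data.frame(sample_id = contemp, panel = halves)
  w <- fst_windows(subset_gm(cb$gm, contemp), pa, "g1", "g2")
  expect_lt(abs(mean(w$value[!is.nan(w$value)])), 0.03)
})

test_that("dual comparison aligns series and flags containing windows", {
  co <- simulate_cohort(sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
                                   aim_density = 10, neutral_snp_density = 10,
                                   g = 4, n_lineages = 24, seed = 73))
  cb <- combine_cohort(co)
  focal <- data.frame(name = "gene", chrom = "chr1",
                      start = 9e5, end = 9.5e5)
  du <- dual_comparison(cb$gm, cb$panels, "contemporary", "crop", "weed",
                        focal_regions = focal)
  expect_true(all(c("fst_crop", "fst_weed") %in% names(du$windows)))
  expect_equal(nrow(du$focal), 2L)  # 500 kb windows on a 250 kb step
  mid <- (9e5 + 9.5e5) / 2 - 1
  expect_true(all(du$focal$start <= mid & mid < du$focal$end))
  # a weed group identical to the weed ancestor: no positive differentiation
  ww <- fst_windows(cb$gm, cb$panels, "weed", "weed")
  expect_true(all(ww$value[!is.nan(ww$value)] <= 0.02))
  expect_error(dual_comparison(cb$gm, cb$panels, "contemporary", "crop",
                               "weed",
                               focal_regions = data.frame(
                                 name = "off", chrom = "chr9",
                                 start = 1, end = 2)), "outside")
})
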