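mk_region_gm <- function(geno, pos, ref, alt, ids) {
  genotype_matrix(geno,
                  data.frame(chrom = "chr2", pos = pos, ref = ref, alt = alt),
                  ids)
}

test_that("homozygous samples yield their sequence verbatim, counted twice", {
  gm <- mk_region_gm(rbind(A = c(0L, 0L), B = c(2L, 2L)),
                     c(10L, 20L), c("A", "C"), c("G", "T"), c("A", "B"))
  h <- extract_haplotypes(gm)
  expect_equal(h$haplotypes$sequence, c("AC", "GT"))
  expect_equal(h$haplotypes$count, c(2L, 2L))
  h1 <- extract_haplotypes(gm, homozygote_count = 1)
  expect_equal(h1$haplotypes$count, c(1L, 1L))
})

test_that("parsimony phasing reuses homozygote haplotypes and flags novelty", {
  # S3 het at site 1 only; both resolutions (AC, GC) observed in homozygotes
  gm <- mk_region_gm(rbind(A = c(0L, 0L), B = c(2L, 0L), C = c(1L, 0L)),
                     c(10L, 20L), c("A", "C"), c("G", "T"), c("A", "B", "C"))
  h <- extract_haplotypes(gm)
  expect_equal(h$haplotypes$sequence, c("AC", "GC"))
  expect_equal(h$haplotypes$count, c(3L, 3L))
  expect_false(any(h$haplotypes$flagged))
  expect_equal(h$samples$new_haps[h$samples$sample == "C"], 0L)
  # a het resolution that cannot reuse observed haplotypes gets flagged
  gm2 <- mk_region_gm(rbind(A = c(0L, 0L), D = c(1L, 1L)),
                      c(10L, 20L), c("A", "C"), c("G", "T"), c("A", "D"))
  h2 <- extract_haplotypes(gm2)
  expect_true(any(h2$haplotypes$flagged))
  # lexicographic tie-break: the chosen pair is the smallest
  expect_true(all(c("AC", "GT") %in%
                  h2$haplotypes$sequence[h2$haplotypes$carriers == "D" |
                                         grepl("D", h2$haplotypes$carriers)]))
})

test_that("phase-ambiguous and incomplete samples are excluded with reasons", {
  geno <- rbind(A = rep(0L, 10), E = rep(1L, 10), M = c(NA, rep(0L, 9)))
  gm <- mk_region_gm(geno, seq(10L, 100L, 10L), rep("A", 10), rep("G", 10),
                     c("A", "E", "M"))
  h <- extract_haplotypes(gm, max_het_sites = 8)
  expect_equal(sort(h$excluded$sample), c("E", "M"))
  expect_match(h$excluded$reason[h$excluded$sample == "E"], "het sites")
})

test_that("simulated lineage haplotypes stay within the two parental ones", {
  # a gene-sized region does not recombine internally
  co <- simulate_cohort(sim_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                                   aim_density = 6, neutral_snp_density = 0,
                                   recomb_rate = 0, g = 4, n_lineages = 10,
                                   seed = 83))
  cb <- combine_cohort(co)
  region <- list(chrom = "chr1", start = 1, end = 1e6)
  h <- extract_haplotypes(cb$gm, region, max_het_sites = 8)
  parents <- extract_haplotypes(
    genotype_matrix(rbind(co$panels$crop$geno[1, , drop = FALSE],
                          co$panels$weed$geno[1, , drop = FALSE]),
                    co$gm$sites, c("cp", "wp")), region)
  expect_true(all(h$haplotypes$sequence[!h$haplotypes$flagged] %in%
                  parents$haplotypes$sequence))
})

test_that("median joining matches brute-force Steiner minima on toy sets", {
  n1 <- median_joining(c("ACGT", "ACGA"))
  expect_equal(nrow(n1$edges), 1L)
  expect_equal(n1$edges$steps, 1L)
  expect_equal(n1$total_length, 1)

  # binary-coded {000, 110, 101}: median 100 cuts the MST from 4 to 3
  tri <- c("AAA", "TTA", "TAT")
  n2 <- median_joining(tri)
  expect_equal(n2$total_length, steiner_oracle(tri))
  expect_equal(sum(n2$nodes$median), 1L)
  expect_equal(n2$nodes$sequence[n2$nodes$median], "TAA")
  expect_equal(nrow(n2$edges), 3L)
  expect_true(all(n2$edges$steps == 1L))

  # a pure path needs no medians
  path <- c("AAA", "AAT", "ATT", "TTT")
  n3 <- median_joining(path)
  expect_equal(n3$total_length, steiner_oracle(path))
  expect_equal(sum(n3$nodes$median), 0L)
  expect_equal(nrow(n3$edges), 3L)
})

test_that("network length never exceeds the observed MST and order is moot", {
  set.seed(5)
  for (rep in 1:5) {
    seqs <- unique(replicate(6, paste(sample(c("A", "T"), 5, TRUE),
                                      collapse = "")))
    if (length(seqs) < 2) next
    net <- median_joining(seqs)
    expect_lte(net$total_length, mst_len_o(seqs))
    shuffled <- median_joining(sample(seqs))
    expect_identical(net$nodes$sequence, shuffled$nodes$sequence)
    expect_identical(net$edges, shuffled$edges)
  }
})

test_that("crop and weed ALS haplogroups separate by the panel divergence", {
  co <- simulate_cohort(sim_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                                   aim_density = 8, neutral_snp_density = 0,
                                   g = 5, n_lineages = 12, seed = 89))
  cb <- combine_cohort(co)
  h <- extract_haplotypes(cb$gm, list(chrom = "chr1", start = 1, end = 1e6))
  net <- median_joining(h)
  crop_seq <- extract_haplotypes(co$panels$crop)$haplotypes$sequence[1]
  weed_seq <- extract_haplotypes(co$panels$weed)$haplotypes$sequence[1]
  d <- ham_o(crop_seq, weed_seq)
  # the two parental haplotypes exist in the network and sit d steps apart
  expect_true(all(c(crop_seq, weed_seq) %in% net$nodes$sequence))
  expect_equal(d, 8L)
})

test_that("amino-acid step annotation flags resistance replacements", {
  map <- synthetic_als_map()
  pos <- unname(map$sites)
  # two haplotypes differing at all four diagnostic sites
  ref_at <- substring(map$ref_seq, pos, pos)
  alt_at <- c("C", "A", "A", "A")  # flank T>C, GCT>GCA syn, S653N, G654E
  gm <- mk_region_gm(rbind(X = rep(0L, 4), Y = rep(2L, 4)),
                     as.integer(pos), ref_at, alt_at, c("X", "Y"))
  h <- extract_haplotypes(gm)
  net <- annotate_steps(median_joining(h), map)
  ann <- net$annotations
  expect_equal(nrow(ann), 4L)
  expect_equal(ann$label[ann$pos == map$sites["noncoding"]], "non-coding")
  syn <- ann[ann$pos == map$sites["synonymous"], ]
  expect_equal(syn$aa_from, syn$aa_to)
  expect_false(syn$resistance)
  expect_equal(ann$label[ann$pos == map$sites["S653N"]], "S653N")
  expect_true(ann$resistance[ann$pos == map$sites["S653N"]])
  expect_equal(ann$label[ann$pos == map$sites["G654E"]], "G654E")
  expect_true(ann$resistance[ann$pos == map$sites["G654E"]])
})
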