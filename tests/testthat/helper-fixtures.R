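# Small in-code fixtures shared across test files.

# 3 samples x 5 sites with a missing call and a het column
tiny_gm <- function() {
  geno <- rbind(S1 = c(0L, 1L, 2L, 0L, NA),
                S2 = c(0L, 0L, 2L, 1L, 2L),
                S3 = c(2L, 1L, 0L, 0L, 0L))
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                      pos = c(100L, 250L, 900L, 500L, 2000L),
                      ref = c("A", "C", "G", "T", "A"),
                      alt = c("G", "T", "A", "C", "C"))
  genotype_matrix(geno, sites, c("S1", "S2", "S3"))
}

# hand-written VCF with an indel, a multiallelic record, and two chromosomes
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "chr1\t250\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/1",
    "chr1\t300\t.\tCA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",   # indel
    "chr1\t400\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/2\t0/1",  # multiallelic
    "chr1\t900\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0",
    "chr2\t500\t.\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "chr2\t2000\t.\tA\tC\t.\tPASS\t.\tGT\t./.\t1/1\t0/0"),
    path)
  path
}

# combine a simulated cohort with its ancestral panels into one matrix plus
# a panel-assignment table (crop / weed / contemporary)
combine_cohort <- function(co) {
  gm <- genotype_matrix(
    rbind(co$panels$crop$geno, co$panels$weed$geno, co$gm$geno),
    co$gm$sites,
    c(co$panels$crop$sample_ids, co$panels$weed$sample_ids,
      co$gm$sample_ids))
  pa <- data.frame(
    sample_id = gm$sample_ids,
    panel = rep(c("crop", "weed", "contemporary"),
                c(length(co$panels$crop$sample_ids),
                  length(co$panels$weed$sample_ids),
                  length(co$gm$sample_ids))))
  list(gm = gm, panels = pa)
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "weedhyb")
  if (p == "") p <- file.path("../../inst/extdata", f)
  p
}
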