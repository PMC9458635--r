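#' Genotype matrix container
#'
#' A `genotype_matrix` holds unphased diploid genotypes for a set of samples
#' at biallelic SNP sites, coded as the count of the alternate allele:
#' `0` homozygous reference, `1` heterozygous, `2` homozygous alternate,
#' `NA` missing. Sites carry chromosome, 1-based position, and the reference
#' and alternate alleles; positions must be strictly increasing within each
#' chromosome.
#'
#' @param geno integer matrix, samples in rows and sites in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` (one row
#'   per column of `geno`).
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `geno`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `sites`, `sample_ids`.
#' @export
genotype_matrix <- function(geno, sites, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (nrow(geno) != length(sample_ids))
    stop("geno rows must match sample_ids")
  if (ncol(geno) != nrow(sites))
    stop("geno columns must match site table rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(geno) <- sample_ids
  structure(list(geno = geno, sites = sites, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$sites), "sites on", length(unique(x$sites$chrom)),
      "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids or indices to keep (default all).
#' @param sites logical or integer index over site columns (default all).
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
subset_gm <- function(gm, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_along(gm$sample_ids)
  if (is.character(samples)) {
    idx <- match(samples, gm$sample_ids)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    samples <- idx
  }
  if (is.null(sites)) sites <- seq_len(nrow(gm$sites))
  genotype_matrix(gm$geno[samples, sites, drop = FALSE],
                  gm$sites[sites, , drop = FALSE],
                  gm$sample_ids[samples])
}

## parse "chr" or "chr:start-end" into a list(chrom, start, end)
#' @noRd
parse_region <- function(region) {
  if (is.list(region)) return(region)
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop("malformed region: ", region)
  list(chrom = m[2],
       start = if (m[4] == "") -Inf else as.numeric(m[4]),
       end   = if (m[5] == "") Inf else as.numeric(m[5]))
}

#' Read genotypes from a VCF file
#'
#' Reads the GT field of a VCF 4.x file into a [genotype_matrix()].
#' Multiallelic records and (optionally) indels are skipped; any genotype
#' containing `.` becomes missing. Phase separators (`|`) are ignored —
#' genotypes are treated as unphased on input.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` string (1-based,
#'   inclusive) restricting the returned sites.
#' @param drop_indels drop records whose ref or alt allele is longer than one
#'   base (default `TRUE`).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, drop_indels = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF contains no samples: ", path)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) & !is.na(fix$ALT) & fix$ALT != "."
  if (drop_indels)
    keep <- keep & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  geno <- t(apply(gt, 2, code))
  if (nrow(sites) == 1L) geno <- matrix(geno, ncol = 1L,
                                        dimnames = list(colnames(gt), NULL))
  gm <- genotype_matrix(geno, sites, colnames(gt))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- gm$sites$chrom == r$chrom & gm$sites$pos >= r$start &
      gm$sites$pos <= r$end
    gm <- subset_gm(gm, sites = keep)
  }
  gm
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns; missing genotypes
#' are written as `./.`. Output is deterministic, so identical inputs give
#' byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=weedhyb",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(gm$sites)), function(j) {
    g <- gm$geno[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(gm$sites$chrom[j], gm$sites$pos[j], ".", gm$sites$ref[j],
            gm$sites$alt[j], ".", "PASS", ".", "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the allele counts:
#' the two-sided p-value is the total probability of heterozygote counts whose
#' conditional probability does not exceed that of the observed count (plain,
#' not mid-p). Used to drop grossly out-of-equilibrium sites during variant
#' filtering.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return The exact two-sided p-value, in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  k <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  # log P(k hets | allele counts), Levene's conditional distribution
  logp <- lgamma(n + 1) - lgamma((nA - k) / 2 + 1) - lgamma(k + 1) -
    lgamma((na - k) / 2 + 1) + k * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, k)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

## per-site alt-allele frequency, call rate, and HWE p over called genotypes
#' @noRd
site_stats <- function(gm) {
  g <- gm$geno
  called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p_alt <- ifelse(called > 0, alt / (2 * called), NA_real_)
  hwe <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
  data.frame(called = called, call_rate = called / nrow(g),
             alt_freq = p_alt, maf = pmin(p_alt, 1 - p_alt), hwe_p = hwe)
}

#' Filter variants on allele frequency and Hardy-Weinberg equilibrium
#'
#' Retains biallelic SNP sites with minor allele frequency at least `maf_min`
#' (computed over called genotypes only) and HWE exact p-value at least
#' `hwe_p_min`. Sites with call rate below `min_call_rate` are dropped so
#' that allele frequencies are never computed on tiny denominators. Site
#' order is preserved; an empty result is a warning, not an error.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_p_min minimum HWE exact p-value (default 1e-7).
#' @param drop_indels drop sites with multi-base alleles (default `TRUE`).
#' @param min_call_rate minimum fraction of called genotypes per site
#'   (default 0.5).
#' @return The filtered `genotype_matrix`.
#' @export
filter_variants <- function(gm, maf_min = 0.05, hwe_p_min = 1e-7,
                            drop_indels = TRUE, min_call_rate = 0.5) {
  if (nrow(gm$sites) == 0L) stop("empty genotype matrix")
  st <- site_stats(gm)
  keep <- !is.na(st$maf) & st$call_rate >= min_call_rate &
    st$maf >= maf_min & st$hwe_p >= hwe_p_min
  if (drop_indels)
    keep <- keep & nchar(gm$sites$ref) == 1L & nchar(gm$sites$alt) == 1L
  if (!any(keep)) warning("all sites removed by filters")
  subset_gm(gm, sites = keep)
}

#' Heterozygous genotype fraction for one sample
#'
#' The fraction of called sites at which the sample is heterozygous,
#' `(n_called - n_homozygous) / n_called`. Missing genotypes are excluded
#' from both numerator and denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param sample a sample id present in `gm`.
#' @return A fraction in `[0, 1]`.
#' @export
het_fraction <- function(gm, sample) {
  i <- match(sample, gm$sample_ids)
  if (is.na(i)) stop("unknown sample: ", sample)
  g <- gm$geno[i, ]
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing for sample ", sample)
  sum(g == 1L) / length(g)
}

#' Read a panel assignment table
#'
#' Reads a two-column TSV (`sample_id`, `panel`) mapping samples to
#' population panels (e.g. crop ancestor, historic weed strains,
#' contemporary weeds).
#'
#' @param path TSV path with a header line.
#' @param gm optional [genotype_matrix()]; if given, every listed sample must
#'   be present in it.
#' @return data.frame with columns `sample_id`, `panel`.
#' @export
read_panels <- function(path, gm = NULL) {
  pa <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(pa)[1:2] <- c("sample_id", "panel")
  if (anyDuplicated(pa$sample_id)) stop("panels must be disjoint")
  if (!is.null(gm)) {
    miss <- setdiff(pa$sample_id, gm$sample_ids)
    if (length(miss)) stop("panel samples absent from genotype matrix: ",
                           paste(miss, collapse = ", "))
  }
  pa
}
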