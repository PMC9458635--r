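#' Weir-Cockerham variance components at one site (two populations)
#'
#' Computes the among-population component `a` and total `a + b + c` of the
#' Weir & Cockerham (1984) FST estimator for two populations (`r = 2`),
#' including the observed-heterozygosity term. The site estimate
#' `a / (a + b + c)` may be negative; it is `NaN` when the total is zero
#' (site monomorphic overall).
#'
#' @param countsA,countsB length-3 genotype counts `(n_AA, n_Aa, n_aa)` per
#'   population; each population needs at least 2 called genotypes.
#' @return list with `a`, `abc`, and `fst = a / abc`.
#' @export
wc_fst_components <- function(countsA, countsB) {
  nA <- sum(countsA); nB <- sum(countsB)
  if (nA < 2 || nB < 2) stop("each population needs >= 2 called genotypes")
  pA <- (2 * countsA[1] + countsA[2]) / (2 * nA)  # ref-allele frequency
  pB <- (2 * countsB[1] + countsB[2]) / (2 * nB)
  hA <- countsA[2] / nA
  hB <- countsB[2] / nB
  nbar <- (nA + nB) / 2
  nc <- 2 * nbar - (nA^2 + nB^2) / (2 * nbar)
  pbar <- (nA * pA + nB * pB) / (2 * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / nbar  # (r-1) = 1
  hbar <- (nA * hA + nB * hB) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  abc <- a + b + cc
  list(a = unname(a), abc = unname(abc),
       fst = unname(if (abc == 0) NaN else a / abc))
}

#' @noRd
geno_counts <- function(gm, samples) {
  g <- gm$geno[match(samples, gm$sample_ids), , drop = FALSE]
  rbind(colSums(g == 0L, na.rm = TRUE),
        colSums(g == 1L, na.rm = TRUE),
        colSums(g == 2L, na.rm = TRUE))
}

## half-open windows [start, start + window) anchored at 0, advancing by
## step; terminal partial windows retained
#' @noRd
window_starts <- function(extent, window_bp, step_bp) {
  if (window_bp <= 0 || step_bp <= 0) stop("window and step must be positive")
  seq(0, max(0, extent - 1), by = step_bp)
}

#' @noRd
windowed_stat <- function(sites, value_fun, window_bp, step_bp) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch)
    pos0 <- sites$pos[sel] - 1  # half-open 0-based internally
    ext <- max(sites$pos[sel])
    for (st in window_starts(ext, window_bp, step_bp)) {
      in_win <- sel[pos0 >= st & pos0 < st + window_bp]
      v <- value_fun(in_win)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + window_bp,
        n_sites = v$n, value = v$value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Sliding-window Weir-Cockerham FST between two populations
#'
#' Site components are combined per window as the ratio of sums
#' `sum(a) / sum(a + b + c)` (the weighted estimator); negative site
#' components are retained. Windows are half-open, anchored at position 0 of
#' each chromosome, of width `window_bp` advancing by `step_bp`; empty
#' windows yield `NaN`.
#'
#' @param gm a [genotype_matrix()].
#' @param panels panel assignment data.frame (`sample_id`, `panel`).
#' @param popA,popB panel labels to compare.
#' @param window_bp,step_bp window and step sizes in bp (defaults 500 kb /
#'   250 kb).
#' @return data.frame with `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
fst_windows <- function(gm, panels, popA, popB, window_bp = 500000,
                        step_bp = 250000) {
  sA <- panels$sample_id[panels$panel == popA]
  sB <- panels$sample_id[panels$panel == popB]
  if (length(sA) < 2 || length(sB) < 2)
    stop("both populations need >= 2 samples")
  cA <- geno_counts(gm, sA)
  cB <- geno_counts(gm, sB)
  ok <- colSums(cA) >= 2 & colSums(cB) >= 2
  comp <- matrix(NA_real_, 2, ncol(cA))
  for (j in which(ok)) {
    w <- wc_fst_components(cA[, j], cB[, j])
    comp[, j] <- c(w$a, w$abc)
  }
  windowed_stat(gm$sites, function(idx) {
    idx <- idx[ok[idx]]
    if (!length(idx)) return(list(n = 0L, value = NaN))
    tot <- sum(comp[2, idx])
    list(n = length(idx), value = if (tot == 0) NaN else
      sum(comp[1, idx]) / tot)
  }, window_bp, step_bp)
}

#' @noRd
site_pi <- function(counts) {
  # counts = (n_AA, n_Aa, n_aa); pi = pairwise differences / pairs among
  # the called haploid alleles
  n_alleles <- 2 * sum(counts)
  n_alt <- 2 * counts[3] + counts[2]
  if (n_alleles < 2) return(NA_real_)
  n_alt * (n_alleles - n_alt) / choose(n_alleles, 2)
}

#' Sliding-window nucleotide diversity (pi)
#'
#' Site pi is the proportion of differing pairs among called haploid
#' alleles; the window value is the mean over variant sites in the window
#' (per-variant-site convention, the default) or the sum divided by the
#' window length (`per_base = TRUE`).
#'
#' @param gm a [genotype_matrix()].
#' @param panels panel assignment data.frame.
#' @param population panel label (needs >= 2 samples).
#' @param window_bp,step_bp window geometry as in [fst_windows()].
#' @param per_base divide the window sum by window length instead of
#'   averaging over variant sites.
#' @return data.frame with `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
pi_windows <- function(gm, panels, population, window_bp = 500000,
                       step_bp = 250000, per_base = FALSE) {
  s <- panels$sample_id[panels$panel == population]
  if (length(s) < 2) stop("population needs >= 2 samples")
  cc <- geno_counts(gm, s)
  pi <- apply(cc, 2, site_pi)
  windowed_stat(gm$sites, function(idx) {
    idx <- idx[!is.na(pi[idx])]
    if (!length(idx)) return(list(n = 0L, value = if (per_base) 0 else NaN))
    list(n = length(idx), value = if (per_base)
      sum(pi[idx]) / window_bp else mean(pi[idx]))
  }, window_bp, step_bp)
}

#' Dual FST comparison: weed group vs crop ancestor and vs weed ancestor
#'
#' Runs [fst_windows()] for a contemporary weed group against each of its
#' two presumptive ancestors over identical windows, and reports, per focal
#' region, the containing windows' value pairs with genome-wide percentile
#' ranks. Adaptive introgression of a crop allele shows up as a low
#' crop-comparison and high weed-comparison rank at the focal window.
#'
#' @param gm a [genotype_matrix()].
#' @param panels panel assignment data.frame.
#' @param weed_group,crop_ancestor,weed_ancestor panel labels.
#' @param window_bp,step_bp window geometry.
#' @param focal_regions optional data.frame (`name`, `chrom`, `start`,
#'   `end`).
#' @return list with `windows` (aligned series: `chrom`, `start`, `end`,
#'   `n_sites`, `fst_crop`, `fst_weed`) and `focal` (per region x containing
#'   window: values and percentile ranks `pct_crop`, `pct_weed`).
#' @export
dual_comparison <- function(gm, panels, weed_group, crop_ancestor,
                            weed_ancestor, window_bp = 500000,
                            step_bp = 250000, focal_regions = NULL) {
  wc <- fst_windows(gm, panels, weed_group, crop_ancestor, window_bp, step_bp)
  ww <- fst_windows(gm, panels, weed_group, weed_ancestor, window_bp, step_bp)
  stopifnot(identical(wc[c("chrom", "start", "end")],
                      ww[c("chrom", "start", "end")]))
  win <- data.frame(wc[c("chrom", "start", "end", "n_sites")],
                    fst_crop = wc$value, fst_weed = ww$value)
  pct <- function(v) {
    r <- rank(v, ties.method = "average", na.last = "keep")
    r / sum(!is.na(v))
  }
  win$pct_crop <- pct(ifelse(is.nan(win$fst_crop), NA, win$fst_crop))
  win$pct_weed <- pct(ifelse(is.nan(win$fst_weed), NA, win$fst_weed))
  focal <- NULL
  if (!is.null(focal_regions)) {
    focal <- do.call(rbind, lapply(seq_len(nrow(focal_regions)), function(i) {
      r <- focal_regions[i, ]
      mid <- (r$start + r$end) / 2 - 1
      hit <- win$chrom == r$chrom & win$start <= mid & mid < win$end
      if (!any(hit)) stop("focal region ", r$name,
                          " outside covered chromosomes/windows")
      cbind(name = r$name, win[hit, ], row.names = NULL)
    }))
  }
  list(windows = win, focal = focal)
}
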