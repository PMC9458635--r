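#' Identify ancestry-informative markers between two panels
#'
#' An AIM is a site whose allele-frequency difference between two ancestral
#' panels is at least `min_freq_diff` (default 1.0 — a strict fixed
#' difference). Both panels must meet `min_call_rate` at the site. Each AIM
#' is oriented: `allele_a` is the majority allele in panel A, `allele_b` in
#' panel B.
#'
#' @param panelA,panelB [genotype_matrix()] objects sharing the same site
#'   list (checked on chrom/pos).
#' @param min_call_rate minimum per-panel call rate at the site
#'   (default 0.8).
#' @param min_freq_diff minimum absolute allele-frequency difference
#'   (default 1.0).
#' @return data.frame of class `aim_set` with columns `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `site` (index into the shared site table) and a
#'   `provenance` attribute (panel sizes and thresholds).
#' @export
identify_aims <- function(panelA, panelB, min_call_rate = 0.8,
                          min_freq_diff = 1.0) {
  if (nrow(panelA$geno) < 2L || nrow(panelB$geno) < 2L)
    stop("each panel needs at least 2 samples")
  if (!identical(panelA$sites[c("chrom", "pos")],
                 panelB$sites[c("chrom", "pos")]))
    stop("panels must share the site list")
  sa <- site_stats(panelA)
  sb <- site_stats(panelB)
  ok <- sa$call_rate >= min_call_rate & sb$call_rate >= min_call_rate &
    !is.na(sa$alt_freq) & !is.na(sb$alt_freq) &
    abs(sa$alt_freq - sb$alt_freq) >= min_freq_diff
  if (!any(ok)) warning("no ancestry-informative markers found")
  idx <- which(ok)
  pick <- function(freq_alt, j) ifelse(freq_alt > 0.5, panelA$sites$alt[j],
                                       panelA$sites$ref[j])
  out <- data.frame(chrom = panelA$sites$chrom[idx],
                    pos = panelA$sites$pos[idx],
                    allele_a = pick(sa$alt_freq[idx], idx),
                    allele_b = pick(sb$alt_freq[idx], idx),
                    site = idx, stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(n_panelA = nrow(panelA$geno),
                                  n_panelB = nrow(panelB$geno),
                                  min_call_rate = min_call_rate,
                                  min_freq_diff = min_freq_diff)
  class(out) <- c("aim_set", "data.frame")
  out
}

## match AIM rows to site columns of a genotype matrix (by chrom + pos)
#' @noRd
match_aims <- function(gm, aims) {
  key <- paste(gm$sites$chrom, gm$sites$pos)
  idx <- match(paste(aims$chrom, aims$pos), key)
  if (anyNA(idx)) stop("AIMs absent from genotype matrix")
  idx
}

## genotype codes (alt dosage) -> dosage of allele_a at each AIM
#' @noRd
a_allele_dosage <- function(gm, aims) {
  idx <- match_aims(gm, aims)
  g <- gm$geno[, idx, drop = FALSE]
  a_is_alt <- aims$allele_a == gm$sites$alt[idx]
  d <- g
  d[, !a_is_alt] <- 2L - g[, !a_is_alt, drop = FALSE]
  d
}

#' Supervised ancestry coefficients from AIM genotypes
#'
#' A desk-scale, supervised substitute for a model-based admixture fit: the
#' ancestry proportion for ancestor A is the fraction of A-alleles among a
#' sample's called AIM genotypes; ancestor B is the complement.
#'
#' @param gm a [genotype_matrix()] containing the AIM sites.
#' @param aims an [identify_aims()] result.
#' @param pop_names names for the two ancestries (default `c("A", "B")`).
#' @return data.frame with `sample_id`, the two proportion columns, and
#'   `n_called` (AIMs used).
#' @export
supervised_ancestry <- function(gm, aims, pop_names = c("A", "B")) {
  d <- a_allele_dosage(gm, aims)
  called <- rowSums(!is.na(d))
  if (any(called == 0L))
    stop("zero called AIMs for sample(s): ",
         paste(gm$sample_ids[called == 0L], collapse = ", "))
  pA <- rowSums(d, na.rm = TRUE) / (2 * called)
  out <- data.frame(sample_id = gm$sample_ids, a = pA, b = 1 - pA,
                    n_called = called, stringsAsFactors = FALSE)
  names(out)[2:3] <- pop_names
  out
}

#' Heterozygosity at ancestry-informative markers
#'
#' Observed heterozygous genotype counts restricted to AIM sites — the
#' quantity whose expected decay of 50% per selfing generation dates the
#' hybridization event.
#'
#' @param gm a [genotype_matrix()].
#' @param sample a sample id in `gm`.
#' @param aims an [identify_aims()] result.
#' @return list with `n_het`, `n_called`, `fraction`.
#' @export
aim_heterozygosity <- function(gm, sample, aims) {
  i <- match(sample, gm$sample_ids)
  if (is.na(i)) stop("unknown sample: ", sample)
  g <- gm$geno[i, match_aims(gm, aims)]
  g <- g[!is.na(g)]
  if (!length(g)) stop("zero called AIMs for sample ", sample)
  list(n_het = sum(g == 1L), n_called = length(g),
       fraction = sum(g == 1L) / length(g))
}

#' Estimate generations since hybridization from heterozygosity decay
#'
#' Under strict selfing the expected AIM heterozygosity after `g`
#' generations is `0.5^g`, so `g_hat = -log2(het_fraction)`. The confidence
#' interval is a Clopper-Pearson binomial interval on the heterozygote
#' proportion propagated through `-log2`. A sample with zero observed
#' heterozygotes yields only an open lower bound `g >= log2(n_called)`
#' (flagged `censored`), not a point estimate.
#'
#' @param het_fraction observed heterozygous fraction at AIMs, in `[0, 1]`.
#' @param n_called number of called AIMs underlying the fraction.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `g_hat`, `ci` (length-2), `censored` (logical).
#' @export
estimate_generations <- function(het_fraction, n_called, conf_level = 0.95) {
  if (het_fraction < 0 || het_fraction > 1) stop("het_fraction outside [0,1]")
  if (n_called < 1) stop("n_called must be positive")
  n_het <- round(het_fraction * n_called)
  if (het_fraction == 0)
    return(list(g_hat = NA_real_, ci = c(log2(n_called), Inf),
                censored = TRUE))
  ci_het <- stats::binom.test(n_het, n_called,
                              conf.level = conf_level)$conf.int
  ci_g <- sort(-log2(pmax(ci_het, .Machine$double.xmin)))
  ci_g[ci_g < 0] <- 0
  list(g_hat = max(0, -log2(het_fraction)), ci = ci_g, censored = FALSE)
}

#' Read an ADMIXTURE-style Q matrix
#'
#' Whitespace-delimited proportions, one row per sample, one column per
#' genetic population, with sample order supplied separately (ADMIXTURE
#' writes no ids).
#'
#' @param path path to the Q matrix file.
#' @param sample_ids character vector, or path to a one-id-per-line file, in
#'   the Q matrix row order.
#' @param pop_names column names for the K populations.
#' @return data.frame of proportions with `sample_ids` as row names.
#' @export
read_q_matrix <- function(path, sample_ids, pop_names) {
  q <- utils::read.table(path, header = FALSE)
  if (length(sample_ids) == 1L && file.exists(sample_ids))
    sample_ids <- readLines(sample_ids)
  if (nrow(q) != length(sample_ids)) stop("Q rows != sample ids")
  if (ncol(q) != length(pop_names)) stop("Q columns != population names")
  names(q) <- pop_names
  rownames(q) <- sample_ids
  bad <- abs(rowSums(q) - 1) > 1e-6
  if (any(bad)) stop("Q rows must sum to 1: ",
                     paste(sample_ids[bad], collapse = ", "))
  q
}

#' Classify an admixed accession from its ancestry coefficients
#'
#' Applies the population-structure classification rules for contemporary
#' weeds given membership proportions over the named populations (must
#' include `SH`, `BHA`, `TRJ`, `BETA`):
#' \itemize{
#'   \item admixed flag: proportions above `admix` (0.15) in two or more
#'     populations;
#'   \item `non-admixed-SH` / `non-admixed-BHA`: one historic weed
#'     population at `>= 1 - purity_tol`;
#'   \item `complex`: SH, BHA and TRJ each above `complex` (0.20);
#'   \item `beta`: BETA is the majority population;
#'   \item `SH-like`: SH above `like` (0.10) with BHA at or below
#'     `contrib_floor` (0.05); `BHA-like` symmetric;
#'   \item otherwise the admixed flag itself is the category
#'     (`admixed-flag`).
#' }
#'
#' @param q named numeric vector of membership proportions (sums to 1), or a
#'   one-row slice of [read_q_matrix()] output.
#' @param thresholds list overriding `admix`, `like`, `contrib_floor`,
#'   `complex`, `purity_tol`.
#' @return list with `category` (character) and `admixed` (logical).
#' @export
classify_accession <- function(q, thresholds = list()) {
  th <- utils::modifyList(list(admix = 0.15, like = 0.10,
                               contrib_floor = 0.05, complex = 0.20,
                               purity_tol = 0.05), thresholds)
  q <- unlist(q)
  need <- c("SH", "BHA", "TRJ", "BETA")
  if (!all(need %in% names(q)))
    stop("q must name populations ", paste(need, collapse = ", "))
  if (any(q < 0) || abs(sum(q) - 1) > 1e-6) stop("invalid proportions")
  admixed <- sum(q > th$admix) >= 2
  category <-
    if (q["SH"] >= 1 - th$purity_tol) "non-admixed-SH"
    else if (q["BHA"] >= 1 - th$purity_tol) "non-admixed-BHA"
    else if (q["SH"] > th$complex && q["BHA"] > th$complex &&
             q["TRJ"] > th$complex) "complex"
    else if (names(q)[which.max(q)] == "BETA") "beta"
    else if (q["SH"] > th$like && q["BHA"] <= th$contrib_floor) "SH-like"
    else if (q["BHA"] > th$like && q["SH"] <= th$contrib_floor) "BHA-like"
    else "admixed-flag"
  list(category = unname(category), admixed = admixed)
}

#' Classify every accession in a Q matrix
#'
#' @param q data.frame from [read_q_matrix()] (samples x populations).
#' @param thresholds see [classify_accession()].
#' @return data.frame with `sample_id`, `category`, `admixed`.
#' @export
classify_accessions <- function(q, thresholds = list()) {
  res <- lapply(seq_len(nrow(q)), function(i)
    classify_accession(unlist(q[i, ]), thresholds))
  data.frame(sample_id = rownames(q),
             category = vapply(res, `[[`, character(1), "category"),
             admixed = vapply(res, `[[`, logical(1), "admixed"),
             stringsAsFactors = FALSE)
}
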