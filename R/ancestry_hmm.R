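## emission matrix: P(observed A-allele dosage g | true ancestry dosage d),
## each observed allele mis-read with probability eps
#' @noRd
emission_probs <- function(eps) {
  rbind(`0` = stats::dbinom(0:2, 2, eps),
        `1` = c(eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps)),
        `2` = stats::dbinom(0:2, 2, 1 - eps))
}

## 3x3 dosage transition matrix from two independent per-haplotype switch
## processes, each flipping ancestry with probability q between markers
#' @noRd
dosage_transition <- function(q) {
  p <- 1 - q
  matrix(c(p^2,      2 * p * q,     q^2,
           p * q,    p^2 + q^2,     p * q,
           q^2,      2 * p * q,     p^2),
         3, 3, byrow = TRUE)
}

## forward-backward + Viterbi over one chromosome's AIM observations
#' @noRd
hmm_decode <- function(obs, pos, eps, rho) {
  n <- length(obs)
  E <- emission_probs(eps)
  em <- matrix(1, 3, n)  # missing genotypes emit 1 in every state
  called <- !is.na(obs)
  if (any(called)) em[, called] <- E[, obs[called] + 1L, drop = FALSE]
  q <- 0.5 * (1 - exp(-2 * rho * diff(pos)))
  Tm <- lapply(q, dosage_transition)
  init <- rep(1 / 3, 3)
  # forward (scaled)
  fwd <- matrix(0, 3, n)
  scale <- numeric(n)
  f <- init * em[, 1]
  scale[1] <- sum(f)
  fwd[, 1] <- f / scale[1]
  if (n > 1) for (t in 2:n) {
    f <- as.numeric(crossprod(Tm[[t - 1]], fwd[, t - 1])) * em[, t]
    scale[t] <- sum(f)
    fwd[, t] <- f / scale[t]
  }
  # backward
  bwd <- matrix(0, 3, n)
  bwd[, n] <- 1
  if (n > 1) for (t in (n - 1):1)
    bwd[, t] <- as.numeric(Tm[[t]] %*% (em[, t + 1] * bwd[, t + 1])) / scale[t + 1]
  post <- fwd * bwd
  post <- sweep(post, 2, colSums(post), "/")
  # Viterbi
  lv <- log(init) + log(em[, 1])
  back <- matrix(0L, 3, n)
  if (n > 1) for (t in 2:n) {
    cand <- outer(lv, rep(1, 3)) + log(Tm[[t - 1]])  # cand[i, j]
    back[, t] <- apply(cand, 2, which.max)
    lv <- cand[cbind(back[, t], 1:3)] + log(em[, t])
  }
  path <- integer(n)
  path[n] <- which.max(lv)
  if (n > 1) for (t in (n - 1):1) path[t] <- back[path[t + 1], t + 1]
  list(map_dosage = path - 1L, posterior = t(post))
}

#' Infer local ancestry tracks along the genome from AIM genotypes
#'
#' Decodes per-site diploid crop-ancestry dosage (0, 1, or 2 crop alleles)
#' with a three-state hidden Markov model over the sample's AIM genotypes.
#' Between adjacent AIMs each haplotype switches ancestry with probability
#' `(1 - exp(-2 * rho * d)) / 2` for inter-marker distance `d` bp; genotypes
#' are emitted with per-allele error `eps`. The maximum-a-posteriori path is
#' segmented by merging equal-dosage runs, with segment boundaries snapped
#' to midpoints between adjacent AIMs; dosage 1 contributes one crop and
#' one weed haplotype track.
#'
#' @param gm a [genotype_matrix()] containing the sample.
#' @param sample a sample id in `gm`.
#' @param aims an [identify_aims()] result; `allele_a` is taken as the crop
#'   allele.
#' @param eps per-allele emission error (default 0.01).
#' @param rho ancestry switch rate per bp (default 1e-7).
#' @return An object of class `ancestry_track`: list with `calls`
#'   (data.frame `chrom`, `pos`, `obs`, `dosage`, `post0`, `post1`,
#'   `post2`), `segments` (data.frame `chrom`, `start`, `end`, `dosage`),
#'   and `haplotypes` (data.frame `chrom`, `start`, `end`, `haplotype`,
#'   `ancestry`).
#' @export
infer_tracks <- function(gm, sample, aims, eps = 0.01, rho = 1e-7) {
  i <- match(sample, gm$sample_ids)
  if (is.na(i)) stop("unknown sample: ", sample)
  d <- a_allele_dosage(subset_gm(gm, samples = i), aims)[1, ]
  chroms <- unique(aims$chrom)
  n_by_chr <- table(factor(aims$chrom, levels = chroms))
  if (all(n_by_chr < 2L))
    stop("fewer than 2 AIMs on every chromosome; cannot infer tracks")
  calls <- list(); segs <- list(); haps <- list()
  for (ch in chroms) {
    sel <- aims$chrom == ch
    pos <- aims$pos[sel]
    dec <- hmm_decode(d[sel], pos, eps, rho)
    calls[[ch]] <- data.frame(chrom = ch, pos = pos, obs = d[sel],
                              dosage = dec$map_dosage,
                              post0 = dec$posterior[, 1],
                              post1 = dec$posterior[, 2],
                              post2 = dec$posterior[, 3],
                              stringsAsFactors = FALSE)
    # segment boundaries: chromosome extent with cuts at inter-AIM midpoints
    ext <- range(gm$sites$pos[gm$sites$chrom == ch])
    run <- rle(dec$map_dosage)
    n_run <- length(run$lengths)
    idx_end <- cumsum(run$lengths)
    cut <- if (n_run > 1)
      (pos[idx_end[-n_run]] + pos[idx_end[-n_run] + 1L]) / 2 else numeric(0)
    st <- c(ext[1] - 1, cut)
    en <- c(cut, ext[2])
    segs[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                             dosage = run$values, stringsAsFactors = FALSE)
    lab <- function(dos, hap)
      ifelse(dos >= ifelse(hap == 1, 1, 2), "crop", "weed")
    haps[[ch]] <- rbind(
      data.frame(chrom = ch, start = st, end = en, haplotype = 1L,
                 ancestry = lab(run$values, 1), stringsAsFactors = FALSE),
      data.frame(chrom = ch, start = st, end = en, haplotype = 2L,
                 ancestry = lab(run$values, 2), stringsAsFactors = FALSE))
  }
  structure(list(sample = sample,
                 calls = do.call(rbind, c(calls, make.row.names = FALSE)),
                 segments = do.call(rbind, c(segs, make.row.names = FALSE)),
                 haplotypes = do.call(rbind, c(haps, make.row.names = FALSE)),
                 eps = eps, rho = rho),
            class = "ancestry_track")
}

#' Append the genome-wide average row to a chromosome-by-group bias table
#'
#' The average is the unweighted mean of the per-chromosome proportions
#' (matching the arithmetic of published per-chromosome bias tables); a
#' site-weighted average is available via `weights`.
#'
#' @param per_chrom data.frame or matrix, rows = chromosomes, columns =
#'   groups, cells = weed-ancestry proportions in `[0, 1]`.
#' @param weights optional per-chromosome weights (e.g. AIM counts) for a
#'   weighted average instead of the unweighted mean.
#' @return The table with an `Average` row appended, class `bias_table`.
#' @export
bias_table <- function(per_chrom, weights = NULL) {
  m <- as.matrix(per_chrom)
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("proportions outside [0,1]")
  avg <- if (is.null(weights)) colMeans(m, na.rm = TRUE) else
    apply(m, 2, stats::weighted.mean, w = weights, na.rm = TRUE)
  out <- rbind(m, Average = avg)
  out <- as.data.frame(out)
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Genome-wide weed-ancestry bias by chromosome and group
#'
#' For each sample, the fraction of AIM ancestry calls assigned to the weedy
#' ancestor per chromosome (`(2 - dosage) / 2` averaged over AIMs); cells
#' are group means, and a genome-wide `Average` row is the unweighted mean
#' over chromosomes (see [bias_table()]).
#'
#' @param tracks named list of [infer_tracks()] results (names = sample
#'   ids).
#' @param groups named character vector or data.frame (`sample_id`,
#'   `panel`) assigning tracked samples to groups.
#' @param weighting `"sites"` (per-AIM calls, default) or `"bp"`
#'   (segment-length weighted).
#' @return A [bias_table()] (chromosomes + `Average` row, one column per
#'   group).
#' @export
genome_bias <- function(tracks, groups, weighting = c("sites", "bp")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$panel, groups$sample_id)
  ids <- names(tracks)
  grp <- groups[ids]
  if (anyNA(grp)) stop("ungrouped track sample(s)")
  chroms <- unique(tracks[[1]]$calls$chrom)
  weed_frac <- function(tr, ch) {
    if (weighting == "sites") {
      x <- tr$calls[tr$calls$chrom == ch, ]
      mean((2 - x$dosage) / 2)
    } else {
      s <- tr$segments[tr$segments$chrom == ch, ]
      sum((2 - s$dosage) / 2 * (s$end - s$start)) / sum(s$end - s$start)
    }
  }
  glev <- unique(grp)
  m <- sapply(glev, function(g) {
    members <- tracks[grp == g]
    if (!length(members)) return(rep(NA_real_, length(chroms)))
    vapply(chroms, function(ch)
      mean(vapply(members, weed_frac, numeric(1), ch = ch)), numeric(1))
  })
  m <- matrix(m, nrow = length(chroms),
              dimnames = list(chroms, glev))
  bias_table(m)
}

#' Ancestry label of a focal region
#'
#' Summarizes the ancestry calls overlapping a genomic region: `crop` or
#' `weed` when every overlapping AIM call agrees (dosage 2 or 0
#' respectively), `mixed` otherwise, and `no-marker` when the region
#' contains no AIM.
#'
#' @param track an [infer_tracks()] result.
#' @param region list or data.frame row with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return list with `label`, `n_aims`, `mean_dosage`, and per-haplotype
#'   crop fractions `hap_crop`.
#' @export
focal_block <- function(track, region) {
  x <- track$calls
  sel <- x$chrom == region$chrom & x$pos >= region$start &
    x$pos <= region$end
  if (!any(sel))
    return(list(label = "no-marker", n_aims = 0L, mean_dosage = NA_real_,
                hap_crop = c(NA_real_, NA_real_)))
  d <- x$dosage[sel]
  label <- if (all(d == 2L)) "crop" else if (all(d == 0L)) "weed" else "mixed"
  list(label = label, n_aims = sum(sel), mean_dosage = mean(d),
       hap_crop = c(mean(d >= 1L), mean(d == 2L)))
}
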