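#' Configuration for the crop x weed hybridization simulator
#'
#' Defines the scenario for [simulate_cohort()]: genome layout, marker
#' densities, recombination, number of selfing generations after the F1, and
#' optional selection. Selection has two separable knobs: a viability
#' advantage `s` for the crop (resistance) allele at `selection_site`, and a
#' per-crop-allele multiplicative penalty `background_penalty` applied at
#' every ancestry-informative marker, emulating genome-wide selection against
#' crop ancestry.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (recycled across
#'   chromosomes).
#' @param aim_density ancestry-informative markers per Mbp (fixed differences
#'   between the ancestral panels).
#' @param neutral_snp_density within-panel polymorphic SNPs per Mbp.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (Poisson, uniform placement, no interference).
#' @param g selfing generations after the F1 (`g = 0` returns the F1).
#' @param n_lineages independent hybrid lineages in a cohort.
#' @param selection_site optional `list(chrom =, pos =, s =)`: viability
#'   coefficient `s >= 0` favouring the crop allele at the AIM nearest `pos`.
#' @param background_penalty per-crop-allele fitness penalty in `[0, 1)`
#'   applied across all AIMs.
#' @param fixed_counts if `TRUE`, marker counts per chromosome are
#'   `round(density * length)` exactly instead of Poisson draws (deterministic
#'   fixtures).
#' @param seed RNG seed recorded in the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 12, chrom_length_bp = 5e6,
                       aim_density = 5, neutral_snp_density = 5,
                       recomb_rate = 2, g = 5, n_lineages = 48,
                       selection_site = NULL, background_penalty = 0,
                       fixed_counts = TRUE, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, aim_density > 0,
            neutral_snp_density >= 0, recomb_rate >= 0, g >= 0,
            n_lineages >= 1, background_penalty >= 0, background_penalty < 1)
  if (!is.null(selection_site))
    stopifnot(is.list(selection_site), selection_site$s >= 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = rep_len(chrom_length_bp, n_chromosomes),
                 aim_density = aim_density,
                 neutral_snp_density = neutral_snp_density,
                 recomb_rate = recomb_rate, g = as.integer(g),
                 n_lineages = as.integer(n_lineages),
                 selection_site = selection_site,
                 background_penalty = background_penalty,
                 fixed_counts = fixed_counts, seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected heterozygosity after g selfing generations
#'
#' Under strict self-fertilization the expected fraction of initially
#' heterozygous sites still heterozygous halves every generation:
#' `0.5 ^ g`. This closed form is the basis of the generations-since-
#' hybridization estimator ([estimate_generations()]).
#'
#' @param g number of selfing generations since the F1 (`>= 0`).
#' @return `0.5 ^ g`.
#' @export
expected_het_after_selfing <- function(g) {
  if (any(g < 0)) stop("g must be non-negative")
  0.5 ^ g
}

#' Simulate two diverged, fully inbred ancestral panels
#'
#' Builds a crop-like and a weed-like panel over a shared site list. AIM
#' sites are fixed for opposite alleles (crop panel homozygous reference,
#' weed panel homozygous alternate); neutral sites are polymorphic within
#' each panel with independent uniform(0.1, 0.9) allele frequencies, every
#' individual homozygous (fully inbred ancestors).
#'
#' @param cfg a [sim_config()].
#' @param n_crop,n_weed panel sizes.
#' @return A list with elements `crop`, `weed` (both [genotype_matrix()] on
#'   the same sites), `aims` (data.frame `chrom`, `pos`, `crop_allele`,
#'   `weed_allele`), and `is_aim` (logical per site).
#' @export
make_ancestral_panels <- function(cfg, n_crop = 10, n_weed = 11) {
  bases <- c("A", "C", "G", "T")
  sites <- list(); is_aim <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    L <- cfg$chrom_length_bp[ch]
    n_a <- if (cfg$fixed_counts) round(cfg$aim_density * L / 1e6) else
      stats::rpois(1, cfg$aim_density * L / 1e6)
    n_n <- if (cfg$fixed_counts) round(cfg$neutral_snp_density * L / 1e6) else
      stats::rpois(1, cfg$neutral_snp_density * L / 1e6)
    if (n_a < 1) stop("aim_density too low: chromosome ", ch, " has no AIMs")
    pos <- sort(sample.int(L, n_a + n_n))
    aim_flag <- rep(FALSE, n_a + n_n)
    aim_flag[sample.int(n_a + n_n, n_a)] <- TRUE
    ref <- sample(bases, n_a + n_n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    sites[[ch]] <- data.frame(chrom = sprintf("chr%d", ch), pos = pos,
                              ref = ref, alt = alt, stringsAsFactors = FALSE)
    is_aim[[ch]] <- aim_flag
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  is_aim <- unlist(is_aim)
  n_sites <- nrow(sites)
  crop <- matrix(0L, n_crop, n_sites)
  weed <- matrix(0L, n_weed, n_sites)
  weed[, is_aim] <- 2L
  for (j in which(!is_aim)) {
    crop[, j] <- 2L * stats::rbinom(n_crop, 1, stats::runif(1, 0.1, 0.9))
    weed[, j] <- 2L * stats::rbinom(n_weed, 1, stats::runif(1, 0.1, 0.9))
  }
  list(crop = genotype_matrix(crop, sites, sprintf("crop%02d", seq_len(n_crop))),
       weed = genotype_matrix(weed, sites, sprintf("weed%02d", seq_len(n_weed))),
       aims = data.frame(chrom = sites$chrom[is_aim], pos = sites$pos[is_aim],
                         crop_allele = sites$ref[is_aim],
                         weed_allele = sites$alt[is_aim],
                         stringsAsFactors = FALSE),
       is_aim = is_aim)
}

## haplotype = list(ends, labels): segments [ends[i-1], ends[i]) 0-based,
## labels 1 = crop, 2 = weed; ends[last] = chromosome length
#' @noRd
hap_at <- function(hap, pos0) hap$labels[findInterval(pos0, hap$ends) + 1L]

#' @noRd
new_hap <- function(L, label) list(ends = L, labels = label)

## one meiosis: Poisson crossover count, uniform placement, random start phase
#' @noRd
meiosis <- function(h1, h2, L, rate) {
  n_xo <- stats::rpois(1, rate)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(stats::runif(n_xo, 0, L))
  pts <- sort(unique(c(h1$ends, h2$ends, xo, L)))
  pts <- pts[pts <= L]
  mids <- (c(0, pts[-length(pts)]) + pts) / 2
  parent <- (start - 1L + findInterval(mids, xo)) %% 2L + 1L
  labs <- ifelse(parent == 1L, hap_at(h1, mids), hap_at(h2, mids))
  keep <- c(labs[-1] != labs[-length(labs)], TRUE)
  list(ends = pts[keep], labels = labs[keep])
}

#' Simulate one hybrid lineage: F1 followed by g selfing generations
#'
#' The F1 carries one intact crop and one intact weed haplotype per
#' chromosome. Each selfing generation draws two independent gametes from
#' the current plant (Poisson crossovers, uniform placement). With selection
#' enabled, offspring are accepted by rejection sampling on relative
#' viability `(1+s)^d_sel * (1-bp)^d_aims`, where `d_sel` is the crop-allele
#' dosage at the selected AIM and `d_aims` the summed crop dosage over all
#' AIMs.
#'
#' @param crop_hap,weed_hap per-site haplotype allele codes (0 = ref,
#'   1 = alt) for the two homozygous parents, in site-table order.
#' @param cfg a [sim_config()].
#' @param sites site table (`chrom`, `pos`) shared with the parents.
#' @param aims logical vector marking AIM sites (for the background penalty
#'   and the selected site lookup).
#' @param max_tries rejection-sampling cap per generation.
#' @return list with `geno` (0/1/2 per site), `truth`: list of `g`,
#'   `dosage` (crop-allele dosage per site), `haps` (per chromosome, the two
#'   ancestry haplotypes as segment lists), and `fitness` (final relative
#'   viability).
#' @export
simulate_lineage <- function(crop_hap, weed_hap, cfg, sites, aims,
                             max_tries = 1000L) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  pos0 <- split(sites$pos - 0.5, factor(sites$chrom, levels = chroms))
  sel <- cfg$selection_site
  sel_idx <- NULL
  if (!is.null(sel)) {
    cand <- which(sites$chrom == sel$chrom & aims)
    if (!length(cand)) stop("selection_site chromosome has no AIMs")
    sel_idx <- cand[which.min(abs(sites$pos[cand] - sel$pos))]
  }
  h1 <- lapply(cfg$chrom_length_bp, new_hap, label = 1L)
  h2 <- lapply(cfg$chrom_length_bp, new_hap, label = 2L)
  dosage_of <- function(a, b) {
    unlist(lapply(seq_along(chroms), function(ch) {
      (hap_at(a[[ch]], pos0[[ch]]) == 1L) + (hap_at(b[[ch]], pos0[[ch]]) == 1L)
    }))
  }
  fitness_of <- function(d) {
    f <- 1
    if (!is.null(sel_idx)) f <- f * (1 + sel$s) ^ d[sel_idx]
    if (cfg$background_penalty > 0)
      f <- f * (1 - cfg$background_penalty) ^ sum(d[aims])
    f
  }
  f_cur <- fitness_of(dosage_of(h1, h2))
  if (cfg$g > 0) {
    for (gen in seq_len(cfg$g)) {
      # tight upper bound on offspring fitness given the current parent:
      # selfing cannot push crop dosage below 2 at a fixed-crop site, nor
      # above 0 where the parent carries no crop allele
      d_par <- dosage_of(h1, h2)
      f_max <- 1
      if (!is.null(sel_idx) && d_par[sel_idx] > 0L)
        f_max <- f_max * (1 + sel$s) ^ 2
      if (cfg$background_penalty > 0)
        f_max <- f_max *
          (1 - cfg$background_penalty) ^ (2 * sum(d_par[aims] == 2L))
      for (try in seq_len(max_tries)) {
        c1 <- lapply(seq_along(chroms), function(ch)
          meiosis(h1[[ch]], h2[[ch]], cfg$chrom_length_bp[ch], cfg$recomb_rate))
        c2 <- lapply(seq_along(chroms), function(ch)
          meiosis(h1[[ch]], h2[[ch]], cfg$chrom_length_bp[ch], cfg$recomb_rate))
        f <- fitness_of(dosage_of(c1, c2))
        if (stats::runif(1) <= f / f_max) break
        if (try == max_tries)
          stop("no offspring accepted in ", max_tries,
               " tries at generation ", gen, "; selection too strong")
      }
      h1 <- c1; h2 <- c2; f_cur <- f
    }
  }
  dosage <- dosage_of(h1, h2)
  # alt-allele genotype implied by ancestry dosage and the parent haplotypes
  alt_count <- ifelse(dosage == 2L, 2L * crop_hap,
                      ifelse(dosage == 0L, 2L * weed_hap,
                             crop_hap + weed_hap))
  list(geno = as.integer(alt_count),
       truth = list(g = cfg$g, dosage = dosage,
                    haps = Map(function(a, b) list(a, b), h1, h2),
                    fitness = f_cur))
}

#' Simulate a cohort of independent hybrid lineages
#'
#' Draws `cfg$n_lineages` independent crop x weed hybrid lineages (each with
#' its own randomly chosen panel parents), runs [simulate_lineage()] on
#' each, and optionally writes a VCF of panels + contemporary samples plus
#' plain-text truth tracks.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds all randomness.
#' @param panels optional result of [make_ancestral_panels()]; generated
#'   from `cfg` when `NULL`.
#' @param max_tries rejection-sampling cap per generation, passed to
#'   [simulate_lineage()]; raise it for strong background penalties.
#' @param out_dir if non-`NULL`, writes `cohort.vcf`, `truth_segments.tsv`
#'   (chrom, start, end, lineage, haplotype, ancestry) and
#'   `lineage_truth.tsv` (lineage, g, crop ancestry proportion, fitness)
#'   into it.
#' @return list with `gm` (contemporary samples), `panels`, `truth` (per
#'   lineage, from [simulate_lineage()]), `dosage` (lineages x sites
#'   crop-allele dosage matrix), and `cfg`.
#' @export
simulate_cohort <- function(cfg, panels = NULL, out_dir = NULL,
                            max_tries = 1000L) {
  set.seed(cfg$seed)
  if (is.null(panels)) panels <- make_ancestral_panels(cfg)
  sites <- panels$crop$sites
  is_aim <- panels$is_aim
  n <- cfg$n_lineages
  geno <- matrix(NA_integer_, n, nrow(sites))
  truth <- vector("list", n)
  dosage <- matrix(NA_integer_, n, nrow(sites))
  for (i in seq_len(n)) {
    # parents are fully inbred: one haplotype each, coded as alt-allele dosage
    cp <- panels$crop$geno[sample.int(nrow(panels$crop$geno), 1), ] / 2L
    wp <- panels$weed$geno[sample.int(nrow(panels$weed$geno), 1), ] / 2L
    lin <- simulate_lineage(cp, wp, cfg, sites, is_aim, max_tries = max_tries)
    truth[[i]] <- lin$truth
    dosage[i, ] <- lin$truth$dosage
    geno[i, ] <- lin$geno
  }
  ids <- sprintf("W%02d", seq_len(n))
  gm <- genotype_matrix(geno, sites, ids)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    all_gm <- genotype_matrix(
      rbind(panels$crop$geno, panels$weed$geno, geno), sites,
      c(panels$crop$sample_ids, panels$weed$sample_ids, ids))
    write_vcf(all_gm, file.path(out_dir, "cohort.vcf"))
    segs <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ch) {
        do.call(rbind, lapply(1:2, function(h) {
          hp <- truth[[i]]$haps[[ch]][[h]]
          data.frame(chrom = sprintf("chr%d", ch),
                     start = c(0, utils::head(hp$ends, -1)), end = hp$ends,
                     lineage = ids[i], haplotype = h,
                     ancestry = c("crop", "weed")[hp$labels],
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
    utils::write.table(segs, file.path(out_dir, "truth_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lt <- data.frame(lineage = ids, g = cfg$g,
                     crop_ancestry = rowMeans(dosage) / 2,
                     fitness = vapply(truth, function(t) t$fitness, numeric(1)))
    utils::write.table(lt, file.path(out_dir, "lineage_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(gm = gm, panels = panels, truth = truth, dosage = dosage, cfg = cfg)
}
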