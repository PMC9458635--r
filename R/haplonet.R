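#' Extract gene-region haplotypes with a deterministic phasing rule
#'
#' Builds per-sample haplotype sequences over the sites of a gene region.
#' Homozygous samples contribute their sequence verbatim (counted twice by
#' default — two identical haplotypes). Heterozygous calls are resolved by
#' parsimony: among all phase assignments of the sample's het sites, the one
#' minimizing the number of haplotypes not already observed among
#' homozygous-derived haplotypes is chosen (ties broken lexicographically);
#' samples whose best resolution still creates new haplotypes are flagged.
#' Samples with more than `max_het_sites` het sites (phase ambiguity `2^k`)
#' or with missing calls in the region are excluded with a reason.
#'
#' @param gm a [genotype_matrix()].
#' @param region optional `list(chrom, start, end)` restricting sites
#'   (1-based inclusive); default all sites in `gm`.
#' @param max_het_sites maximum het sites to phase per sample (default 8).
#' @param homozygote_count 2 (default) to count a homozygote's haplotype
#'   twice, 1 to count it once.
#' @return list with `haplotypes` (data.frame `sequence`, `count`,
#'   `carriers`, `flagged`), `samples` (per-sample phasing report), and
#'   `excluded`; site positions in attribute `positions`.
#' @export
extract_haplotypes <- function(gm, region = NULL, max_het_sites = 8,
                               homozygote_count = 2) {
  if (!is.null(region)) {
    keep <- gm$sites$chrom == region$chrom & gm$sites$pos >= region$start &
      gm$sites$pos <= region$end
    if (!any(keep)) stop("no sites in region")
    gm <- subset_gm(gm, sites = keep)
  }
  homozygote_count <- as.integer(homozygote_count)
  refc <- gm$sites$ref; altc <- gm$sites$alt
  hom_set <- character(0)
  seq_of <- function(g, het_to) {  # het_to: allele index (1 ref, 2 alt) at hets
    s <- ifelse(g == 0L, refc, ifelse(g == 2L, altc, NA))
    s[g == 1L] <- ifelse(het_to[g == 1L] == 1L, refc[g == 1L], altc[g == 1L])
    paste(s, collapse = "")
  }
  samples <- list(); excluded <- list(); haps <- list()
  add_hap <- function(seqs, id, n_each, flagged) {
    for (s in seqs) {
      if (is.null(haps[[s]]))
        haps[[s]] <<- list(count = 0L, carriers = character(0),
                           flagged = FALSE)
      haps[[s]]$count <<- haps[[s]]$count + n_each
      haps[[s]]$carriers <<- union(haps[[s]]$carriers, id)
      haps[[s]]$flagged <<- haps[[s]]$flagged || flagged
    }
  }
  g_all <- gm$geno
  het_counts <- rowSums(g_all == 1L, na.rm = TRUE)
  ord <- order(gm$sample_ids)
  # pass 1: homozygous samples define the observed haplotype set
  for (i in ord[het_counts[ord] == 0L]) {
    g <- g_all[i, ]
    if (anyNA(g)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample = gm$sample_ids[i], reason = "missing calls")
      next
    }
    s <- seq_of(g, integer(length(g)))
    hom_set <- union(hom_set, s)
    add_hap(s, gm$sample_ids[i], homozygote_count, FALSE)
    samples[[length(samples) + 1L]] <-
      data.frame(sample = gm$sample_ids[i], n_het = 0L, new_haps = 0L,
                 flagged = FALSE)
  }
  # pass 2: phase heterozygous samples against the homozygote set
  for (i in ord[het_counts[ord] > 0L]) {
    id <- gm$sample_ids[i]
    g <- g_all[i, ]
    if (anyNA(g)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample = id, reason = "missing calls")
      next
    }
    k <- sum(g == 1L)
    if (k > max_het_sites) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample = id,
                   reason = sprintf("%d het sites (> %d)", k, max_het_sites))
      next
    }
    het_idx <- which(g == 1L)
    best <- NULL; best_score <- Inf
    for (m in 0:(2^k - 1)) {
      bits <- as.integer(intToBits(m))[seq_len(k)]
      h1 <- integer(length(g)); h2 <- integer(length(g))
      h1[het_idx] <- 1L + bits
      h2[het_idx] <- 2L - bits
      pair <- sort(c(seq_of(g, h1), seq_of(g, h2)))
      score <- sum(!(pair %in% hom_set))
      key <- paste(pair, collapse = "|")
      if (score < best_score ||
          (score == best_score && key < paste(best, collapse = "|"))) {
        best <- pair; best_score <- score
      }
    }
    flagged <- best_score > 0
    add_hap(best, id, 1L, flagged)
    samples[[length(samples) + 1L]] <-
      data.frame(sample = id, n_het = k, new_haps = best_score,
                 flagged = flagged)
  }
  hseq <- sort(names(haps))
  out <- list(
    haplotypes = data.frame(
      sequence = hseq,
      count = vapply(haps[hseq], `[[`, integer(1), "count"),
      carriers = vapply(haps[hseq], function(h)
        paste(sort(h$carriers), collapse = ","), character(1)),
      flagged = vapply(haps[hseq], `[[`, logical(1), "flagged"),
      stringsAsFactors = FALSE, row.names = NULL),
    samples = do.call(rbind, c(samples, make.row.names = FALSE)),
    excluded = if (length(excluded))
      do.call(rbind, c(excluded, make.row.names = FALSE)) else NULL)
  attr(out, "positions") <- gm$sites$pos
  attr(out, "chrom") <- gm$sites$chrom[1]
  out
}

#' Read aligned consensus sequences as haplotypes
#'
#' Parity path for externally assembled, already-phased consensus FASTA:
#' each record is one haplotype; identical sequences are collapsed with
#' their carrier lists.
#'
#' @param path FASTA of equal-length aligned sequences.
#' @param positions optional genomic positions of the alignment columns.
#' @return list shaped like [extract_haplotypes()] output.
#' @export
haplotypes_from_fasta <- function(path, positions = NULL) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- toupper(vapply(fa, `[[`, character(1), 1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length")
  ids <- names(fa)
  u <- sort(unique(seqs))
  out <- list(haplotypes = data.frame(
    sequence = u,
    count = vapply(u, function(s) sum(seqs == s), integer(1)),
    carriers = vapply(u, function(s)
      paste(sort(ids[seqs == s]), collapse = ","), character(1)),
    flagged = FALSE, stringsAsFactors = FALSE, row.names = NULL),
    samples = NULL, excluded = NULL)
  attr(out, "positions") <- if (is.null(positions))
    seq_len(nchar(u[1])) else positions
  out
}

#' @noRd
hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' @noRd
hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  D <- matrix(0L, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
  D
}

## total length of a minimum spanning tree (Prim)
#' @noRd
mst_length <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  dist <- D[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(dist[cand])]
    total <- total + dist[v]
    in_tree[v] <- TRUE
    dist <- pmin(dist, D[v, ])
  }
  total
}

## epsilon-relaxed minimum spanning network: an edge of weight w is kept iff
## its endpoints lie in different components of the graph restricted to
## edges of weight < w - epsilon
#' @noRd
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = integer(0)))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  comp_at <- function(thr) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    sel <- which(w < thr)
    for (e in sel) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, integer(1))
  }
  keep <- logical(length(w))
  for (lvl in sort(unique(w))) {
    comp <- comp_at(lvl - epsilon)
    sel <- which(w == lvl)
    keep[sel] <- comp[pairs[sel, 1]] != comp[pairs[sel, 2]]
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep])
}

#' Median-joining haplotype network
#'
#' Builds a median-joining network over the distinct haplotypes: iteratively
#' adds majority-consensus median (Steiner) vectors of triplets linked in
#' the epsilon-relaxed minimum spanning network whenever the addition
#' shortens the minimum spanning tree over the node set, then prunes median
#' nodes of degree below 3. Processing is lexicographic throughout, so the
#' result is invariant to input order; the number of co-optimal median
#' choices encountered is recorded (equally parsimonious arrangements).
#'
#' @param haps an [extract_haplotypes()] result, or a character vector of
#'   equal-length sequences (optionally named by sample).
#' @param epsilon relaxation of the spanning-network weight comparison
#'   (default 0, the strict network).
#' @return list of class `haplotype_network`: `nodes` (data.frame `id`,
#'   `sequence`, `count`, `median`), `edges` (data.frame `from`, `to`,
#'   `steps` in node ids), `total_length`, `co_optimal`; position metadata
#'   is carried through for [annotate_steps()].
#' @export
median_joining <- function(haps, epsilon = 0) {
  positions <- NULL
  if (is.list(haps) && !is.null(haps$haplotypes)) {
    positions <- attr(haps, "positions")
    counts <- stats::setNames(haps$haplotypes$count, haps$haplotypes$sequence)
  } else {
    seqs <- as.character(haps)
    counts <- table(seqs)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  obs <- sort(names(counts))
  if (length(obs) < 2) stop("need at least 2 distinct haplotypes")
  if (length(unique(nchar(obs))) != 1L)
    stop("haplotypes must have equal length")
  nodes <- obs
  co_optimal <- 0L
  repeat {
    D <- hamming_matrix(nodes)
    base_len <- mst_length(D)
    net <- msn_edges(D, epsilon)
    adj <- matrix(FALSE, length(nodes), length(nodes))
    adj[cbind(net$from, net$to)] <- TRUE
    adj <- adj | t(adj)
    cand <- character(0)
    n <- length(nodes)
    if (n >= 3) {
      mat <- do.call(rbind, strsplit(nodes, ""))
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2) next
        trip <- mat[c(i, j, k), , drop = FALSE]
        med <- apply(trip, 2, function(col) {
          tb <- sort(table(col), decreasing = TRUE)
          if (tb[1] >= 2) names(tb)[1] else sort(col)[1]
        })
        cand <- c(cand, paste(med, collapse = ""))
      }
    }
    cand <- sort(setdiff(unique(cand), nodes))
    if (!length(cand)) break
    gains <- vapply(cand, function(s)
      base_len - mst_length(hamming_matrix(c(nodes, s))), numeric(1))
    best <- max(gains)
    if (best <= 0) break
    tied <- cand[gains == best]
    co_optimal <- co_optimal + length(tied) - 1L
    nodes <- sort(c(nodes, tied[1]))
  }
  # prune medians of degree < 3 in the final network
  repeat {
    D <- hamming_matrix(nodes)
    net <- msn_edges(D, epsilon)
    deg <- tabulate(c(net$from, net$to), nbins = length(nodes))
    drop <- which(!(nodes %in% obs) & deg < 3)
    if (!length(drop)) break
    nodes <- nodes[-drop]
  }
  D <- hamming_matrix(nodes)
  net <- msn_edges(D, epsilon)
  ids <- sprintf("H%02d", seq_along(nodes))
  res <- list(
    nodes = data.frame(id = ids, sequence = nodes,
                       count = ifelse(nodes %in% obs,
                                      as.integer(counts[nodes]), 0L),
                       median = !(nodes %in% obs), stringsAsFactors = FALSE),
    edges = data.frame(from = ids[net$from], to = ids[net$to],
                       steps = net$weight, stringsAsFactors = FALSE),
    total_length = mst_length(D),
    co_optimal = co_optimal)
  attr(res, "positions") <- positions
  class(res) <- "haplotype_network"
  res
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$median), "median ),", nrow(x$edges),
      "edges, total length", x$total_length, "\n")
  invisible(x)
}

#' @noRd
translate_codon <- function(codon) {
  toupper(seqinr::translate(tolower(strsplit(codon, "")[[1]])))
}

#' @noRd
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Annotate mutational steps with amino-acid replacements
#'
#' For each network edge and each differing site along it, maps the genomic
#' position through the gene's CDS coordinates, translates the affected
#' codon for both alleles with the standard genetic code, and flags steps
#' matching configured resistance replacements (defaults: the two ALS
#' replacements S653N and G654E). Sites outside the CDS are labelled
#' `non-coding`.
#'
#' @param net a [median_joining()] network whose haplotype columns carry
#'   genomic positions (attribute set by [extract_haplotypes()]).
#' @param cds_map list with `ref_seq` (reference sequence of the gene
#'   region), `seq_start` (genomic position of its first base), `cds`
#'   (data.frame `start`, `end`, 1-based inclusive genomic intervals in
#'   transcription order), `strand` (`"+"` or `"-"`).
#' @param resistance character vector of replacement labels to flag.
#' @return `net` with an `annotations` element: data.frame `edge` (from-to),
#'   `pos`, `nt_from`, `nt_to`, `coding`, `codon`, `aa_from`, `aa_to`,
#'   `label`, `resistance`.
#' @export
annotate_steps <- function(net, cds_map, resistance = c("S653N", "G654E")) {
  positions <- attr(net, "positions")
  if (is.null(positions)) stop("network carries no site positions")
  strand <- if (is.null(cds_map$strand)) "+" else cds_map$strand
  cds <- cds_map$cds[order(cds_map$cds$start), , drop = FALSE]
  cds_lens <- cds$end - cds$start + 1
  offs <- cumsum(c(0, utils::head(cds_lens, -1)))
  region_at <- function(p) {
    hit <- which(p >= cds$start & p <= cds$end)
    if (!length(hit)) return(NA_integer_)
    offs[hit] + (p - cds$start[hit] + 1)  # 1-based plus-strand CDS position
  }
  cds_seq <- paste(vapply(seq_len(nrow(cds)), function(i)
    substr(cds_map$ref_seq, cds$start[i] - cds_map$seq_start + 1,
           cds$end[i] - cds_map$seq_start + 1), character(1)), collapse = "")
  total_cds <- nchar(cds_seq)
  if (strand == "-") cds_seq <- revcomp(cds_seq)
  ann <- list()
  for (e in seq_len(nrow(net$edges))) {
    a <- net$nodes$sequence[net$nodes$id == net$edges$from[e]]
    b <- net$nodes$sequence[net$nodes$id == net$edges$to[e]]
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    for (col in which(av != bv)) {
      p <- positions[col]
      cpos <- region_at(p)
      nt_from <- av[col]; nt_to <- bv[col]
      # orient each step from the reference allele where one side matches it
      ref_base <- substr(cds_map$ref_seq, p - cds_map$seq_start + 1,
                         p - cds_map$seq_start + 1)
      if (nt_to == ref_base && nt_from != ref_base) {
        nt_from <- bv[col]; nt_to <- av[col]
      }
      gen_from <- nt_from; gen_to <- nt_to  # genomic-strand, oriented
      if (is.na(cpos)) {
        ann[[length(ann) + 1L]] <- data.frame(
          edge = paste0(net$edges$from[e], "-", net$edges$to[e]), pos = p,
          nt_from = nt_from, nt_to = nt_to, coding = FALSE,
          codon = NA_integer_, aa_from = NA_character_,
          aa_to = NA_character_, label = "non-coding", resistance = FALSE)
        next
      }
      if (strand == "-") {
        cpos <- total_cds - cpos + 1
        nt_from <- chartr("ACGT", "TGCA", nt_from)
        nt_to <- chartr("ACGT", "TGCA", nt_to)
      }
      codon_n <- ceiling(cpos / 3)
      in_codon <- (cpos - 1) %% 3 + 1
      ref_codon <- substr(cds_seq, (codon_n - 1) * 3 + 1, codon_n * 3)
      c_from <- ref_codon; substr(c_from, in_codon, in_codon) <- nt_from
      c_to <- ref_codon; substr(c_to, in_codon, in_codon) <- nt_to
      aa_from <- translate_codon(c_from)
      aa_to <- translate_codon(c_to)
      label <- paste0(aa_from, codon_n, aa_to)
      ann[[length(ann) + 1L]] <- data.frame(
        edge = paste0(net$edges$from[e], "-", net$edges$to[e]), pos = p,
        nt_from = gen_from, nt_to = gen_to, coding = TRUE, codon = codon_n,
        aa_from = aa_from, aa_to = aa_to, label = label,
        resistance = aa_from != aa_to & label %in% resistance)
    }
  }
  net$annotations <- if (length(ann))
    do.call(rbind, c(ann, make.row.names = FALSE)) else NULL
  net
}

#' Write a haplotype network as edge-list and node-table TSVs
#'
#' @param net a [median_joining()] network (annotated or not).
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and, if present, `<prefix>_annotations.tsv`.
#' @return The written paths, invisibly.
#' @export
write_network_tsv <- function(net, prefix) {
  paths <- c(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"))
  utils::write.table(net$nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(net$annotations)) {
    paths <- c(paths, paste0(prefix, "_annotations.tsv"))
    utils::write.table(net$annotations, paths[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Synthetic ALS-like gene map for annotation examples
#'
#' A deterministic, fully synthetic stand-in for the acetolactate synthase
#' gene region (no real coordinates or sequence): a 50 bp 5' flank, a
#' single-exon CDS of 660 codons on the plus strand with serine at codon
#' 653 (AGT) and glycine at codon 654 (GGA) — so the canonical resistance
#' replacements S653N (AGT>AAT) and G654E (GGA>GAA) fall at genomic
#' positions 2008 and 2011 — and a 50 bp 3' flank.
#'
#' @return A `cds_map` list for [annotate_steps()] with an extra element
#'   `sites` (named genomic positions: `noncoding`, `synonymous` third base
#'   of codon 100, `S653N`, `G654E`).
#' @export
synthetic_als_map <- function() {
  codons <- rep("GCT", 660)
  codons[653] <- "AGT"
  codons[654] <- "GGA"
  codons[660] <- "TGA"
  ref_seq <- paste0(strrep("T", 50), paste(codons, collapse = ""),
                    strrep("T", 50))
  list(ref_seq = ref_seq, seq_start = 1,
       cds = data.frame(start = 51, end = 50 + 3 * 660), strand = "+",
       sites = c(noncoding = 10,
                 synonymous = 50 + 99 * 3 + 3,
                 S653N = 50 + 652 * 3 + 2,
                 G654E = 50 + 653 * 3 + 2))
}
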