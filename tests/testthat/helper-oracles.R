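# Independent oracles used to cross-check the package implementations.

# Conditional HWE exact test by direct enumeration: probabilities of every
# attainable heterozygote count built from binomial coefficients, normalized
# by the enumerated total (no closed-form shortcut shared with the package).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  ks <- Filter(function(k) (nA - k) %% 2 == 0 && k <= nA && k <= 2 * n - nA,
               0:n)
  wt <- vapply(ks, function(k) {
    naa_k <- (nA - k) / 2
    choose(n, naa_k) * choose(n - naa_k, k) * 2^k
  }, numeric(1))
  pr <- wt / sum(wt)
  obs <- pr[ks == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Weir & Cockerham (1984) variance components transcribed in their general
# r-population form and evaluated at r = 2.
wc_oracle <- function(counts_list) {
  r <- length(counts_list)
  n_i <- vapply(counts_list, sum, numeric(1))
  p_i <- vapply(counts_list, function(x) (2 * x[1] + x[2]) / (2 * sum(x)),
                numeric(1))
  h_i <- vapply(counts_list, function(x) x[2] / sum(x), numeric(1))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, abc = a + b + cc)
}

# Brute-force Steiner oracle: minimal total spanning length over the
# observed haplotypes allowing any subset (up to max_extra) of candidate
# intermediate vectors built from the per-site alphabets.
ham_o <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

mst_len_o <- function(seqs) {  # Kruskal, independent of the package's Prim
  n <- length(seqs)
  if (n < 2) return(0)
  e <- do.call(rbind, lapply(1:(n - 1), function(i)
    do.call(rbind, lapply((i + 1):n, function(j)
      data.frame(i = i, j = j, w = ham_o(seqs[i], seqs[j]))))))
  e <- e[order(e$w), ]
  parent <- 1:n
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0
  for (k in seq_len(nrow(e))) {
    a <- find(e$i[k]); b <- find(e$j[k])
    if (a != b) { parent[a] <- b; total <- total + e$w[k] }
  }
  total
}

steiner_oracle <- function(seqs, max_extra = 3) {
  chars <- strsplit(seqs, "")
  alph <- lapply(seq_len(nchar(seqs[1])), function(s)
    unique(vapply(chars, `[`, character(1), s)))
  cand <- apply(expand.grid(alph, stringsAsFactors = FALSE), 1, paste,
                collapse = "")
  cand <- setdiff(cand, seqs)
  best <- mst_len_o(seqs)
  for (k in seq_len(min(max_extra, length(cand)))) {
    for (pick in utils::combn(length(cand), k, simplify = FALSE)) {
      best <- min(best, mst_len_o(c(seqs, cand[pick])))
    }
  }
  best
}
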