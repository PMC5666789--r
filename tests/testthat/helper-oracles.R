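# Independent brute-force oracles used by the unit and acceptance tests.
# These re-derive the expected results directly from first principles
# (genetic code, exhaustive enumeration) without touching any of the
# package's internal tables or memoisation.

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_sense <- names(.oracle_gc)[.oracle_gc != "*"]
.oracle_nt <- c("A", "C", "G", "T")

# NG86 synonymous site count of one codon: per position, the fraction of
# non-stop single-base changes that preserve the amino acid.
oracle_sites_codon <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- .oracle_gc[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    nonstop <- 0
    for (alt in setdiff(.oracle_nt, ch[pos])) {
      ch2 <- ch
      ch2[pos] <- alt
      to_aa <- .oracle_gc[[paste(ch2, collapse = "")]]
      if (to_aa == "*") next
      nonstop <- nonstop + 1
      if (to_aa == aa) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# Equal-weight pathway enumeration between two codons: mean synonymous and
# nonsynonymous step counts over all orderings of the differing positions,
# with orderings passing through a stop codon excluded (steps on a blocked
# ordering count as nonsynonymous if no ordering is stop-free).
oracle_pair_diffs <- function(a, b) {
  la <- strsplit(a, "")[[1]]
  lb <- strsplit(b, "")[[1]]
  diffs <- which(la != lb)
  if (length(diffs) == 0L) return(c(sd = 0, nd = 0))
  tallies <- lapply(oracle_perms(diffs), function(ord) {
    cur <- la
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (pos in ord) {
      from_aa <- .oracle_gc[[paste(cur, collapse = "")]]
      cur[pos] <- lb[pos]
      to_aa <- .oracle_gc[[paste(cur, collapse = "")]]
      if (to_aa == "*") blocked <- TRUE
      if (!blocked && from_aa == to_aa) sd <- sd + 1 else nd <- nd + 1
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(tallies, `[[`, logical(1), "blocked")
  use <- if (any(ok)) tallies[ok] else tallies
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# Full NG86 oracle over paired codon vectors.
oracle_ng86 <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  sa <- sum(vapply(codons_a, oracle_sites_codon, numeric(1)))
  sb <- sum(vapply(codons_b, oracle_sites_codon, numeric(1)))
  S <- (sa + sb) / 2
  N <- 3 * length(codons_a) - S
  dd <- vapply(seq_along(codons_a),
               function(i) oracle_pair_diffs(codons_a[i], codons_b[i]),
               numeric(2))
  Sd <- sum(dd["sd", ])
  Nd <- sum(dd["nd", ])
  jc <- function(p) {
    if (!is.finite(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# Optimal global alignment score under affine gaps (cost open + L * extend)
# by plain three-state dynamic programming, independent of Biostrings.
oracle_affine_score <- function(a, b, submat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  neg <- -1e9
  M <- Ix <- Iy <- matrix(neg, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - i * gap_extend
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Random unrooted binary tree with distinct branch lengths plus its
# additive leaf-to-leaf distance matrix.
oracle_random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n_leaves))
  d <- ape::cophenetic.phylo(tr)
  ord <- order(rownames(d))
  list(tree = tr, d = d[ord, ord])
}
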