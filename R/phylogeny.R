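# Neighbor-joining phylogenies over p-distances, with bootstrap supports
# and sister-pair (cherry) extraction. Trees are ape "phylo" objects.

.as_msa <- function(msa) {
  m <- .as_protein_vector(msa)
  if (length(m) < 2L) stop("an alignment needs at least 2 sequences")
  if (length(unique(nchar(m))) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  toupper(m)
}

#' p-distance matrix from an alignment
#'
#' Proportion of differing sites per sequence pair, computed over the
#' columns where neither sequence has a gap (`-`), i.e. pairwise deletion.
#' A pair with zero comparable columns is an error.
#'
#' @param msa Named character vector of equal-length aligned sequences (or
#'   a data.frame from [read_fasta()]).
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
p_distance_matrix <- function(msa) {
  m <- .as_msa(msa)
  chars <- do.call(rbind, strsplit(m, ""))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(m), names(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", names(m)[i], " and ", names(m)[j])
      }
      d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
    }
  }
  d
}

#' Gamma + invariant-sites distance correction
#'
#' Element-wise transform of raw p-distances under a gamma distribution of
#' site rates (shape `alpha`) with a proportion `p_inv` of invariant sites:
#' `d' = alpha * (1 - p_inv) * ((1 - d/(1 - p_inv))^(-1/alpha) - 1)`.
#' The correction is monotone (`d' >= d`) and approaches the Poisson
#' correction `-(1 - p_inv) * log(1 - d/(1 - p_inv))` as `alpha -> Inf`.
#' Entries with `d >= 1 - p_inv` are undefined and raise an error.
#'
#' @param d Numeric matrix (or scalar) of raw distances in `[0, 1)`.
#' @param alpha Gamma shape (> 0).
#' @param p_inv Invariant-site proportion in `[0, 1)`.
#' @return Corrected matrix of the same shape.
#' @export
correct_distance <- function(d, alpha, p_inv = 0) {
  if (alpha <= 0) stop("alpha must be positive")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (any(d >= 1 - p_inv)) {
    stop("distance(s) >= 1 - p_inv cannot be corrected")
  }
  alpha * (1 - p_inv) * ((1 - d / (1 - p_inv))^(-1 / alpha) - 1)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion. Ties on Q are broken by the
#' lexicographically smallest (i, j) index pair, negative branch lengths
#' are clamped to zero, and the result is the standard unrooted NJ tree
#' represented with a trifurcating root.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 3L) stop("neighbor-joining needs at least 3 taxa")
  labs <- rownames(d)
  quote_lab <- function(x) {
    ifelse(grepl("[^A-Za-z0-9_.-]", x), paste0("'", x, "'"), x)
  }
  frags <- quote_lab(labs)
  D <- unname(d)
  bl <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newfrag <- paste0("(", frags[i], ":", bl(vi), ",", frags[j], ":", bl(vj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frags <- c(frags[keep], newfrag)
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", frags[1], ":", bl(v1), ",", frags[2], ":", bl(v2),
                   ",", frags[3], ":", bl(v3), ");")
  ape::read.tree(text = newick)
}

# canonical bipartition keys of a tree's internal edges: for each internal
# node, the tips on its side, represented by whichever side excludes the
# alphabetically first taxon (so the key is rooting-invariant)
.split_keys <- function(tree) {
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(idx) {
    side <- sort(labs[idx])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    paste(side, collapse = "\r")
  }, character(1))
  names(keys) <- seq_along(keys) + length(tree$tip.label) # node numbers
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times; the support of
#' each internal bipartition of the reference tree is the percentage of
#' replicate trees containing it. Deterministic given `seed`.
#'
#' @inheritParams p_distance_matrix
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param correction Optional list with `alpha` and `p_inv` applied to
#'   every distance matrix via [correct_distance()]; `NULL` for raw
#'   p-distances.
#' @return The reference [ape::phylo] tree with supports (0-100) in
#'   `node.label` (the root label is empty).
#' @export
bootstrap_support <- function(msa, replicates = 1000L, seed = 1L,
                              correction = NULL) {
  m <- .as_msa(msa)
  if (replicates < 1L) stop("replicates must be >= 1")
  L <- nchar(m[1])
  dist_fun <- function(seqs) {
    d <- p_distance_matrix(seqs)
    if (!is.null(correction)) {
      d <- correct_distance(d, correction$alpha, correction$p_inv %||% 0)
    }
    d
  }
  ref <- nj_tree(dist_fun(m))
  ref_keys <- .split_keys(ref)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  rng <- .new_rng(seed)
  cols <- .with_rng(rng, matrix(sample.int(L, L * replicates, replace = TRUE),
                                nrow = replicates))
  chars <- strsplit(m, "")
  for (b in seq_len(replicates)) {
    idx <- cols[b, ]
    boot <- vapply(chars, function(ch) paste(ch[idx], collapse = ""), character(1))
    names(boot) <- names(m)
    bt <- try(nj_tree(dist_fun(boot)), silent = TRUE)
    if (inherits(bt, "try-error")) next
    bk <- .split_keys(bt)
    hit <- ref_keys %in% bk
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / replicates, 1)
  node_labels <- rep("", ref$Nnode)
  node_nums <- as.integer(names(ref_keys))
  root_num <- length(ref$tip.label) + 1L
  for (k in seq_along(ref_keys)) {
    if (node_nums[k] == root_num) next
    node_labels[node_nums[k] - length(ref$tip.label)] <-
      as.character(support[k])
  }
  ref$node.label <- node_labels
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract strongly supported sister pairs
#'
#' Reports every cherry (two-leaf clade) of the tree whose bootstrap
#' support is strictly greater than `min_support`; cherries are disjoint,
#' so each leaf appears in at most one pair.
#'
#' @param tree An [ape::phylo] tree with numeric supports in `node.label`.
#' @param min_support Support threshold (strict `>`), on the 0-100 scale.
#' @return data.frame with columns `taxon_a`, `taxon_b`, `support`.
#' @export
extract_sister_pairs <- function(tree, min_support = 90) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep(NA_character_, tree$Nnode)
  out <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 2L && all(kids <= ntip)) {
      lab <- labs[node - ntip]
      sup <- suppressWarnings(as.numeric(lab))
      if (!is.na(sup) && sup > min_support) {
        tips <- sort(tree$tip.label[kids])
        out[[length(out) + 1L]] <- data.frame(
          taxon_a = tips[1], taxon_b = tips[2], support = sup,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      support = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
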