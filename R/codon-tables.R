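# Codon-level lookup tables for Ka/Ks counting.
#
# Everything here is derived once from the universal genetic code
# (Biostrings::GENETIC_CODE) and cached in the package environment:
#   - the 61 sense codons and their amino acids,
#   - per-codon mutation descriptors (is each single-base change synonymous,
#     a transition, or a nonsense change),
#   - per-codon-pair pathway tables: for every ordering of the differing
#     positions, how many synonymous/nonsynonymous transition/transversion
#     steps it takes, with orderings that pass through a stop codon flagged.

.nucs <- c("A", "C", "G", "T")

.is_transition <- function(from, to) {
  purine <- c("A", "G")
  (from %in% purine) == (to %in% purine)
}

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate a coding sequence
#'
#' Translates an in-frame CDS under the universal genetic code. Codons
#' containing characters outside ACGT translate to `"X"`; stop codons
#' translate to `"*"`.
#'
#' @param cds A single nucleotide string with length divisible by 3.
#' @return Single-character amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length (", nchar(cds), ") is not divisible by 3")
  }
  if (nchar(cds) == 0L) return("")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.codon_split <- function(codon) strsplit(codon, "")[[1]]

# Build (and cache) the master codon tables.
.codon_tables <- function() {
  if (!is.null(.auxevol_cache$codon_tables)) return(.auxevol_cache$codon_tables)
  gc <- .genetic_code()
  all_codons <- names(gc)
  sense <- all_codons[gc != "*"]
  aa_of <- gc

  # mutation descriptor: for each sense codon, position, alternative base:
  # target codon, synonymous flag, transition flag, stop flag
  mut <- vector("list", length(sense))
  names(mut) <- sense
  for (cod in sense) {
    letters3 <- .codon_split(cod)
    rows <- list()
    for (pos in 1:3) {
      for (alt in setdiff(.nucs, letters3[pos])) {
        to <- letters3
        to[pos] <- alt
        to <- paste(to, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, to = to,
          syn = identical(aa_of[[to]], aa_of[[cod]]) && aa_of[[to]] != "*",
          ts = .is_transition(letters3[pos], alt),
          stop = aa_of[[to]] == "*",
          stringsAsFactors = FALSE
        )
      }
    }
    mut[[cod]] <- do.call(rbind, rows)
  }

  .auxevol_cache$codon_tables <- list(
    sense = sense,
    aa_of = aa_of,
    mut = mut
  )
  .auxevol_cache$codon_tables
}

# NG86 synonymous site count per sense codon: per position the fraction of
# non-stop single-base changes that are synonymous (stop changes removed from
# numerator and denominator so S + N = 3 holds exactly per codon).
.ng86_site_table <- function() {
  if (!is.null(.auxevol_cache$ng86_sites)) return(.auxevol_cache$ng86_sites)
  tb <- .codon_tables()
  s <- setNames(numeric(length(tb$sense)), tb$sense)
  for (cod in tb$sense) {
    m <- tb$mut[[cod]]
    tot <- 0
    for (pos in 1:3) {
      mp <- m[m$pos == pos & !m$stop, , drop = FALSE]
      if (nrow(mp) > 0) tot <- tot + sum(mp$syn) / nrow(mp)
    }
    s[cod] <- tot
  }
  .auxevol_cache$ng86_sites <- s
  s
}

# Kappa-weighted synonymous site count per codon (transitions weighted kappa,
# transversions 1; stop changes excluded from both sides of the ratio).
.weighted_site_count <- function(codons, kappa) {
  tb <- .codon_tables()
  vapply(codons, function(cod) {
    m <- tb$mut[[cod]]
    tot <- 0
    for (pos in 1:3) {
      mp <- m[m$pos == pos & !m$stop, , drop = FALSE]
      if (nrow(mp) == 0) next
      w <- ifelse(mp$ts, kappa, 1)
      tot <- tot + sum(w[mp$syn]) / sum(w)
    }
    tot
  }, numeric(1))
}

# Degeneracy class of each codon position: 0-fold (no synonymous change),
# 4-fold (all non-stop changes synonymous), else 2/3-fold. Used for kappa
# estimation from 4-fold and 0-fold sites.
.degeneracy_table <- function() {
  if (!is.null(.auxevol_cache$degeneracy)) return(.auxevol_cache$degeneracy)
  tb <- .codon_tables()
  deg <- matrix(NA_integer_, nrow = length(tb$sense), ncol = 3,
                dimnames = list(tb$sense, NULL))
  for (cod in tb$sense) {
    m <- tb$mut[[cod]]
    for (pos in 1:3) {
      mp <- m[m$pos == pos & !m$stop, , drop = FALSE]
      nsyn <- sum(mp$syn)
      deg[cod, pos] <- if (nsyn == 0) 0L else if (nsyn == nrow(mp) && nrow(mp) == 3) 4L else 2L
    }
  }
  .auxevol_cache$degeneracy <- deg
  deg
}

# Pathway table for one ordered codon pair: a matrix with one row per valid
# ordering of the differing positions and columns syn_ts, syn_tv, nonsyn_ts,
# nonsyn_tv. Orderings through stop codons are dropped; if every ordering is
# blocked the stop-passing orderings are used as a fallback (never happens
# for <=2 differences under the universal code, rare at 3).
.pathways_for_pair <- function(a, b) {
  tb <- .codon_tables()
  aa_of <- tb$aa_of
  la <- .codon_split(a)
  lb <- .codon_split(b)
  diffs <- which(la != lb)
  k <- length(diffs)
  if (k == 0L) {
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("syn_ts", "syn_tv", "nonsyn_ts", "nonsyn_tv"))))
  }
  orderings <- if (k == 1L) list(diffs) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    perms(diffs)
  }
  walk <- function(ord) {
    cur <- la
    counts <- c(syn_ts = 0, syn_tv = 0, nonsyn_ts = 0, nonsyn_tv = 0)
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- lb[pos]
      from_cod <- paste(cur, collapse = "")
      to_cod <- paste(nxt, collapse = "")
      if (aa_of[[to_cod]] == "*") blocked <- TRUE
      syn <- !blocked && identical(aa_of[[from_cod]], aa_of[[to_cod]])
      ts <- .is_transition(cur[pos], lb[pos])
      key <- paste0(if (syn) "syn" else "nonsyn", if (ts) "_ts" else "_tv")
      counts[key] <- counts[key] + 1
      cur <- nxt
    }
    list(counts = counts, blocked = blocked)
  }
  walked <- lapply(orderings, walk)
  ok <- !vapply(walked, `[[`, logical(1), "blocked")
  use <- if (any(ok)) walked[ok] else walked
  do.call(rbind, lapply(use, `[[`, "counts"))
}

# Memoised pathway lookup keyed on "A|B".
.pair_pathways <- function(a, b) {
  if (is.null(.auxevol_cache$pathways)) {
    .auxevol_cache$pathways <- new.env(parent = emptyenv())
  }
  key <- paste(a, b, sep = "|")
  env <- .auxevol_cache$pathways
  if (is.null(env[[key]])) env[[key]] <- .pathways_for_pair(a, b)
  env[[key]]
}

.split_codons <- function(cds) {
  cds <- toupper(cds)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}
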