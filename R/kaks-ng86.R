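#' Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Counts synonymous (S) and nonsynonymous (N) sites by fractional
#' classification of every codon position (changes to stop codons excluded
#' and the per-position fractions renormalized, so `S + N = 3 * codons`
#' exactly), counts synonymous/nonsynonymous differences by equal weighting
#' of all shortest substitution pathways between differing codons (pathways
#' through stop codons dropped and the weights renormalized), and corrects
#' the proportions `ps = Sd/S`, `pn = Nd/N` with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - (4/3) p)`.
#'
#' When `ps` or `pn` reaches 3/4 the corresponding rate is undefined and
#' returned as `NA` (reported, not thrown); `omega` is `NA` whenever
#' `Ks` is 0 or undefined.
#'
#' @param codon_alignment A [codon_alignment] (from [project_to_codons()] or
#'   built directly with [codon_alignment()]).
#' @return A one-row data.frame with columns `Ka`, `Ks`, `omega`, `S`, `N`,
#'   `Sd`, `Nd`, `method` (`"NG86"`) and `kappa` (`NA` for NG86).
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
estimate_kaks_ng86 <- function(codon_alignment) {
  ca <- as_codon_alignment(codon_alignment)
  if (length(ca$codon_a) < 1L) stop("codon alignment is empty")
  site_tab <- .ng86_site_table()
  s_a <- sum(site_tab[ca$codon_a])
  s_b <- sum(site_tab[ca$codon_b])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca$codon_a) - S

  Sd <- 0
  Nd <- 0
  diff_idx <- which(ca$codon_a != ca$codon_b)
  for (i in diff_idx) {
    pw <- .pair_pathways(ca$codon_a[i], ca$codon_b[i])
    Sd <- Sd + mean(pw[, "syn_ts"] + pw[, "syn_tv"])
    Nd <- Nd + mean(pw[, "nonsyn_ts"] + pw[, "nonsyn_tv"])
  }

  ps <- Sd / S
  pn <- Nd / N
  # p is NaN when the site class is empty (S = 0 or N = 0): rate undefined
  jc <- function(p) {
    # "+ 0" normalizes the negative zero that -log(1) produces
    if (!is.finite(p) || p >= 3 / 4) NA_real_ else -0.75 * log(1 - 4 * p / 3) + 0
  }
  Ks <- jc(ps)
  Ka <- jc(pn)
  omega <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  data.frame(Ka = Ka, Ks = Ks, omega = omega, S = S, N = N, Sd = Sd, Nd = Nd,
             method = "NG86", kappa = NA_real_, stringsAsFactors = FALSE)
}

#' Build a codon alignment from two in-frame coding sequences
#'
#' Pairs codons positionally (the sequences must already be gap-free and of
#' equal length); codon pairs containing stop codons or ambiguous bases are
#' dropped.
#'
#' @param cds_a,cds_b Equal-length nucleotide strings, length divisible by 3.
#' @return An object of class `codon_alignment`: a list with character
#'   vectors `codon_a`, `codon_b` (sense codons only) and the count of
#'   `dropped` codon columns.
#' @export
codon_alignment <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("coding sequences differ in length")
  a <- .split_codons(cds_a)
  b <- .split_codons(cds_b)
  keep <- .usable_codon(a) & .usable_codon(b)
  structure(list(codon_a = a[keep], codon_b = b[keep],
                 dropped = sum(!keep)),
            class = "codon_alignment")
}

.usable_codon <- function(codons) {
  tb <- .codon_tables()
  codons %in% tb$sense
}

as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  stop("expected a codon_alignment object")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$codon_a), "codon pairs,",
      x$dropped, "columns dropped\n")
  invisible(x)
}

#' Ka/Ks ratio for reporting
#'
#' The selection ratio omega = Ka / Ks, rounded to 4 decimals as reported in
#' family-evolution tables. `Ks = 0` (or a missing rate) yields `NA`.
#'
#' @param Ka,Ks Nonsynonymous and synonymous substitution rates per site.
#' @return Numeric ratio rounded to 4 decimals, or `NA_real_`.
#' @export
omega_ratio <- function(Ka, Ks) {
  out <- ifelse(is.na(Ka) | is.na(Ks) | Ks <= 0, NA_real_, round(Ka / Ks, 4))
  out
}
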