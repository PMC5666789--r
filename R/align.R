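#' Global protein alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch global alignment of two protein sequences under
#' an affine gap model (a gap of length L costs
#' `gap_open + L * gap_extend`). Scoring uses a standard residue
#' substitution matrix; the packaged default is BLOSUM62 with the gap
#' penalties commonly used for family-wide protein alignments
#' (opening 10, extension 0.1).
#'
#' @param a,b Non-empty protein strings (20-letter alphabet plus X).
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"PAM250"`), or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of class `protein_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length strings over residues and `-`) and `score`.
#' @export
align_proteins_global <- function(a, b, matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.1) {
  for (s in c(a, b)) {
    if (!nzchar(s)) stop("cannot align an empty sequence")
    bad <- setdiff(strsplit(toupper(s), "")[[1]],
                   c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]))
    if (length(bad) > 0) {
      stop("non-residue characters in input sequence: ",
           paste(bad, collapse = ", "))
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  structure(list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  ), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("global protein alignment (score ", format(x$score), ")\n",
      x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of two proteins
#'
#' Globally aligns the two sequences and reports the percentage of identical
#' residues over the aligned columns in which neither sequence has a gap.
#'
#' @inheritParams align_proteins_global
#' @return Percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.1) {
  aln <- align_proteins_global(a, b, matrix = matrix,
                               gap_open = gap_open, gap_extend = gap_extend)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(0)
  100 * sum(ca[keep] == cb[keep]) / sum(keep)
}

#' Project a protein alignment onto codons
#'
#' Back-translates a pairwise protein alignment to codon level. Each CDS
#' must be the exact in-frame coding sequence of its protein (length 3x the
#' ungapped protein length, and translating to it; `X` in the protein
#' matches any codon). Columns with a gap in either row, a stop codon, or
#' ambiguous bases are dropped and counted.
#'
#' @param alignment A `protein_alignment` from [align_proteins_global()].
#' @param cds_a,cds_b Spliced coding sequences matching the two proteins.
#' @return A [codon_alignment].
#' @export
project_to_codons <- function(alignment, cds_a, cds_b) {
  if (!inherits(alignment, "protein_alignment")) {
    stop("expected a protein_alignment object")
  }
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  check_one <- function(al, cds, who) {
    prot <- paste(al[al != "-"], collapse = "")
    if (nchar(cds) != 3 * nchar(prot)) {
      stop("CDS length for sequence ", who, " (", nchar(cds),
           ") is not 3x its protein length (", nchar(prot), ")")
    }
    tr <- strsplit(translate_cds(cds), "")[[1]]
    pr <- strsplit(prot, "")[[1]]
    bad <- which(tr != pr & tr != "X" & pr != "X")
    if (length(bad) > 0) {
      stop("CDS for sequence ", who, " does not translate to its protein",
           " (first mismatch at residue ", bad[1], ")")
    }
  }
  check_one(ca, cds_a, "a")
  check_one(cb, cds_b, "b")

  cods_a <- .split_codons(cds_a)
  cods_b <- .split_codons(cds_b)
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  ungapped <- ca != "-" & cb != "-"
  pair_a <- cods_a[ia[ungapped]]
  pair_b <- cods_b[ib[ungapped]]
  keep <- .usable_codon(pair_a) & .usable_codon(pair_b)
  dropped <- sum(!ungapped) + sum(!keep)
  if (any(!keep)) {
    warning(sum(!keep), " codon column(s) dropped (stop codon or ambiguous base)")
  }
  structure(list(codon_a = pair_a[keep], codon_b = pair_b[keep],
                 dropped = dropped),
            class = "codon_alignment")
}
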