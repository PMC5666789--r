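#' Packaged transcriptions of the published family tables
#'
#' Loads the three tables shipped with the package, transcribed verbatim
#' from the published survey of the Aux/IAA family across 17 plant genomes:
#'
#' * `table1`: per-species predicted gene loci and Aux/IAA gene counts
#'   (17 rows). Note that the printed per-species counts sum to 435 while
#'   the publication's stated family total is 434; the table is stored as
#'   printed and downstream percentage claims use the stated total.
#' * `table2`: Ka, Ks, Ka/Ks and duplication type for ten selected paralog
#'   pairs in four species.
#' * `table3`: per-species intact/degenerated/lack counts for the three
#'   nuclear localization signal categories (bipartite Part 1 "KR",
#'   bipartite Part 2 "RxxRK", SV40-like "KRxRxxK"; 16 species rows).
#'
#' @return A list with data.frames `table1`, `table2`, `table3`.
#' @export
load_fixture_tables <- function() {
  read_one <- function(name) {
    path <- system.file("extdata", name, package = "auxevol", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  tabs <- list(
    table1 = read_one("table1_family_counts.tsv"),
    table2 = read_one("table2_kaks_pairs.tsv"),
    table3 = read_one("table3_nls_counts.tsv")
  )
  stopifnot(nrow(tabs$table1) == 17L, nrow(tabs$table2) == 10L,
            nrow(tabs$table3) == 16L)
  count_cols <- names(tabs$table3)[-1]
  stopifnot(all(as.matrix(tabs$table3[count_cols]) >= 0))
  tabs
}

#' Packaged consensus patterns for the five conserved family motifs
#'
#' The five motifs map onto the four conserved Aux/IAA domains: motif 5
#' (`LxLxLx`, domain I repression motif), motif 3 (`VGWPPV`, the domain II
#' degron), motif 2 (`VKVxM`, domain III), and motifs 4 (`KRxRxxK`, the
#' SV40-type NLS) and 1 (`GDVPW`) forming domain IV. `x` is a wildcard.
#'
#' @return A data.frame with columns `motif_id` (`m1`..`m5`) and `pattern`.
#' @export
load_consensus_motifs <- function() {
  path <- system.file("extdata", "consensus_motifs.tsv",
                      package = "auxevol", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
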