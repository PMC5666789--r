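# Nuclear localization signal scanning.
#
# Aux/IAA proteins carry two putative NLSs: a bipartite signal whose first
# basic cluster ("KR") sits between domains I and II and whose second
# ("RxxRK") sits in domain II, and an SV40-like signal ("KRxRxxK") in
# domain IV. Each category is called intact, degenerated (exactly one
# basic-position substitution) or lack.

#' Canonical NLS patterns
#'
#' @return Named list over categories `bipartite_part1`, `bipartite_part2`,
#'   `sv40`; each element has `category`, `pattern` (with `x` wildcards)
#'   and `basic_positions` (indices of the K/R letters).
#' @export
nls_patterns <- function() {
  list(
    bipartite_part1 = list(category = "bipartite_part1", pattern = "KR",
                           basic_positions = c(1L, 2L)),
    bipartite_part2 = list(category = "bipartite_part2", pattern = "RxxRK",
                           basic_positions = c(1L, 4L, 5L)),
    sv40 = list(category = "sv40", pattern = "KRxRxxK",
                basic_positions = c(1L, 2L, 4L, 7L))
  )
}

#' Locate NLS search windows from motif anchors
#'
#' Bipartite Part 1 is searched between the domain-I (motif 5) and
#' domain-II (motif 3) anchors; Part 2 around the motif-3 hit (plus/minus
#' 10 residues); the SV40-like signal around the motif-4 hit (plus/minus 10
#' residues). When an anchoring motif is absent the window falls back to
#' the N-terminal, middle or C-terminal third of the protein, respectively.
#' Windows may be empty.
#'
#' @param protein Protein string.
#' @param profile `motif_profile` from [call_presence()] (may have all
#'   motifs absent).
#' @param flank Residues added on each side of an anchoring hit.
#' @return Named list over the three categories; each element has `start`,
#'   `end` (1-based, `start > end` for an empty window) and `window`.
#' @export
locate_search_windows <- function(protein, profile, flank = 10L) {
  protein <- toupper(protein)
  L <- nchar(protein)
  third <- function(k) {
    lo <- floor((k - 1) * L / 3) + 1L
    hi <- floor(k * L / 3)
    c(lo, hi)
  }
  hit_range <- function(m) {
    h <- profile$hits[[m]]
    if (is.null(h)) NULL else c(h$start, h$start + nchar(h$matched) - 1L)
  }
  m5 <- hit_range("m5"); m3 <- hit_range("m3"); m4 <- hit_range("m4")
  p1 <- if (!is.null(m5) && !is.null(m3)) c(m5[2] + 1L, m3[1] - 1L) else third(1)
  p2 <- if (!is.null(m3)) c(m3[1] - flank, m3[2] + flank) else third(2)
  sv <- if (!is.null(m4)) c(m4[1] - flank, m4[2] + flank) else third(3)
  clamp <- function(r) c(max(r[1], 1L), min(r[2], L))
  mk <- function(r) {
    r <- clamp(r)
    list(start = r[1], end = r[2],
         window = if (r[1] > r[2]) "" else substring(protein, r[1], r[2]))
  }
  list(bipartite_part1 = mk(p1), bipartite_part2 = mk(p2), sv40 = mk(sv))
}

#' Match an NLS pattern against a window
#'
#' A placement is *intact* when every non-wildcard position matches
#' exactly, *degenerated* when exactly one basic position is substituted
#' and every other non-wildcard position matches; otherwise the signal is
#' *lack*. Intact placements take precedence over degenerated ones; among
#' equals the leftmost placement wins.
#'
#' @param window Subsequence to search (possibly empty).
#' @param pattern One element of [nls_patterns()].
#' @param window_offset 1-based position of the window's first residue in
#'   the full protein (so reported `window_start` is protein-relative).
#' @param sequence_id Optional id.
#' @return One-row data.frame: `sequence_id`, `category`, `status`,
#'   `window_start` (NA when lack), `matched` (NA when lack).
#' @export
match_nls <- function(window, pattern, window_offset = 1L,
                      sequence_id = NA_character_) {
  window <- toupper(window)
  pat <- strsplit(pattern$pattern, "")[[1]]
  w <- length(pat)
  fixed <- which(pat != "x")
  res <- function(status, start = NA_integer_, matched = NA_character_) {
    data.frame(sequence_id = sequence_id, category = pattern$category,
               status = status, window_start = start, matched = matched,
               stringsAsFactors = FALSE)
  }
  L <- nchar(window)
  if (L < w) return(res("lack"))
  chars <- strsplit(window, "")[[1]]
  starts <- seq_len(L - w + 1L)
  mism <- lapply(starts, function(s) fixed[chars[s + fixed - 1L] != pat[fixed]])
  n_mism <- lengths(mism)
  exact <- which(n_mism == 0L)
  if (length(exact) > 0L) {
    s <- starts[exact[1]]
    return(res("intact", window_offset + s - 1L, substring(window, s, s + w - 1L)))
  }
  degen <- which(n_mism == 1L &
                   vapply(mism, function(m) length(m) == 1L &&
                            m %in% pattern$basic_positions, logical(1)))
  if (length(degen) > 0L) {
    s <- starts[degen[1]]
    return(res("degenerated", window_offset + s - 1L,
               substring(window, s, s + w - 1L)))
  }
  res("lack")
}

#' Tag primordial bipartite Part-2 variants
#'
#' Lower plants carry characteristic substituted forms of the `RxxRK`
#' cluster: `QxxRK` (moss) and `KxxNK` (lycophyte). Windows containing an
#' exact occurrence of either form are tagged as primordial variants on
#' top of their degenerated status.
#'
#' @param window Part-2 search window.
#' @param species Optional species label carried through to the output.
#' @return One-row data.frame: `species`, `variant_tag` (`"QxxRK"`,
#'   `"KxxNK"` or `NA`).
#' @export
detect_species_variants <- function(window, species = NA_character_) {
  window <- toupper(window)
  has_form <- function(form) {
    pat <- strsplit(form, "")[[1]]
    fixed <- which(pat != "x")
    L <- nchar(window)
    if (L < length(pat)) return(FALSE)
    chars <- strsplit(window, "")[[1]]
    any(vapply(seq_len(L - length(pat) + 1L), function(s) {
      all(chars[s + fixed - 1L] == pat[fixed])
    }, logical(1)))
  }
  tag <- if (has_form("QxxRK")) "QxxRK"
  else if (has_form("KxxNK")) "KxxNK"
  else NA_character_
  data.frame(species = species, variant_tag = tag, stringsAsFactors = FALSE)
}

#' Full NLS report for one protein
#'
#' Locates the three search windows from the protein's motif profile and
#' classifies each NLS category; Part-2 windows are additionally screened
#' for the primordial lower-plant variants.
#'
#' @param protein Protein string.
#' @param models Motif models for anchoring (defaults to the packaged
#'   consensus patterns).
#' @param sequence_id Optional id.
#' @param species Optional species label (recorded in the variant tag).
#' @return data.frame with one row per category: `sequence_id`, `category`,
#'   `status`, `window_start`, `matched`, `variant_tag`.
#' @export
scan_nls <- function(protein, models = consensus_models(),
                     sequence_id = NA_character_, species = NA_character_) {
  profile <- call_presence(protein, models, sequence_id = sequence_id)
  windows <- locate_search_windows(protein, profile)
  pats <- nls_patterns()
  rows <- lapply(names(pats), function(cat) {
    w <- windows[[cat]]
    call <- match_nls(w$window, pats[[cat]], window_offset = w$start,
                      sequence_id = sequence_id)
    call$variant_tag <- if (cat == "bipartite_part2") {
      detect_species_variants(w$window, species)$variant_tag
    } else NA_character_
    call
  })
  do.call(rbind, rows)
}

#' Aggregate NLS calls by species
#'
#' @param reports data.frame of stacked [scan_nls()] rows.
#' @param species_of Named character vector mapping every `sequence_id` to
#'   a species; an unmapped sequence is an error.
#' @return List with `summary` (per species x category counts of
#'   intact/degenerated/lack; the three statuses sum to the number of
#'   proteins scanned per species) and `overall` (per category, percentage
#'   of proteins in each status).
#' @export
aggregate_species <- function(reports, species_of) {
  ids <- unique(reports$sequence_id)
  missing <- ids[!ids %in% names(species_of)]
  if (length(missing) > 0L) {
    stop("sequence(s) not mapped to a species: ", paste(missing, collapse = ", "))
  }
  reports$species <- unname(species_of[reports$sequence_id])
  statuses <- c("intact", "degenerated", "lack")
  combos <- expand.grid(species = unique(reports$species),
                        category = unique(reports$category),
                        stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- reports[reports$species == combos$species[i] &
                     reports$category == combos$category[i], ]
    counts <- table(factor(sub$status, levels = statuses))
    data.frame(species = combos$species[i], category = combos$category[i],
               intact = as.integer(counts["intact"]),
               degenerated = as.integer(counts["degenerated"]),
               lack = as.integer(counts["lack"]),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  stopifnot(all(summary$intact + summary$degenerated + summary$lack == summary$n))
  n_total <- length(ids)
  overall <- do.call(rbind, lapply(unique(reports$category), function(cat) {
    sub <- reports[reports$category == cat, ]
    counts <- table(factor(sub$status, levels = statuses))
    data.frame(category = cat,
               pct_intact = 100 * counts[["intact"]] / n_total,
               pct_degenerated = 100 * counts[["degenerated"]] / n_total,
               pct_lack = 100 * counts[["lack"]] / n_total,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, overall = overall)
}
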