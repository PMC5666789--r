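# Duplication-mode calling.
#
# Tandem pairs: same chromosome, nearest-boundary distance <= 50 kb and
# protein identity above 50% (both thresholds configurable). Segmental
# pairs: anchor pairs of a collinearity block. A pair satisfying both rules
# is classified "both"; pairs examined but matching neither are "unlinked".

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# nearest-boundary distance between two gene intervals (0 when overlapping)
.gene_distance <- function(s1, e1, s2, e2) {
  if (e1 < s2) s2 - e1 else if (e2 < s1) s1 - e2 else 0L
}

#' Find tandem-duplicated gene pairs
#'
#' Reports every unordered gene pair on the same chromosome whose
#' nearest-boundary distance is at most `max_distance` and whose global
#' protein identity exceeds `identity_min`.
#'
#' @param gene_models data.frame from [read_gff3()] (or with the same
#'   columns `gene_id`, `chromosome`, `start`, `end`).
#' @param proteins Named character vector of protein sequences, or a
#'   data.frame from [read_fasta()]; every gene id must have a sequence.
#' @param identity_min Identity threshold in percent (strict `>`).
#' @param max_distance Distance cap in bp (inclusive).
#' @return data.frame with columns `gene_a`, `gene_b`, `identity_pct`,
#'   `distance_bp`, `classification` (`"tandem"`).
#' @export
find_tandem_pairs <- function(gene_models, proteins, identity_min = 50,
                              max_distance = 50000) {
  prots <- .as_protein_vector(proteins)
  missing <- setdiff(gene_models$gene_id, names(prots))
  if (length(missing) > 0L) {
    stop("gene(s) without a protein sequence: ", paste(missing, collapse = ", "))
  }
  out <- list()
  gm <- gene_models[order(gene_models$chromosome, gene_models$start), ]
  for (chrom in unique(gm$chromosome)) {
    sub <- gm[gm$chromosome == chrom, ]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        d <- .gene_distance(sub$start[i], sub$end[i], sub$start[j], sub$end[j])
        if (d > max_distance) next
        ident <- pairwise_identity(prots[[sub$gene_id[i]]],
                                   prots[[sub$gene_id[j]]])
        if (ident > identity_min) {
          out[[length(out) + 1L]] <- data.frame(
            gene_a = sub$gene_id[i], gene_b = sub$gene_id[j],
            identity_pct = ident, distance_bp = d,
            classification = "tandem", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity_pct = numeric(), distance_bp = integer(),
                      classification = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[!duplicated(.pair_key(res$gene_a, res$gene_b)), , drop = FALSE]
}

#' Overlay segmental (collinearity-anchored) classification
#'
#' Merges tandem calls with block anchor pairs: a pair appearing as an
#' anchor pair in any collinearity block is segmental; a pair that is also
#' a tandem call becomes `"both"`. Pairs present in `pairs_universe` but in
#' neither class are `"unlinked"`.
#'
#' @param pairs_universe data.frame of candidate pairs (columns `gene_a`,
#'   `gene_b`, optionally `identity_pct`, `distance_bp`, `classification`),
#'   e.g. the output of [find_tandem_pairs()] possibly extended with other
#'   pairs of interest.
#' @param blocks data.frame from [read_collinearity_blocks()].
#' @return data.frame of classified pairs (`tandem`, `segmental`, `both`
#'   or `unlinked`); anchor pairs absent from `pairs_universe` are added.
#' @export
assign_segmental <- function(pairs_universe, blocks) {
  if (is.null(pairs_universe) || nrow(pairs_universe) == 0L) {
    pairs_universe <- data.frame(gene_a = character(), gene_b = character(),
                                 identity_pct = numeric(),
                                 distance_bp = integer(),
                                 classification = character(),
                                 stringsAsFactors = FALSE)
  }
  for (col in c("identity_pct", "distance_bp", "classification")) {
    if (!col %in% names(pairs_universe)) pairs_universe[[col]] <- NA
  }
  anchor_keys <- if (nrow(blocks) > 0L) {
    unique(.pair_key(blocks$gene_a, blocks$gene_b))
  } else character()
  keys <- .pair_key(pairs_universe$gene_a, pairs_universe$gene_b)
  is_tandem <- !is.na(pairs_universe$classification) &
    pairs_universe$classification == "tandem"
  is_anchor <- keys %in% anchor_keys
  pairs_universe$classification <- ifelse(
    is_tandem & is_anchor, "both",
    ifelse(is_anchor, "segmental",
           ifelse(is_tandem, "tandem", "unlinked")))
  # anchor pairs not in the universe yet
  new_keys <- setdiff(anchor_keys, keys)
  if (length(new_keys) > 0L) {
    parts <- strsplit(new_keys, "\r", fixed = TRUE)
    extra <- data.frame(gene_a = vapply(parts, `[[`, character(1), 1L),
                        gene_b = vapply(parts, `[[`, character(1), 2L),
                        identity_pct = NA_real_, distance_bp = NA_integer_,
                        classification = "segmental", stringsAsFactors = FALSE)
    pairs_universe <- rbind(pairs_universe[names(extra)], extra)
  }
  rownames(pairs_universe) <- NULL
  pairs_universe
}

#' Per-species duplication summary
#'
#' A gene counts toward the segmental (tandem) class when it participates
#' in at least one segmental-or-both (tandem-or-both) pair; `seg_and_tan`
#' counts genes participating in both classes. Percentages use the species'
#' total gene count as denominator, reported to two decimals.
#'
#' @param classified_pairs data.frame from [assign_segmental()].
#' @param gene_universe Character vector of all gene ids under study.
#' @param species_of Named character vector mapping gene ids to species.
#' @return data.frame with one row per species: counts and percentages for
#'   `seg`, `tan`, `seg_and_tan` over `total`.
#' @export
duplication_summary <- function(classified_pairs, gene_universe, species_of) {
  missing <- setdiff(gene_universe, names(species_of))
  if (length(missing) > 0L) {
    stop("gene(s) not mapped to a species: ", paste(missing, collapse = ", "))
  }
  seg_pairs <- classified_pairs[classified_pairs$classification %in%
                                  c("segmental", "both"), ]
  tan_pairs <- classified_pairs[classified_pairs$classification %in%
                                  c("tandem", "both"), ]
  seg_genes <- unique(c(seg_pairs$gene_a, seg_pairs$gene_b))
  tan_genes <- unique(c(tan_pairs$gene_a, tan_pairs$gene_b))
  species <- unique(unname(species_of[gene_universe]))
  out <- do.call(rbind, lapply(species, function(sp) {
    genes <- gene_universe[species_of[gene_universe] == sp]
    n_seg <- sum(genes %in% seg_genes)
    n_tan <- sum(genes %in% tan_genes)
    n_both <- sum(genes %in% seg_genes & genes %in% tan_genes)
    total <- length(genes)
    data.frame(species = sp, seg = n_seg, tan = n_tan, seg_and_tan = n_both,
               total = total,
               seg_pct = round(100 * n_seg / total, 2),
               tan_pct = round(100 * n_tan / total, 2),
               seg_and_tan_pct = round(100 * n_both / total, 2),
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(out$seg_and_tan <= pmin(out$seg, out$tan)))
  out
}
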