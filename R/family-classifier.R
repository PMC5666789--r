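#' Assign a motif-composition type
#'
#' Maps a five-motif presence profile onto the eleven family types. With
#' motifs 5, 3, 2 standing for domains I, II, III and motifs 1 + 4 jointly
#' forming domain IV, the decision table is:
#'
#' * type I (canonical): all five motifs;
#' * type II: all but motif 4; type III: lacking motifs 1 and 4;
#' * type IV: motifs 2 and 5 plus exactly one of motifs 1/4 (motif 3
#'   absent) - domain I, domain III and an incomplete domain IV;
#' * type V: all but motif 5; type VI: motifs 1, 2, 3 only;
#' * type VII: motifs 1, 2, 4 only (lacking domains I and II);
#' * type VIII: motifs 1 and 2 only; type IX: motif 2 only;
#' * type X: motif 1 only; everything else: `other`.
#'
#' The mapping is total over all 32 presence subsets.
#'
#' @param profile A `motif_profile` from [call_presence()], or a named
#'   logical vector over `m1`..`m5`.
#' @return data.frame with columns `sequence_id`, `type_label`, `canonical`.
#' @export
classify_type <- function(profile) {
  if (inherits(profile, "motif_profile")) {
    present <- profile$present
    id <- profile$sequence_id
  } else {
    present <- profile
    id <- NA_character_
  }
  if (!all(paste0("m", 1:5) %in% names(present))) {
    stop("profile must cover all five motifs m1..m5")
  }
  p <- as.logical(present[paste0("m", 1:5)])
  set <- which(p) # indices of present motifs
  eq <- function(v) setequal(set, v)
  label <-
    if (eq(1:5)) "I"
    else if (eq(c(1, 2, 3, 5))) "II"
    else if (eq(c(2, 3, 5))) "III"
    else if (eq(c(1, 2, 5)) || eq(c(2, 4, 5))) "IV"
    else if (eq(1:4)) "V"
    else if (eq(1:3)) "VI"
    else if (eq(c(1, 2, 4))) "VII"
    else if (eq(1:2)) "VIII"
    else if (eq(2)) "IX"
    else if (eq(1)) "X"
    else "other"
  data.frame(sequence_id = id, type_label = label,
             canonical = label == "I", stringsAsFactors = FALSE)
}

#' PB1 interaction-surface signature
#'
#' Within the shared PB1 (domains III/IV) region, Aux/IAA proteins carry a
#' `GDVP` motif between strand beta-3 and helix alpha-2 where ARF proteins
#' carry `GDDP`; the extra acidic residue marks candidate ARF-derived
#' truncations. The call is by simple substring presence; if both occur the
#' first occurrence along the sequence wins.
#'
#' @param protein Protein string.
#' @param sequence_id Optional id.
#' @return data.frame with columns `sequence_id`, `signature`
#'   (`"GDVP"`, `"GDDP"` or `"neither"`).
#' @export
classify_pb1_signature <- function(protein, sequence_id = NA_character_) {
  protein <- toupper(protein)
  pos_v <- regexpr("GDVP", protein, fixed = TRUE)
  pos_d <- regexpr("GDDP", protein, fixed = TRUE)
  signature <- if (pos_v < 0 && pos_d < 0) "neither"
  else if (pos_d < 0 || (pos_v > 0 && pos_v < pos_d)) "GDVP"
  else "GDDP"
  data.frame(sequence_id = sequence_id, signature = signature,
             stringsAsFactors = FALSE)
}

#' Tabulate type assignments
#'
#' @param assignments data.frame of [classify_type()] rows (>= 1).
#' @return data.frame with columns `type_label`, `count`, `percent`
#'   (one decimal place); counts sum to the number of assignments.
#' @export
summarize_types <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    stop("cannot summarize an empty set of assignments")
  }
  levs <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X", "other")
  counts <- table(factor(assignments$type_label, levels = levs))
  out <- data.frame(type_label = levs, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$count / nrow(assignments), 1)
  out
}
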