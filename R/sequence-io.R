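#' Read a FASTA file of protein or coding sequences
#'
#' Wraps the Biostrings FASTA reader and applies the package's record
#' contract: record ids (the first whitespace-delimited token of each
#' header) must be unique, residues are upper-cased, and protein records
#' must use the 20-letter alphabet plus `X`. Non-ACGT characters in coding
#' sequences are tolerated on read; any codon containing them is unusable
#' downstream.
#'
#' @param path Path to a FASTA file.
#' @param molecule `"protein"`, `"cds"`, or `"auto"` (detect from content:
#'   records made only of A/C/G/T/N/U are treated as nucleotide).
#' @return A data.frame with columns `id`, `molecule`, `residues`, one row
#'   per record in file order.
#' @export
read_fasta <- function(path, molecule = c("auto", "protein", "cds")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  residues <- toupper(as.character(set))
  mol <- if (molecule == "auto") {
    ifelse(!grepl("[^ACGTNU]", residues), "cds", "protein")
  } else rep(molecule, length(ids))
  for (i in seq_along(ids)) {
    if (mol[i] == "protein") {
      bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", residues[i])
      if (nzchar(bad)) {
        stop("illegal protein character(s) '", bad, "' in record ", ids[i])
      }
    } else {
      if (grepl("[^A-Z]", residues[i])) {
        stop("illegal character in CDS record ", ids[i])
      }
      if (nchar(residues[i]) == 0L) stop("empty CDS record ", ids[i])
    }
  }
  data.frame(id = ids, molecule = mol, residues = residues,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame with columns `id` and `residues` (as returned
#'   by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for the sequence body.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$residues[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `CDS` features from a GFF3 file (1-based, inclusive
#' coordinates). CDS features are linked to genes through their `Parent`
#' attribute, either directly or via one intermediate feature (mRNA).
#' Genes without CDS children are kept with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` and a list-column `cds_ids`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  genes <- list()
  parent_of <- character()   # feature id -> parent id (for mRNA chaining)
  cds_parent <- list()       # parent id -> cds ids
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 9L) {
      stop("malformed GFF3 line ", line_no[i], ": expected 9 columns, got ",
           length(f))
    }
    type <- f[3]
    if (!type %in% c("gene", "CDS", "mRNA")) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      stop("invalid coordinates on GFF3 line ", line_no[i])
    }
    if (!f[7] %in% c("+", "-")) {
      stop("unknown strand '", f[7], "' on GFF3 line ", line_no[i])
    }
    id <- attr_val(f[9], "ID")
    parent <- attr_val(f[9], "Parent")
    if (type == "gene") {
      if (is.na(id)) stop("gene without ID attribute on GFF3 line ", line_no[i])
      genes[[id]] <- data.frame(gene_id = id, chromosome = f[1],
                                start = start, end = end, strand = f[7],
                                stringsAsFactors = FALSE)
    } else if (type == "mRNA") {
      if (!is.na(id) && !is.na(parent)) parent_of[[id]] <- parent
    } else { # CDS
      if (is.na(parent)) stop("CDS without Parent attribute on GFF3 line ", line_no[i])
      cid <- if (is.na(id)) paste0("cds_line", line_no[i]) else id
      cds_parent[[parent]] <- c(cds_parent[[parent]], cid)
    }
  }
  if (length(genes) == 0L) stop("no gene features found in ", path)
  out <- do.call(rbind, genes)
  out$cds_ids <- lapply(out$gene_id, function(g) {
    direct <- cds_parent[[g]]
    via_mrna <- unlist(cds_parent[names(parent_of)[parent_of == g]],
                       use.names = FALSE)
    unique(c(direct, via_mrna))
  })
  empty <- lengths(out$cds_ids) == 0L
  if (any(empty)) {
    warning("gene(s) without CDS children: ",
            paste(out$gene_id[empty], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Read segmental-duplication collinearity blocks
#'
#' Reads a tab-separated anchor-pair list (`block_id`, `gene_a`, `gene_b`,
#' no header). Pairs are grouped by block in input order; self-pairs are
#' rejected.
#'
#' @param path Path to the tab-separated file.
#' @return A data.frame with columns `block_id`, `gene_a`, `gene_b` (empty
#'   if the file has no rows).
#' @export
read_collinearity_blocks <- function(path) {
  if (!file.exists(path)) stop("collinearity file not found: ", path)
  empty <- data.frame(block_id = character(), gene_a = character(),
                      gene_b = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  tab <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("collinearity file must have 3 tab-separated columns")
  tab <- tab[, 1:3]
  names(tab) <- c("block_id", "gene_a", "gene_b")
  self <- tab$gene_a == tab$gene_b
  if (any(self)) {
    stop("self-pair in collinearity block ", tab$block_id[self][1], ": ",
         tab$gene_a[self][1])
  }
  tab$block_id <- as.character(tab$block_id)
  tab[order(match(tab$block_id, unique(tab$block_id))), , drop = FALSE]
}
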