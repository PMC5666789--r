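# Synthetic gene families with known ground truth.
#
# Three generators: a continuous-time codon-substitution simulator
# (MG94 x HKY style: transition/transversion bias kappa, selection omega,
# proposals creating stops rejected), a protein scaffold planter that lays
# the five family motifs in domain order with chosen NLS statuses, and a
# family simulator producing coordinates, tandem/segmental duplications,
# collinearity blocks and a truth log.

# letters that occur in no consensus motif and are not K/R: linkers drawn
# from this alphabet cannot create accidental motif or NLS matches
.STERILE_AA <- strsplit("ACEFHINQSTY", "")[[1]]

#' Evolve a coding sequence under an MG94 x HKY codon process
#'
#' Continuous-time Gillespie simulation over single-nucleotide codon
#' changes: transitions are weighted `kappa`, nonsynonymous changes
#' `omega`, and changes creating stop codons are rejected. Time is scaled
#' so that the expected number of synonymous substitutions per synonymous
#' site (kappa-weighted site count of the starting sequence) equals `t`.
#'
#' @param cds Stop-free in-frame coding sequence (length divisible by 3,
#'   A/C/G/T only).
#' @param t Branch length in expected synonymous substitutions per
#'   synonymous site (>= 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return The mutated CDS string, with attributes `n_events`,
#'   `n_syn_events`, `n_nonsyn_events` and `syn_sites` (the kappa-weighted
#'   synonymous site count of the ancestor).
#' @export
evolve_codon_sequence <- function(cds, t, omega, kappa, seed) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS must contain only A/C/G/T")
  if (t < 0) stop("t must be >= 0")
  if (omega < 0 || kappa <= 0) stop("invalid omega/kappa")
  cods <- .split_codons(cds)
  tb <- .codon_tables()
  if (!all(cods %in% tb$sense)) stop("CDS contains a stop codon")

  # per-codon mutation rates at the given kappa/omega (stops excluded)
  rate_tab <- lapply(tb$sense, function(cod) {
    m <- tb$mut[[cod]]
    m <- m[!m$stop, , drop = FALSE]
    w <- ifelse(m$ts, kappa, 1) * ifelse(m$syn, 1, omega)
    list(to = m$to, syn = m$syn, rate = w, total = sum(w),
         syn_total = sum(w[m$syn]))
  })
  names(rate_tab) <- tb$sense

  syn_sites <- sum(.weighted_site_count(cods, kappa))
  syn_flux <- sum(vapply(cods, function(c) rate_tab[[c]]$syn_total, numeric(1)))
  out_attrs <- c(n_events = 0L, n_syn_events = 0L, n_nonsyn_events = 0L)
  if (t == 0 || syn_flux == 0) {
    res <- cds
    attributes(res) <- c(as.list(out_attrs), list(syn_sites = syn_sites))
    return(res)
  }
  mu <- syn_sites / syn_flux  # unit time = 1 expected syn sub per syn site

  rng <- .new_rng(seed)
  sim <- .with_rng(rng, {
    codon_rate <- vapply(cods, function(c) rate_tab[[c]]$total, numeric(1)) * mu
    time <- 0
    n_ev <- n_syn <- 0L
    repeat {
      total <- sum(codon_rate)
      time <- time + rexp(1, total)
      if (time > t) break
      i <- sample.int(length(cods), 1L, prob = codon_rate)
      rt <- rate_tab[[cods[i]]]
      k <- sample.int(length(rt$to), 1L, prob = rt$rate)
      cods[i] <- rt$to[k]
      codon_rate[i] <- rate_tab[[cods[i]]]$total * mu
      n_ev <- n_ev + 1L
      if (rt$syn[k]) n_syn <- n_syn + 1L
    }
    list(cods = cods, n_ev = n_ev, n_syn = n_syn)
  })
  res <- paste(sim$cods, collapse = "")
  attr(res, "n_events") <- sim$n_ev
  attr(res, "n_syn_events") <- sim$n_syn
  attr(res, "n_nonsyn_events") <- sim$n_ev - sim$n_syn
  attr(res, "syn_sites") <- syn_sites
  res
}

# canonical motif instances used by the scaffold planter (wildcards filled
# with sterile letters)
.MOTIF_INSTANCE <- c(m1 = "GDVPW", m2 = "VKVAM", m3 = "VGWPPV",
                     m4 = "KRARAAK", m5 = "LALALA")
.SV40_DEGEN <- "KRARAAQ"  # final basic K substituted
.PART1_INSERT <- c(intact = "KR", degenerated = "KA")
.PART2_INSERT <- c(intact = "RQQRK", degenerated = "CQQRK")

#' Plant motif scaffolds with chosen NLS statuses
#'
#' Builds synthetic proteins that carry a requested subset of the five
#' family motifs in domain order (5 - 3 - 2 - 4 - 1) separated by random
#' linkers from an alphabet that cannot create accidental motif or NLS
#' matches, and edits the NLS regions so the scanner's calls have a known
#' truth: intact inserts the canonical cluster, degenerated a single
#' basic-position substitution, lack leaves the window free of basic
#' residues.
#'
#' A plan is contradictory (and an error) when a non-lack NLS status is
#' requested without its anchoring motifs: bipartite Part 1 needs motifs 5
#' and 3, Part 2 needs motif 3, and the SV40-like signal needs motif 4
#' (conversely, planting motif 4 forces an intact or degenerated SV40
#' signal, since the motif is the signal).
#'
#' @param plan data.frame with one row per protein: columns `id`, `m1` ..
#'   `m5` (logical), `part1`, `part2`, `sv40` (each `"intact"`,
#'   `"degenerated"` or `"lack"`).
#' @param seed Integer seed for linker generation.
#' @param linker_range Length range (min, max) for the random linkers.
#' @return data.frame with columns `id`, `residues` plus the plan columns
#'   (the truth).
#' @export
plant_motifs_and_nls <- function(plan, seed = 1L, linker_range = c(12L, 40L)) {
  statuses <- c("intact", "degenerated", "lack")
  for (col in c("id", paste0("m", 1:5), "part1", "part2", "sv40")) {
    if (!col %in% names(plan)) stop("plan is missing column ", col)
  }
  if (!all(unlist(plan[c("part1", "part2", "sv40")]) %in% statuses)) {
    stop("NLS statuses must be intact, degenerated or lack")
  }
  bad_p1 <- plan$part1 != "lack" & !(plan$m5 & plan$m3)
  bad_p2 <- plan$part2 != "lack" & !plan$m3
  bad_sv <- (plan$sv40 != "lack" & !plan$m4) | (plan$sv40 == "lack" & plan$m4)
  if (any(bad_p1 | bad_p2 | bad_sv)) {
    stop("contradictory plan for protein(s): ",
         paste(plan$id[bad_p1 | bad_p2 | bad_sv], collapse = ", "))
  }
  rng <- .new_rng(seed)
  residues <- .with_rng(rng, {
    linker <- function() {
      n <- sample(linker_range[1]:linker_range[2], 1L)
      paste(sample(.STERILE_AA, n, replace = TRUE), collapse = "")
    }
    vapply(seq_len(nrow(plan)), function(i) {
      p <- plan[i, ]
      parts <- character(0)
      parts <- c(parts, linker())
      if (p$m5) parts <- c(parts, .MOTIF_INSTANCE[["m5"]])
      # Part-1 region between domains I and II
      p1 <- linker()
      if (p$part1 != "lack") {
        p1 <- paste0(p1, .PART1_INSERT[[p$part1]], linker())
      }
      parts <- c(parts, p1)
      if (p$m3) parts <- c(parts, .MOTIF_INSTANCE[["m3"]])
      # Part-2 cluster sits right after the degron motif
      if (p$part2 != "lack") parts <- c(parts, .PART2_INSERT[[p$part2]])
      parts <- c(parts, linker())
      if (p$m2) parts <- c(parts, .MOTIF_INSTANCE[["m2"]])
      parts <- c(parts, linker())
      if (p$m4) {
        parts <- c(parts, if (p$sv40 == "intact") .MOTIF_INSTANCE[["m4"]]
                   else .SV40_DEGEN)
      }
      parts <- c(parts, linker())
      if (p$m1) parts <- c(parts, .MOTIF_INSTANCE[["m1"]])
      parts <- c(parts, linker())
      paste(parts, collapse = "")
    }, character(1))
  })
  out <- plan
  out$residues <- residues
  out
}

#' Simulate a gene family with known duplication history
#'
#' Starting from random ancestral genes laid out on chromosomes, each
#' epoch duplicates every gene independently (tandem with probability
#' `tandem_rate`, placing the child 1-40 kb from its parent on the same
#' chromosome; segmental with probability `segmental_rate`, placing the
#' child on another chromosome at least `segmental_clearance` bp from any
#' family gene and registering the parent/child anchor pair in a
#' collinearity block), then evolves every coding sequence by
#' `branch_length` expected synonymous substitutions per synonymous site
#' under the codon model. All events are recorded in a truth log.
#'
#' @param config List; recognized entries (with defaults):
#'   `seed` (mandatory), `n_ancestral_genes` (5), `n_chromosomes` (3),
#'   `chromosome_length` (2e6), `gene_length_codons` (200),
#'   `tandem_rate` (0.2), `segmental_rate` (0.2), `n_epochs` (2),
#'   `omega` (0.2), `kappa` (2), `branch_length` (0.05),
#'   `segmental_clearance` (60000).
#' @return List of class `simulated_family`: `proteins` and `cds`
#'   (data.frames as from [read_fasta()]), `gene_models`, `blocks`,
#'   `truth` (event log: `event`, `parent`, `child`, `epoch`), and the
#'   filled-in `config`.
#' @export
simulate_family <- function(config) {
  defaults <- list(n_ancestral_genes = 5L, n_chromosomes = 3L,
                   chromosome_length = 2e6, gene_length_codons = 200L,
                   tandem_rate = 0.2, segmental_rate = 0.2, n_epochs = 2L,
                   omega = 0.2, kappa = 2, branch_length = 0.05,
                   segmental_clearance = 60000)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  cfg <- utils::modifyList(defaults, config)
  if (cfg$tandem_rate < 0 || cfg$segmental_rate < 0 || cfg$omega < 0 ||
      cfg$kappa <= 0 || cfg$branch_length < 0) {
    stop("rates must be >= 0, omega >= 0, kappa > 0")
  }
  tb <- .codon_tables()
  gene_bp <- 3L * cfg$gene_length_codons

  rng <- .new_rng(cfg$seed)
  state <- .with_rng(rng, {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    genes <- list()   # gene_id -> list(chrom, start, end, cds)
    occupied <- setNames(vector("list", length(chroms)), chroms)

    overlaps <- function(chrom, start, end, clearance = 0) {
      for (iv in occupied[[chrom]]) {
        if (start <= iv[2] + clearance && end >= iv[1] - clearance) return(TRUE)
      }
      FALSE
    }
    place <- function(chrom, start, end) {
      occupied[[chrom]][[length(occupied[[chrom]]) + 1L]] <<- c(start, end)
    }

    random_cds <- function() {
      paste(sample(tb$sense, cfg$gene_length_codons, replace = TRUE),
            collapse = "")
    }
    for (g in seq_len(cfg$n_ancestral_genes)) {
      for (try in 1:200) {
        chrom <- sample(chroms, 1L)
        start <- sample.int(cfg$chromosome_length - gene_bp, 1L)
        if (!overlaps(chrom, start, start + gene_bp - 1L,
                      cfg$segmental_clearance)) break
        if (try == 200) stop("impossible layout: cannot place ancestral genes")
      }
      id <- sprintf("g%03d", g)
      genes[[id]] <- list(chrom = chrom, start = start,
                          end = start + gene_bp - 1L, cds = random_cds())
      place(chrom, start, start + gene_bp - 1L)
    }

    truth <- data.frame(event = character(), parent = character(),
                        child = character(), epoch = integer(),
                        stringsAsFactors = FALSE)
    blocks <- data.frame(block_id = character(), gene_a = character(),
                         gene_b = character(), stringsAsFactors = FALSE)
    counter <- cfg$n_ancestral_genes
    for (epoch in seq_len(cfg$n_epochs)) {
      for (id in names(genes)) {
        parent <- genes[[id]]
        if (runif(1) < cfg$tandem_rate) {
          gap <- sample(1000:40000, 1L)
          start <- parent$end + gap
          end <- start + gene_bp - 1L
          if (end > cfg$chromosome_length || overlaps(parent$chrom, start, end)) {
            start <- parent$start - gap - gene_bp
            end <- start + gene_bp - 1L
            if (start < 1 || overlaps(parent$chrom, start, end)) {
              stop("impossible layout: no room for a tandem copy of ", id)
            }
          }
          counter <- counter + 1L
          child <- sprintf("g%03d", counter)
          genes[[child]] <- list(chrom = parent$chrom, start = start,
                                 end = end, cds = parent$cds)
          place(parent$chrom, start, end)
          truth <- rbind(truth, data.frame(event = "tandem", parent = id,
                                           child = child, epoch = epoch,
                                           stringsAsFactors = FALSE))
        }
        if (runif(1) < cfg$segmental_rate) {
          others <- setdiff(chroms, parent$chrom)
          placed <- FALSE
          for (try in 1:200) {
            chrom <- if (length(others) == 1L) others else sample(others, 1L)
            start <- sample.int(cfg$chromosome_length - gene_bp, 1L)
            end <- start + gene_bp - 1L
            if (!overlaps(chrom, start, end, cfg$segmental_clearance)) {
              placed <- TRUE
              break
            }
          }
          if (!placed) stop("impossible layout: no room for a segmental copy of ", id)
          counter <- counter + 1L
          child <- sprintf("g%03d", counter)
          genes[[child]] <- list(chrom = chrom, start = start, end = end,
                                 cds = parent$cds)
          place(chrom, start, end)
          truth <- rbind(truth, data.frame(event = "segmental", parent = id,
                                           child = child, epoch = epoch,
                                           stringsAsFactors = FALSE))
          blocks <- rbind(blocks, data.frame(
            block_id = sprintf("block_%03d", nrow(blocks) + 1L),
            gene_a = id, gene_b = child, stringsAsFactors = FALSE))
        }
      }
      # all lineages evolve through the epoch
      if (cfg$branch_length > 0) {
        for (id in names(genes)) {
          sub_seed <- sample.int(2^30, 1L)
          genes[[id]]$cds <- as.character(
            evolve_codon_sequence(genes[[id]]$cds, cfg$branch_length,
                                  cfg$omega, cfg$kappa, sub_seed))
        }
      }
    }
    list(genes = genes, truth = truth, blocks = blocks)
  })

  ids <- names(state$genes)
  gene_models <- data.frame(
    gene_id = ids,
    chromosome = vapply(state$genes, `[[`, character(1), "chrom"),
    start = vapply(state$genes, function(g) as.integer(g$start), integer(1)),
    end = vapply(state$genes, function(g) as.integer(g$end), integer(1)),
    strand = "+", row.names = NULL, stringsAsFactors = FALSE)
  gene_models$cds_ids <- as.list(paste0(ids, ".cds"))
  cds <- data.frame(id = ids, molecule = "cds",
                    residues = vapply(state$genes, `[[`, character(1), "cds"),
                    row.names = NULL, stringsAsFactors = FALSE)
  proteins <- data.frame(id = ids, molecule = "protein",
                         residues = vapply(cds$residues, translate_cds,
                                           character(1), USE.NAMES = FALSE),
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(proteins = proteins, cds = cds, gene_models = gene_models,
                 blocks = state$blocks, truth = state$truth, config = cfg),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("simulated family:", nrow(x$proteins), "genes,",
      sum(x$truth$event == "tandem"), "tandem and",
      sum(x$truth$event == "segmental"), "segmental events\n")
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits the formats the package readers consume: protein and CDS FASTA,
#' GFF3 gene models, the collinearity anchor-pair TSV, and the truth log.
#'
#' @param family A `simulated_family`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteins = file.path(dir, "proteins.fa"),
             cds = file.path(dir, "cds.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             blocks = file.path(dir, "collinearity.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(family$proteins, paths["proteins"])
  write_fasta(family$cds, paths["cds"])
  gm <- family$gene_models
  con <- file(paths["gff3"], "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gm))) {
    writeLines(paste(gm$chromosome[i], "auxevol", "gene", gm$start[i],
                     gm$end[i], ".", gm$strand[i], ".",
                     paste0("ID=", gm$gene_id[i]), sep = "\t"), con)
    writeLines(paste(gm$chromosome[i], "auxevol", "CDS", gm$start[i],
                     gm$end[i], ".", gm$strand[i], "0",
                     paste0("ID=", gm$cds_ids[[i]][1], ";Parent=", gm$gene_id[i]),
                     sep = "\t"), con)
  }
  close(con)
  write.table(family$blocks, paths["blocks"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(family$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
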