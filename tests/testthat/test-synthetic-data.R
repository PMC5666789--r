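test_that("codon evolution is deterministic, stop-free and t = 0 exact", {
  set.seed(4)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anc <- paste(sample(sense, 100, replace = TRUE), collapse = "")
  same <- evolve_codon_sequence(anc, 0, 0.5, 2, seed = 1)
  expect_equal(as.character(same), anc)
  expect_equal(attr(same, "n_events"), 0L)
  a <- evolve_codon_sequence(anc, 0.2, 0.5, 2, seed = 7)
  b <- evolve_codon_sequence(anc, 0.2, 0.5, 2, seed = 7)
  expect_identical(as.character(a), as.character(b))
  expect_false(as.character(a) == anc)
  expect_false(grepl("\\*", translate_cds(as.character(a))))
  expect_equal(attr(a, "n_syn_events") + attr(a, "n_nonsyn_events"),
               attr(a, "n_events"))
  expect_error(evolve_codon_sequence("ATGA", 0.1, 0.5, 2, 1), "divisible")
  expect_error(evolve_codon_sequence("ATGTAA", 0.1, 0.5, 2, 1), "stop codon")
  expect_error(evolve_codon_sequence("ATGGCN", 0.1, 0.5, 2, 1), "A/C/G/T")
  expect_error(evolve_codon_sequence("ATG", -1, 0.5, 2, 1), "t must be")
})

test_that("omega = 0 yields only synonymous events", {
  set.seed(6)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anc <- paste(sample(sense, 150, replace = TRUE), collapse = "")
  ev <- evolve_codon_sequence(anc, 0.3, 0, 2, seed = 2)
  expect_equal(attr(ev, "n_nonsyn_events"), 0L)
  expect_gt(attr(ev, "n_events"), 0L)
  expect_equal(translate_cds(as.character(ev)), translate_cds(anc))
})

test_that("event counts calibrate against the branch length", {
  set.seed(8)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anc <- paste(sample(sense, 500, replace = TRUE), collapse = "")
  t <- 0.2
  n_syn <- vapply(1:20, function(s) {
    attr(evolve_codon_sequence(anc, t, 0.5, 2, seed = 100 + s),
         "n_syn_events")
  }, integer(1))
  syn_sites <- attr(evolve_codon_sequence(anc, 0, 0.5, 2, 1), "syn_sites")
  # mean synonymous events per synonymous site should be close to t
  expect_equal(mean(n_syn) / syn_sites, t, tolerance = 0.15)
})

test_that("planted motif subsets are recovered by the scanner", {
  plan <- data.frame(
    id = sprintf("p%d", 1:4),
    m1 = c(TRUE, TRUE, FALSE, TRUE),
    m2 = c(TRUE, TRUE, TRUE, FALSE),
    m3 = c(TRUE, FALSE, TRUE, FALSE),
    m4 = c(TRUE, FALSE, FALSE, FALSE),
    m5 = c(TRUE, TRUE, FALSE, FALSE),
    part1 = c("intact", "lack", "lack", "lack"),
    part2 = c("degenerated", "lack", "intact", "lack"),
    sv40 = c("intact", "lack", "lack", "lack"),
    stringsAsFactors = FALSE)
  prots <- plant_motifs_and_nls(plan, seed = 11)
  for (i in seq_len(nrow(prots))) {
    prof <- call_presence(prots$residues[i])
    expect_equal(unname(prof$present),
                 unname(unlist(plan[i, paste0("m", 1:5)])),
                 info = plan$id[i])
  }
  # determinism
  expect_identical(prots$residues,
                   plant_motifs_and_nls(plan, seed = 11)$residues)
  expect_false(identical(prots$residues,
                         plant_motifs_and_nls(plan, seed = 12)$residues))
})

test_that("contradictory NLS plans are rejected", {
  base <- data.frame(id = "p", m1 = TRUE, m2 = TRUE, m3 = TRUE, m4 = TRUE,
                     m5 = TRUE, part1 = "intact", part2 = "intact",
                     sv40 = "intact", stringsAsFactors = FALSE)
  p <- base; p$m3 <- FALSE  # part1 and part2 need motif 3
  expect_error(plant_motifs_and_nls(p), "contradictory")
  p <- base; p$m4 <- FALSE  # sv40 intact needs motif 4
  expect_error(plant_motifs_and_nls(p), "contradictory")
  p <- base; p$sv40 <- "lack"  # motif 4 present forces a non-lack sv40
  expect_error(plant_motifs_and_nls(p), "contradictory")
  p <- base; p$part1 <- "sometimes"
  expect_error(plant_motifs_and_nls(p), "statuses")
  expect_error(plant_motifs_and_nls(base[, -1]), "missing column id")
})

test_that("simulate_family produces a consistent, deterministic truth log", {
  fam <- simulate_family(list(seed = 7, tandem_rate = 0.3,
                              segmental_rate = 0.2))
  fam2 <- simulate_family(list(seed = 7, tandem_rate = 0.3,
                               segmental_rate = 0.2))
  expect_identical(fam$cds$residues, fam2$cds$residues)
  expect_identical(fam$truth, fam2$truth)
  expect_s3_class(fam, "simulated_family")
  gm <- fam$gene_models
  expect_equal(nrow(gm), nrow(fam$proteins))
  expect_true(all(fam$truth$child %in% gm$gene_id))
  chrom_of <- setNames(gm$chromosome, gm$gene_id)
  for (i in seq_len(nrow(fam$truth))) {
    ev <- fam$truth[i, ]
    if (ev$event == "tandem") {
      expect_equal(chrom_of[[ev$parent]], chrom_of[[ev$child]])
    } else {
      expect_false(chrom_of[[ev$parent]] == chrom_of[[ev$child]])
    }
  }
  # every segmental event has its anchor pair in a block
  seg <- fam$truth[fam$truth$event == "segmental", ]
  expect_equal(nrow(fam$blocks), nrow(seg))
  expect_true(all(paste(seg$parent, seg$child) %in%
                    paste(fam$blocks$gene_a, fam$blocks$gene_b)))
  # proteins translate their CDS
  expect_equal(fam$proteins$residues,
               vapply(fam$cds$residues, translate_cds, character(1),
                      USE.NAMES = FALSE))
  expect_error(simulate_family(list()), "seed")
  expect_error(simulate_family(list(seed = 1, kappa = 0)), "kappa")
})

test_that("write_family emits files the package readers accept", {
  fam <- simulate_family(list(seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_family(fam, dir)
  expect_true(all(file.exists(paths)))
  prots <- read_fasta(paths[["proteins"]], molecule = "protein")
  expect_equal(prots$id, fam$proteins$id)
  expect_equal(prots$residues, fam$proteins$residues)
  cds <- read_fasta(paths[["cds"]])
  expect_equal(cds$residues, fam$cds$residues)
  gm <- read_gff3(paths[["gff3"]])
  gm <- gm[match(fam$gene_models$gene_id, gm$gene_id), ]
  expect_equal(gm$start, fam$gene_models$start)
  expect_equal(gm$end, fam$gene_models$end)
  expect_equal(gm$chromosome, fam$gene_models$chromosome)
  blocks <- read_collinearity_blocks(paths[["blocks"]])
  expect_equal(nrow(blocks), nrow(fam$blocks))
})
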