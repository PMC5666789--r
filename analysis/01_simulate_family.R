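#!/usr/bin/env Rscript
# Simulate the study system: a multi-gene family with known tandem and
# segmental duplication history, evolved under a codon model with purifying
# selection. Writes the standard input formats (FASTA, GFF3, collinearity
# TSV) plus the ground-truth event log for the downstream steps.

library(auxevol)

out_dir <- file.path("results", "family")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

family <- simulate_family(list(
  seed = 2024,
  n_ancestral_genes = 6,
  n_chromosomes = 4,
  gene_length_codons = 200,
  tandem_rate = 0.3,
  segmental_rate = 0.2,
  n_epochs = 2,
  omega = 0.2,        # purifying selection, the regime typical of the family
  kappa = 2,          # mild transition bias
  branch_length = 0.05
))

print(family)
paths <- write_family(family, out_dir)
cat("inputs written to", out_dir, ":", paste(basename(paths), collapse = ", "),
    "\n")

# Second study set: protein scaffolds carrying chosen motif subsets and
# NLS statuses (the motif/NLS analyses need proteins with known domain
# truth, which the codon-level family above does not model).
scaffold_dir <- file.path("results", "scaffolds")
dir.create(scaffold_dir, recursive = TRUE, showWarnings = FALSE)
plan <- data.frame(
  id = sprintf("s%02d", 1:10),
  m1 = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
  m2 = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  m3 = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
  m4 = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
  m5 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
  part1 = c("intact", "intact", "intact", "lack", "degenerated", "lack",
            "intact", "lack", "degenerated", "lack"),
  part2 = c("intact", "degenerated", "intact", "lack", "intact", "lack",
            "intact", "lack", "degenerated", "lack"),
  sv40 = c("intact", "intact", "lack", "lack", "lack", "degenerated",
           "degenerated", "intact", "lack", "lack"),
  stringsAsFactors = FALSE)
scaffolds <- plant_motifs_and_nls(plan, seed = 515)
write_fasta(scaffolds, file.path(scaffold_dir, "proteins.fa"))
write.table(plan, file.path(scaffold_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("scaffold proteins written to", scaffold_dir, "\n")
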