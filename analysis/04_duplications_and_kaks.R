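#!/usr/bin/env Rscript
# Call duplication modes (tandem: same chromosome, <= 50 kb, > 50%
# identity; segmental: collinearity anchor pair), estimate Ka/Ks for every
# called pair with both NG86 and MYN, compare against the simulation
# truth, and test tandem vs segmental selection pressure.

library(auxevol)

fam_dir <- file.path("results", "family")
proteins <- read_fasta(file.path(fam_dir, "proteins.fa"), molecule = "protein")
cds <- read_fasta(file.path(fam_dir, "cds.fa"), molecule = "cds")
gene_models <- read_gff3(file.path(fam_dir, "genes.gff3"))
blocks <- read_collinearity_blocks(file.path(fam_dir, "collinearity.tsv"))
truth <- read.delim(file.path(fam_dir, "truth.tsv"))
out_dir <- file.path("results", "duplication")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

prots <- setNames(proteins$residues, proteins$id)
cds_of <- setNames(cds$residues, cds$id)

tandem <- find_tandem_pairs(gene_models, prots)
pairs <- assign_segmental(tandem, blocks)
write.table(pairs, file.path(out_dir, "duplication_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

species_of <- setNames(rep("simulated", nrow(gene_models)),
                       gene_models$gene_id)
write.table(duplication_summary(pairs, gene_models$gene_id, species_of),
            file.path(out_dir, "duplication_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

key <- function(a, b) paste(pmin(a, b), pmax(a, b))
truth_tan <- truth[truth$event == "tandem", ]
cat("planted tandem events recovered:",
    sum(key(truth_tan$parent, truth_tan$child) %in%
          key(pairs$gene_a, pairs$gene_b)), "of", nrow(truth_tan), "\n")

kaks <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  a <- pairs$gene_a[i]
  b <- pairs$gene_b[i]
  aln <- align_proteins_global(prots[[a]], prots[[b]])
  ca <- project_to_codons(aln, cds_of[[a]], cds_of[[b]])
  rbind(cbind(pair = paste(a, b, sep = "/"),
              duplication_type = pairs$classification[i],
              estimate_kaks_ng86(ca)),
        cbind(pair = paste(a, b, sep = "/"),
              duplication_type = pairs$classification[i],
              estimate_kaks_myn(ca)))
}))
kaks$ka_ks <- omega_ratio(kaks$Ka, kaks$Ks)
write.table(kaks, file.path(out_dir, "kaks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(kaks[, c("pair", "duplication_type", "method", "Ka", "Ks", "ka_ks")])

myn <- kaks[kaks$method == "MYN", ]
myn$lineage <- "simulated"
means <- group_kaks_means(myn)
write.table(means, file.path(out_dir, "kaks_group_means.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

seg <- myn$omega[myn$duplication_type %in% c("segmental", "both")]
tan <- myn$omega[myn$duplication_type %in% c("tandem", "both")]
seg <- seg[!is.na(seg)]
tan <- tan[!is.na(tan)]
if (length(seg) >= 2 && length(tan) >= 2) {
  tt <- students_t_test(seg, tan)
  write.table(tt, file.path(out_dir, "seg_vs_tan_ttest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(tt)
} else {
  cat("too few pairs per class for the tandem vs segmental t test\n")
}
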