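#!/usr/bin/env Rscript
# Classify the two putative nuclear localization signals of each protein
# (bipartite Part 1 "KR", Part 2 "RxxRK", SV40-like "KRxRxxK") as intact,
# degenerated or lacking, and aggregate by species.

library(auxevol)

proteins <- read_fasta(file.path("results", "scaffolds", "proteins.fa"),
                       molecule = "protein")
out_dir <- file.path("results", "nls")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

reports <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
  scan_nls(proteins$residues[i], sequence_id = proteins$id[i],
           species = "simulated")
}))
write.table(reports, file.path(out_dir, "nls_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

species_of <- setNames(rep("simulated", nrow(proteins)), proteins$id)
agg <- aggregate_species(reports, species_of)
write.table(agg$summary, file.path(out_dir, "nls_species_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(agg$overall, file.path(out_dir, "nls_overall_pct.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(agg$summary)
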