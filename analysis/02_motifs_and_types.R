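#!/usr/bin/env Rscript
# Scan every protein for the five conserved family motifs, assign the
# motif-composition type (I-X / other) and the PB1 interaction signature,
# and tabulate the type distribution.

library(auxevol)

proteins <- read_fasta(file.path("results", "scaffolds", "proteins.fa"),
                       molecule = "protein")
out_dir <- file.path("results", "motifs")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

models <- consensus_models()
profiles <- lapply(seq_len(nrow(proteins)), function(i) {
  call_presence(proteins$residues[i], models, sequence_id = proteins$id[i])
})

presence <- do.call(rbind, lapply(profiles, function(p) {
  data.frame(sequence_id = p$sequence_id, t(p$present))
}))
write.table(presence, file.path(out_dir, "motif_presence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

types <- do.call(rbind, lapply(profiles, classify_type))
pb1 <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
  classify_pb1_signature(proteins$residues[i], proteins$id[i])
}))
assignments <- merge(types, pb1, by = "sequence_id")
write.table(assignments, file.path(out_dir, "types.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summary <- summarize_types(types)
write.table(summary, file.path(out_dir, "type_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary[summary$count > 0, ])
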