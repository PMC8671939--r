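#!/usr/bin/env Rscript
# Stage 1 -- expression-construct bookkeeping.
#
# Cleaves the His6-tagged AGP2 expression construct to mature numbering,
# applies the C-terminal truncation (stop at mature 173), and scans for
# N-glycosylation sequons and cysteines.  The headline findings: a 183-aa
# mature protein starting QIPLC; the truncated NMR/crystallography
# construct is 172 aa (11 residues removed); five sequons at
# 15/38/54/75/85; cysteines at 5/72/147/165 (the two disulfides are
# 5-147 and 72-165; position 149 is Arg in this C149R variant).

library(ligmap)
out_dir <- "results/01_sequence"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

full <- sequence_report(agp2_construct())
trunc <- sequence_report(agp2_truncated_construct())

cat(sprintf("mature protein: %d aa, starts %s\n", full$mature_length,
            substr(full$mature, 1, 5)))
cat(sprintf("truncated product: %d aa (%d residues removed at Glu173)\n",
            trunc$product_length, trunc$truncation$removed))
cat("sequons:", trunc$sequons$position, "\n")
cat("cysteines:", trunc$cysteines, "\n")

write_fasta(c(AGP2_mature = full$mature,
              AGP2_truncated = trunc$mature),
            file.path(out_dir, "agp2_mature.fasta"))
write.table(trunc$sequons, file.path(out_dir, "sequons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(position = trunc$cysteines),
            file.path(out_dir, "cysteines.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
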