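#!/usr/bin/env Rscript
# Stage 5 -- affinity and stability thermodynamics.
#
# Scalar comparisons from the measured constants: the staurosporine
# (88 nM) vs UCN-01 (3.5 nM) affinity gap expressed as a binding
# free-energy difference and fold change -- the energetic cost of losing
# the C7 hydroxyl and its hydrogen bond to Glu64 -- and the thermal
# stabilization of AGP2 on UCN-01 binding.

library(ligmap)
out_dir <- "results/05_thermo"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ddg <- delta_delta_g(88, 3.5, temperature_k = 298)
fc <- fold_change(88, 3.5)
dtm <- delta_tm(61.9, 75.6)

cat(sprintf("ddG (staurosporine vs UCN-01, 298 K): %.2f kJ/mol\n", ddg))
cat(sprintf("fold change in Kd: %.1f\n", fc))
cat(sprintf("Tm shift on binding: %.1f C (61.9 -> 75.6)\n", dtm))

write.table(
  data.frame(quantity = c("ddG_kJ_mol", "kd_fold_change", "delta_tm_C"),
             value = c(ddg, fc, dtm)),
  file.path(out_dir, "thermodynamics.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
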