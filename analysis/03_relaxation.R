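#!/usr/bin/env Rscript
# Stage 3 -- backbone 15N relaxation profiling.
#
# Simulates T1/T2 decay series on the published delay grids (13 T1
# delays to 2500 ms, 10 T2 delays to 320 ms) plus hetNOE pairs for a
# protein with a uniformly rigid core and mobile termini, fits every
# residue with the two-parameter mono-exponential model, and builds the
# mobility profile.  The expected outcome mirrors the solution finding:
# flat core T1/T2 and NOE, depressed values only at the termini, and no
# contiguous low-T2 patch (no us-ms exchange signature).

library(ligmap)
out_dir <- "results/03_relaxation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- simulation_spec(seed = 1)
sim <- simulate_relaxation(spec)
tab <- fit_relaxation_table(sim$decays, sim$noe)
cat(sprintf("fitted %d/%d residues; core T1 ~ %.2f s, T2 ~ %.3f s\n",
            sum(tab$ok), nrow(tab), median(tab$t1_s, na.rm = TRUE),
            median(tab$t2_s, na.rm = TRUE)))

mob <- mobility_profile(tab)
print(mob)

write.table(tab, file.path(out_dir, "relaxation_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mob$table, file.path(out_dir, "mobility_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
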