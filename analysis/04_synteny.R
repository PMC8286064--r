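#!/usr/bin/env Rscript
# Step 4: microsynteny of the irp loci.
#
# Clusters the two simulated species layouts at the 1 Mb gap threshold,
# checks the conserved octinsulin-IGF-dilp7 arrangement (IGF in the middle)
# and compares cluster compositions between the layouts. Writes
# results/synteny_clusters.tsv and results/synteny_comparison.tsv.

suppressPackageStartupMessages(library(irpannot))

layouts <- list(
  echinozoa = cluster_loci(read_locus_table("results/sim/loci_clustered.tsv")),
  asterozoa = cluster_loci(read_locus_table("results/sim/loci_scattered.tsv")))

write_cluster_table(c(layouts$echinozoa, layouts$asterozoa),
                    "results/synteny_clusters.tsv")
comparison <- compare_layouts(layouts)
utils::write.table(comparison, "results/synteny_comparison.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (sp in names(layouts)) {
  cat(sp, ":", length(layouts[[sp]]), "cluster(s)\n")
  for (cl in layouts[[sp]]) {
    cat("  ", cl$seq_region, ":",
        paste(cl$members$family_label, collapse = " - "),
        if (length(cl$gaps_kb)) sprintf("(gaps %s kb)",
                                        paste(round(cl$gaps_kb), collapse = ", "))
        else "(singleton)",
        "->", conserved_arrangement_check(cl), "\n")
  }
}
cat("\nShared compositions between layouts:",
    sum(comparison$verdict == "shared"), "\n")
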