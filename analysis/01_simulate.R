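#!/usr/bin/env Rscript
# Step 1: materialize the synthetic study data set.
#
# Emits, under results/sim/:
#   precursors_clean.fa   one noise-free precursor per irp family
#   precursors_noisy.fa   10 replicates per family at 5% residue noise
#   gene_models.gff3      CDS gene models matching the clean precursors
#   loci_clustered.tsv    echinozoan-style microsynteny layout
#   loci_scattered.tsv    asterozoan-style layout (synteny lost)
#   receptors.fa          GRL101-type and single-LDLa LGR-type receptors

suppressPackageStartupMessages(library(irpannot))

SEED <- 1234L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
families <- c("IGF", "GSS", "octinsulin", "dilp7", "multinsulin")

clean <- lapply(families, make_precursor, seed = SEED)
write_fasta(clean, file.path(out_dir, "precursors_clean.fa"))

noisy <- make_precursor_batch(10, SEED, noise_rate = 0.05)
write_fasta(noisy, file.path(out_dir, "precursors_noisy.fa"))

gms <- lapply(families, make_gene_model, seed = SEED)
write_gff3_gene_models(lapply(gms, `[[`, "gene"),
                       file.path(out_dir, "gene_models.gff3"))

write_locus_table(make_synteny_layout("echinozoa_clustered", SEED),
                  file.path(out_dir, "loci_clustered.tsv"))
write_locus_table(make_synteny_layout("asterozoa_scattered", SEED),
                  file.path(out_dir, "loci_scattered.tsv"))

receptors <- list(make_receptor("GRL101", SEED),
                  make_receptor("single_LDLa_LGR", SEED))
write_fasta(receptors, file.path(out_dir, "receptors.fa"))

cat("Synthetic study set written to", out_dir, "\n")
cat(sprintf("  %d clean precursors, %d noisy replicates, %d gene models,\n",
            length(clean), length(noisy), length(gms)))
cat("  2 synteny layouts, 2 receptor presets.\n")
cat("Precursor lengths:",
    paste(sprintf("%s=%d", families,
                  vapply(clean, function(r) nchar(r$residues), 0L)),
          collapse = ", "), "\n")
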