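#!/usr/bin/env Rscript
# Generate the synthetic study: a four-species isolation-with-migration
# demography at the composite-likelihood point estimates of the winning
# topology (((P,A),C),S), two outgroup species, 100 unlinked 2-kb loci with
# 8 haplotypes per species. Writes gene trees, alignments, a polarized
# variant table and the species map under results/study/.

library(quartetcoal)

dem <- candidate_demographies(1, outgroups = TRUE)
print(dem)

design <- sample_design(haplotypes_per_species = 8, n_loci = 100,
                        locus_length = 2000, include_outgroups = TRUE,
                        seed = 20150717)
study <- emit_study(dem, design, out_dir = "results/study")

cat("\nSimulated", length(study$genealogies), "loci;",
    nrow(study$variants), "segregating sites across",
    nrow(study$species_map), "haplotypes.\n")
cat("Artifacts written under results/study/\n")
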