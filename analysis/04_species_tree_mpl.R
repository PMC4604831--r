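#!/usr/bin/env Rscript
# Pseudo-likelihood species-tree estimation from rooted triples, the
# loci-resubsampling precision curve, and the recovery experiment across all
# four candidate demographies (which shows how gene flow can mislead a
# no-migration estimator).

library(quartetcoal)
dir.create("results", showWarnings = FALSE)

dem <- candidate_demographies(1)
ep <- quartetcoal:::compile_epochs(dem)
set.seed(8)
n_loci <- 2000
sim <- quartetcoal:::sim_coal_batch_cpp(as.integer(ep$pop_of), ep,
                                        as.integer(n_loci))
keys <- vapply(seq_len(n_loci), function(i)
  canonical_key(quartetcoal:::pt_to_phylo(sim$parent[i, ], sim$time[i, ],
                                          dem$species)), "")

fit <- fit_species_tree(keys, dem$species)
print(fit)
jsonlite::write_json(list(best = fit$key, branch_lengths = fit$branch_lengths,
                          logL = fit$logL, scores = as.list(fit$scores)),
                     "results/species_tree_fit.json", auto_unbox = TRUE,
                     digits = NA)

rc <- resubsample_consistency(keys, dem$species,
                              grid = c(10, 25, 50, 100, 200, 500, 1000),
                              n_reps = 200, seed = 9)
write.table(rc, "results/resubsampling_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nResubsampling precision (fraction matching the full-data tree):\n")
print(rc)
cat("A few hundred loci are enough to recover the full-data topology.\n")

cat("\nRecovery across the four candidate demographies (6 reps each):\n")
mpl <- mpl_recovery_experiment(n_reps_per_model = 6, n_loci = 1000, seed = 61)
print(aggregate(hit ~ generating, mpl, mean))
write.table(mpl, "results/mpl_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Under the fourth candidate, fitted gene-flow rates make the symmetric\n")
cat("topology the most frequent gene tree; a no-migration pseudo-likelihood\n")
cat("estimator is positively misled there.\n")
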