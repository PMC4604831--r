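test_that("pairwise TMRCA in a panmictic population matches 2N", {
  dem <- toy_demography(1, N = 1e4)
  ep <- quartetcoal:::compile_epochs(dem)
  set.seed(5)
  sim <- quartetcoal:::sim_coal_batch_cpp(c(0L, 0L), ep, 5000L)
  tm <- sim$time[, 3]
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2e4), 3 * se)
})

test_that("isolation forbids cross-species coalescence before the split", {
  dem <- toy_demography(2, N = 2e4, t_split = 5e4)
  ep <- quartetcoal:::compile_epochs(dem)
  set.seed(4)
  sim <- quartetcoal:::sim_coal_batch_cpp(as.integer(ep$pop_of), ep, 2000L)
  expect_gt(min(sim$time[, 3]), 5e4)
})

test_that("invalid designs are rejected", {
  expect_error(sample_design(haplotypes_per_species = 1), "invalid-design")
  expect_error(sample_design(locus_length = 0), "invalid-design")
  dem <- toy_demography(2)
  des <- sample_design(haplotypes_per_species = 2, include_outgroups = TRUE)
  expect_error(simulate_genealogy(dem, des, 1), "outgroups")
})

test_that("genealogies are rooted binary trees with generation-scale depths", {
  dem <- candidate_demographies(1, outgroups = TRUE)
  des <- sample_design(haplotypes_per_species = 4, n_loci = 3,
                       include_outgroups = TRUE, seed = 8)
  tr <- simulate_genealogy(dem, des, 1)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  n_og <- 4                      # two outgroup species x 2 haplotypes
  expect_equal(length(tr$tip.label), 4 * 4 + n_og)
  # root must predate the deepest outgroup join
  depth <- max(ape::node.depth.edgelength(tr))
  expect_gt(depth, 4.5e6)
})

test_that("mutation dropping follows the infinite-sites model", {
  dem <- toy_demography(2)
  des <- sample_design(haplotypes_per_species = 4, n_loci = 1, seed = 3)
  tr <- simulate_genealogy(dem, des, 1)
  expect_error(drop_mutations(tr, -1, 100), "invalid-parameter")
  none <- drop_mutations(tr, 0, 1000, seed = 1)
  expect_length(none$pos, 0)
  mu <- drop_mutations(tr, 1e-7, 5000, seed = 2)
  expect_gt(length(mu$pos), 0)
  expect_false(anyDuplicated(mu$pos) > 0)
  expect_true(all(mu$anc != mu$der))
  # derived carriers form a clade of the genealogy
  for (k in seq_along(mu$pos)) {
    carriers <- colnames(mu$geno)[mu$geno[k, ] == 1]
    if (length(carriers) > 1) {
      mrca <- ape::getMRCA(tr, carriers)
      below <- ape::extract.clade(tr, mrca)$tip.label
      expect_setequal(below, carriers)
    }
  }
})

test_that("segregating sites match the Watterson expectation", {
  N <- 25000; n_loci <- 1500; L <- 2000; n_hap <- 12
  dem <- toy_demography(1, N = N)
  des <- sample_design(haplotypes_per_species = n_hap, n_loci = n_loci,
                       locus_length = L, seed = 9)
  st <- emit_study(dem, des)
  S <- table(factor(st$variants$chrom,
                    levels = sprintf("locus_%04d", seq_len(n_loci))))
  expected <- 4 * N * dem$mu * L * sum(1 / seq_len(n_hap - 1))
  se <- sd(S) / sqrt(n_loci)
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("emit_study is deterministic and matches its design", {
  dem <- candidate_demographies(1, outgroups = TRUE)
  des <- sample_design(haplotypes_per_species = 4, n_loci = 10,
                       locus_length = 500, include_outgroups = TRUE,
                       seed = 21)
  a <- emit_study(dem, des)
  b <- emit_study(dem, des)
  expect_length(a$genealogies, 10)
  expect_length(a$alignments, 10)
  expect_identical(a$variants, b$variants)
  expect_equal(nrow(a$species_map), 4 * 4 + 4)
  # polarization of the emitted outgroups recovers the recorded truth
  v <- a$variants
  og1 <- sapply(grep("^O_", names(v), value = TRUE),
                function(cc) ifelse(v[[cc]] == 1, v$der, v$anc))
  og2 <- sapply(grep("^H_", names(v), value = TRUE),
                function(cc) ifelse(v[[cc]] == 1, v$der, v$anc))
  anc_hat <- polarize(og1, og2)
  ok <- !is.na(anc_hat)
  expect_gt(sum(ok), 0)
  expect_true(all(anc_hat[ok] == v$anc[ok]))
})

test_that("study files round-trip through the writers", {
  dem <- toy_demography(2)
  des <- sample_design(haplotypes_per_species = 3, n_loci = 4,
                       locus_length = 5000, seed = 17)
  out <- file.path(tempdir(), "study_rt")
  st <- emit_study(dem, des, out_dir = out)
  trees <- read_trees(file.path(out, "trees.nwk"))
  expect_length(trees, 4)
  expect_setequal(trees[[1]]$tip.label, st$genealogies[[1]]$tip.label)
  v <- read_variants(file.path(out, "variants.tsv"))
  expect_equal(nrow(v), nrow(st$variants))
  sm <- read_species_map(file.path(out, "species_map.tsv"))
  expect_equal(unname(sm[st$species_map$haplotype]), st$species_map$species)
  aln <- quartetcoal:::read_fasta_matrix(file.path(out,
                                                   "alignments/locus_0001.fa"))
  expect_identical(dim(aln), dim(st$alignments[[1]]))
  expect_identical(unname(aln), unname(st$alignments[[1]]))
  unlink(out, recursive = TRUE)
})

test_that("high symmetric migration drives PhiST toward zero", {
  dem <- toy_demography(2, N = 2e4, t_split = 4e5,
                        migration = c("A<-B" = 20, "B<-A" = 20))
  des <- sample_design(haplotypes_per_species = 6, n_loci = 400,
                       locus_length = 2000, seed = 12)
  per_locus <- quartetcoal:::simulate_pair_stat_matrix(dem, des)
  ph <- per_locus[, "phist_A-B"]
  ph <- ph[!is.na(ph)]
  se <- sd(ph) / sqrt(length(ph))
  expect_lt(abs(mean(ph)), 4 * se + 0.01)
})
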