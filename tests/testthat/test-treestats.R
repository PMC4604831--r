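test_that("gsi is 1 for monophyletic groups and matches the oracle", {
  tr <- ape::read.tree(text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,(c1:2,c2:2):1);")
  sm <- stats::setNames(c("A", "A", "B", "B", "C", "C"), tr$tip.label)
  expect_equal(gsi(tr, "A", sm), 1)
  expect_equal(gsi(tr, "C", sm), 1)
  # two focal leaves as immediate sisters anywhere
  tr2 <- ape::read.tree(text = "((((x1,x2),b1),c1),(b2,c2));")
  sm2 <- stats::setNames(c("X", "X", "B", "C", "B", "C"), tr2$tip.label)
  expect_equal(gsi(tr2, "X", sm2), 1)
  expect_error(gsi(tr2, "Z", sm2), "undefined")
  # interleaved fixtures match the independent brute-force oracle
  set.seed(31)
  for (r in 1:10) {
    tr3 <- ape::rtree(10)
    sm3 <- stats::setNames(sample(rep(c("A", "B"), 5)), tr3$tip.label)
    for (sp in c("A", "B"))
      expect_equal(gsi(tr3, sp, sm3), gsi_oracle(tr3, sp, sm3),
                   info = paste("replicate", r, sp))
  }
  # invariance to branch-length rescaling
  tr4 <- ape::rtree(8)
  sm4 <- stats::setNames(rep(c("A", "B"), 4), tr4$tip.label)
  tr5 <- tr4; tr5$edge.length <- tr5$edge.length * 1000
  expect_equal(gsi(tr4, "A", sm4), gsi(tr5, "A", sm4))
})

test_that("tdi follows its normalized Simpson form", {
  keys <- enumerate_topologies(4)
  p <- stats::setNames(rep(0, 15), keys)
  p[1] <- 1
  expect_equal(tdi(p), 0)
  expect_equal(tdi(rep(1 / 15, 15)), 1)
  p2 <- stats::setNames(rep(0, 15), keys)
  p2[c(2, 9)] <- 0.5
  expect_equal(tdi(p2), (1 - 0.5) / (1 - 1 / 15))  # 15/28
  expect_true(is.na(tdi(numeric(0))))
})

test_that("LCA relative depth matches an all-pairs path-length computation", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):2,O:4);")
  sm <- stats::setNames(c("A", "B", "C", "O"), tr$tip.label)
  expect_equal(lca_relative_depth(tr, c("A", "B", "C"), sm), 0.5)
  expect_equal(lca_relative_depth(tr, c("A", "B", "C", "O"), sm), 1)
  # non-ultrametric fixture: oracle via cophenetic distances
  tr2 <- ape::read.tree(text = "(((A:1,B:3):2,C:1.5):1,O:9);")
  sm2 <- stats::setNames(c("A", "B", "C", "O"), tr2$tip.label)
  coph <- ape::cophenetic.phylo(tr2)
  # height of ingroup MRCA = half the max ingroup pairwise distance is wrong
  # in general; use max root-to-leaf decomposition instead
  depth <- ape::node.depth.edgelength(tr2)
  mrca <- ape::getMRCA(tr2, c("A", "B", "C"))
  h_mrca <- max(depth[1:3]) - depth[mrca]
  h_root <- max(depth)
  expect_equal(lca_relative_depth(tr2, c("A", "B", "C"), sm2),
               h_mrca / h_root)
  tr3 <- tr2; tr3$edge.length <- NULL
  expect_true(is.na(lca_relative_depth(tr3, c("A", "B", "C"), sm2)))
})

test_that("subsampled spectra converge to the exhaustive enumeration", {
  # 8-leaf tree, two leaves per species, rooted input (no outgroup rooting)
  tr <- ape::read.tree(
    text = "(((a1:1,b1:1):1,(a2:1,c1:1):2):1,((b2:1,d1:1):1,(c2:1,d2:2):1):1);")
  sm <- stats::setNames(c("A", "B", "A", "C", "B", "D", "C", "D"),
                        tr$tip.label)
  picks <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                       C = c("c1", "c2"), D = c("d1", "d2"),
                       stringsAsFactors = FALSE)
  exact <- table(vapply(seq_len(nrow(picks)), function(i)
    canonical_key(ape::keep.tip(tr, unlist(picks[i, ])), sm), ""))
  exact <- exact / sum(exact)
  spec <- subsample_spectrum(tr, sm, ingroup = c("A", "B", "C", "D"),
                             n_rounds = 4000, seed = 2)
  expect_equal(sum(spec$freq), 1)
  for (k in names(exact)) {
    se <- sqrt(exact[[k]] * (1 - exact[[k]]) / 4000)
    expect_lt(abs(spec$freq[[k]] - exact[[k]]), 4 * se + 0.005)
  }
  # a fixed seed reproduces the spectrum
  spec2 <- subsample_spectrum(tr, sm, ingroup = c("A", "B", "C", "D"),
                              n_rounds = 200, seed = 7)
  spec3 <- subsample_spectrum(tr, sm, ingroup = c("A", "B", "C", "D"),
                              n_rounds = 200, seed = 7)
  expect_identical(spec2$freq, spec3$freq)
})

test_that("outgroup rooting picks the deepest outgroup", {
  # H joins deeper than O; rooting must use H and then drop both
  dem <- candidate_demographies(1, outgroups = TRUE)
  des <- sample_design(haplotypes_per_species = 2, n_loci = 1,
                       include_outgroups = TRUE, seed = 5)
  tr <- simulate_genealogy(dem, des, 1)
  cfg <- quartetcoal:::lineage_config(dem, des)
  sm <- stats::setNames(cfg$species, cfg$labels)
  spec <- subsample_spectrum(tr, sm, ingroup = dem$species,
                             outgroups = c("O", "H"), n_rounds = 50, seed = 1)
  expect_equal(sum(spec$freq), 1)
  expect_error(subsample_spectrum(tr, sm, ingroup = dem$species,
                                  outgroups = "Z", n_rounds = 10, seed = 1),
               "rooting error")
})

test_that("window scan flags, aggregates and orders correctly", {
  # two alternating pure topologies across an aggregate
  t_a <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  t_b <- ape::read.tree(text = "(((A:1,C:1):1,B:2):1,D:3);")
  sm <- stats::setNames(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  n_win <- 10
  windows <- data.frame(chrom = "chr1",
                        start = (seq_len(n_win) - 1) * 5e4,
                        end = (seq_len(n_win) - 1) * 5e4 + 1e4)
  trees <- rep(list(t_a, t_b), n_win / 2)
  scan <- window_scan(windows, trees, sm, ingroup = c("A", "B", "C", "D"),
                      n_rounds = 10, aggregate_bp = 5e5, seed = 3)
  expect_equal(scan$windows$tdi, rep(0, n_win))
  expect_equal(scan$aggregates$tdi, 15 / 28)
  # all windows sharing one topology aggregate to zero
  scan0 <- window_scan(windows, rep(list(t_a), n_win), sm,
                       ingroup = c("A", "B", "C", "D"), n_rounds = 10,
                       aggregate_bp = 5e5, seed = 3)
  expect_equal(scan0$aggregates$tdi, 0)
  # unsorted windows are refused
  expect_error(window_scan(windows[c(2, 1, 3:10), ], trees, sm,
                           ingroup = c("A", "B", "C", "D"), n_rounds = 5),
               "ordering error")
})

test_that("support filter removes exactly the low-support windows", {
  mk <- function(s1, s2) {
    tr <- ape::read.tree(text = sprintf("(((A:1,B:1)%d:1,C:2)%d:1,D:3)root;",
                                        s1, s2))
    tr
  }
  sm <- stats::setNames(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  windows <- data.frame(chrom = "chr1", start = c(0, 5e4, 1e5),
                        end = c(1e4, 6e4, 11e4))
  trees <- list(mk(90, 80), mk(30, 40), mk(60, 45))
  scan <- window_scan(windows, trees, sm, ingroup = c("A", "B", "C", "D"),
                      n_rounds = 5, support_threshold = 50, seed = 1)
  expect_equal(scan$windows$mean_support, c(85, 35, 52.5))
  expect_equal(scan$windows$pass_support, c(TRUE, FALSE, TRUE))
})

test_that("genome-wide ranking and pairing classes behave", {
  keys <- enumerate_topologies(c("A", "B", "C", "D"))
  spectra <- matrix(0, 4, 15, dimnames = list(NULL, keys))
  spectra[, "(((A,B),C),D)"] <- 1          # all windows one asymmetric key
  windows <- data.frame(chrom = "chr1", start = (0:3) * 5e4,
                        end = (0:3) * 5e4 + 1e4)
  rk <- genome_topology_ranking(spectra, windows)
  expect_equal(rk$all$topologies$key[1], "(((A,B),C),D)")
  expect_equal(rk$all$topologies$freq[1], 1)
  expect_equal(unname(rk$all$pairings["AB"]), 1)
  # single-window input: ranking equals that window's spectrum
  rk1 <- genome_topology_ranking(spectra[1, , drop = FALSE], windows[1, ])
  expect_equal(rk1$all$topologies$freq, sort(spectra[1, ], decreasing = TRUE),
               ignore_attr = TRUE)
  # empty partition warns
  expect_warning(
    genome_topology_ranking(spectra, windows,
                            partitions = list(z = data.frame(chrom = "chrZ",
                                                             start = 0,
                                                             end = 1e6))),
    "empty partition")
})

test_that("mean gsi rises as Ne falls (accelerated lineage sorting)", {
  mean_gsi <- function(N, seed) {
    dem <- demography(species = c("A", "B"), topology = "(A,B);",
                      split_times = c(AB = 2e5), ne = c(A = N, B = N),
                      ne_anc = c(AB = N), mu = 2.5e-9)
    des <- sample_design(haplotypes_per_species = 4, n_loci = 60, seed = seed)
    trees <- simulate_gene_trees(dem, des)
    cfg <- quartetcoal:::lineage_config(dem, des)
    sm <- stats::setNames(cfg$species, cfg$labels)
    mean(vapply(trees, function(tr) gsi(tr, "A", sm), 0))
  }
  g <- vapply(c(2e5, 5e4, 1e4), mean_gsi, 0, seed = 77)
  expect_true(all(diff(g) > 0))
})

test_that("coverage-based subsampling keeps the highest-coverage leaves", {
  tr <- ape::read.tree(text = "(((a1:1,a2:1):1,(a3:1,b1:1):1):1,(b2:1,b3:1):1);")
  sm <- stats::setNames(c("A", "A", "A", "B", "B", "B"), tr$tip.label)
  cov <- c(a1 = 30, a2 = 5, a3 = 20, b1 = 8, b2 = 25, b3 = 9)
  pruned <- quartetcoal:::prune_by_coverage(tr, sm, c("A", "B"), cov, k = 2)
  expect_setequal(pruned$tip.label, c("a1", "a3", "b2", "b3"))
  # through window_scan: a four-species tree pruned to one leaf per species
  tr4 <- ape::read.tree(text = paste0("((((a1:1,a2:1):1,(b1:1,b2:1):1):1,",
                                      "(c1:1,c2:1):2):1,(d1:1,d2:1):3);"))
  sm4 <- stats::setNames(rep(c("A", "B", "C", "D"), each = 2), tr4$tip.label)
  cov4 <- stats::setNames(c(9, 1, 1, 9, 9, 1, 1, 9), tr4$tip.label)
  windows <- data.frame(chrom = "c", start = 0, end = 1e4)
  scan <- window_scan(windows, list(tr4), sm4,
                      ingroup = c("A", "B", "C", "D"), n_rounds = 5,
                      coverage = cov4, max_per_species = 1, seed = 1)
  # with one leaf per species the spectrum is the pruned tree's topology
  expect_equal(unname(scan$spectra[1, "(((A,B),C),D)"]), 1)
  expect_true(is.na(scan$windows$gsi_A))   # < 2 focal leaves after pruning
})
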