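test_that("polarization follows the two-outgroup parsimony rule", {
  og1 <- rbind(c("A", "A"), c("A", "G"), c("A", "A"), c("A", "."),
               c("G", "G"))
  og2 <- rbind(c("A", "A"), c("A", "A"), c("G", "G"), c("A", "A"),
               c("G", "G"))
  anc <- polarize(og1, og2)
  expect_equal(anc, c("A", NA, NA, NA, "G"))
})

test_that("site filters apply each rule with audit counts", {
  # 40 clean sites plus one violator of each rule
  n0 <- 40
  sites <- data.frame(
    mq = rep(30, n0), coverage = rep(c(9, 11), n0 / 2),
    callable_A = rep(12, n0), callable_B = rep(12, n0),
    allhet_A = FALSE, allhet_B = FALSE)
  sites <- rbind(sites,
                 data.frame(mq = c(10, 30, 30, 30),
                            coverage = c(10, 10, 500, 10),
                            callable_A = c(12, 5, 12, 12),
                            callable_B = 12,
                            allhet_A = c(FALSE, FALSE, FALSE, TRUE),
                            allhet_B = FALSE))
  res <- filter_sites(sites)
  expect_equal(unname(res$audit), c(1L, 1L, 1L, 1L))
  expect_equal(res$pass, c(rep(TRUE, n0), rep(FALSE, 4)))
  # all thresholds disabled: everything passes
  res0 <- filter_sites(sites, min_mq = NULL, min_callable = NULL,
                       max_cov_sd = NULL, exclude_allhet = FALSE)
  expect_true(all(res0$pass))
  # exclusion is strictly-greater: sites at or below the threshold stay
  s2 <- data.frame(mq = 30, coverage = c(rep(c(9, 11), 10), 30),
                   callable_A = 12, allhet_A = FALSE)
  thr <- mean(s2$coverage) + 2 * sd(s2$coverage)
  res2 <- filter_sites(s2, max_cov_sd = 2)
  expect_equal(res2$pass, s2$coverage <= thr)
  expect_false(res2$pass[21])
})

test_that("allele sharing partitions polarized sites into 15 cells", {
  haps <- paste0(rep(c("C", "P", "A", "S"), each = 2), "_", 1:2)
  sm <- stats::setNames(rep(c("C", "P", "A", "S"), each = 2), haps)
  sp <- c("C", "P", "A", "S")
  geno <- rbind(
    c(1, 1, 1, 1, 1, 1, 1, 1),    # all four species
    c(1, 0, 0, 0, 0, 0, 0, 0),    # C only
    c(0, 0, 1, 1, 1, 0, 0, 0),    # P and A
    c(1, 0, 1, 0, 1, 0, 1, 0),    # all four
    c(0, 0, 0, 0, 0, 0, 0, 1))    # S only
  colnames(geno) <- haps
  res <- allele_sharing(geno, sm, sp)
  expect_equal(unname(res$cells[quartetcoal:::clade_key(sp)]), 2L)
  expect_equal(unname(res$cells["C"]), 1L)
  expect_equal(unname(res$cells["AP"]), 1L)
  expect_equal(unname(res$cells["S"]), 1L)
  expect_equal(sum(res$cells), 5)
  # unpolarized rows are skipped and counted
  res2 <- allele_sharing(geno, sm, sp, polarized = c(TRUE, TRUE, FALSE,
                                                     TRUE, NA))
  expect_equal(res2$skipped, 2L)
  expect_equal(sum(res2$cells), 3)
})

test_that("diversity matches direct pairwise counting", {
  expect_error(diversity(matrix(1, 2, 1), 10), "undefined")
  g0 <- matrix(0, 3, 4)
  expect_equal(diversity(g0, 100)$pi, 0)
  expect_equal(diversity(g0, 100)$theta_w, 0)
  # 2 haplotypes, k differences over L
  g2 <- cbind(rep(1, 5), rep(0, 5))
  expect_equal(diversity(g2, 50)$pi, 5 / 50)
  # 5-haplotype fixture vs brute-force oracle
  g <- random_geno(12, paste0("h", 1:5), seed = 4)
  d <- diversity(g, 200)
  expect_equal(d$pi, pi_oracle(g, 200))
  expect_equal(d$theta_w, sum(apply(g, 1, function(x) length(unique(x)) > 1)) /
                 (sum(1 / (1:4)) * 200))
})

test_that("pair statistics match independent brute-force computation", {
  gA <- random_geno(15, paste0("a", 1:4), p = 0.4, seed = 11)
  gB <- random_geno(15, paste0("b", 1:4), p = 0.2, seed = 12)
  st <- pair_stats(gA, gB, 300)
  expect_equal(st$dxy, dxy_oracle(gA, gB, 300))
  expect_equal(st$phist, phist_oracle(gA, gB))
  # definitional checks
  k <- rowSums(cbind(gA, gB)); m <- 8
  expect_equal(st$S, sum(k > 0 & k < m))
  # fixed differences at every variable site give fixed = 1 and PhiST = 1
  gA2 <- matrix(1, 4, 3); gB2 <- matrix(0, 4, 3)
  st2 <- pair_stats(gA2, gB2, 100)
  expect_equal(st2$fixed, 1)
  expect_equal(st2$phist, 1)
  expect_equal(st2$shared, 0)
  # PhiST invariant to haplotype ordering
  st3 <- pair_stats(gA[, c(3, 1, 4, 2)], gB[, c(2, 4, 1, 3)], 300)
  expect_equal(st3$phist, st$phist)
  # PhiST is exactly zero when the among-group mean square equals the
  # within-group mean square (variance-component zero point)
  gA4 <- cbind(c(0, 0), c(1, 0)); gB4 <- cbind(c(0, 0), c(0, 1))
  expect_equal(pair_stats(gA4, gB4, 10)$phist, 0)
  expect_equal(phist_oracle(gA4, gB4), 0)
})

test_that("dXY is bounded below by within-species diversity under isolation", {
  dem <- toy_demography(2, N = 2e4, t_split = 3e5)
  des <- sample_design(haplotypes_per_species = 6, n_loci = 300,
                       locus_length = 2000, seed = 19)
  per_locus <- quartetcoal:::simulate_pair_stat_matrix(dem, des)
  dxy <- mean(per_locus[, "dxy_A-B"])
  # E[dxy] = 2*T*mu + 4*N*mu under isolation; within-species pi = 4*N*mu
  expect_gt(dxy, 4 * 2e4 * 2.5e-9)
})

test_that("the summary vector has 60 fixed-order labeled statistics", {
  dem <- candidate_demographies(1)
  des <- sample_design(haplotypes_per_species = 4, n_loci = 6,
                       locus_length = 500, seed = 23)
  st <- emit_study(dem, des)
  sv <- summary_vector(st)
  expect_length(sv, 60)
  expect_equal(names(sv)[1:2], c("mean_S_C-P", "var_S_C-P"))
  expect_equal(names(sv)[59:60], c("mean_phist_A-S", "var_phist_A-S"))
  # duplicated single locus: all variances zero
  genos <- quartetcoal:::study_locus_genos(st)
  sv2 <- summary_vector(rep(genos[1], 3),
                        stats::setNames(st$species_map$species,
                                        st$species_map$haplotype),
                        dem$species, 500)
  expect_true(all(sv2[grep("^var", names(sv2))] == 0, na.rm = TRUE))
  expect_error(summary_vector(genos[1],
                              stats::setNames(st$species_map$species,
                                              st$species_map$haplotype),
                              dem$species, 500),
               "need >= 2 loci")
})

test_that("3-locus moments match hand computation", {
  haps <- c("a1", "a2", "b1", "b2")
  sm <- stats::setNames(c("A", "A", "B", "B"), haps)
  g1 <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list(NULL, haps))
  g2 <- matrix(c(1, 1, 0, 0,
                 0, 1, 1, 0), 2, 4, byrow = TRUE,
               dimnames = list(NULL, haps))
  g3 <- matrix(numeric(0), 0, 4, dimnames = list(NULL, haps))
  sv <- summary_vector(list(g1, g2, g3), sm, c("A", "B"), 100)
  S <- c(1, 2, 0)
  expect_equal(unname(sv["mean_S_A-B"]), mean(S))
  expect_equal(unname(sv["var_S_A-B"]), var(S))
  dxy <- c((1 * 2 + 0) / 4 / 100, ((2 * 2) + (1 * 1 + 1 * 1)) / 4 / 100, 0)
  expect_equal(unname(sv["mean_dxy_A-B"]), mean(dxy))
})

test_that("fused compiled statistics agree with the genotype-matrix route", {
  dem <- candidate_demographies(1)
  des <- sample_design(haplotypes_per_species = 6, n_loci = 400,
                       locus_length = 1000, seed = 31)
  a <- quartetcoal:::simulate_summary_vector(dem, des, engine = "cpp")
  b <- quartetcoal:::simulate_summary_vector(dem, des, engine = "r")
  expect_identical(names(a), names(b))
  means <- grep("^mean", names(a), value = TRUE)
  # independent random streams: agreement within sampling error of 400 loci
  for (nm in means) {
    scale <- max(abs(b[nm]), 1e-4)
    expect_lt(abs(a[nm] - b[nm]) / scale, 0.25)
  }
})
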