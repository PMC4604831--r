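# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's internal code paths: oracles are written
# from the definitions, so agreement is evidence, not tautology.

# gsi oracle: minimal spanning subtree of the focal leaves via all-pairs
# node paths (ape::nodepath), degrees read off the edge table.
gsi_oracle <- function(tree, focal_species, species_map) {
  sp <- species_map[tree$tip.label]
  focal <- which(sp == focal_species)
  n <- length(focal)
  ntip <- length(tree$tip.label)
  nodes <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    nodes <- union(nodes, ape::nodepath(tree, focal[i], focal[j]))
  internal <- nodes[nodes > ntip]
  degree <- function(nd) sum(tree$edge == nd)
  gs <- (n - 1) / sum(vapply(internal, degree, 0) - 2)
  all_internal <- (ntip + 1):(ntip + tree$Nnode)
  gs_min <- (n - 1) / sum(vapply(all_internal, degree, 0) - 2)
  (gs - gs_min) / (1 - gs_min)
}

# PhiST oracle: explicit AMOVA sums of squares from a haplotype distance
# matrix computed by double loop.
phist_oracle <- function(genoA, genoB) {
  G <- cbind(genoA, genoB)
  n1 <- ncol(genoA); n2 <- ncol(genoB); N <- n1 + n2
  d <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    d[i, j] <- sum(G[, i] != G[, j])
  grp <- rep(1:2, c(n1, n2))
  ss_total <- sum(d[upper.tri(d)]) / N
  ss_within <- 0
  for (g in 1:2) {
    idx <- which(grp == g)
    dg <- d[idx, idx]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
  }
  ms_among <- (ss_total - ss_within) / 1
  ms_within <- ss_within / (N - 2)
  n_c <- N - (n1^2 + n2^2) / N
  s_a <- (ms_among - ms_within) / n_c
  s_a / (s_a + ms_within)
}

# pi oracle: mean pairwise difference by double loop over haplotypes
pi_oracle <- function(geno, L) {
  n <- ncol(geno)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(geno[, i] != geno[, j])
    np <- np + 1
  }
  tot / np / L
}

# dXY oracle: mean between-species per-site difference by double loop
dxy_oracle <- function(genoA, genoB, L) {
  tot <- 0; np <- 0
  for (i in seq_len(ncol(genoA))) for (j in seq_len(ncol(genoB))) {
    tot <- tot + sum(genoA[, i] != genoB[, j])
    np <- np + 1
  }
  tot / np / L
}

# sort-based percentile oracle (linear interpolation of order statistics)
percentile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# a reproducible random 0/1 genotype matrix
random_geno <- function(n_sites, haps, p = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * length(haps), 1, p), n_sites, length(haps))
  colnames(m) <- haps
  m
}

# small two-species panmictic-style demography for fast simulations
toy_demography <- function(n_species = 2, N = 2e4, t_split = 5e4,
                           migration = numeric(0)) {
  if (n_species == 1)
    return(demography(species = "A", topology = NULL,
                      split_times = numeric(0), ne = c(A = N),
                      ne_anc = numeric(0), mu = 2.5e-9))
  if (n_species == 2)
    return(demography(species = c("A", "B"), topology = "(A,B);",
                      split_times = c(AB = t_split), ne = c(A = N, B = N),
                      ne_anc = c(AB = N), migration = migration, mu = 2.5e-9))
  demography(species = c("A", "B", "C"), topology = "((A,B),C);",
             split_times = c(AB = t_split, ABC = 2 * t_split),
             ne = c(A = N, B = N, C = N), ne_anc = c(AB = N, ABC = N),
             migration = migration, mu = 2.5e-9)
}

# canonical keys of a batch of simulated one-lineage-per-species genealogies
simulated_keys <- function(dem, n_rep, seed) {
  ep <- quartetcoal:::compile_epochs(dem)
  set.seed(seed)
  sim <- quartetcoal:::sim_coal_batch_cpp(as.integer(ep$pop_of), ep,
                                          as.integer(n_rep))
  vapply(seq_len(n_rep), function(r)
    canonical_key(quartetcoal:::pt_to_phylo(sim$parent[r, ], sim$time[r, ],
                                            dem$species)), "")
}
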