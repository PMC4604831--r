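#' Sampling design for a synthetic study
#'
#' @param haplotypes_per_species integer, or named integer per species:
#'   haploid sequences sampled per ingroup species (>= 2 each).
#' @param n_loci number of unlinked loci.
#' @param locus_length locus length in bp.
#' @param locus_spacing nominal spacing between loci in bp (used only to lay
#'   loci out on a synthetic coordinate system; loci are simulated unlinked).
#' @param include_outgroups logical; sample one diploid individual (two
#'   haplotypes) from each outgroup species.
#' @param seed master RNG seed; per-locus streams are derived from it.
#' @return object of class `"sample_design"`.
#' @export
sample_design <- function(haplotypes_per_species = 24, n_loci = 100,
                          locus_length = 2000, locus_spacing = 50000,
                          include_outgroups = FALSE, seed = 1) {
  if (any(haplotypes_per_species < 2))
    stop("invalid-design: need >= 2 haplotypes per ingroup species")
  if (locus_length < 1) stop("invalid-design: locus_length must be >= 1")
  if (n_loci < 1) stop("invalid-design: need at least one locus")
  structure(list(haplotypes_per_species = haplotypes_per_species,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 locus_spacing = as.integer(locus_spacing),
                 include_outgroups = isTRUE(include_outgroups),
                 seed = as.integer(seed)),
            class = "sample_design")
}

# Haplotype labels and per-lineage species/population assignment.
# Labels follow SPECIES_individual_hap, e.g. "C_003_1".
lineage_config <- function(dem, design) {
  hps <- design$haplotypes_per_species
  if (is.null(names(hps)))
    hps <- stats::setNames(rep(hps[[1]], length(dem$species)), dem$species)
  labs <- character(0); sp <- character(0)
  for (s in dem$species) {
    h <- hps[[s]]
    ind <- rep(seq_len(ceiling(h / 2)), each = 2)[seq_len(h)]
    hap <- ave(ind, ind, FUN = seq_along)
    labs <- c(labs, sprintf("%s_%03d_%d", s, ind, hap))
    sp <- c(sp, rep(s, h))
  }
  if (design$include_outgroups) {
    if (is.null(dem$outgroups))
      stop("design requests outgroups but the demography has none")
    for (s in dem$outgroups$label) {
      labs <- c(labs, sprintf("%s_%03d_%d", s, 1L, 1:2))
      sp <- c(sp, rep(s, 2))
    }
  }
  list(labels = labs, species = sp)
}

#' Simulate one gene genealogy under a demography
#'
#' Runs the structured coalescent backward in time: lineages coalesce within
#' populations at rate C(k,2)/(2 Ne), migrate between extant species at
#' backward rate Nm/(2 Ne_recipient), and populations merge at species splits.
#' Branch lengths are in generations.
#'
#' @param dem a [demography()].
#' @param design a [sample_design()].
#' @param locus_index locus number (>= 1); combined with `design$seed` to give
#'   a deterministic per-locus random stream.
#' @return a rooted `phylo` genealogy with tip labels `SPECIES_ind_hap`.
#' @export
simulate_genealogy <- function(dem, design, locus_index = 1) {
  cfg <- lineage_config(dem, design)
  ep <- compile_epochs(dem, include_outgroups = design$include_outgroups)
  lin_pop <- ep$pop_of[cfg$species]
  set.seed(derive_seed(design$seed, locus_index))
  sim <- sim_coal_batch_cpp(as.integer(lin_pop), ep, 1L)
  pt_to_phylo(sim$parent[1, ], sim$time[1, ], cfg$labels)
}

# derive a per-stream seed < 2^31 from a master seed and an index
derive_seed <- function(master, i) {
  as.integer(((as.double(master) %% 65521) * 31771 +
                (as.double(i) %% 65521) * 271 + 13) %% 2147483647)
}

#' Simulate a batch of independent gene genealogies
#'
#' @inheritParams simulate_genealogy
#' @param n_rep number of independent genealogies.
#' @param as_phylo return `phylo` objects (default) or the raw parent/time
#'   matrices from the compiled core.
#' @return list of `phylo` trees, or the raw batch.
#' @export
simulate_gene_trees <- function(dem, design, n_rep = design$n_loci,
                                as_phylo = TRUE) {
  cfg <- lineage_config(dem, design)
  ep <- compile_epochs(dem, include_outgroups = design$include_outgroups)
  lin_pop <- ep$pop_of[cfg$species]
  set.seed(design$seed)
  sim <- sim_coal_batch_cpp(as.integer(lin_pop), ep, as.integer(n_rep))
  if (!as_phylo) return(c(sim, list(labels = cfg$labels)))
  lapply(seq_len(n_rep), function(r)
    pt_to_phylo(sim$parent[r, ], sim$time[r, ], cfg$labels))
}

# Convert parent-pointer/node-time output of the compiled simulator into an
# ape phylo. Tips are 0..n-1 (0-based), internal nodes in coalescence order,
# root last.
pt_to_phylo <- function(parent, tnode, tip_labels) {
  n <- length(tip_labels)
  nn <- 2L * n - 1L
  # ape numbering: tips 1..n, root n+1, other internal nodes arbitrary
  map <- integer(nn)
  map[seq_len(n)] <- seq_len(n)
  map[(n + 1):nn] <- (n + 1L) + rev(seq_len(n - 1L)) - 1L  # root (last) -> n+1
  child <- seq_len(nn)[-nn]
  edge <- cbind(map[parent[child] + 1L], map[child])
  len <- tnode[parent[child] + 1L] - tnode[child]
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = tip_labels, Nnode = n - 1L),
                  class = "phylo", order = "postorder")
  ape::reorder.phylo(tr, "cladewise")
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places a Poisson(mu * L * total branch length) number of biallelic
#' mutations on the genealogy, each assigned to a branch with probability
#' proportional to its length and to a distinct position (uniform with
#' collision redraw). Derived carriers are exactly the tips below the mutated
#' branch.
#'
#' @param tree rooted `phylo` with branch lengths in generations.
#' @param mu mutation rate per site per generation.
#' @param length locus length in bp.
#' @param seed optional integer seed.
#' @return data.frame-free list: `pos` (1-based, sorted), `anc`, `der`
#'   (nucleotides), and `geno`, a sites x haplotypes 0/1 matrix with tip
#'   labels as column names.
#' @export
drop_mutations <- function(tree, mu, length, seed = NULL) {
  if (mu < 0 || length < 0) stop("invalid-parameter: mu and length must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- base::length(tree$tip.label)
  pt <- phylo_to_pt(tree)
  res <- drop_mutations_cpp(pt$parent, pt$time, n, as.integer(length), mu)
  k <- base::length(res$pos)
  ord <- order(res$pos)
  geno <- res$geno[ord, , drop = FALSE]
  colnames(geno) <- tree$tip.label
  anc <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  list(pos = res$pos[ord], anc = anc, der = unname(der), geno = geno)
}

# Inverse of pt_to_phylo: parent pointers (0-based) and node times from a
# phylo with branch lengths.
phylo_to_pt <- function(tr) {
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  parent <- rep(-1L, nn)
  parent[tr$edge[, 2]] <- tr$edge[, 1] - 1L
  # node times: height above the tips, from root depths
  depth <- ape::node.depth.edgelength(tr)
  tmax <- max(depth)
  tnode <- tmax - depth
  list(parent = parent, time = tnode)
}

#' Generate a complete synthetic study
#'
#' Simulates `design$n_loci` unlinked genealogies under the demography, drops
#' infinite-sites mutations, and assembles per-locus haplotype alignments and
#' a polarized variant table with the true ancestral state recorded. With
#' outgroups included, outgroup sequences carry the true ancestral allele at
#' every ingroup SNP (plus mutations private to the outgroup lineages).
#'
#' @param dem a [demography()].
#' @param design a [sample_design()].
#' @param out_dir optional directory; when given, writes `trees.nwk` (one
#'   newick per line), `alignments/locus_XXXX.fa`, `variants.tsv` and
#'   `species_map.tsv`.
#' @return object of class `"synthetic_study"`: `genealogies` (phylo list),
#'   `alignments` (list of character matrices, haplotypes x sites),
#'   `variants` (data.frame: chrom, pos, anc, der, one 0/1 column per
#'   haplotype), `species_map`, `truth` (the demography), `design`.
#' @export
emit_study <- function(dem, design, out_dir = NULL) {
  trees <- simulate_gene_trees(dem, design)
  cfg <- lineage_config(dem, design)
  L <- design$locus_length
  aln <- vector("list", design$n_loci)
  vr <- vector("list", design$n_loci)
  for (i in seq_len(design$n_loci)) {
    mu_res <- drop_mutations(trees[[i]], dem$mu, L,
                             seed = derive_seed(design$seed + 1L, i))
    set.seed(derive_seed(design$seed + 2L, i))
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (length(mu_res$pos)) bases[mu_res$pos] <- mu_res$anc
    m <- matrix(rep(bases, each = length(cfg$labels)),
                nrow = length(cfg$labels), ncol = L,
                dimnames = list(cfg$labels, NULL))
    if (length(mu_res$pos)) {
      for (k in seq_along(mu_res$pos))
        m[mu_res$geno[k, ] == 1L, mu_res$pos[k]] <- mu_res$der[k]
    }
    aln[[i]] <- m
    if (length(mu_res$pos)) {
      g <- mu_res$geno
      colnames(g) <- cfg$labels
      vr[[i]] <- data.frame(chrom = sprintf("locus_%04d", i),
                            pos = mu_res$pos, anc = mu_res$anc,
                            der = mu_res$der, g, check.names = FALSE)
    }
  }
  variants <- do.call(rbind, vr)
  if (is.null(variants)) {              # a study can be monomorphic
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           anc = character(0), der = character(0))
    for (h in cfg$labels) variants[[h]] <- numeric(0)
  }
  rownames(variants) <- NULL
  species_map <- data.frame(haplotype = cfg$labels, species = cfg$species)
  study <- structure(list(genealogies = trees, alignments = aln,
                          variants = variants, species_map = species_map,
                          truth = dem, design = design),
                     class = "synthetic_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$genealogies), "loci x",
      nrow(x$species_map), "haplotypes;",
      if (is.null(x$variants)) 0 else nrow(x$variants), "SNPs\n")
  invisible(x)
}

#' Simulate observed joint SFS counts directly
#'
#' Fast path used for composite-likelihood experiments: simulates independent
#' 100-bp-style windows under the demography and tallies derived-allele
#' configurations into the six pairwise joint spectra, including the
#' monomorphic cells.
#'
#' @param dem a [demography()].
#' @param n_per_species haploid sample size per species (chromosomes).
#' @param n_windows number of independent windows.
#' @param window_bp window length in bp.
#' @param seed integer seed.
#' @return list of `sfs2d` objects, one per unordered species pair, named
#'   `"X-Y"`.
#' @export
simulate_sfs_counts <- function(dem, n_per_species = 24, n_windows = 1000,
                                window_bp = 100, seed = 1) {
  ep <- compile_epochs(dem, include_outgroups = FALSE)
  sp <- rep(seq_along(dem$species) - 1L, each = n_per_species)
  lin_pop <- rep(ep$pop_of[dem$species], each = n_per_species)
  pairs <- utils::combn(seq_along(dem$species), 2)
  set.seed(seed)
  res <- obs_sfs_cpp(as.integer(lin_pop), ep, as.integer(sp),
                     length(dem$species),
                     as.integer(pairs[1, ] - 1L), as.integer(pairs[2, ] - 1L),
                     as.integer(n_windows), as.integer(window_bp), dem$mu)
  out <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    a <- dem$species[pairs[1, q]]; b <- dem$species[pairs[2, q]]
    out[[q]] <- sfs2d(res$counts[[q]], pair = c(a, b),
                      total_sites = res$total_sites)
  }
  names(out) <- vapply(seq_len(ncol(pairs)), function(q)
    paste(dem$species[pairs[, q]], collapse = "-"), "")
  out
}

# Write study artifacts to disk (newick, FASTA, TSV).
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  ape::write.tree(do.call(c, study$genealogies),
                  file = file.path(out_dir, "trees.nwk"))
  for (i in seq_along(study$alignments))
    write_fasta_matrix(study$alignments[[i]],
                       file.path(out_dir, sprintf("alignments/locus_%04d.fa", i)))
  write_variants(study$variants, file.path(out_dir, "variants.tsv"))
  utils::write.table(study$species_map,
                     file.path(out_dir, "species_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(out_dir)
}
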