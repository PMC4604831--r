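#' Topology spectrum of a gene tree by leaf subsampling
#'
#' Repeatedly samples one leaf per species (including outgroups), roots the
#' subsampled tree on the deepest outgroup leaf, and records the canonical
#' rooted topology key of the ingroup species. Frequencies are normalized by
#' the number of rounds; rounds hitting a polytomy are flagged, not counted.
#'
#' @param tree `phylo` gene tree with one or more leaves per species.
#' @param species_map named character vector leaf -> species.
#' @param ingroup character vector of ingroup species.
#' @param outgroups character vector of outgroup species present in the tree;
#'   `NULL` if the tree is already rooted and no outgroup rooting is wanted.
#' @param n_rounds subsampling rounds (reference setting 200).
#' @param seed integer seed.
#' @param rooted record rooted (default) or unrooted keys.
#' @return object of class `"topology_spectrum"`: named frequency vector over
#'   the enumerated key set, plus counts, rounds used, and the number of
#'   unresolved (polytomy) rounds.
#' @export
subsample_spectrum <- function(tree, species_map, ingroup,
                               outgroups = NULL, n_rounds = 200, seed = 1,
                               rooted = TRUE) {
  sp <- species_map[tree$tip.label]
  if (anyNA(sp)) stop("leaf without species assignment")
  need <- c(ingroup, outgroups)
  if (!all(need %in% sp)) {
    if (rooted && length(outgroups) && !all(outgroups %in% sp))
      stop("rooting error: no outgroup leaf present")
    stop("species missing from tree: ", paste(setdiff(need, sp), collapse = ","))
  }
  keys <- enumerate_topologies(ingroup, rooted = rooted)
  counts <- stats::setNames(numeric(length(keys)), keys)
  unresolved <- 0L
  leaves_by_sp <- split(tree$tip.label, sp)
  set.seed(seed)
  for (r in seq_len(n_rounds)) {
    pick <- vapply(need, function(s) {
      lv <- leaves_by_sp[[s]]
      if (length(lv) == 1) lv else lv[sample.int(length(lv), 1)]
    }, "")
    k <- tryCatch(
      subsampled_key(tree, pick, species_map, ingroup, outgroups, rooted),
      quartetcoal_polytomy = function(e) NA_character_)
    if (is.na(k)) unresolved <- unresolved + 1L else
      counts[k] <- counts[k] + 1
  }
  used <- n_rounds - unresolved
  structure(list(freq = if (used > 0) counts / used else counts * NA,
                 counts = counts, n_rounds = used, unresolved = unresolved,
                 ingroup = ingroup, rooted = rooted),
            class = "topology_spectrum")
}

# Key of one subsampled leaf set: restrict, root on the deepest outgroup
# (oldest MRCA with the ingroup; ties broken by lexicographic label), drop
# outgroups, canonicalize.
subsampled_key <- function(tree, pick, species_map, ingroup, outgroups,
                           rooted = TRUE) {
  sub <- ape::keep.tip(tree, pick)
  sp <- species_map[sub$tip.label]
  if (length(outgroups)) {
    og_leaves <- sub$tip.label[sp %in% outgroups]
    if (length(og_leaves) > 1) {
      dp <- vapply(og_leaves, function(l) og_depth(sub, l), 0)
      og_leaves <- og_leaves[order(-dp, og_leaves)]
    }
    deepest <- og_leaves[1]
    sub <- ape::root(sub, outgroup = deepest, resolve.root = TRUE)
    sub <- ape::keep.tip(sub, sub$tip.label[species_map[sub$tip.label] %in% ingroup])
  }
  canonical_key(sub, species_map, rooted = rooted)
}

# Depth proxy for outgroup rooting: the root-ward distance of the leaf's
# attachment, measured as the leaf's total path length when branch lengths
# are present, otherwise its edge count from the root.
og_depth <- function(tr, leaf) {
  i <- match(leaf, tr$tip.label)
  if (!is.null(tr$edge.length)) ape::node.depth.edgelength(tr)[i]
  else -ape::node.depth(tr)[i]
}

#' Topology diversity index
#'
#' Normalized Simpson-type diversity of topology frequencies within a window:
#' tdi = (1 - sum p_i^2) / (1 - sum (1/I)^2), with I the number of possible
#' topologies for the species count. 0 when a single topology is present, 1
#' when all I topologies are equifrequent.
#'
#' @param spectrum a `"topology_spectrum"`, or a frequency vector over the
#'   full enumerated key set.
#' @return value in [0, 1], or `NA` for an empty spectrum.
#' @export
tdi <- function(spectrum) {
  p <- if (inherits(spectrum, "topology_spectrum")) spectrum$freq else spectrum
  if (!length(p) || anyNA(p) || sum(p) == 0) return(NA_real_)
  I <- length(p)
  (1 - sum(p^2)) / (1 - sum((1 / I)^2) * I)
}

#' Genealogical sorting index
#'
#' Degree of monophyly of the focal species' leaves on a rooted gene tree:
#' gs = (n-1) / sum(d_u - 2) over the internal nodes u of the minimal subtree
#' uniting the focal leaves from their most recent common ancestor (d_u = node
#' degree in the tree; the root has degree 2). The index rescales gs between
#' its minimum on the tree (all internal nodes needed) and its maximum of 1:
#' gsi = 1 exactly when the focal leaves are monophyletic.
#'
#' @param tree rooted binary `phylo`.
#' @param focal_species focal species label.
#' @param species_map named character vector leaf -> species.
#' @return value in [0, 1].
#' @export
gsi <- function(tree, focal_species, species_map) {
  sp <- species_map[tree$tip.label]
  focal <- which(sp == focal_species)
  n <- length(focal)
  if (n < 2) stop("undefined: gsi needs >= 2 focal leaves")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # path from each focal leaf to the MRCA: climb to root, then intersect
  paths <- lapply(focal, function(l) {
    p <- integer(0); nd <- l
    while (nd != root) { nd <- parent[nd]; p <- c(p, nd) }
    p
  })
  shared <- Reduce(intersect, paths)
  mrca <- shared[1]                      # closest shared ancestor
  union_nodes <- unique(unlist(lapply(paths, function(p)
    p[seq_len(match(mrca, p))])))        # internal nodes incl. the MRCA
  deg <- function(nodes) {
    nch <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)[nodes]
    nch + ifelse(nodes == root, 0L, 1L)
  }
  gs_obs <- (n - 1) / sum(deg(union_nodes) - 2)
  all_internal <- (ntip + 1L):(ntip + tree$Nnode)
  gs_min <- (n - 1) / sum(deg(all_internal) - 2)
  if (gs_min >= 1) return(1)             # degenerate tiny tree
  (gs_obs - gs_min) / (1 - gs_min)
}

#' Relative depth of the ingroup's common ancestor
#'
#' Height of the MRCA of all ingroup leaves divided by the height of the
#' root, heights measured as the maximum path length to a descendant leaf.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param ingroup character vector of ingroup species.
#' @param species_map named character vector leaf -> species.
#' @return value in [0, 1]; `NA` when branch lengths are absent.
#' @export
lca_relative_depth <- function(tree, ingroup, species_map) {
  if (is.null(tree$edge.length)) return(NA_real_)
  sp <- species_map[tree$tip.label]
  leaves <- which(sp %in% ingroup)
  ntip <- length(tree$tip.label)
  mrca <- if (length(leaves) == 1) leaves else ape::getMRCA(tree, leaves)
  depth <- ape::node.depth.edgelength(tree)      # distance from root
  height <- max(depth)                           # tree height (to deepest leaf)
  # height of a node = max distance to a descendant leaf
  node_height <- height_of(tree, depth)
  node_height[mrca] / node_height[ntip + 1L]
}

# per-node height: max path length to any descendant leaf
height_of <- function(tree, depth = ape::node.depth.edgelength(tree)) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  h <- rep(0, nn)
  # process edges child-major from deepest: accumulate max leaf depth
  maxleaf <- rep(-Inf, nn)
  maxleaf[seq_len(ntip)] <- depth[seq_len(ntip)]
  ed <- tree$edge[order(-depth[tree$edge[, 2]]), , drop = FALSE]
  for (e in seq_len(nrow(ed))) {
    a <- ed[e, 1]; b <- ed[e, 2]
    if (maxleaf[b] > maxleaf[a]) maxleaf[a] <- maxleaf[b]
  }
  maxleaf - depth
}

#' Windowed gene-tree discordance scan
#'
#' Computes per-window topology spectra, tdi, per-species gsi, relative LCA
#' depth and the mean support of the two internal species-defining branches,
#' then aggregates spectra over larger intervals (frequencies averaged across
#' member windows, tdi recomputed on the average).
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open), sorted within chromosomes.
#' @param trees list of `phylo`, one per window row.
#' @param species_map named character vector leaf -> species.
#' @param ingroup,outgroups species sets, as in [subsample_spectrum()].
#' @param n_rounds subsampling rounds per window.
#' @param aggregate_bp aggregation span (default 500 kb).
#' @param support_threshold windows whose mean internal support is below this
#'   are flagged (filter applied only when supports are present).
#' @param coverage optional named numeric vector (per haplotype): before any
#'   statistic is computed, each window's tree is pruned to the
#'   `max_per_species` highest-coverage leaves per ingroup species (ties by
#'   label). Default `NULL`: all leaves are used.
#' @param max_per_species leaves kept per ingroup species when `coverage`
#'   is supplied (default 5, matching a five-individuals-per-population
#'   subsampling rule).
#' @param seed integer seed.
#' @return list with `windows` (per-window stats data.frame), `spectra`
#'   (windows x keys frequency matrix), `aggregates` (per-aggregate tdi).
#' @export
window_scan <- function(windows, trees, species_map, ingroup,
                        outgroups = NULL, n_rounds = 200,
                        aggregate_bp = 5e5, support_threshold = NULL,
                        coverage = NULL, max_per_species = 5,
                        seed = 1) {
  stopifnot(nrow(windows) == length(trees))
  if (!is.null(coverage))
    trees <- lapply(trees, prune_by_coverage, species_map = species_map,
                    ingroup = ingroup, coverage = coverage,
                    k = max_per_species)
  for (ch in unique(windows$chrom)) {
    s <- windows$start[windows$chrom == ch]
    if (is.unsorted(s, strictly = TRUE))
      stop("ordering error: windows must be sorted within chromosomes")
  }
  keys <- enumerate_topologies(ingroup, rooted = TRUE)
  spectra <- matrix(0, nrow(windows), length(keys),
                    dimnames = list(NULL, keys))
  stats <- data.frame(windows,
                      tdi = NA_real_, lca_depth = NA_real_,
                      mean_support = NA_real_, pass_support = TRUE)
  for (s in ingroup) stats[[paste0("gsi_", s)]] <- NA_real_
  for (i in seq_len(nrow(windows))) {
    tr <- trees[[i]]
    spec <- subsample_spectrum(tr, species_map, ingroup, outgroups,
                               n_rounds = n_rounds,
                               seed = derive_seed(seed, i))
    spectra[i, ] <- spec$freq
    stats$tdi[i] <- tdi(spec)
    stats$lca_depth[i] <- lca_relative_depth(tr, ingroup, species_map)
    sp <- species_map[tr$tip.label]
    for (s in ingroup)
      if (sum(sp == s) >= 2)
        stats[[paste0("gsi_", s)]][i] <- gsi(tr, s, species_map)
    stats$mean_support[i] <- mean_internal_support(tr, species_map, ingroup,
                                                   outgroups, seed = derive_seed(seed + 1L, i))
  }
  if (!is.null(support_threshold))
    stats$pass_support <- is.na(stats$mean_support) |
      stats$mean_support >= support_threshold
  agg_id <- paste(windows$chrom, windows$start %/% aggregate_bp)
  agg <- vapply(split(seq_len(nrow(windows)), agg_id), function(idx) {
    tdi(colMeans(spectra[idx, , drop = FALSE]))
  }, 0)
  list(windows = stats, spectra = spectra,
       aggregates = data.frame(aggregate = names(agg), tdi = unname(agg)))
}

# Keep the k highest-coverage leaves per ingroup species (ties broken by
# label); leaves of other species (outgroups) are always kept.
prune_by_coverage <- function(tree, species_map, ingroup, coverage, k) {
  sp <- species_map[tree$tip.label]
  keep <- unlist(lapply(unique(sp), function(s) {
    lv <- tree$tip.label[sp == s]
    if (!(s %in% ingroup) || length(lv) <= k) return(lv)
    cv <- coverage[lv]
    cv[is.na(cv)] <- -Inf
    lv[order(-cv, lv)][seq_len(k)]
  }))
  ape::keep.tip(tree, keep)
}

# Mean support of the two internal species-defining branches of the
# one-leaf-per-species rooted tree, when node labels carry supports.
mean_internal_support <- function(tree, species_map, ingroup, outgroups,
                                  seed = 1) {
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label)))
    return(NA_real_)
  sp <- species_map[tree$tip.label]
  set.seed(seed)
  pick <- vapply(c(ingroup, outgroups), function(s) {
    lv <- tree$tip.label[sp == s]
    if (length(lv) == 1) lv else lv[sample.int(length(lv), 1)]
  }, "")
  sub <- tryCatch(ape::keep.tip(tree, pick), error = function(e) NULL)
  if (is.null(sub)) return(NA_real_)
  if (length(outgroups)) {
    og <- sub$tip.label[species_map[sub$tip.label] %in% outgroups]
    sub <- tryCatch(ape::root(sub, outgroup = og[1], resolve.root = TRUE),
                    error = function(e) NULL)
    if (is.null(sub)) return(NA_real_)
    sub <- ape::keep.tip(sub, sub$tip.label[species_map[sub$tip.label] %in% ingroup])
  }
  nl <- suppressWarnings(as.numeric(sub$node.label))
  ntip <- length(sub$tip.label)
  internal <- setdiff(seq_len(sub$Nnode) + ntip, ntip + 1L)  # non-root
  v <- nl[internal - ntip]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Genome-wide topology ranking by partition
#'
#' Averages window spectra within genomic partitions and ranks the rooted
#' topology keys, together with the frequencies of the species-pairing
#' classes (which pair forms a cherry; symmetric topologies contribute to
#' both of their pairings).
#'
#' @param spectra windows x keys frequency matrix (as from [window_scan()]).
#' @param windows matching data.frame of intervals (`chrom`,`start`,`end`).
#' @param partitions named list of interval data.frames, or `NULL` entries
#'   meaning all windows.
#' @param thin keep every other window (linkage thinning).
#' @return list per partition: `topologies` (ranked data.frame) and
#'   `pairings` (pairing-class frequencies).
#' @export
genome_topology_ranking <- function(spectra, windows, partitions = list(all = NULL),
                                    thin = FALSE) {
  out <- list()
  for (nm in names(partitions)) {
    part <- partitions[[nm]]
    idx <- if (is.null(part)) seq_len(nrow(windows)) else
      which(overlaps_any(windows, part))
    if (thin) idx <- idx[seq_along(idx) %% 2 == 1]
    if (!length(idx)) {
      warning("empty partition: ", nm)
      out[[nm]] <- list(topologies = data.frame(key = character(0),
                                                freq = numeric(0)),
                        pairings = numeric(0))
      next
    }
    fr <- colMeans(spectra[idx, , drop = FALSE], na.rm = TRUE)
    topo <- data.frame(key = names(fr), freq = unname(fr))
    topo <- topo[order(-topo$freq), ]
    rownames(topo) <- NULL
    pr <- numeric(0)
    for (k in names(fr))
      for (cp in cherry_pairs(k))
        pr[cp] <- (if (is.na(pr[cp][1])) 0 else pr[cp]) + fr[[k]]
    out[[nm]] <- list(topologies = topo, pairings = sort(pr, decreasing = TRUE))
  }
  out
}

# which interval rows of `windows` overlap any interval in `part`
overlaps_any <- function(windows, part) {
  vapply(seq_len(nrow(windows)), function(i) {
    any(part$chrom == windows$chrom[i] &
          part$start < windows$end[i] &
          part$end > windows$start[i])
  }, TRUE)
}
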