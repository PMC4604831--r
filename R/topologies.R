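#' Enumerate canonical leaf-labeled tree topologies
#'
#' Generates all distinct leaf-labeled binary topologies over a set of species
#' labels, as canonical keys. Rooted trees on n labels number (2n-3)!!;
#' unrooted trees (2n-5)!!. The canonical key of a rooted tree is its newick
#' string with children sorted lexicographically at every node; an unrooted
#' topology is keyed by rooting on the pendant edge of the smallest label.
#'
#' @param species character vector of species labels (3 to 6).
#' @param rooted logical.
#' @return character vector of canonical keys, sorted.
#' @export
enumerate_topologies <- function(species, rooted = TRUE) {
  if (is.numeric(species)) species <- LETTERS[seq_len(species)]
  n <- length(species)
  if (n < 3 || n > 6) stop("unsupported: 3 to 6 species required")
  species <- sort(species)
  if (rooted) {
    trees <- grow_rooted(species)
  } else {
    # unrooted tree <-> rooted tree with the smallest label as pendant root
    sub <- grow_rooted(species[-1])
    trees <- lapply(sub, function(s) list(species[1], s))
  }
  sort(vapply(trees, nest_key, ""))
}

# All rooted leaf-labeled binary trees, as nested lists, by edge insertion.
grow_rooted <- function(labels) {
  trees <- list(list(labels[1], labels[2]))
  for (lab in labels[-(1:2)]) {
    nxt <- list()
    for (tr in trees)
      nxt <- c(nxt, insert_leaf(tr, lab))
    trees <- nxt
  }
  trees
}

# Insert a leaf on every edge of a nested-list tree, including above the root.
insert_leaf <- function(tr, lab) {
  out <- list(list(tr, lab))
  if (!is.list(tr)) return(out)
  for (i in 1:2) {
    for (sub in insert_leaf(tr[[i]], lab)) {
      cp <- tr; cp[[i]] <- sub
      out <- c(out, list(cp))
    }
  }
  out
}

# Canonical key of a nested-list tree: children sorted at every node.
nest_key <- function(tr) {
  if (!is.list(tr)) return(tr)
  kids <- sort(c(nest_key(tr[[1]]), nest_key(tr[[2]])))
  paste0("(", kids[1], ",", kids[2], ")")
}

# phylo -> nested list of species labels; errors on polytomies.
phylo_to_nest <- function(tr, node = NULL, labels = tr$tip.label) {
  n <- length(tr$tip.label)
  if (is.null(node)) node <- n + 1L
  rec <- function(nd) {
    if (nd <= n) return(labels[nd])
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    if (length(ch) != 2)
      stop(structure(class = c("quartetcoal_polytomy", "error", "condition"),
                     list(message = "polytomy: tree is not strictly bifurcating",
                          call = sys.call(-1))))
    list(rec(ch[1]), rec(ch[2]))
  }
  rec(node)
}

#' Canonical topology key of a one-leaf-per-species gene tree
#'
#' Relabels the leaves by species and returns the canonical key, invariant
#' to branch lengths, child order and leaf identity within a species.
#'
#' @param tree rooted `phylo` with exactly one leaf per species.
#' @param species_map named character vector mapping leaf label to species
#'   (or NULL if leaves are already species labels).
#' @param rooted logical; if `FALSE` the key identifies the unrooted topology.
#' @return canonical key string.
#' @export
canonical_key <- function(tree, species_map = NULL, rooted = TRUE) {
  labs <- tree$tip.label
  sp <- if (is.null(species_map)) labs else unname(species_map[labs])
  if (anyNA(sp)) stop("incomplete-subsample: leaf with unknown species")
  if (anyDuplicated(sp))
    stop("incomplete-subsample: need exactly one leaf per species")
  if (!rooted) {
    root_sp <- sort(sp)[1]
    tree <- ape::root(tree, outgroup = labs[sp == root_sp],
                      resolve.root = TRUE)
    sp <- if (is.null(species_map)) tree$tip.label else
      unname(species_map[tree$tip.label])
  }
  nest_key(phylo_to_nest(tree, labels = sp))
}

#' Cherry pairs of a rooted topology key
#'
#' The species pairs that form cherries (two-leaf clades) in a canonical
#' rooted key; asymmetric four-taxon trees have one, symmetric trees two.
#' These define the "internal pairing" classes used in genome-wide topology
#' rankings.
#'
#' @param key canonical key string.
#' @return character vector of pair keys such as `"AP"` (sorted labels).
#' @export
cherry_pairs <- function(key) {
  m <- gregexpr("\\(([A-Za-z]),([A-Za-z])\\)", key)[[1]]
  if (m[1] == -1) return(character(0))
  starts <- as.integer(m); lens <- attr(m, "match.length")
  vapply(seq_along(starts), function(i) {
    s <- substr(key, starts[i], starts[i] + lens[i] - 1)
    clade_key(strsplit(gsub("[(),]", "", s), "")[[1]])
  }, "")
}

# Clade sets of a canonical key (all internal clades, as sorted keys).
key_clades <- function(key) {
  chars <- strsplit(key, "")[[1]]
  out <- character(0)
  stack <- list()
  cur <- character(0)
  depth <- 0
  members <- list()
  for (ch in chars) {
    if (ch == "(") {
      depth <- depth + 1
      members[[depth]] <- character(0)
    } else if (ch == ")") {
      out <- c(out, clade_key(members[[depth]]))
      if (depth > 1)
        members[[depth - 1]] <- c(members[[depth - 1]], members[[depth]])
      depth <- depth - 1
    } else if (ch != ",") {
      members[[depth]] <- c(members[[depth]], ch)
    }
  }
  out
}

# For a rooted key and a triple of species, which pair of the triple is the
# cherry in the restriction of the topology to the triple.
restricted_cherry <- function(key, triple) {
  clades <- key_clades(key)
  sets <- strsplit(clades, "")
  prs <- utils::combn(sort(triple), 2)
  third <- function(q) setdiff(triple, q)
  for (j in seq_len(ncol(prs))) {
    pr <- prs[, j]
    # smallest clade containing the pair
    has <- vapply(sets, function(s) all(pr %in% s), TRUE)
    sizes <- lengths(sets)
    sm <- sets[[which(has)[which.min(sizes[has])]]]
    if (!(third(pr) %in% sm)) return(clade_key(pr))
  }
  stop("no resolved cherry for triple (unexpected for a binary tree)")
}
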