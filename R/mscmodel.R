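#' Ranked coalescent histories of four lineages
#'
#' Enumerates the 18 ranked labeled histories of four lineages (one per
#' species): a sequence of three coalescence events, each merging two of the
#' currently active lineages. Under a star species tree (all internal branch
#' lengths zero) the exchangeable coalescent makes every ranked history
#' equally likely.
#'
#' @param species four species labels.
#' @return data.frame with one row per ranked history and its rooted
#'   topology key.
#' @export
ranked_histories <- function(species = c("A", "B", "C", "D")) {
  stopifnot(length(species) == 4)
  out <- list()
  rec <- function(active, steps) {
    if (length(active) == 1) {
      out[[length(out) + 1]] <<- list(steps = steps, key = nest_key(active[[1]]))
      return(invisible())
    }
    prs <- utils::combn(length(active), 2)
    for (j in seq_len(ncol(prs))) {
      i1 <- prs[1, j]; i2 <- prs[2, j]
      merged <- list(active[[i1]], active[[i2]])
      rec(c(active[-c(i1, i2)], list(merged)),
          c(steps, paste0(nest_key(active[[i1]]), "+", nest_key(active[[i2]]))))
    }
  }
  rec(as.list(sort(species)), character(0))
  data.frame(history = vapply(out, function(h) paste(h$steps, collapse = "; "), ""),
             key = vapply(out, `[[`, "", "key"))
}

#' Rooted topology probabilities under a star species tree
#'
#' With both internal branches of the species tree at length zero, all 18
#' ranked histories are uniform; each asymmetric (caterpillar) topology owns
#' one history (probability 1/18, about 5.6%) and each symmetric (balanced)
#' topology owns two (2/18, about 11.1%).
#'
#' @param species four species labels.
#' @return named probability vector over the 15 rooted keys (sums to 1).
#' @export
star_tree_topology_probs <- function(species = c("A", "B", "C", "D")) {
  h <- ranked_histories(species)
  tab <- table(h$key) / nrow(h)
  keys <- enumerate_topologies(species, rooted = TRUE)
  p <- stats::setNames(as.numeric(tab[keys]), keys)
  p[is.na(p)] <- 0
  p
}

#' Rooted-triple topology probabilities under the coalescent
#'
#' For a rooted three-species tree with internal branch length `t` in
#' coalescent units, the concordant gene-tree topology has probability
#' 1 - (2/3) exp(-t) and each discordant topology (1/3) exp(-t).
#'
#' @param t internal branch length, coalescent units (>= 0).
#' @return numeric c(concordant, discordant, discordant).
#' @export
triple_prob <- function(t) {
  if (any(t < 0)) stop("invalid: t must be >= 0")
  c(concordant = 1 - (2 / 3) * exp(-t),
    discordant1 = (1 / 3) * exp(-t),
    discordant2 = (1 / 3) * exp(-t))
}

#' Rooted-triple counts from a set of gene trees
#'
#' For each of the four species triples, counts how often each pair of the
#' triple is the cherry in the gene tree restricted to that triple.
#' Trees with unresolved (polytomous) triples contribute only their resolved
#' triples.
#'
#' @param trees list of rooted one-leaf-per-species `phylo` trees, or a
#'   character vector of canonical rooted keys.
#' @param species the four species labels.
#' @param species_map optional leaf -> species map for `phylo` input.
#' @return integer matrix, rows = triples (named by their clade key), columns
#'   = cherry pair keys of that triple.
#' @export
count_triples <- function(trees, species = c("A", "B", "C", "D"),
                          species_map = NULL) {
  species <- sort(species)
  keys <- if (is.character(trees)) trees else
    vapply(trees, function(tr)
      tryCatch(canonical_key(tr, species_map),
               quartetcoal_polytomy = function(e) NA_character_), "")
  triples <- utils::combn(species, 3)
  counts <- matrix(0L, 4, 3)
  rownames(counts) <- apply(triples, 2, clade_key)
  colnames(counts) <- paste0("pair", 1:3)
  pair_keys <- matrix("", 4, 3)
  for (ti in 1:4) {
    prs <- utils::combn(triples[, ti], 2)
    pair_keys[ti, ] <- apply(prs, 2, clade_key)
  }
  # memoize per observed full-tree key
  for (k in unique(keys[!is.na(keys)])) {
    nk <- sum(keys == k, na.rm = TRUE)
    for (ti in 1:4) {
      ch <- restricted_cherry(k, strsplit(rownames(counts)[ti], "")[[1]])
      counts[ti, match(ch, pair_keys[ti, ])] <-
        counts[ti, match(ch, pair_keys[ti, ])] + nk
    }
  }
  colnames(counts) <- NULL
  attr(counts, "pair_keys") <- pair_keys
  counts
}

#' Pseudo-likelihood species-tree estimation from rooted triples
#'
#' For each of the 15 candidate rooted four-taxon topologies, maximizes over
#' its two internal branch lengths (coalescent units) the product of
#' multinomial likelihoods of the four observed rooted-triple count vectors
#' under the coalescent triple probabilities, and returns the best candidate.
#' Branch lengths are optimized coordinate-wise by bounded golden-section
#' search (tolerance 1e-6). Candidates whose scores differ by less than 1e-9
#' from the best are reported as a tie set.
#'
#' @param trees gene trees (as in [count_triples()]) or a triple-count matrix
#'   with a `pair_keys` attribute.
#' @param species the four species labels.
#' @param species_map optional leaf -> species map.
#' @return object of class `"species_tree_fit"`: best `key`, `branch_lengths`,
#'   `logL`, `ties`, and `scores` over all 15 candidates.
#' @export
fit_species_tree <- function(trees, species = c("A", "B", "C", "D"),
                             species_map = NULL) {
  species <- sort(species)
  counts <- if (is.matrix(trees)) trees else
    count_triples(trees, species, species_map)
  if (sum(counts) == 0) stop("no-data: no resolved triples")
  pair_keys <- attr(counts, "pair_keys")
  cands <- enumerate_topologies(species, rooted = TRUE)
  res <- lapply(cands, function(key) fit_candidate(key, counts, pair_keys))
  logls <- vapply(res, `[[`, 0, "logL")
  best <- which.max(logls)
  ties <- which(logls >= logls[best] - 1e-9)
  structure(list(key = cands[best],
                 branch_lengths = res[[best]]$t,
                 logL = logls[best],
                 ties = cands[ties],
                 scores = stats::setNames(logls, cands)),
            class = "species_tree_fit")
}

#' @export
print.species_tree_fit <- function(x, ...) {
  cat("Pseudo-likelihood species tree:", x$key, "\n")
  cat("  internal branches (coalescent units):",
      paste(signif(x$branch_lengths, 4), collapse = ", "), "\n")
  cat("  log pseudo-likelihood:", format(x$logL), "\n")
  if (length(x$ties) > 1)
    cat("  TIE among:", paste(x$ties, collapse = "  "), "\n")
  invisible(x)
}

# Maximize the pseudo-likelihood of one candidate topology.
# The candidate's two non-root internal branches carry lengths t1, t2; each
# species triple restricted to the candidate has a concordant cherry and an
# internal length equal to the sum of the candidate branches between the
# cherry join and the triple MRCA.
fit_candidate <- function(key, counts, pair_keys) {
  all_cl <- key_clades(key)
  root_cl <- all_cl[which.max(nchar(all_cl))]
  internal <- setdiff(all_cl, root_cl)       # the two non-root internal clades
  triples <- rownames(counts)
  # mapping per triple: concordant column + coefficient on (t1, t2)
  conc_col <- integer(4); coefs <- matrix(0, 4, length(internal))
  sets <- strsplit(all_cl, "")
  for (ti in 1:4) {
    trip <- strsplit(triples[ti], "")[[1]]
    ch <- restricted_cherry(key, trip)
    conc_col[ti] <- match(ch, pair_keys[ti, ])
    # candidate clades on the path from the cherry join (inclusive) to the
    # triple MRCA (exclusive): their parent branches make up the triple's
    # internal branch
    pr <- strsplit(ch, "")[[1]]
    contains_pair <- vapply(sets, function(s) all(pr %in% s), TRUE)
    contains_trip <- vapply(sets, function(s) all(trip %in% s), TRUE)
    join_sz <- min(lengths(sets)[contains_pair])
    mrca_sz <- min(lengths(sets)[contains_trip])
    on_path <- contains_pair & lengths(sets) >= join_sz &
      lengths(sets) < mrca_sz
    coefs[ti, ] <- vapply(internal, function(cl)
      as.numeric(cl %in% all_cl[on_path]), 0)
  }
  negll <- function(t) {
    ll <- 0
    for (ti in 1:4) {
      tau <- sum(coefs[ti, ] * t)
      pc <- 1 - (2 / 3) * exp(-tau)
      pd <- (1 / 3) * exp(-tau)
      nc <- counts[ti, conc_col[ti]]
      nd <- sum(counts[ti, ]) - nc
      ll <- ll + nc * log(pc) + nd * log(pd)
    }
    -ll
  }
  t <- c(0.1, 0.1)
  for (it in 1:60) {
    told <- t
    for (j in 1:2) {
      opt <- stats::optimize(function(x) { tt <- t; tt[j] <- x; negll(tt) },
                             interval = c(0, 30), tol = 1e-8)
      t[j] <- opt$minimum
    }
    if (max(abs(t - told)) < 1e-6) break
  }
  list(t = t, logL = -negll(t))
}

#' Topology-recovery experiment for the pseudo-likelihood estimator
#'
#' Simulates one-lineage-per-species gene trees under each of the four
#' candidate demographies in turn and scores how often the pseudo-likelihood
#' species-tree fit recovers the generating topology.
#'
#' @param n_reps_per_model replicates per generating model.
#' @param n_loci gene trees per replicate.
#' @param seed integer seed.
#' @return data.frame: generating model index, replicate, inferred key, hit.
#' @export
mpl_recovery_experiment <- function(n_reps_per_model = 6, n_loci = 1000,
                                    seed = 1) {
  out <- NULL
  for (g in 1:4) {
    dem <- candidate_demographies(g)
    ep <- compile_epochs(dem)
    true_key <- canonical_key(ape::read.tree(text = dem$topology))
    for (r in seq_len(n_reps_per_model)) {
      set.seed(derive_seed(seed, g * 50L + r))
      sim <- sim_coal_batch_cpp(as.integer(ep$pop_of), ep, as.integer(n_loci))
      keys <- vapply(seq_len(n_loci), function(i)
        canonical_key(pt_to_phylo(sim$parent[i, ], sim$time[i, ],
                                  dem$species)), "")
      fit <- fit_species_tree(keys, dem$species)
      out <- rbind(out, data.frame(generating = g, replicate = r,
                                   inferred = fit$key,
                                   hit = fit$key == true_key &&
                                     length(fit$ties) == 1))
    }
  }
  out
}

#' Loci-resubsampling consistency of the species-tree fit
#'
#' Re-subsamples gene trees without replacement at a grid of locus counts and
#' reports, per grid value, the fraction of replicate fits whose topology
#' matches the fit on the complete set.
#'
#' @param trees gene trees or canonical keys (see [count_triples()]).
#' @param species four species labels.
#' @param grid locus counts to subsample.
#' @param n_reps replicates per grid value.
#' @param seed integer seed.
#' @param species_map optional leaf -> species map.
#' @return data.frame with `n_loci` and `prop_match`.
#' @export
resubsample_consistency <- function(trees, species = c("A", "B", "C", "D"),
                                    grid = c(10, 50, 200), n_reps = 100,
                                    seed = 1, species_map = NULL) {
  keys <- if (is.character(trees)) trees else
    vapply(trees, function(tr)
      tryCatch(canonical_key(tr, species_map),
               quartetcoal_polytomy = function(e) NA_character_), "")
  keys <- keys[!is.na(keys)]
  full <- fit_species_tree(keys, species)$key
  set.seed(seed)
  res <- lapply(grid, function(m) {
    if (m > length(keys)) {
      warning("grid value ", m, " exceeds available loci; skipped")
      return(NULL)
    }
    hits <- vapply(seq_len(n_reps), function(r) {
      sub <- sample(keys, m, replace = FALSE)
      fit_species_tree(sub, species)$key == full
    }, TRUE)
    data.frame(n_loci = m, prop_match = mean(hits))
  })
  do.call(rbind, res)
}
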