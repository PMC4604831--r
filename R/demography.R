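#' Isolation-with-migration demography for up to six species
#'
#' Describes a rooted species tree together with per-branch diploid effective
#' population sizes, split times in generations before present, directional
#' migration intensities between extant species, and a per-site per-generation
#' mutation rate. This is the generating model for the structured-coalescent
#' simulator and the parameter schema for demographic inference.
#'
#' Ancestral branches and split times are keyed by the sorted concatenation of
#' the member species labels (e.g. the ancestor of P and A is `"AP"`), and
#' migration rates by `"X<-Y"`, the number of migrants per generation entering
#' species X from species Y (forward in time).
#'
#' @param species character vector of ingroup species labels (single
#'   characters), in a fixed reference order.
#' @param topology rooted binary newick string over `species` (no branch
#'   lengths needed).
#' @param split_times named numeric, generations before present per internal
#'   clade; names are clade keys.
#' @param ne named numeric, current diploid Ne per species.
#' @param ne_anc named numeric, diploid Ne per ancestral branch (clade keys).
#' @param migration named numeric of Nm values (migrants/generation), names
#'   `"X<-Y"`; may be empty.
#' @param mu mutation rate per site per generation.
#' @param gen_time years per generation; used only to convert reported times,
#'   never internally. Default `NA` (unknown).
#' @param outgroups optional data.frame with columns `label`, `time`
#'   (generations, beyond the ingroup root), `ne` (Ne of the outgroup branch)
#'   and optionally `anc_ne` (Ne of the merged ancestor; defaults to the
#'   previous ancestral size).
#' @return an object of class `"demography"`.
#' @export
demography <- function(species, topology, split_times, ne, ne_anc,
                       migration = numeric(0), mu = 2.5e-9, gen_time = NA,
                       outgroups = NULL) {
  stopifnot(is.character(species), length(species) >= 1,
            !anyDuplicated(species))
  if (any(nchar(species) != 1))
    stop("species labels must be single characters")
  names(split_times) <- vapply(names(split_times), clade_key, "")
  names(ne_anc) <- vapply(names(ne_anc), clade_key, "")
  if (length(species) > 1) {
    tr <- ape::read.tree(text = topology)
    if (is.null(tr)) stop("could not parse topology newick")
    if (!setequal(tr$tip.label, species))
      stop("topology leaves must match the species labels")
    if (tr$Nnode != length(species) - 1)
      stop("topology must be a rooted binary tree")
    clades <- internal_clades(tr)
    if (!setequal(names(split_times), clades))
      stop("split_times must name exactly the internal clades: ",
           paste(clades, collapse = ", "))
    if (!setequal(names(ne_anc), clades))
      stop("ne_anc must name exactly the internal clades")
  } else {
    tr <- NULL
    if (length(split_times)) stop("a single species has no splits")
  }
  if (!setequal(names(ne), species)) stop("ne must name every species")
  if (any(ne <= 0) || any(ne_anc <= 0)) stop("all Ne must be > 0")
  if (any(split_times <= 0)) stop("split times must be > 0")
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (length(migration)) {
    prs <- parse_migration_names(names(migration))
    bad <- !(prs$to %in% species & prs$from %in% species) | prs$to == prs$from
    if (any(bad))
      stop("invalid-demography: migration must connect two distinct ",
           "extant species")
    if (any(migration < 0)) stop("all Nm must be >= 0")
  }
  if (!is.null(outgroups)) {
    stopifnot(is.data.frame(outgroups),
              all(c("label", "time", "ne") %in% names(outgroups)))
    if (is.null(outgroups$anc_ne)) outgroups$anc_ne <- NA_real_
    outgroups <- outgroups[order(outgroups$time), , drop = FALSE]
    root_t <- if (length(split_times)) max(split_times) else 0
    if (any(outgroups$time <= root_t))
      stop("outgroup split times must predate the ingroup root")
  }
  obj <- list(species = species, topology = topology, tree = tr,
              split_times = split_times, ne = ne[species],
              ne_anc = ne_anc, migration = migration, mu = mu,
              gen_time = gen_time, outgroups = outgroups)
  class(obj) <- "demography"
  validate_split_order(obj)
  obj
}

#' @export
print.demography <- function(x, ...) {
  cat("Isolation-with-migration demography\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  if (!is.null(x$tree)) cat("  topology:", x$topology, "\n")
  if (length(x$split_times)) {
    st <- sort(x$split_times)
    cat("  splits (generations):",
        paste(sprintf("%s=%g", names(st), st), collapse = ", "), "\n")
  }
  cat("  Ne:", paste(sprintf("%s=%g", names(x$ne), x$ne), collapse = ", "),
      "\n")
  if (length(x$migration))
    cat("  Nm:", paste(sprintf("%s=%g", names(x$migration), x$migration),
                       collapse = ", "), "\n")
  cat("  mu:", format(x$mu), "per site per generation\n")
  if (!is.null(x$outgroups))
    cat("  outgroups:", paste(x$outgroups$label, collapse = ", "), "\n")
  invisible(x)
}

# Canonical clade key: member labels sorted and concatenated.
clade_key <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  paste(sort(x), collapse = "")
}

parse_migration_names <- function(nm) {
  parts <- strsplit(nm, "<-", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("migration names must have the form 'X<-Y'")
  list(to = vapply(parts, `[`, "", 1), from = vapply(parts, `[`, "", 2))
}

# Clade keys of the internal nodes of a rooted species tree.
internal_clades <- function(tr) {
  n <- length(tr$tip.label)
  vapply((n + 1):(n + tr$Nnode), function(nd) {
    clade_key(tr$tip.label[tip_descendants(tr, nd)])
  }, "")
}

# Tips below a node, via the edge table (works on any phylo).
tip_descendants <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}

validate_split_order <- function(d) {
  if (is.null(d$tree)) return(invisible(TRUE))
  tr <- d$tree
  n <- length(tr$tip.label)
  key_of <- vapply((n + 1):(n + tr$Nnode),
                   function(nd) clade_key(tr$tip.label[tip_descendants(tr, nd)]),
                   "")
  names(key_of) <- as.character((n + 1):(n + tr$Nnode))
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    if (b > n) {
      ta <- d$split_times[[key_of[[as.character(a)]]]]
      tb <- d$split_times[[key_of[[as.character(b)]]]]
      if (tb >= ta)
        stop("split times must strictly increase toward the root (clade ",
             key_of[[as.character(b)]], " vs ", key_of[[as.character(a)]], ")")
    }
  }
  invisible(TRUE)
}

#' Compile a demography into simulator epochs
#'
#' Internal representation used by the C++ coalescent core: population slots
#' (one per sampled species, merged backward in time at split events),
#' per-epoch Ne vectors and backward per-lineage migration-rate matrices.
#' Migration between a pair of species is active only while both are extant
#' (unmerged) leaf populations; the backward rate for a lineage in recipient X
#' toward donor Y is Nm[X<-Y] / (2 Ne_X).
#'
#' @param d a [demography()].
#' @param include_outgroups logical; include outgroup populations.
#' @return a list understood by the compiled simulator, with `pop_of` mapping
#'   species label to 0-based population slot.
#' @keywords internal
compile_epochs <- function(d, include_outgroups = FALSE) {
  labs <- d$species
  ogs <- if (include_outgroups && !is.null(d$outgroups)) d$outgroups else NULL
  all_labs <- c(labs, if (!is.null(ogs)) ogs$label)
  P <- length(all_labs)
  pop_of <- stats::setNames(seq_len(P) - 1L, all_labs)

  # event list: ingroup splits then outgroup joins, by time
  ev <- list()
  if (length(d$split_times)) {
    for (k in names(sort(d$split_times))) {
      ev[[length(ev) + 1]] <- list(time = d$split_times[[k]],
                                   members = strsplit(k, "")[[1]],
                                   ne = d$ne_anc[[k]], type = "split")
    }
  }
  if (!is.null(ogs)) {
    for (i in seq_len(nrow(ogs))) {
      ev[[length(ev) + 1]] <- list(time = ogs$time[i],
                                   members = ogs$label[i],
                                   ne = ogs$anc_ne[i], type = "outgroup")
    }
  }
  times <- vapply(ev, `[[`, 0, "time")
  ev <- ev[order(times)]
  bounds <- sort(unique(vapply(ev, `[[`, 0, "time")))
  E <- length(bounds) + 1L

  # state tracked while walking epochs
  slot_of <- pop_of                  # current slot per original label
  ne_slot <- c(d$ne[labs], if (!is.null(ogs)) ogs$ne)
  active <- rep(TRUE, P)             # slot currently holds lineages
  is_leaf <- stats::setNames(rep(TRUE, length(all_labs)), all_labs)

  mig_pairs <- if (length(d$migration)) parse_migration_names(names(d$migration))

  end <- c(bounds, Inf)
  ne_mat <- matrix(0, E, P)
  mig_list <- vector("list", E)
  merge_list <- vector("list", E)
  merge_list[[1]] <- matrix(integer(0), 0, 2)

  build_mig <- function() {
    m <- matrix(0, P, P)
    if (length(d$migration)) {
      for (i in seq_along(d$migration)) {
        to <- mig_pairs$to[i]; from <- mig_pairs$from[i]
        if (is_leaf[[to]] && is_leaf[[from]] && to %in% labs && from %in% labs) {
          m[slot_of[[to]] + 1L, slot_of[[from]] + 1L] <-
            d$migration[i] / (2 * ne_slot[slot_of[[to]] + 1L])
        }
      }
    }
    m
  }

  for (e in seq_len(E)) {
    if (e > 1) {
      t0 <- bounds[e - 1]
      mg <- matrix(integer(0), 0, 2)
      for (evi in ev) {
        if (evi$time != t0) next
        if (evi$type == "split") {
          slots <- unique(vapply(evi$members, function(s) slot_of[[s]], 0L))
          target <- min(slots)
          for (s in setdiff(slots, target)) {
            mg <- rbind(mg, c(s, target))
            active[s + 1L] <- FALSE
          }
          for (s in names(slot_of))
            if (slot_of[[s]] %in% slots) slot_of[[s]] <- target
          ne_slot[target + 1L] <- evi$ne
          is_leaf[evi$members] <- FALSE
          # the host species of the target slot is no longer a pure leaf
          host <- names(pop_of)[pop_of == target]
          is_leaf[host] <- FALSE
        } else {                     # outgroup joins the current root slot
          og <- evi$members
          root_slot <- slot_of[[labs[1]]]
          mg <- rbind(mg, c(slot_of[[og]], root_slot))
          active[slot_of[[og]] + 1L] <- FALSE
          slot_of[[og]] <- root_slot
          if (!is.na(evi$ne)) ne_slot[root_slot + 1L] <- evi$ne
          is_leaf[og] <- FALSE
        }
      }
      merge_list[[e]] <- mg
    }
    ne_mat[e, ] <- ifelse(active, ne_slot, 0)
    mig_list[[e]] <- build_mig()
  }
  list(end = end, ne = ne_mat, mig = mig_list, merges = merge_list,
       pop_of = pop_of, labels = all_labs)
}

#' The four candidate species-tree demographies
#'
#' Demographies for the four most frequent rooted gene-tree topologies of the
#' collared (C), pied (P), Atlas (A) and semicollared (S) flycatcher system,
#' parameterized at the composite-likelihood point estimates of the winning
#' model. Only the winning topology has published estimates; the other three
#' reuse the same values positionally (first split, second split, root), so
#' that all four models are equally strongly parameterized in recovery
#' experiments.
#'
#' @param which integer 1..4 or `"all"`.
#' @param outgroups logical; attach two synthetic outgroup species (O and H)
#'   at 3 and 4.5 million generations with the root ancestral Ne.
#' @return a `demography` or a list of four.
#' @export
candidate_demographies <- function(which = "all", outgroups = FALSE) {
  ne_now <- c(C = 449385, P = 304853, A = 244520, S = 238722)
  mig <- c("C<-P" = 0.538, "P<-C" = 0.124, "P<-A" = 0.047,
           "A<-P" = 0.168, "C<-S" = 0.156, "S<-C" = 0.515)
  t1 <- 561326; t2 <- 638933; t3 <- 1218623
  n1 <- 256334; n2 <- 1067020; n3 <- 304660
  og <- if (outgroups)
    data.frame(label = c("O", "H"), time = c(3e6, 4.5e6),
               ne = c(n3, n3), anc_ne = c(n3, n3))
  specs <- list(
    list(top = "(((P,A),C),S);",
         st = c(AP = t1, ACP = t2, ACPS = t3),
         na = c(AP = n1, ACP = n2, ACPS = n3)),
    list(top = "((P,A),(C,S));",
         st = c(AP = t1, CS = t2, ACPS = t3),
         na = c(AP = n1, CS = n2, ACPS = n3)),
    list(top = "(((C,P),A),S);",
         st = c(CP = t1, ACP = t2, ACPS = t3),
         na = c(CP = n1, ACP = n2, ACPS = n3)),
    list(top = "(((P,A),S),C);",
         st = c(AP = t1, APS = t2, ACPS = t3),
         na = c(AP = n1, APS = n2, ACPS = n3)))
  build <- function(s)
    demography(species = c("C", "P", "A", "S"), topology = s$top,
               split_times = s$st, ne = ne_now, ne_anc = s$na,
               migration = mig, mu = 2.5e-9, outgroups = og)
  if (identical(which, "all")) lapply(specs, build) else build(specs[[which]])
}

#' Model topology labels for the four candidate demographies
#' @return character vector of the four newick topology strings.
#' @export
candidate_topologies <- function() {
  c("(((P,A),C),S);", "((P,A),(C,S));", "(((C,P),A),S);", "(((P,A),S),C);")
}

#' Prior specification per candidate demography
#'
#' The prior table used for ABC sampling and as composite-likelihood search
#' ranges: log-uniform current Ne in [3e4, 1e6], log-uniform ancestral Ne
#' ([1e5, 3e6] for the two younger internal branches, [3e4, 1e6] for the
#' root), uniform split times in [144e3, 720e3] / [360e3, 1.08e6] /
#' [720e3, 1.8e6] generations (ordered), and log-uniform Nm in [1e-3, 10].
#'
#' @param model integer 1..4 indexing [candidate_topologies()].
#' @return data.frame with columns `name`, `dist` ("unif"/"logunif"),
#'   `lo`, `hi`, `role`.
#' @export
model_priors <- function(model) {
  d <- candidate_demographies(model)
  st <- names(sort(d$split_times))
  rbind(
    data.frame(name = paste0("N_", d$species), dist = "logunif",
               lo = 3e4, hi = 1e6, role = "ne_now"),
    data.frame(name = paste0("NA_", st),
               dist = "logunif",
               lo = c(1e5, 1e5, 3e4), hi = c(3e6, 3e6, 1e6),
               role = "ne_anc"),
    data.frame(name = paste0("T_", st), dist = "unif",
               lo = c(144e3, 360e3, 720e3), hi = c(720e3, 1.08e6, 1.8e6),
               role = "split"),
    data.frame(name = paste0("Nm_", names(d$migration)), dist = "logunif",
               lo = 1e-3, hi = 10, role = "mig"))
}

#' Default fixture demography (prior midpoints)
#'
#' The winning-topology demography with every parameter at its prior midpoint
#' (geometric midpoint for log-uniform parameters, arithmetic for uniform).
#' @param outgroups logical, as in [candidate_demographies()].
#' @return a `demography`.
#' @export
default_demography <- function(outgroups = FALSE) {
  gmid <- function(lo, hi) sqrt(lo * hi)
  nn <- gmid(3e4, 1e6)
  na12 <- gmid(1e5, 3e6); na3 <- gmid(3e4, 1e6)
  og <- if (outgroups)
    data.frame(label = c("O", "H"), time = c(3e6, 4.5e6),
               ne = c(na3, na3), anc_ne = c(na3, na3))
  demography(species = c("C", "P", "A", "S"), topology = "(((P,A),C),S);",
             split_times = c(AP = mean(c(144e3, 720e3)),
                             ACP = mean(c(360e3, 1.08e6)),
                             ACPS = mean(c(720e3, 1.8e6))),
             ne = c(C = nn, P = nn, A = nn, S = nn),
             ne_anc = c(AP = na12, ACP = na12, ACPS = na3),
             migration = stats::setNames(rep(gmid(1e-3, 10), 6),
                                         c("C<-P", "P<-C", "P<-A",
                                           "A<-P", "C<-S", "S<-C")),
             mu = 2.5e-9, outgroups = og)
}

#' Build a demography from a parameter vector under a model's schema
#'
#' Maps a named parameter vector (as produced by [sample_priors()] or used by
#' the composite-likelihood optimizer) onto a [demography()] for one of the
#' four candidate topologies.
#'
#' @param model integer 1..4.
#' @param par named numeric vector matching `model_priors(model)$name`.
#' @param outgroups logical.
#' @return a `demography`.
#' @export
demography_from_par <- function(model, par, outgroups = FALSE) {
  pr <- model_priors(model)
  stopifnot(all(pr$name %in% names(par)))
  d0 <- candidate_demographies(model, outgroups = outgroups)
  ne <- par[paste0("N_", d0$species)]
  names(ne) <- d0$species
  st_keys <- names(sort(d0$split_times))
  st <- par[paste0("T_", st_keys)]
  names(st) <- st_keys
  na <- par[paste0("NA_", st_keys)]
  names(na) <- st_keys
  mg <- par[paste0("Nm_", names(d0$migration))]
  names(mg) <- names(d0$migration)
  og <- if (outgroups)
    data.frame(label = c("O", "H"), time = c(3e6, 4.5e6),
               ne = c(na[[3]], na[[3]]), anc_ne = c(na[[3]], na[[3]]))
  demography(species = d0$species, topology = d0$topology,
             split_times = st, ne = ne, ne_anc = na, migration = mg,
             mu = d0$mu, outgroups = og)
}
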