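#' Polarize sites with two outgroup genotypes
#'
#' Parsimony polarization: the ancestral allele of a site is the allele for
#' which both outgroup individuals are monomorphic. If either outgroup has
#' missing data, is polymorphic, or the two outgroups are fixed for different
#' alleles, the site is undetermined (`NA`) and should be treated as missing
#' in all individuals downstream.
#'
#' @param og1,og2 character matrices (sites x alleles, typically two columns
#'   per diploid outgroup individual) with `"."` or `NA` for missing.
#' @return character vector of ancestral alleles, `NA` where undetermined.
#' @export
polarize <- function(og1, og2) {
  og1 <- as.matrix(og1); og2 <- as.matrix(og2)
  stopifnot(nrow(og1) == nrow(og2))
  mono <- function(m) {
    apply(m, 1, function(x) {
      x[x == "."] <- NA
      if (anyNA(x)) return(NA_character_)
      u <- unique(x)
      if (length(u) == 1) u else NA_character_
    })
  }
  a1 <- mono(og1); a2 <- mono(og2)
  ifelse(!is.na(a1) & !is.na(a2) & a1 == a2, a1, NA_character_)
}

#' Site filters with per-rule audit counts
#'
#' Applies the study's standing site filters to a site table: minimum RMS
#' mapping quality, minimum number of callable individuals per species,
#' exclusion of coverage outliers (strictly greater than mean + k standard
#' deviations of the per-site mean coverage, estimated once over the whole
#' table), and exclusion of sites exclusively heterozygous within any
#' species. Each rule can be disabled by setting its threshold to `NULL`.
#'
#' @param sites data.frame with columns `mq` (site RMS mapping quality),
#'   `coverage` (mean depth over individuals), `callable_<sp>` (callable
#'   individuals per species) and logical `allhet_<sp>` columns.
#' @param min_mq minimum mapping quality (default 20).
#' @param min_callable minimum callable individuals per species (default 10).
#' @param max_cov_sd coverage-outlier multiplier (default 5).
#' @param exclude_allhet drop sites exclusively heterozygous in any species.
#' @return list: logical `pass` mask, and `audit`, the number of sites
#'   failing each rule (counted independently).
#' @export
filter_sites <- function(sites, min_mq = 20, min_callable = 10,
                         max_cov_sd = 5, exclude_allhet = TRUE) {
  n <- nrow(sites)
  pass <- rep(TRUE, n)
  audit <- c(mq = 0L, callable = 0L, coverage = 0L, allhet = 0L)
  if (!is.null(min_mq)) {
    bad <- sites$mq < min_mq
    audit["mq"] <- sum(bad); pass <- pass & !bad
  }
  cal_cols <- grep("^callable_", names(sites), value = TRUE)
  if (!is.null(min_callable) && length(cal_cols)) {
    bad <- apply(as.matrix(sites[cal_cols]) < min_callable, 1, any)
    audit["callable"] <- sum(bad); pass <- pass & !bad
  }
  if (!is.null(max_cov_sd)) {
    thr <- mean(sites$coverage) + max_cov_sd * stats::sd(sites$coverage)
    bad <- sites$coverage > thr        # strictly greater: boundary retained
    audit["coverage"] <- sum(bad); pass <- pass & !bad
  }
  het_cols <- grep("^allhet_", names(sites), value = TRUE)
  if (isTRUE(exclude_allhet) && length(het_cols)) {
    bad <- apply(as.matrix(sites[het_cols]), 1, any)
    audit["allhet"] <- sum(bad); pass <- pass & !bad
  }
  list(pass = pass, audit = audit)
}

#' Derived-allele sharing partition across four species
#'
#' Assigns every polarized polymorphic site to one of the 2^4 - 1 cells of
#' the presence partition: which species carry the derived allele in at least
#' one haplotype.
#'
#' @param geno 0/1 numeric matrix (sites x haplotypes; NA = missing), with
#'   haplotype column names.
#' @param species_map named character vector haplotype -> species.
#' @param species the four species labels.
#' @param polarized logical vector per site (`FALSE`/`NA` rows are skipped
#'   and counted).
#' @return list: `cells`, named counts over the 15 presence patterns (clade
#'   keys), and `skipped`, the number of unpolarized sites.
#' @export
allele_sharing <- function(geno, species_map, species, polarized = NULL) {
  sp <- species_map[colnames(geno)]
  if (is.null(polarized)) polarized <- rep(TRUE, nrow(geno))
  keys <- unlist(lapply(seq_along(species), function(k)
    apply(utils::combn(sort(species), k), 2, clade_key)))
  cells <- stats::setNames(integer(length(keys)), keys)
  skipped <- 0L
  pres <- vapply(species, function(s)
    rowSums(geno[, sp == s, drop = FALSE] == 1, na.rm = TRUE) > 0,
    logical(nrow(geno)))
  for (i in seq_len(nrow(geno))) {
    if (is.na(polarized[i]) || !polarized[i]) { skipped <- skipped + 1L; next }
    present <- species[pres[i, ]]
    if (!length(present)) next         # no derived allele among these species
    k <- clade_key(present)
    cells[k] <- cells[k] + 1L
  }
  list(cells = cells, skipped = skipped)
}

#' Nucleotide diversity and Watterson's theta
#'
#' Per-base-pair diversity of one species' haplotypes: pi is the mean
#' pairwise difference per site, thetaW is S divided by the harmonic number
#' of (n-1) and the callable length. Missing data are handled per site by
#' using the callable haplotypes only.
#'
#' @param geno 0/1 numeric matrix (sites x haplotypes) of segregating sites;
#'   monomorphic sites need not be included.
#' @param L callable locus length in bp.
#' @return list with `pi`, `theta_w`, `S`.
#' @export
diversity <- function(geno, L) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (ncol(geno) < 2) stop("undefined: need >= 2 haplotypes")
  k <- rowSums(geno == 1, na.rm = TRUE)
  m <- rowSums(!is.na(geno))
  ok <- m >= 2
  k <- k[ok]; m <- m[ok]
  poly <- k > 0 & k < m
  pi <- sum(k * (m - k) / choose(m, 2)) / L
  a <- function(n) sum(1 / seq_len(n - 1))
  theta_w <- sum(ifelse(poly, 1 / vapply(m, a, 0), 0)) / L
  list(pi = pi, theta_w = theta_w, S = sum(poly))
}

#' Pairwise two-species locus statistics
#'
#' Computes, over one locus, the number of segregating sites in the pooled
#' sample, the proportions of shared and fixed polymorphism (normalized by
#' the pooled S by default; per-bp values are also returned), the average
#' between-species divergence dXY, and the AMOVA-style PhiST on pairwise
#' haplotype sequence differences.
#'
#' @param genoA,genoB 0/1 matrices (sites x haplotypes) for the two species,
#'   over the same sites.
#' @param L callable locus length in bp.
#' @return list: `S`, `shared`, `fixed`, `dxy`, `phist`, plus `shared_bp`,
#'   `fixed_bp`.
#' @export
pair_stats <- function(genoA, genoB, L) {
  if (ncol(genoA) < 2 || ncol(genoB) < 2)
    stop("undefined: need >= 2 haplotypes per species")
  kA <- rowSums(genoA == 1, na.rm = TRUE); mA <- rowSums(!is.na(genoA))
  kB <- rowSums(genoB == 1, na.rm = TRUE); mB <- rowSums(!is.na(genoB))
  ok <- mA >= 2 & mB >= 2
  kA <- kA[ok]; mA <- mA[ok]; kB <- kB[ok]; mB <- mB[ok]
  k <- kA + kB; m <- mA + mB
  S <- sum(k > 0 & k < m)
  polyA <- kA > 0 & kA < mA
  polyB <- kB > 0 & kB < mB
  n_shared <- sum(polyA & polyB)
  n_fixed <- sum((kA == mA & kB == 0) | (kA == 0 & kB == mB))
  pA <- kA / mA; pB <- kB / mB
  dxy <- sum(pA * (1 - pB) + pB * (1 - pA)) / L
  phist <- phi_st(genoA[ok, , drop = FALSE], genoB[ok, , drop = FALSE])
  list(S = S,
       shared = if (S > 0) n_shared / S else NA_real_,
       fixed = if (S > 0) n_fixed / S else NA_real_,
       dxy = dxy, phist = phist,
       shared_bp = n_shared / L, fixed_bp = n_fixed / L)
}

# AMOVA-style PhiST from pairwise haplotype differences (haploid units):
# ratio of the among-group variance component to the total.
phi_st <- function(genoA, genoB) {
  G <- cbind(genoA, genoB)
  n1 <- ncol(genoA); n2 <- ncol(genoB); N <- n1 + n2
  if (anyNA(G)) {
    d <- matrix(0, N, N)
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      both <- !is.na(G[, i]) & !is.na(G[, j])
      d[i, j] <- d[j, i] <- sum(G[both, i] != G[both, j])
    }
  } else {
    s <- colSums(G)
    cp <- crossprod(G)
    d <- outer(s, s, "+") - 2 * cp
    diag(d) <- 0
  }
  d2 <- d                                 # squared Euclidean = count for 0/1
  idx1 <- seq_len(n1); idx2 <- n1 + seq_len(n2)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ss_w1 <- sum(d2[idx1, idx1][upper.tri(d2[idx1, idx1])]) / n1
  ss_w2 <- sum(d2[idx2, idx2][upper.tri(d2[idx2, idx2])]) / n2
  ss_within <- ss_w1 + ss_w2
  ss_among <- ss_tot - ss_within
  df_among <- 1; df_within <- N - 2
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_c <- (N - (n1^2 + n2^2) / N) / df_among
  sigma_a <- (ms_among - ms_within) / n_c
  sigma_w <- ms_within
  if (sigma_a + sigma_w == 0) return(NA_real_)
  sigma_a / (sigma_a + sigma_w)
}

# Per-locus pairwise statistics for all species pairs, from one polarized
# locus genotype matrix. Returns a named numeric vector (pair x stat).
locus_pair_stats <- function(geno, species_map, species, L) {
  sp <- species_map[colnames(geno)]
  prs <- utils::combn(species, 2)
  out <- c()
  for (q in seq_len(ncol(prs))) {
    a <- prs[1, q]; b <- prs[2, q]
    st <- pair_stats(geno[, sp == a, drop = FALSE],
                     geno[, sp == b, drop = FALSE], L)
    v <- c(st$S, st$shared, st$fixed, st$dxy, st$phist)
    names(v) <- paste(c("S", "shared", "fixed", "dxy", "phist"),
                      paste0(a, "-", b), sep = "_")
    out <- c(out, v)
  }
  out
}

#' The 60-statistic ABC summary vector
#'
#' Mean and variance over loci of five pairwise statistics (S, shared
#' polymorphism proportion, fixed difference proportion, dXY, PhiST) for each
#' of the six species pairs: 6 x 5 x 2 = 60 labeled values. Label order is
#' fixed: pairs in `combn(species, 2)` order, stats in the order above, mean
#' before variance (`mean_S_C-P`, `var_S_C-P`, ...). Missing per-locus values
#' are excluded from the moments.
#'
#' @param study a `synthetic_study`, or a list of per-locus 0/1 genotype
#'   matrices (sites x haplotypes, named columns).
#' @param species_map named character vector haplotype -> species (taken from
#'   the study if omitted).
#' @param species the four species labels.
#' @param L locus length (taken from the study design if omitted).
#' @return named numeric vector of length 60.
#' @export
summary_vector <- function(study, species_map = NULL, species = NULL,
                           L = NULL) {
  if (inherits(study, "synthetic_study")) {
    species_map <- stats::setNames(study$species_map$species,
                                   study$species_map$haplotype)
    species <- study$truth$species
    L <- study$design$locus_length
    geno_list <- study_locus_genos(study)
  } else geno_list <- study
  if (length(geno_list) < 2) stop("variance undefined: need >= 2 loci")
  per_locus <- t(vapply(geno_list, function(g)
    locus_pair_stats(g, species_map, species, L),
    numeric(5 * choose(length(species), 2))))
  stat_moments(per_locus, species)
}

# means and variances over loci of a per-locus statistic matrix, in the
# documented fixed label order (pair-major, stat, mean before variance)
stat_moments <- function(per_locus, species) {
  out <- c()
  for (nm in colnames(per_locus)) {
    x <- per_locus[, nm]
    out[paste0("mean_", nm)] <- mean(x, na.rm = TRUE)
    out[paste0("var_", nm)] <- stats::var(x[!is.na(x)])
  }
  prs <- utils::combn(species, 2)
  ord <- c()
  for (q in seq_len(ncol(prs)))
    for (st in c("S", "shared", "fixed", "dxy", "phist"))
      ord <- c(ord, paste0(c("mean_", "var_"), st, "_",
                           prs[1, q], "-", prs[2, q]))
  out[ord]
}

# split a study's variant table into per-locus ingroup genotype matrices
study_locus_genos <- function(study) {
  sm <- stats::setNames(study$species_map$species, study$species_map$haplotype)
  ing <- study$species_map$haplotype[sm[study$species_map$haplotype] %in%
                                       study$truth$species]
  v <- study$variants
  lapply(sprintf("locus_%04d", seq_along(study$genealogies)), function(ch) {
    rows <- v$chrom == ch
    m <- as.matrix(v[rows, ing, drop = FALSE])
    storage.mode(m) <- "numeric"
    m
  })
}
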