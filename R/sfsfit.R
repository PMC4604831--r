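#' Two-dimensional joint site-frequency spectrum
#'
#' @param counts (n1+1) x (n2+1) matrix of site counts over derived-allele
#'   configurations, including the monomorphic (0,0) and (n1,n2) cells.
#' @param pair character vector of the two species labels.
#' @param total_sites total number of sites scanned.
#' @return object of class `"sfs2d"`.
#' @export
sfs2d <- function(counts, pair, total_sites = sum(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("SFS counts must be >= 0")
  structure(list(counts = counts, pair = pair,
                 n = c(nrow(counts) - 1L, ncol(counts) - 1L),
                 total_sites = total_sites),
            class = "sfs2d")
}

#' @export
print.sfs2d <- function(x, ...) {
  cat(sprintf("2D-SFS %s-%s: %d x %d chromosomes, %.0f sites (%.0f polymorphic cells mass)\n",
              x$pair[1], x$pair[2], x$n[1], x$n[2], x$total_sites,
              sum(x$counts) - x$counts[1, 1]))
  invisible(x)
}

#' Build an observed 2D-SFS from polarized variants
#'
#' Assigns sites to fixed-width windows, drops windows exceeding the repeat
#' mask threshold, optionally samples windows without replacement, projects
#' each remaining biallelic site down to a fixed number of chromosomes per
#' species by the hypergeometric expectation, and fills the monomorphic
#' (0,0) cell from the total number of sites scanned. Sites without enough
#' callable chromosomes in any of the checked species are excluded entirely.
#'
#' @param variants data.frame: `chrom`, `pos` (1-based), plus one 0/1/NA
#'   column per haplotype.
#' @param species_map named character vector haplotype -> species.
#' @param pair the two species labels of this spectrum.
#' @param project_to chromosomes per species after projection (default 24).
#' @param check_species species whose callability gates a site (default all
#'   species in the map); a site failing in any is excluded for the pair.
#' @param window_bp window width for the sampling scheme (default 100).
#' @param mask optional data.frame `chrom`, `window` (0-based index),
#'   `masked_frac`; windows with masked_frac > `mask_threshold` are excluded.
#' @param mask_threshold default 0.2.
#' @param n_windows optional number of windows sampled without replacement.
#' @param seed seed for window sampling.
#' @return an [sfs2d()].
#' @export
build_sfs <- function(variants, species_map, pair, project_to = 24,
                      check_species = NULL, window_bp = 100,
                      mask = NULL, mask_threshold = 0.2,
                      n_windows = NULL, seed = 1) {
  if (!all(pair %in% species_map))
    stop("key error: pair not present in the dataset")
  if (is.null(check_species)) check_species <- unique(unname(species_map))
  win <- data.frame(chrom = variants$chrom,
                    window = (variants$pos - 1) %/% window_bp)
  wkey <- paste(win$chrom, win$window)
  all_windows <- unique(wkey)
  if (!is.null(mask)) {
    bad <- with(mask, paste(chrom, window))[mask$masked_frac > mask_threshold]
    all_windows <- setdiff(all_windows, bad)
  }
  if (!is.null(n_windows)) {
    if (n_windows > length(all_windows)) n_windows <- length(all_windows)
    set.seed(seed)
    all_windows <- sample(all_windows, n_windows, replace = FALSE)
  }
  keep <- wkey %in% all_windows
  v <- variants[keep, , drop = FALSE]
  hap_cols <- intersect(names(variants), names(species_map))
  mat <- function(sp) {
    m <- as.matrix(v[, hap_cols[species_map[hap_cols] == sp], drop = FALSE])
    storage.mode(m) <- "numeric"
    m
  }
  kc <- lapply(check_species, function(s) {
    g <- mat(s)
    list(k = rowSums(g == 1, na.rm = TRUE), m = rowSums(!is.na(g)))
  })
  names(kc) <- check_species
  enough <- Reduce(`&`, lapply(kc, function(x) x$m >= project_to))
  acc <- matrix(0, project_to + 1, project_to + 1)
  ka <- kc[[pair[1]]]$k[enough]; ma <- kc[[pair[1]]]$m[enough]
  kb <- kc[[pair[2]]]$k[enough]; mb <- kc[[pair[2]]]$m[enough]
  n_used <- 0
  for (i in seq_along(ka)) {
    wa <- stats::dhyper(0:project_to, ka[i], ma[i] - ka[i], project_to)
    wb <- stats::dhyper(0:project_to, kb[i], mb[i] - kb[i], project_to)
    acc <- acc + outer(wa, wb)
    n_used <- n_used + 1
  }
  total_sites <- length(all_windows) * window_bp
  acc[1, 1] <- acc[1, 1] + total_sites - n_used
  sfs2d(acc, pair, total_sites = total_sites)
}

#' Expected 2D-SFS probabilities under a demography
#'
#' Simulation-based expectation in the style of sequential coalescent SFS
#' fitting: the relative length of the branches subtending each derived
#' configuration, averaged over simulated genealogies, scaled by the per-site
#' mutation probability mu * E[total length]; the remaining mass is
#' monomorphic and assigned to the (0,0) cell.
#'
#' @param dem a [demography()].
#' @param n_per_species chromosomes sampled per species.
#' @param n_sims number of simulated genealogies (>= 100).
#' @param seed integer seed.
#' @param ratio_of_means average the per-genealogy ratio (default, FALSE) or
#'   use the ratio of mean branch length to mean total length.
#' @return named list of probability matrices per species pair (each summing
#'   to 1), with attribute `mean_total_length`.
#' @export
expected_sfs <- function(dem, n_per_species = 24, n_sims = 1000, seed = 1,
                         ratio_of_means = FALSE) {
  ep <- compile_epochs(dem, include_outgroups = FALSE)
  sp <- rep(seq_along(dem$species) - 1L, each = n_per_species)
  lin_pop <- rep(ep$pop_of[dem$species], each = n_per_species)
  pairs <- utils::combn(seq_along(dem$species), 2)
  set.seed(seed)
  res <- sfs_expect_cpp(as.integer(lin_pop), ep, as.integer(sp),
                        length(dem$species),
                        as.integer(pairs[1, ] - 1L),
                        as.integer(pairs[2, ] - 1L), as.integer(n_sims))
  mu_t <- dem$mu * res$mean_total_length
  out <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    p <- if (ratio_of_means) dem$mu * res$mean_length[[q]] else
      res$ratio[[q]] * mu_t
    p[1, 1] <- p[1, 1] + (1 - mu_t)
    out[[q]] <- p
  }
  names(out) <- apply(pairs, 2, function(ij)
    paste(dem$species[ij], collapse = "-"))
  attr(out, "mean_total_length") <- res$mean_total_length
  out
}

#' Composite log-likelihood of observed spectra
#'
#' Sum over the six pairwise spectra and their cells of count * log(p), with
#' a floor of 1e-12 on every expected probability; empty cells contribute
#' zero regardless of p.
#'
#' @param obs named list of [sfs2d()] (names `"X-Y"`).
#' @param expectation named list of probability matrices, as from
#'   [expected_sfs()].
#' @param floor probability floor.
#' @return log composite likelihood (natural log).
#' @export
composite_loglik <- function(obs, expectation, floor = 1e-12) {
  ll <- 0
  for (nm in names(obs)) {
    cnt <- obs[[nm]]$counts
    p <- expectation[[nm]]
    if (!all(dim(cnt) == dim(p)))
      stop("shape error: SFS dimensions differ for pair ", nm)
    nz <- cnt > 0
    ll <- ll + sum(cnt[nz] * log(pmax(p[nz], floor)))
  }
  ll
}

# inverse of par_from_unit: unit-scale coordinates of a parameter vector
unit_from_par <- function(model, par) {
  pr <- model_priors(model)
  u <- numeric(nrow(pr)); names(u) <- pr$name
  tprev <- 0
  for (i in seq_len(nrow(pr))) {
    lo <- pr$lo[i]; hi <- pr$hi[i]; x <- par[[pr$name[i]]]
    if (pr$role[i] == "split") {
      lo <- max(lo, tprev * 1.0001)
      u[i] <- (x - lo) / (hi - lo)
      tprev <- x
    } else if (pr$dist[i] == "logunif") {
      u[i] <- (log10(x) - log10(lo)) / (log10(hi) - log10(lo))
    } else u[i] <- (x - lo) / (hi - lo)
  }
  pmin(pmax(u, 1e-6), 1 - 1e-6)
}

# map an unconstrained vector in [0,1]^k to a model parameter vector,
# respecting prior bounds, scales, and split-time ordering
par_from_unit <- function(model, u) {
  pr <- model_priors(model)
  stopifnot(length(u) == nrow(pr))
  par <- numeric(nrow(pr)); names(par) <- pr$name
  tprev <- 0
  for (i in seq_len(nrow(pr))) {
    lo <- pr$lo[i]; hi <- pr$hi[i]
    if (pr$role[i] == "split") {
      lo <- max(lo, tprev * 1.0001)      # enforce ordering toward the root
      par[i] <- lo + u[i] * (hi - lo)
      tprev <- par[i]
    } else if (pr$dist[i] == "logunif") {
      par[i] <- 10^(log10(lo) + u[i] * (log10(hi) - log10(lo)))
    } else {
      par[i] <- lo + u[i] * (hi - lo)
    }
  }
  par
}

#' Fit one candidate demography to observed spectra
#'
#' Multistart derivative-free maximization of the composite likelihood over
#' the model's 16 parameters (log scale for Ne and Nm, ordered split times),
#' with common random numbers: each likelihood evaluation re-seeds the
#' genealogy simulation identically so the objective is deterministic within
#' a fit. Optimization stops when the relative improvement falls below the
#' stop criterion (default 0.001).
#'
#' @param model integer 1..4 (see [candidate_topologies()]).
#' @param obs named list of [sfs2d()] observed spectra.
#' @param n_runs independent starts (reference setting 100; desk scale small).
#' @param seed integer seed.
#' @param n_sims genealogies per likelihood evaluation.
#' @param maxit Nelder-Mead iteration cap per run.
#' @param reltol stop criterion on relative improvement.
#' @param start optional named start vector (unit scale applied otherwise).
#' @return object of class `"model_fit"`: `model`, `topology`, `par`, `logL`,
#'   `AIC`, `runs` (per-run best logL), `n_params`.
#' @export
fit_model <- function(model, obs, n_runs = 3, seed = 1, n_sims = 500,
                      n_sims_final = max(20 * n_sims, 5000),
                      maxit = 120, reltol = 1e-3, start = NULL,
                      ratio_of_means = TRUE) {
  n_per <- obs[[1]]$n[1]
  crn_seed <- derive_seed(seed, 977L + model)
  lnl_at <- function(z, sims, sd) {
    par <- par_from_unit(model, stats::plogis(z))
    dem <- demography_from_par(model, par)
    ex <- expected_sfs(dem, n_per_species = n_per, n_sims = sims,
                       seed = sd, ratio_of_means = ratio_of_means)
    composite_loglik(obs, ex)
  }
  objective <- function(z) -lnl_at(z, n_sims, crn_seed)
  set.seed(derive_seed(seed, model))
  best <- NULL; run_ll <- numeric(0)
  for (r in seq_len(n_runs)) {
    z0 <- if (r == 1) {
      if (!is.null(start)) stats::qlogis(start) else
        rep(0, nrow(model_priors(model)))         # prior midpoint
    } else stats::qlogis(stats::runif(nrow(model_priors(model)), 0.15, 0.85))
    o <- stats::optim(z0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    run_ll <- c(run_ll, -o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  # final high-precision evaluation at the selected optimum (the noisy
  # within-fit surface uses common random numbers; the reported lnL uses a
  # larger simulation batch so model comparisons are not noise-limited)
  lnl_final <- lnl_at(best$par, n_sims_final, derive_seed(seed, 555L + model))
  par <- par_from_unit(model, stats::plogis(best$par))
  k <- length(par)
  structure(list(model = model, topology = candidate_topologies()[model],
                 par = par, logL = lnl_final,
                 AIC = 2 * k - 2 * lnl_final,
                 runs = run_ll, n_params = k),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Composite-likelihood fit:", x$topology, "\n")
  cat("  lnL =", format(x$logL), " AIC =", format(x$AIC),
      " (", x$n_params, "parameters,", length(x$runs), "runs )\n")
  invisible(x)
}

#' Compare fitted demographies by AIC
#'
#' @param fits list of `model_fit` objects (>= 2).
#' @return data.frame: topology, logL, AIC, delta_aic, weight (Akaike
#'   weights, summing to 1), ordered by fit.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits to compare")
  aic <- vapply(fits, `[[`, 0, "AIC")
  d <- aic - min(aic)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(topology = vapply(fits, `[[`, "", "topology"),
                    logL = vapply(fits, `[[`, 0, "logL"),
                    AIC = aic, delta_aic = d, weight = w)
  out[order(out$delta_aic), ]
}

# unit-scale coordinates of the candidate demography's own parameter values
# under its model schema: the common positional anchor used as the first
# multistart point in recovery experiments (identical positional values for
# every candidate, so no model is privileged)
analog_start <- function(model) {
  d <- candidate_demographies(model)
  st <- names(sort(d$split_times))
  par <- c(stats::setNames(d$ne, paste0("N_", names(d$ne))),
           stats::setNames(d$ne_anc[st], paste0("NA_", st)),
           stats::setNames(sort(d$split_times), paste0("T_", st)),
           stats::setNames(d$migration, paste0("Nm_", names(d$migration))))
  unit_from_par(model, par)
}

#' Topology-recovery experiment for the SFS model comparison
#'
#' Simulates observed joint spectra under each of the four candidate
#' demographies in turn, fits all four models to each data set
#' (multistart: one anchored start at the common positional parameter values
#' plus random starts; high-precision final likelihood evaluation), and
#' scores whether the Akaike-best topology matches the generating one.
#'
#' @param n_reps_per_model replicates per generating model.
#' @param seed integer seed.
#' @param n_windows observed 100-bp windows per replicate.
#' @param n_per_species chromosomes per species.
#' @param fit_args extra arguments to [fit_model()].
#' @return data.frame: generating model, replicate, winning topology, hit,
#'   and the winner's Akaike weight.
#' @export
sfs_recovery_experiment <- function(n_reps_per_model = 5, seed = 1,
                                    n_windows = 30000, n_per_species = 24,
                                    fit_args = list(n_runs = 2, n_sims = 300,
                                                    n_sims_final = 6000,
                                                    maxit = 150)) {
  out <- NULL
  for (g in 1:4) {
    for (r in seq_len(n_reps_per_model)) {
      sd_r <- derive_seed(seed, g * 1000L + r)
      obs <- simulate_sfs_counts(candidate_demographies(g),
                                 n_per_species = n_per_species,
                                 n_windows = n_windows, seed = sd_r)
      fits <- lapply(1:4, function(m)
        do.call(fit_model, c(list(model = m, obs = obs, seed = sd_r,
                                  start = analog_start(m)), fit_args)))
      cmp <- compare_models(fits)
      out <- rbind(out, data.frame(generating = candidate_topologies()[g],
                                   replicate = r,
                                   winner = cmp$topology[1],
                                   hit = cmp$topology[1] ==
                                     candidate_topologies()[g],
                                   weight = cmp$weight[1]))
    }
  }
  out
}

#' Block-resampling confidence intervals for fitted parameters
#'
#' Repeats the window-subsampling and fitting procedure and reports the
#' empirical 5th-95th percentile interval per parameter. Percentiles use the
#' standard linear-interpolation definition of [stats::quantile()] type 7.
#'
#' @param obs_builder function(replicate_seed) returning the observed spectra
#'   list for one resampled window set.
#' @param model model index to fit.
#' @param n_reps number of resampling replicates (reference setting 50).
#' @param fit_args list of arguments forwarded to [fit_model()] (typically
#'   reduced `n_runs`).
#' @param seed integer seed.
#' @param level central interval mass (default 0.9).
#' @return list: `ci` (parameters x lo/hi), `estimates` (replicates x
#'   parameters).
#' @export
block_resample_ci <- function(obs_builder, model, n_reps = 50,
                              fit_args = list(), seed = 1, level = 0.9) {
  if (n_reps < 2) stop("need >= 2 replicates")
  est <- NULL
  fit_seed <- derive_seed(seed, 1000L)   # fixed across replicates: all
  for (r in seq_len(n_reps)) {           # variation comes from the resample
    obs <- obs_builder(derive_seed(seed, r))
    fit <- do.call(fit_model, c(list(model = model, obs = obs,
                                     seed = fit_seed), fit_args))
    est <- rbind(est, fit$par)
  }
  a <- (1 - level) / 2
  ci <- t(apply(est, 2, stats::quantile, probs = c(a, 1 - a), type = 7))
  colnames(ci) <- c("lo", "hi")
  list(ci = ci, estimates = est)
}
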