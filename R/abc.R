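#' Configuration for ABC model choice and estimation
#'
#' Bundles the simulation design and algorithm settings for the ABC analyses.
#' Paper-scale values (2e6 simulations per model, 2962 loci of 2 kb, 0.1%
#' tolerance, 10 PLS components, 200 cross-validation sets) are the reference
#' points; desk-scale runs shrink `n_sims` and the locus count.
#'
#' @param models model indices compared (subset of 1:4).
#' @param n_sims reference-table rows per model.
#' @param tolerance retained fraction for rejection (in (0, 1]).
#' @param n_pls number of PLS components for parameter estimation.
#' @param n_crossval pseudo-observed sets per model in cross-validation.
#' @param n_loci,locus_length,haplotypes_per_species simulation design.
#' @param seed master seed.
#' @return object of class `"abc_config"`.
#' @export
abc_config <- function(models = 1:4, n_sims = 1000, tolerance = 0.001,
                       n_pls = 10, n_crossval = 200, n_loci = 200,
                       locus_length = 2000, haplotypes_per_species = 12,
                       seed = 1) {
  stopifnot(tolerance > 0, tolerance <= 1, n_pls >= 1)
  structure(list(models = models, n_sims = n_sims, tolerance = tolerance,
                 n_pls = n_pls, n_crossval = n_crossval, n_loci = n_loci,
                 locus_length = locus_length,
                 haplotypes_per_species = haplotypes_per_species,
                 seed = seed),
            class = "abc_config")
}

#' Draw parameters from a model's priors
#'
#' Independent uniform / log-uniform draws within the prior bounds
#' (log-uniform = uniform on the log10 scale); draws violating the split-time
#' ordering are rejected and redrawn.
#'
#' @param model model index 1..4.
#' @param n number of draws.
#' @param seed integer seed.
#' @return matrix n x parameters with prior names as columns.
#' @export
sample_priors <- function(model, n, seed = 1) {
  pr <- model_priors(model)
  if (any(pr$lo >= pr$hi)) stop("config error: inverted prior bounds")
  set.seed(seed)
  draw <- function(m) {
    out <- matrix(0, m, nrow(pr), dimnames = list(NULL, pr$name))
    for (i in seq_len(nrow(pr))) {
      if (pr$dist[i] == "logunif")
        out[, i] <- 10^stats::runif(m, log10(pr$lo[i]), log10(pr$hi[i]))
      else out[, i] <- stats::runif(m, pr$lo[i], pr$hi[i])
    }
    out
  }
  tcols <- which(pr$role == "split")
  res <- NULL
  while (is.null(res) || nrow(res) < n) {
    d <- draw(n)
    ok <- d[, tcols[1]] < d[, tcols[2]] & d[, tcols[2]] < d[, tcols[3]]
    res <- rbind(res, d[ok, , drop = FALSE])
  }
  res[seq_len(n), , drop = FALSE]
}

# Summary vector of a freshly simulated study. The default engine fuses
# genealogy simulation, mutation dropping and per-locus pairwise statistics
# in compiled code (complete data lets every statistic, including the AMOVA
# PhiST, be computed from per-species derived-allele counts); the "r" engine
# takes the genotype-matrix route through summary_vector() and serves as the
# cross-check in tests.
simulate_summary_vector <- function(dem, design, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "r") {
    raw <- simulate_gene_trees(dem, design, as_phylo = FALSE)
    labels <- raw$labels
    cfg <- lineage_config(dem, design)
    species_map <- stats::setNames(cfg$species, labels)
    n <- length(labels)
    geno_list <- lapply(seq_len(design$n_loci), function(i) {
      set.seed(derive_seed(design$seed + 1L, i))
      res <- drop_mutations_cpp(raw$parent[i, ], raw$time[i, ], n,
                                design$locus_length, dem$mu)
      g <- res$geno
      colnames(g) <- labels
      g
    })
    return(summary_vector(geno_list, species_map, dem$species,
                          design$locus_length))
  }
  per_locus <- simulate_pair_stat_matrix(dem, design)
  stat_moments(per_locus, dem$species)
}

# per-locus pairwise statistic matrix from the fused compiled kernel
simulate_pair_stat_matrix <- function(dem, design) {
  hps <- design$haplotypes_per_species
  if (is.null(names(hps)))
    hps <- stats::setNames(rep(hps[[1]], length(dem$species)), dem$species)
  ep <- compile_epochs(dem, include_outgroups = FALSE)
  sp_idx <- rep(seq_along(dem$species) - 1L, times = hps[dem$species])
  lin_pop <- rep(ep$pop_of[dem$species], times = hps[dem$species])
  prs <- utils::combn(seq_along(dem$species), 2)
  set.seed(design$seed)
  m <- sim_pairstats_cpp(as.integer(lin_pop), ep, as.integer(sp_idx),
                         length(dem$species),
                         as.integer(prs[1, ] - 1L), as.integer(prs[2, ] - 1L),
                         design$n_loci, design$locus_length, dem$mu)
  cn <- c()
  for (q in seq_len(ncol(prs)))
    cn <- c(cn, paste(c("S", "shared", "fixed", "dxy", "phist"),
                      paste0(dem$species[prs[1, q]], "-",
                             dem$species[prs[2, q]]), sep = "_"))
  colnames(m) <- cn
  m
}

#' Simulate an ABC reference table for one model
#'
#' Each row draws parameters from the model's priors, simulates a synthetic
#' study under the resulting demography, and records the 60-statistic
#' summary vector.
#'
#' @param model model index 1..4.
#' @param config an [abc_config()].
#' @return list: `model`, `params` (n x 16), `stats` (n x 60).
#' @export
simulate_reference_table <- function(model, config) {
  n <- config$n_sims
  params <- sample_priors(model, n, seed = derive_seed(config$seed, model))
  stats_m <- NULL
  for (r in seq_len(n)) {
    dem <- demography_from_par(model, params[r, ])
    design <- sample_design(haplotypes_per_species = config$haplotypes_per_species,
                            n_loci = config$n_loci,
                            locus_length = config$locus_length,
                            seed = derive_seed(config$seed, model * 100000L + r))
    sv <- tryCatch(simulate_summary_vector(dem, design),
                   error = function(e) NULL)
    if (is.null(sv)) { params[r, ] <- NA; next }
    if (is.null(stats_m)) stats_m <- matrix(NA_real_, n, length(sv),
                                            dimnames = list(NULL, names(sv)))
    stats_m[r, ] <- sv
  }
  keep <- which(!is.na(params[, 1]))
  list(model = model, params = params[keep, , drop = FALSE],
       stats = stats_m[keep, , drop = FALSE])
}

# robust per-statistic scale for rejection distances: MAD, falling back to
# the standard deviation, dropping constant statistics
stat_scales <- function(stats_m) {
  s <- apply(stats_m, 2, stats::mad, na.rm = TRUE)
  sd_ <- apply(stats_m, 2, stats::sd, na.rm = TRUE)
  s[s == 0 | is.na(s)] <- sd_[s == 0 | is.na(s)]
  s
}

#' Rejection step
#'
#' Standardizes every statistic by its median absolute deviation estimated
#' from the reference table and retains the `ceiling(tolerance * N)` rows
#' closest to the observed vector in Euclidean distance.
#'
#' @param observed named numeric summary vector.
#' @param stats_m reference-table statistics matrix.
#' @param tolerance retained fraction.
#' @return list: `idx` (retained row indices, by increasing distance),
#'   `dist` (their distances), `n_retained`.
#' @export
abc_reject <- function(observed, stats_m, tolerance) {
  if (tolerance * nrow(stats_m) < 1)
    stop("tolerance x N < 1: nothing would be retained")
  n_keep <- ceiling(tolerance * nrow(stats_m))
  sc <- stat_scales(stats_m)
  use <- which(sc > 0 & !is.na(sc))
  z <- sweep(stats_m[, use, drop = FALSE], 2, sc[use], "/")
  zo <- observed[colnames(stats_m)[use]] / sc[use]
  d <- sqrt(colSums((t(z) - zo)^2, na.rm = TRUE))
  ord <- order(d)
  idx <- ord[seq_len(n_keep)]
  list(idx = idx, dist = d[idx], n_retained = n_keep)
}

epanechnikov <- function(d, dmax) {
  w <- 1 - (d / max(dmax, .Machine$double.eps))^2
  pmax(w, 1e-8)
}

#' Posterior model probabilities by multinomial logistic regression
#'
#' Pools the models' reference tables, retains the rows closest to the
#' observed vector, and fits a weighted multinomial logistic regression of
#' the model label on the (standardized) statistics, evaluated at the
#' observed vector. Falls back to retained-set category frequencies when the
#' regression is degenerate.
#'
#' @param tables list of reference tables (as from
#'   [simulate_reference_table()]).
#' @param observed named numeric summary vector.
#' @param tolerance retained fraction of the pooled table.
#' @param exclude optional pooled row indices excluded before rejection
#'   (used by cross-validation for leave-one-out).
#' @return named probability vector over models (sums to 1), with attribute
#'   `"method"` (`"mnlogistic"` or `"rejection"`).
#' @export
model_posterior <- function(tables, observed, tolerance = 0.001,
                            exclude = NULL) {
  stats_m <- do.call(rbind, lapply(tables, `[[`, "stats"))
  labels <- unlist(lapply(tables, function(tb)
    rep(tb$model, nrow(tb$stats))))
  keep <- setdiff(seq_len(nrow(stats_m)), exclude)
  stats_m <- stats_m[keep, , drop = FALSE]
  labels <- labels[keep]
  rej <- abc_reject(observed, stats_m, tolerance)
  lab <- labels[rej$idx]
  models <- sort(unique(unlist(lapply(tables, `[[`, "model"))))
  pp <- stats::setNames(rep(0, length(models)), models)
  if (length(unique(lab)) == 1) {
    warning("single model in retained set; posterior probability 1")
    pp[as.character(lab[1])] <- 1
    attr(pp, "method") <- "rejection"
    return(pp)
  }
  sc <- stat_scales(stats_m)
  use <- which(sc > 0 & !is.na(sc))
  X <- sweep(stats_m[rej$idx, use, drop = FALSE], 2, sc[use], "/")
  xo <- observed[colnames(stats_m)[use]] / sc[use]
  w <- epanechnikov(rej$dist, max(rej$dist))
  df <- data.frame(.model = factor(lab, levels = models), X,
                   check.names = FALSE)
  fit <- tryCatch(
    suppressWarnings(nnet::multinom(.model ~ ., data = df, weights = w,
                                    trace = FALSE, maxit = 500,
                                    MaxNWts = 5000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tab <- tapply(w, factor(lab, levels = models), sum)
    tab[is.na(tab)] <- 0
    pp[] <- tab / sum(tab)
    attr(pp, "method") <- "rejection"
    return(pp)
  }
  newd <- as.data.frame(as.list(xo), check.names = FALSE)
  pred <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pred))) {
    if (length(pred) == 1) {           # two-class multinom returns P(class2)
      pp[1] <- 1 - pred; pp[2] <- pred
    } else pp[names(pred)] <- pred
  } else pp[colnames(pred)] <- pred[1, ]
  pp <- pp / sum(pp)
  attr(pp, "method") <- "mnlogistic"
  pp
}

#' Partial least-squares reduction of the summary statistics
#'
#' SIMPLS components of the (standardized) statistics that maximize
#' covariance with the model parameters; scores are orthogonal on the
#' training rows. A root-mean-squared-error curve on held-out rows documents
#' the gain per added component.
#'
#' @param stats_m reference statistics (n x 60).
#' @param params_m reference parameters (n x k).
#' @param n_components components to extract (default 10).
#' @param holdout fraction of rows held out for the RMSE curve.
#' @param seed integer seed for the holdout split.
#' @return list: `projection` (statistics x components, applied to
#'   standardized stats), `center`, `scale`, `kept` (statistic names used),
#'   `scores` (training scores), `rmse` (components x parameters matrix).
#' @export
pls_reduce <- function(stats_m, params_m, n_components = 10, holdout = 0.2,
                       seed = 1) {
  if (nrow(stats_m) < n_components)
    stop("need at least as many rows as components")
  const <- apply(stats_m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                   anyNA(x))
  if (any(const))
    warning("dropping constant/NA statistics: ",
            paste(colnames(stats_m)[const], collapse = ", "))
  X <- stats_m[, !const, drop = FALSE]
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Yc <- sweep(as.matrix(params_m), 2, colMeans(params_m))
  Ys <- sweep(Yc, 2, apply(params_m, 2, stats::sd), "/")
  R <- simpls(Xs, Ys, n_components)
  scores <- Xs %*% R
  # RMSE curve on a holdout split
  set.seed(seed)
  n <- nrow(Xs)
  te <- sample.int(n, max(2, floor(holdout * n)))
  tr <- setdiff(seq_len(n), te)
  Rtr <- simpls(Xs[tr, , drop = FALSE], Ys[tr, , drop = FALSE], n_components)
  rmse <- matrix(NA_real_, n_components, ncol(Ys),
                 dimnames = list(NULL, colnames(params_m)))
  for (a in seq_len(n_components)) {
    Ttr <- Xs[tr, , drop = FALSE] %*% Rtr[, seq_len(a), drop = FALSE]
    Tte <- Xs[te, , drop = FALSE] %*% Rtr[, seq_len(a), drop = FALSE]
    B <- stats::lm.fit(cbind(1, Ttr), Ys[tr, , drop = FALSE])$coefficients
    pred <- cbind(1, Tte) %*% B
    rmse[a, ] <- sqrt(colMeans((Ys[te, , drop = FALSE] - pred)^2))
  }
  list(projection = R, center = ctr, scale = scl, kept = colnames(X),
       scores = scores, rmse = rmse)
}

# SIMPLS (de Jong 1993): returns the p x A projection matrix R such that
# scores T = Xc %*% R are orthogonal and maximize covariance with Y.
simpls <- function(X, Y, A) {
  S <- crossprod(X, Y)
  p <- ncol(X)
  R <- matrix(0, p, A)
  V <- matrix(0, p, A)
  for (a in seq_len(A)) {
    sv <- svd(S, nu = 0, nv = 1)
    q <- sv$v[, 1]
    r <- S %*% q
    t_ <- X %*% r
    t_ <- t_ - mean(t_)
    nt <- sqrt(sum(t_^2))
    if (nt < 1e-12) { R <- R[, seq_len(a - 1), drop = FALSE]; break }
    t_ <- t_ / nt; r <- r / nt
    pvec <- crossprod(X, t_)
    v <- pvec
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pvec)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
  }
  R
}

# transform new statistics into PLS score space
pls_transform <- function(pls, stats_new) {
  if (is.null(dim(stats_new))) stats_new <- rbind(stats_new)
  X <- stats_new[, pls$kept, drop = FALSE]
  Xs <- sweep(sweep(X, 2, pls$center), 2, pls$scale, "/")
  Xs %*% pls$projection
}

#' Regression-adjusted parameter posteriors
#'
#' Rejection in PLS score space followed by weighted local-linear regression
#' adjustment (Epanechnikov weights) of every parameter on the scores; the
#' posterior mode is taken from a weighted kernel density and the 90%
#' highest-posterior-density interval from the same density, both clipped to
#' the prior support.
#'
#' @param observed named numeric summary vector.
#' @param model model index 1..4.
#' @param table that model's reference table.
#' @param config an [abc_config()].
#' @param pls optional precomputed [pls_reduce()] result.
#' @return data.frame per parameter: `mode`, `hpd_lo`, `hpd_hi`, plus
#'   attribute `"adjusted"` (the weighted posterior sample) and `"method"`.
#' @export
estimate_posteriors <- function(observed, model, table, config, pls = NULL) {
  if (is.null(pls))
    pls <- pls_reduce(table$stats, table$params,
                      n_components = min(config$n_pls, nrow(table$stats) - 1))
  sc_tab <- pls_transform(pls, table$stats)
  sc_obs <- pls_transform(pls, rbind(observed))[1, ]
  d <- sqrt(colSums((t(sc_tab) - sc_obs)^2))
  n_keep <- max(2, ceiling(config$tolerance * nrow(sc_tab)))
  idx <- order(d)[seq_len(n_keep)]
  w <- epanechnikov(d[idx], max(d[idx]))
  pr <- model_priors(model)
  adj <- matrix(NA_real_, n_keep, ncol(table$params),
                dimnames = list(NULL, colnames(table$params)))
  degenerate <- FALSE
  Xl <- cbind(1, sc_tab[idx, , drop = FALSE])
  for (j in seq_len(ncol(table$params))) {
    y <- table$params[idx, j]
    fit <- tryCatch(stats::lm.wfit(Xl, y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      adj[, j] <- y
      degenerate <- TRUE
    } else {
      pred_obs <- sum(c(1, sc_obs) * fit$coefficients)
      adj[, j] <- y - fit$fitted.values + pred_obs
    }
    adj[, j] <- pmin(pmax(adj[, j], pr$lo[j]), pr$hi[j])
  }
  out <- data.frame(parameter = colnames(adj), mode = NA_real_,
                    hpd_lo = NA_real_, hpd_hi = NA_real_)
  for (j in seq_len(ncol(adj))) {
    hp <- weighted_hpd(adj[, j], w, level = 0.9)
    out$mode[j] <- min(max(hp$mode, pr$lo[j]), pr$hi[j])
    out$hpd_lo[j] <- max(hp$lo, pr$lo[j])
    out$hpd_hi[j] <- min(hp$hi, pr$hi[j])
  }
  attr(out, "adjusted") <- adj
  attr(out, "weights") <- w
  attr(out, "method") <- if (degenerate) "rejection" else "loclinear"
  out
}

# mode and HPD interval from a weighted kernel density
weighted_hpd <- function(x, w, level = 0.9) {
  if (length(unique(x)) == 1)
    return(list(mode = x[1], lo = x[1], hi = x[1]))
  dn <- stats::density(x, weights = w / sum(w), bw = stats::bw.nrd0(x),
                       n = 512)
  mode <- dn$x[which.max(dn$y)]
  ord <- order(dn$y, decreasing = TRUE)
  mass <- cumsum(dn$y[ord]) / sum(dn$y)
  inc <- ord[seq_len(which(mass >= level)[1])]
  list(mode = mode, lo = min(dn$x[inc]), hi = max(dn$x[inc]))
}

#' Topology-recovery experiment for ABC model choice
#'
#' Builds (or reuses) reference tables for all four candidate models,
#' simulates pseudo-observed data sets at the candidate demographies' own
#' parameter values, and scores whether the ABC posterior favors the
#' generating model. The retained-set size for the multinomial-logistic step
#' defaults to 8,000 pooled rows (the regression sample the reference
#' analysis obtains from its 0.1% tolerance), because at reduced table sizes
#' the regression sample, not the rejection radius, limits accuracy.
#'
#' @param config an [abc_config()].
#' @param n_reps_per_model pseudo-observed replicates per generating model.
#' @param retain number of pooled rows retained for the regression.
#' @param tables optional precomputed reference tables.
#' @return list: `results` data.frame (generating, replicate, winner, hit,
#'   pp_true), `confusion` 4 x 4 matrix, `tables` (invisibly reusable).
#' @export
abc_recovery_experiment <- function(config, n_reps_per_model = 6,
                                    retain = 8000, tables = NULL) {
  if (is.null(tables))
    tables <- lapply(1:4, simulate_reference_table, config = config)
  n_pool <- sum(vapply(tables, function(tb) nrow(tb$stats), 0))
  tol <- min(1, retain / n_pool)
  res <- NULL
  confusion <- matrix(0, 4, 4, dimnames = list(true = 1:4, assigned = 1:4))
  for (g in 1:4) {
    dem <- candidate_demographies(g)
    for (r in seq_len(n_reps_per_model)) {
      des <- sample_design(haplotypes_per_species = config$haplotypes_per_species,
                           n_loci = config$n_loci,
                           locus_length = config$locus_length,
                           seed = derive_seed(config$seed, 7000L + g * 100L + r))
      obs <- simulate_summary_vector(dem, des)
      pp <- suppressWarnings(model_posterior(tables, obs, tolerance = tol))
      win <- as.integer(names(pp)[which.max(pp)])
      confusion[g, win] <- confusion[g, win] + 1
      res <- rbind(res, data.frame(generating = g, replicate = r,
                                   winner = win, hit = win == g,
                                   pp_true = unname(pp[as.character(g)])))
    }
  }
  list(results = res, confusion = confusion, tables = tables)
}

#' Cross-validation of ABC model selection
#'
#' Leave-one-out: pseudo-observed data sets are drawn from each model's
#' reference table, removed from the pooled table, and run through the same
#' rejection + multinomial-logistic model choice as real data. Reports the
#' misassignment matrix (fraction of pseudo-observed sets from each true
#' model assigned to each model) and the mean posterior probability of the
#' true model.
#'
#' @param tables list of reference tables for all models.
#' @param config an [abc_config()]; `n_crossval` sets per model.
#' @param tolerance retained fraction (defaults to `config$tolerance`).
#' @return list: `confusion` (true x assigned fractions), `mean_true_pp`
#'   (per true model), `n_per_model`.
#' @export
cross_validate <- function(tables, config, tolerance = config$tolerance) {
  models <- vapply(tables, `[[`, 0L, "model")
  offsets <- c(0, cumsum(vapply(tables, function(tb) nrow(tb$stats), 0)))
  n_cv <- config$n_crossval
  conf <- matrix(0, length(models), length(models),
                 dimnames = list(true = models, assigned = models))
  mean_pp <- stats::setNames(numeric(length(models)), models)
  set.seed(derive_seed(config$seed, 4242L))
  for (mi in seq_along(models)) {
    n_m <- nrow(tables[[mi]]$stats)
    if (n_cv > n_m) stop("n_crossval exceeds the reference table size")
    rows <- sample.int(n_m, n_cv)
    for (r in rows) {
      obs <- tables[[mi]]$stats[r, ]
      pooled_row <- offsets[mi] + r
      pp <- suppressWarnings(
        model_posterior(tables, obs, tolerance, exclude = pooled_row))
      assigned <- which.max(pp)
      conf[mi, assigned] <- conf[mi, assigned] + 1
      mean_pp[mi] <- mean_pp[mi] + pp[as.character(models[mi])]
    }
    conf[mi, ] <- conf[mi, ] / n_cv
    mean_pp[mi] <- mean_pp[mi] / n_cv
  }
  list(confusion = conf, mean_true_pp = mean_pp, n_per_model = n_cv)
}
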