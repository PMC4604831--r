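test_that("prior sampling respects bounds, scales and ordering", {
  d <- sample_priors(1, 4000, seed = 2)
  pr <- model_priors(1)
  for (i in seq_len(nrow(pr))) {
    expect_gte(min(d[, i]), pr$lo[i])
    expect_lte(max(d[, i]), pr$hi[i])
  }
  # log-uniform: median at the geometric midpoint
  nm <- d[, "Nm_C<-P"]
  expect_equal(median(log10(nm)), mean(log10(c(1e-3, 10))), tolerance = 0.1)
  # split ordering in every draw
  expect_true(all(d[, "T_AP"] < d[, "T_ACP"] & d[, "T_ACP"] < d[, "T_ACPS"]))
  # reproducible
  expect_identical(sample_priors(1, 50, seed = 9), sample_priors(1, 50, seed = 9))
})

test_that("rejection retains exactly the closest rows", {
  set.seed(4)
  stats_m <- matrix(rnorm(5000 * 12), 5000, 12,
                    dimnames = list(NULL, paste0("s", 1:12)))
  obs <- stats_m[17, ]
  rej <- abc_reject(obs, stats_m, 0.01)
  expect_equal(rej$n_retained, 50)
  expect_length(rej$idx, 50)
  # the observed row itself is retained with distance 0
  expect_equal(rej$idx[1], 17)
  expect_equal(rej$dist[1], 0)
  # retained distances never exceed excluded distances
  sc <- quartetcoal:::stat_scales(stats_m)
  z <- sweep(stats_m, 2, sc, "/")
  d <- sqrt(colSums((t(z) - obs / sc)^2))
  expect_lte(max(d[rej$idx]), min(d[-rej$idx]))
  expect_error(abc_reject(obs, stats_m[1:10, ], 0.001), "tolerance")
  expect_equal(abc_reject(obs, stats_m[1:1500, ], 0.001)$n_retained, 2)
  # standardization is invariant to affine rescaling of any statistic
  stats_s <- stats_m; stats_s[, 3] <- stats_s[, 3] * 1000
  obs_s <- obs; obs_s[3] <- obs_s[3] * 1000
  expect_equal(abc_reject(obs_s, stats_s, 0.01)$idx, rej$idx)
})

test_that("model posteriors identify a separated cluster and sum to one", {
  set.seed(8)
  mk <- function(m, shift) list(model = m,
                                params = matrix(runif(300 * 2), 300, 2),
                                stats = matrix(rnorm(300 * 6, shift), 300, 6,
                                               dimnames = list(NULL, paste0("s", 1:6))))
  tables <- list(mk(1, 0), mk(2, 6), mk(3, 12), mk(4, 18))
  obs <- stats::setNames(rep(6, 6), paste0("s", 1:6))
  pp <- suppressWarnings(model_posterior(tables, obs, tolerance = 0.2))
  expect_equal(sum(pp), 1, tolerance = 1e-12)
  expect_equal(unname(which.max(pp)), 2L)
  expect_gt(pp[["2"]], 0.9)
  # exchangeable models: posterior near uniform on average
  tabs_same <- lapply(1:4, function(m) mk(m, 0))
  pps <- vapply(1:12, function(r) {
    o <- stats::setNames(rnorm(6), paste0("s", 1:6))
    model_posterior(tabs_same, o, tolerance = 0.5)
  }, numeric(4))
  expect_lt(max(abs(rowMeans(pps) - 0.25)), 0.15)
})

test_that("PLS components are orthogonal and capture linear signal", {
  set.seed(5)
  n <- 400
  y <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  X <- cbind(y[, 1] * 2 + rnorm(n, 0, 1e-4),
             matrix(rnorm(n * 9), n, 9))
  colnames(X) <- paste0("s", 1:10)
  pls <- pls_reduce(X, y, n_components = 4)
  G <- crossprod(pls$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # single target perfectly linear in one statistic: first component
  # explains essentially all of it (large n so chance correlations of the
  # noise statistics are negligible)
  nb <- 20000
  yb <- matrix(runif(nb), nb, 1, dimnames = list(NULL, "p1"))
  Xb <- cbind(yb[, 1] * 2 + rnorm(nb, 0, 1e-4), matrix(rnorm(nb * 9), nb, 9))
  colnames(Xb) <- paste0("s", 1:10)
  pls1 <- pls_reduce(Xb, yb, n_components = 2)
  expect_gt(summary(lm(yb[, 1] ~ pls1$scores[, 1]))$r.squared, 0.999)
  # RMSE is reported per component and is non-increasing overall for p1
  expect_equal(dim(pls$rmse), c(4, 3))
  expect_lt(pls$rmse[4, "p1"], pls$rmse[1, "p1"] + 1e-8)
  # constant columns are dropped with a warning
  X2 <- X; X2[, 7] <- 1
  expect_warning(pls_reduce(X2, y, n_components = 2), "constant")
})

test_that("regression-adjusted posteriors stay in the prior and cover truth", {
  # table for model 1 around a known truth region
  cfg <- abc_config(n_sims = 500, tolerance = 0.1, n_pls = 5,
                    n_loci = 40, locus_length = 1000,
                    haplotypes_per_species = 8, seed = 11)
  tab <- simulate_reference_table(1, cfg)
  dem <- candidate_demographies(1)
  des <- sample_design(haplotypes_per_species = 8, n_loci = 40,
                       locus_length = 1000, seed = 99)
  obs <- quartetcoal:::simulate_summary_vector(dem, des)
  post <- estimate_posteriors(obs, 1, tab, cfg)
  pr <- model_priors(1)
  expect_equal(post$parameter, pr$name)
  expect_true(all(post$hpd_lo >= pr$lo - 1e-9))
  expect_true(all(post$hpd_hi <= pr$hi + 1e-9))
  expect_true(all(post$mode >= pr$lo & post$mode <= pr$hi))
  expect_true(all(post$hpd_lo <= post$mode & post$mode <= post$hpd_hi))
  # with a wide prior and modest data most HPDs should cover the truth
  truth <- c(stats::setNames(dem$ne, paste0("N_", names(dem$ne))),
             stats::setNames(dem$ne_anc[c("AP", "ACP", "ACPS")],
                             paste0("NA_", c("AP", "ACP", "ACPS"))),
             stats::setNames(sort(dem$split_times),
                             paste0("T_", names(sort(dem$split_times)))),
             stats::setNames(dem$migration,
                             paste0("Nm_", names(dem$migration))))
  covered <- post$hpd_lo <= truth[post$parameter] &
    truth[post$parameter] <= post$hpd_hi
  expect_gte(mean(covered), 0.7)
})

test_that("cross-validation on exchangeable models is near-uniform", {
  set.seed(13)
  mk <- function(m) list(model = m,
                         params = matrix(runif(150 * 2), 150, 2),
                         stats = matrix(rnorm(150 * 5), 150, 5,
                                        dimnames = list(NULL, paste0("s", 1:5))))
  tables <- lapply(1:4, mk)
  cfg <- abc_config(n_sims = 150, n_crossval = 12, seed = 17)
  cv <- cross_validate(tables, cfg, tolerance = 0.4)
  expect_equal(dim(cv$confusion), c(4, 4))
  expect_equal(unname(rowSums(cv$confusion)), rep(1, 4))
  # identical generating processes: roughly 3/4 of assignments off-diagonal
  expect_lt(mean(diag(cv$confusion)), 0.6)
  expect_error(cross_validate(tables, abc_config(n_crossval = 999, seed = 1)),
               "exceeds")
})
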