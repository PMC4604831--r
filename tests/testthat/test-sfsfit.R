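test_that("sfs2d enforces its invariants", {
  s <- sfs2d(matrix(1:9, 3, 3), pair = c("A", "B"))
  expect_equal(s$n, c(2L, 2L))
  expect_equal(s$total_sites, 45)
  expect_error(sfs2d(matrix(-1, 2, 2), c("A", "B")), ">= 0")
})

test_that("build_sfs matches hand counts on a toy table", {
  v <- data.frame(chrom = "c1", pos = c(5, 17, 101, 150, 420, 999),
                  anc = "A", der = "G",
                  a1 = c(1, 0, 1, 1, 0, 1), a2 = c(0, 0, 1, 0, 0, 1),
                  b1 = c(0, 1, 1, 0, 0, 0), b2 = c(0, 1, 0, 0, 1, 0),
                  check.names = FALSE)
  sm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  s <- build_sfs(v, sm, pair = c("A", "B"), project_to = 2, window_bp = 100)
  # hand count: windows 0,1,4,9 scanned -> 400 sites; configurations
  # (1,0) x2, (0,2), (2,1), (0,1), (2,0)
  expect_equal(s$total_sites, 400)
  expect_equal(s$counts[2, 1], 2)
  expect_equal(s$counts[1, 3], 1)
  expect_equal(s$counts[3, 2], 1)
  expect_equal(s$counts[1, 2], 1)
  expect_equal(s$counts[3, 1], 1)
  expect_equal(s$counts[1, 1], 400 - 6)
  expect_equal(sum(s$counts), 400)
  expect_error(build_sfs(v, sm, pair = c("A", "Z")), "key error")
  # masked windows are excluded
  mask <- data.frame(chrom = "c1", window = c(0, 4), masked_frac = c(0.5, 0.1))
  s2 <- build_sfs(v, sm, pair = c("A", "B"), project_to = 2,
                  window_bp = 100, mask = mask)
  expect_equal(s2$total_sites, 300)
})

test_that("hypergeometric projection matches a sampling oracle", {
  # one site: 30 derived among 48 chromosomes projected to 24
  haps_a <- paste0("a", 1:48); haps_b <- paste0("b", 1:48)
  v <- data.frame(chrom = "c1", pos = 1, anc = "A", der = "G",
                  check.names = FALSE)
  for (h in haps_a) v[[h]] <- as.integer(match(h, haps_a) <= 30)
  for (h in haps_b) v[[h]] <- 0L
  sm <- c(stats::setNames(rep("A", 48), haps_a),
          stats::setNames(rep("B", 48), haps_b))
  s <- build_sfs(v, sm, pair = c("A", "B"), project_to = 24, window_bp = 100)
  w <- rowSums(s$counts)
  w[1] <- w[1] - (100 - 1)              # remove the monomorphic filler
  expect_equal(sum(w), 1)
  expect_equal(sum((0:24) * w), 24 * 30 / 48)   # E[i] = 15
  # sampling oracle
  set.seed(1)
  draws <- vapply(1:10000, function(r) sum(sample(rep(c(1, 0), c(30, 18)), 24)), 0)
  emp <- tabulate(draws + 1, 25) / 10000
  expect_lt(max(abs(emp - w)), 4 * sqrt(max(w * (1 - w)) / 10000) + 0.002)
})

test_that("expected spectra have the analytic limits", {
  dem <- toy_demography(2, N = 2e4, t_split = 1)
  ex <- expected_sfs(dem, n_per_species = 8, n_sims = 3000, seed = 3,
                     ratio_of_means = TRUE)
  p <- ex[["A-B"]]
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # near-panmictic pooled marginal follows Watterson's 1/i law
  marg <- vapply(1:15, function(i) {
    s <- 0
    for (a in 0:8) for (b in 0:8) if (a + b == i) s <- s + p[a + 1, b + 1]
    s
  }, 0)
  expect_lt(max(abs(marg * (1:15) / marg[1] - 1)), 0.2)
  # exchangeable demography: symmetric under (i,j) <-> (j,i)
  expect_lt(max(abs(p - t(p))), 0.05 * max(p[-1, -1]))
  # mu -> 0 concentrates all mass at (0,0)
  dem0 <- demography(species = c("A", "B"), topology = "(A,B);",
                     split_times = c(AB = 1), ne = c(A = 2e4, B = 2e4),
                     ne_anc = c(AB = 2e4), mu = 1e-300)
  p0 <- expected_sfs(dem0, n_per_species = 4, n_sims = 200, seed = 1)[["A-B"]]
  expect_equal(p0[1, 1], 1, tolerance = 1e-10)
})

test_that("composite log-likelihood is exact and Gibbs-maximal", {
  cnt <- matrix(c(5, 2, 0, 1, 0, 3, 0, 0, 4), 3, 3)
  p <- matrix(c(.3, .1, .05, .1, .05, .1, .05, .05, .2), 3, 3)
  obs <- list("A-B" = sfs2d(cnt, c("A", "B")))
  expect_equal(composite_loglik(obs, list("A-B" = p)),
               sum(cnt[cnt > 0] * log(p[cnt > 0])))
  # zero-count cells do not contribute even with p = 0
  p2 <- p; p2[3, 1] <- 0
  expect_equal(composite_loglik(obs, list("A-B" = p2)),
               composite_loglik(obs, list("A-B" = p)))
  expect_error(composite_loglik(obs, list("A-B" = p[1:2, 1:2])), "shape")
  # maximal at the generating proportions along a 1-D mixture slice
  truth <- cnt / sum(cnt)
  other <- matrix(1 / 9, 3, 3)
  ll <- vapply(seq(0, 1, 0.1), function(a)
    composite_loglik(obs, list("A-B" = (1 - a) * truth + a * other)), 0)
  expect_equal(which.max(ll), 1)
})

test_that("AIC comparison reproduces the published arithmetic", {
  mk <- function(lnl, m) structure(list(model = m,
                                        topology = candidate_topologies()[m],
                                        par = numeric(16), logL = lnl,
                                        AIC = 2 * 16 - 2 * lnl,
                                        runs = lnl, n_params = 16),
                                   class = "model_fit")
  # equal fits: equal weights
  cmp0 <- compare_models(lapply(1:4, function(m) mk(-1000, m)))
  expect_equal(cmp0$weight, rep(0.25, 4))
  # a 1,060 natural-log-unit gap at equal k gives delta AIC = 2,120 and
  # essentially all weight on the best model
  cmp <- compare_models(list(mk(-4052489, 1), mk(-4053549, 2)))
  expect_equal(cmp$delta_aic, c(0, 2120))
  expect_gt(cmp$weight[1], 0.999)
  expect_equal(cmp$delta_aic[1], 0)
  expect_equal(sum(cmp$weight), 1)
  expect_error(compare_models(list(mk(-1, 1))), ">= 2")
})

test_that("model fitting is reproducible and reports its best run", {
  dem <- candidate_demographies(1)
  obs <- simulate_sfs_counts(dem, n_per_species = 8, n_windows = 3000,
                             window_bp = 100, seed = 6)
  f1 <- fit_model(1, obs, n_runs = 1, seed = 5, n_sims = 120,
                  n_sims_final = 500, maxit = 25)
  f2 <- fit_model(1, obs, n_runs = 1, seed = 5, n_sims = 120,
                  n_sims_final = 500, maxit = 25)
  expect_equal(f1$par, f2$par)
  expect_equal(f1$logL, f2$logL)
  expect_equal(f1$AIC, 2 * 16 - 2 * f1$logL)
  f3 <- fit_model(1, obs, n_runs = 3, seed = 5, n_sims = 120,
                  n_sims_final = 500, maxit = 25)
  expect_gte(max(f3$runs), max(f1$runs))
})

test_that("block resampling yields percentile intervals", {
  # degenerate pool: identical replicates give zero-width intervals
  dem <- candidate_demographies(1)
  obs_fixed <- simulate_sfs_counts(dem, n_per_species = 8, n_windows = 2000,
                                   window_bp = 100, seed = 9)
  ci <- block_resample_ci(function(seed) obs_fixed, model = 1, n_reps = 3,
                          fit_args = list(n_runs = 1, n_sims = 100,
                                          n_sims_final = 200, maxit = 10),
                          seed = 2)
  expect_true(all(ci$ci[, "hi"] - ci$ci[, "lo"] < 1e-8))
  expect_error(block_resample_ci(function(seed) obs_fixed, 1, n_reps = 1),
               ">= 2")
  # percentile definition matches the sort-based oracle
  x <- c(4, 9, 1, 7, 3, 8, 2)
  expect_equal(unname(stats::quantile(x, 0.05, type = 7)),
               percentile_oracle(x, 0.05))
  expect_equal(unname(stats::quantile(x, 0.95, type = 7)),
               percentile_oracle(x, 0.95))
})

test_that("SFS text files round-trip", {
  s <- sfs2d(matrix(c(90, 3, 2, 5), 2, 2), pair = c("C", "P"),
             total_sites = 100)
  f <- tempfile(fileext = ".txt")
  write_sfs(s, f)
  s2 <- read_sfs(f)
  expect_equal(s2$counts, s$counts)
  expect_equal(s2$pair, s$pair)
  expect_equal(s2$total_sites, s$total_sites)
  unlink(f)
})
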