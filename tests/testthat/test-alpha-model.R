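test_that("the parametric covariance has the stated closed forms", {
  set.seed(2)
  S <- 6
  D <- as.matrix(dist(cbind(runif(S), runif(S))))
  D <- D / sd(D[lower.tri(D)])
  E <- as.matrix(dist(rnorm(S)))
  E <- E / sd(E[lower.tri(E)])

  # no isolation: every entry 1/alpha0 (diagonal plus jitter)
  Om0 <- build_covariance(list(alpha0 = 4, alphaD = 0, alphaE = 0,
                               alpha2 = 1), D, list(E))
  off <- Om0[lower.tri(Om0)]
  expect_equal(off, rep(1 / 4, length(off)), tolerance = 1e-12)
  expect_equal(diag(Om0), rep(1 / 4 + 1e-8 / 4, S), ignore_attr = TRUE)

  # alpha2 = 1: -log(alpha0 * Omega_ij) recovers the linear predictor exactly
  p <- list(alpha0 = 2, alphaD = 0.7, alphaE = 0.4, alpha2 = 1)
  Om <- build_covariance(p, D, list(E))
  lin <- p$alphaD * D + p$alphaE * E
  expect_equal(-log(p$alpha0 * Om[lower.tri(Om)]), lin[lower.tri(lin)],
               tolerance = 1e-10)
})

test_that("random geographic/ecological configurations stay positive definite", {
  ok <- 0L
  tries <- 0L
  for (seed in 1:34) {
    for (a2 in c(0.5, 1, 2)) {
      if (tries >= 100L) break
      tries <- tries + 1L
      set.seed(seed * 100 + a2 * 10)
      s <- simulate_sites(8, seed = seed)
      D <- standardize_distance(great_circle_matrix(s))
      E <- standardize_distance(climate_pca_distance(s))
      p <- list(alpha0 = runif(1, 0.5, 10), alphaD = runif(1, 0, 1),
                alphaE = runif(1, 0, 1), alpha2 = a2)
      Om <- tryCatch(build_covariance(p, D, list(E)), error = function(e) NULL)
      # oracle: eigenvalue check, independent of the chol route
      if (!is.null(Om) && min(eigen(Om, symmetric = TRUE,
                                    only.values = TRUE)$values) > 0)
        ok <- ok + 1L
    }
  }
  expect_identical(ok, tries)
})

test_that("covariance entries strictly decrease as alpha terms grow", {
  set.seed(3)
  s <- simulate_sites(6, seed = 3)
  D <- standardize_distance(great_circle_matrix(s))
  E <- standardize_distance(climate_pca_distance(s))
  base <- list(alpha0 = 2, alphaD = 0.2, alphaE = 0.2, alpha2 = 1)
  Om1 <- build_covariance(base, D, list(E))
  for (bump in list(list(alphaD = 0.5), list(alphaE = 0.5))) {
    p2 <- utils::modifyList(base, bump)
    Om2 <- build_covariance(p2, D, list(E))
    expect_true(all(Om2[lower.tri(Om2)] < Om1[lower.tri(Om1)]))
  }
})

test_that("log posterior matches the longhand 1x1 evaluation and edge cases", {
  # single locus, single site: Normal + Binomial + priors, all longhand
  b <- biallelic_counts(matrix(3, 1, 1, dimnames = list("s1", "l1")),
                        matrix(10, 1, 1, dimnames = list("s1", "l1")))
  st <- list(alpha0 = 2, alphaD = 0.5, alphaE = 0.7, alpha2 = 1,
             mu = 0.4, theta = matrix(0.35, 1, 1))
  lp <- log_posterior(st, b, matrix(0, 1, 1), list(matrix(0, 1, 1)))
  expect_equal(lp, -5.088532366200690, tolerance = 1e-10)

  # x = 0 everywhere with theta < 0 (f clamps to 0): binomial terms vanish,
  # posterior stays finite
  b0 <- biallelic_counts(matrix(0, 2, 2, dimnames = list(c("s1", "s2"),
                                                         c("l1", "l2"))),
                         matrix(10, 2, 2, dimnames = list(c("s1", "s2"),
                                                          c("l1", "l2"))))
  D2 <- matrix(c(0, 1, 1, 0), 2, 2)
  st0 <- list(alpha0 = 2, alphaD = 0.5, alphaE = numeric(0), alpha2 = 1,
              mu = c(0.3, 0.4), theta = matrix(-0.2, 2, 2))
  lp0 <- log_posterior(st0, b0, D2, list())
  expect_true(is.finite(lp0))

  # f = 0 with x > 0 is impossible data: -Inf, not an exception
  bx <- biallelic_counts(matrix(c(2, 0, 0, 0), 2, 2,
                                dimnames = dimnames(b0$x)),
                         b0$n)
  expect_identical(log_posterior(st0, bx, D2, list()), -Inf)

  # doubling n with x = n/2 at f = 0.5 changes only computable constants
  mk <- function(n) biallelic_counts(
    matrix(n / 2, 2, 1, dimnames = list(c("s1", "s2"), "l1")),
    matrix(n, 2, 1, dimnames = list(c("s1", "s2"), "l1")))
  st5 <- list(alpha0 = 2, alphaD = 0.5, alphaE = numeric(0), alpha2 = 1,
              mu = 0.5, theta = matrix(0.5, 2, 1))
  delta <- log_posterior(st5, mk(20), D2, list()) -
    log_posterior(st5, mk(10), D2, list())
  longhand <- (lchoose(20, 10) - lchoose(10, 5)) * 2 + 2 * 10 * log(0.5)
  expect_equal(delta, longhand, tolerance = 1e-10)
})

test_that("chains are exactly reproducible under a fixed seed", {
  sim <- simulate_pair(pair_config(S = 6, L = 15, seed = 17))
  D <- unclass(great_circle_matrix(sim$pair$sites))
  E <- list(host = unclass(pairwise_fst(sim$pair$host)))
  cfg <- mcmc_desk_config(n_iter = 3000, thin_to = 300)
  m1 <- run_mcmc(sim$pair$associate, D, E, cfg, seed = 5)
  m2 <- run_mcmc(sim$pair$associate, D, E, cfg, seed = 5)
  expect_identical(m1$draws, m2$draws)
  expect_true(all(m1$acc_rate >= 0 & m1$acc_rate <= 1, na.rm = TRUE))
  # a different seed gives a different chain
  m3 <- run_mcmc(sim$pair$associate, D, E, cfg, seed = 6)
  expect_false(identical(m1$draws, m3$draws))
})

test_that("posterior summaries reduce to order statistics", {
  # constant chain
  d <- cbind(alpha0 = rep(2.5, 100), alphaD = rep(1, 100), alpha2 = 1,
             lp = 0, iter = 1:100)
  ps <- posterior_summary(d, burn_frac = 0.5)
  expect_equal(ps["alpha0", "median"], 2.5)
  expect_equal(ps["alpha0", "l95"], 2.5)
  expect_equal(ps["alpha0", "u95"], 2.5)
  # chain 1..1000, burn half: summaries of 501..1000
  d2 <- cbind(alphaD = 1:1000, lp = 0, iter = 1:1000)
  ps2 <- posterior_summary(d2, burn_frac = 0.5)
  expect_equal(ps2["alphaD", "median"], median(501:1000))
  expect_equal(ps2["alphaD", "l95"], unname(quantile(501:1000, 0.025)))
  expect_equal(ps2["alphaD", "n_draws"], 500)
  expect_error(posterior_summary(d2, burn_frac = 1), "no retained")
})

test_that("an IBD-only model recovers geographic isolation without ecological channels", {
  # alphaE list empty: pure isolation by distance
  sites <- simulate_sites(10, seed = 41)
  D <- standardize_distance(great_circle_matrix(sites))
  counts <- simulate_species_counts(sites, D, list(),
                                    params = list(alpha0 = 10, alphaD = 1,
                                                  alphaE = numeric(0),
                                                  alpha2 = 1),
                                    L = 50, seed = 42)
  m <- run_mcmc(counts, unclass(great_circle_matrix(sites)), list(),
                mcmc_desk_config(n_iter = 3e4, thin_to = 1000), seed = 7)
  ps <- posterior_summary(m)
  expect_false("alphaE" %in% rownames(ps))
  # posterior for alphaD concentrates away from 0 and below 10x truth
  expect_gt(ps["alphaD", "median"], 0.05)
  expect_lt(ps["alphaD", "u95"], 10)
})

test_that("alpha traces pass a Geweke-style stationarity check on stationary runs", {
  sim <- simulate_pair(pair_config(S = 8, L = 25, seed = 23))
  D <- unclass(great_circle_matrix(sim$pair$sites))
  E <- list(host = unclass(pairwise_fst(sim$pair$host)))
  m <- run_mcmc(sim$pair$associate, D, E, mcmc_desk_config(n_iter = 5e4),
                seed = 11)
  keep <- m$draws[m$draws[, "iter"] > m$n_burn, ]
  for (par in c("alphaD", "alphaE_host")) {
    v <- keep[, par]
    n <- length(v)
    a <- v[seq_len(floor(0.1 * n))]
    b <- v[seq.int(floor(0.5 * n) + 1, n)]
    # batch-means standard errors to absorb autocorrelation
    bm <- function(x, nb = 10) {
      bs <- floor(length(x) / nb)
      mns <- vapply(seq_len(nb), function(i)
        mean(x[seq.int((i - 1) * bs + 1, i * bs)]), 0)
      sd(mns) / sqrt(nb)
    }
    z <- (mean(a) - mean(b)) / sqrt(bm(a)^2 + bm(b)^2)
    expect_lt(abs(z), 3)
  }
})
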