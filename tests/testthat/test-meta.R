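test_that("correlation pooling matches longhand DerSimonian-Laird arithmetic", {
  # frozen longhand fixture: 4 studies on the Fisher-z scale
  r <- pool_correlations(c(0.6, 0.3, 0.45, -0.1), c(15, 45, 10, 105))
  expect_equal(r$estimate, 0.265528307627980, tolerance = 1e-10)
  expect_equal(r$tau2, 0.093785433653338, tolerance = 1e-10)
  expect_equal(r$Q, 11.174867738322845, tolerance = 1e-10)
  expect_equal(r$ci95, c(-0.097846044936238, 0.566432048911881),
               tolerance = 1e-10)
  expect_equal(r$df, 3L)

  # single study: identity within 1e-12
  r1 <- pool_correlations(0.42, 28)
  expect_equal(r1$estimate, 0.42, tolerance = 1e-12)
  expect_equal(r1$tau2, 0)

  # equal studies: pooled = common value, no heterogeneity
  re <- pool_correlations(rep(0.3, 5), rep(21, 5))
  expect_equal(re$estimate, 0.3, tolerance = 1e-12)
  expect_equal(re$Q, 0)
  expect_equal(re$tau2, 0)

  expect_error(pool_correlations(0.5, 3), "n_pairs")

  # a perfect correlation from few site pairs is shrunk, not infinite
  rp <- pool_correlations(c(1, 0.5, 0.4), c(6, 10, 15))
  expect_true(is.finite(rp$estimate))
  expect_lt(rp$estimate, 1)
  expect_equal(fisher_z(1, 6), atanh(1 - 1 / 12), tolerance = 1e-12)
})

test_that("mean-effect pooling matches longhand DerSimonian-Laird arithmetic", {
  r <- pool_means(c(1.2, 0.8, 2.0, 1.5, 0.4), c(0.3, 0.5, 0.4, 0.25, 0.6))
  expect_equal(r$estimate, 1.299943784963592, tolerance = 1e-10)
  expect_equal(r$tau2, 0.101902292446702, tolerance = 1e-10)
  expect_equal(r$Q, 6.967523260284505, tolerance = 1e-10)
  expect_equal(r$ci95, c(0.862975134918958, 1.736912435008226),
               tolerance = 1e-10)

  ri <- pool_means(c(0.7, 0.7, 0.7), c(0.2, 0.2, 0.2))
  expect_equal(ri$estimate, 0.7, tolerance = 1e-12)
  expect_equal(ri$tau2, 0)
  expect_equal(pool_means(1.3, 0.4)$estimate, 1.3, tolerance = 1e-12)
  expect_error(pool_means(c(1, 2), c(0.1, 0)), "positive")
})

test_that("pooling agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(20)
  y <- rnorm(8, 0.8, 0.5)
  se <- runif(8, 0.1, 0.5)
  ours <- pool_means(y, se)
  ref <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(ours$estimate, unname(ref$beta[1]), tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(ours$Q, ref$QE, tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)

  rho <- c(0.6, 0.2, 0.4, -0.1, 0.5)
  np <- c(15, 45, 28, 66, 10)
  oc <- pool_correlations(rho, np)
  rc <- metafor::rma(yi = atanh(rho), vi = 1 / (np - 3), method = "DL")
  expect_equal(atanh(oc$estimate), unname(rc$beta[1]), tolerance = 1e-8)
  expect_equal(oc$tau2, rc$tau2, tolerance = 1e-8)

  # subgroup test equals the omnibus moderator test of a categorical
  # mixed-effects meta-regression
  g <- c("A", "B", "A", "B", "A", "B", "A", "A")
  oss <- subgroup_test(y, se, g)
  rs <- metafor::rma(yi = y, sei = se, mods = ~ factor(g), method = "DL")
  expect_equal(oss$subgroup$Q_between, rs$QM, tolerance = 1e-8)
  expect_equal(oss$subgroup$p_between, rs$QMp, tolerance = 1e-8)
  expect_equal(oss$subgroup$tau2_common, rs$tau2, tolerance = 1e-8)
})

test_that("subgroup heterogeneity uses common-tau2 partitioning", {
  # frozen longhand fixture
  est <- c(1.2, 0.8, 2.0, 1.5, 0.4)
  se <- c(0.3, 0.5, 0.4, 0.25, 0.6)
  sg <- subgroup_test(est, se, c("A", "A", "B", "B", "B"))
  expect_equal(sg$subgroup$Q_between, 0.688562963585266, tolerance = 1e-10)
  expect_equal(sg$subgroup$p_between, 0.406653600548708, tolerance = 1e-10)
  expect_equal(sg$subgroup$tau2_common, 0.127256637168142, tolerance = 1e-10)
  expect_equal(sg$subgroup$df_between, 1L)

  # identically composed groups: no between-group heterogeneity
  s0 <- subgroup_test(c(1, 2, 1, 2), c(0.3, 0.3, 0.3, 0.3),
                      c("A", "A", "B", "B"))
  expect_equal(s0$subgroup$Q_between, 0, tolerance = 1e-12)
  expect_equal(s0$subgroup$p_between, 1, tolerance = 1e-12)

  # grossly separated means with tiny variances: overwhelming evidence
  s1 <- subgroup_test(c(0.1, 0.12, 5, 5.1), c(0.05, 0.05, 0.05, 0.05),
                      c("A", "A", "B", "B"))
  expect_lt(s1$subgroup$p_between, 1e-3)

  expect_error(subgroup_test(1:3, rep(0.1, 3), rep("A", 3)), "2 groups")
})

test_that("subgroup test keeps nominal size on homogeneous null panels", {
  # homogeneous effects, random interaction-type labels: the chi-square
  # reference for Q_between holds its level (under real extra heterogeneity
  # the DL chi-square test is known to be mildly anti-conservative; the
  # homogeneous case is the calibration contract)
  nrep <- 200
  hits <- 0L
  for (r in seq_len(nrep)) {
    set.seed(r + 880)
    se <- runif(12, 0.15, 0.3)
    y <- rnorm(12, 1, se)
    g <- sample(rep(c("antagonist", "mutualist"), c(5, 7)))
    hits <- hits + (subgroup_test(y, se, g)$subgroup$p_between < 0.05)
  }
  band <- qbinom(c(0.025, 0.975), nrep, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("meta invariants: order invariance, range containment, Q shift invariance", {
  set.seed(9)
  rho <- runif(6, -0.2, 0.7)
  np <- sample(10:60, 6)
  r1 <- pool_correlations(rho, np)
  o <- sample(6)
  r2 <- pool_correlations(rho[o], np[o])
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r1$tau2, r2$tau2, tolerance = 1e-12)

  # with no heterogeneity the pooled value lies within the study range
  re <- pool_correlations(c(0.30, 0.31, 0.29), c(30, 28, 25))
  expect_gte(re$estimate, 0.29 - 1e-9)
  expect_lte(re$estimate, 0.31 + 1e-9)

  # Q is invariant to adding a constant to every z
  z <- atanh(rho)
  v <- 1 / (np - 3)
  q1 <- hostassoc:::dl_pool(z, v)$Q
  q2 <- hostassoc:::dl_pool(z + 0.7, v)$Q
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("close-relative pruning enumerates exclusions and flags pivotal studies", {
  eff <- data.frame(
    pair_id = sprintf("p%02d", 1:10),
    estimate = c(0.5, 0.6, 0.4, 0.55, 0.5, 0.45, 0.6, 0.5, 0.4, 0.5),
    se = rep(0.2, 10),
    relative_group = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4", NA, NA),
    stringsAsFactors = FALSE)
  scan <- prune_relatives_scan(eff)
  expect_length(scan$results, 16L)  # 2^4 pruned datasets
  expect_false(any(scan$report$flagged))  # homogeneous panel: no flips

  # no relative groups: single result identical to the full pooling
  eff0 <- eff[, c("pair_id", "estimate", "se")]
  scan0 <- prune_relatives_scan(eff0)
  expect_length(scan0$results, 1L)
  expect_equal(scan0$results[[1]]$estimate, scan0$full$estimate)

  # one relative drives the pooled effect: its exclusions get flagged
  # (a precise strong study among imprecise weak ones; removing it drags
  # the pooled CI across zero)
  effd <- data.frame(
    pair_id = c("big", "twin", "a", "b", "c"),
    estimate = c(0.6, 0.3, 0.2, 0.25, 0.15),
    se = c(0.1, 0.3, 0.3, 0.3, 0.3),
    relative_group = c("g1", "g1", NA, NA, NA),
    stringsAsFactors = FALSE)
  scand <- prune_relatives_scan(effd)
  expect_length(scand$results, 2L)
  flagged <- scand$report$flagged[scand$report$excluded == "big"]
  expect_true(flagged)

  effbad <- eff
  effbad$relative_group[2] <- "g9"
  expect_error(prune_relatives_scan(effbad), "exactly 2")
})
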