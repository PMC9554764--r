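test_that("multiallelic loci recode into per-allele pseudoloci, biallelic pass through", {
  g <- tiny_genotypes()
  b <- recode_pseudoloci(g)
  # triallelic ssr1 -> 3 pseudoloci; biallelic snp1 -> 1 (focal = first allele)
  expect_identical(b$pseudoloci, c("ssr1.A", "ssr1.B", "ssr1.C", "snp1"))
  expect_identical(b$origin_locus, c("ssr1", "ssr1", "ssr1", "snp1"))
  # conservation: focal counts of the k pseudoloci sum to the locus sample size
  tot <- rowSums(g$counts$ssr1)
  expect_equal(unname(rowSums(b$x[, 1:3])), unname(tot))
  # site with counts {A:3, B:1, C:0}
  expect_equal(unname(b$x["a", 1:3]), c(3, 1, 0))
  # biallelic focal allele is lexicographically first (G before T)
  expect_equal(unname(b$x[, "snp1"]), unname(g$counts$snp1[, "G"]))
  # every pseudolocus n equals its origin-locus total
  expect_true(all(b$n[, 1:3] == tot))
})

test_that("all-zero loci are dropped with a warning", {
  sites <- c("a", "b", "c", "d")
  empty <- matrix(0, 4, 2, dimnames = list(sites, c("A", "B")))
  keep <- matrix(c(3, 1, 2, 2, 1, 3, 4, 0), 4, 2,
                 dimnames = list(sites, c("A", "B")))
  g <- multiallelic_genotypes(list(dead = empty, ok = keep))
  expect_warning(b <- recode_pseudoloci(g), "dead")
  expect_identical(b$pseudoloci, "ok")
})

test_that("pairwise FST matches the longhand variance-component oracle", {
  sites <- c("p1", "p2")
  x <- matrix(c(6, 2, 5, 5), 2, 2, dimnames = list(sites, c("l1", "l2")))
  n <- matrix(10, 2, 2, dimnames = dimnames(x))
  th <- pairwise_fst(biallelic_counts(x, n))[1, 2]
  expect_equal(th, oracle_theta(c(6, 5), c(2, 5), c(10, 10), c(10, 10)),
               tolerance = 1e-12)
  expect_equal(th, 0.056603773584906, tolerance = 1e-12)
})

test_that("FST is 1 for fixed differences and <= 0 for identical frequencies", {
  sites <- c("p1", "p2")
  xf <- matrix(c(20, 0, 20, 0), 2, 2, dimnames = list(sites, c("l1", "l2")))
  nf <- matrix(20, 2, 2, dimnames = dimnames(xf))
  expect_equal(pairwise_fst(biallelic_counts(xf, nf))[1, 2], 1)

  xi <- matrix(c(8, 8, 12, 12), 2, 2, dimnames = list(sites, c("l1", "l2")))
  expect_lte(pairwise_fst(biallelic_counts(xi, nf))[1, 2], 0)
})

test_that("FST handles monomorphic pairs, bad sample sizes, and permutations", {
  sites <- c("p1", "p2", "p3")
  # p1-p2 monomorphic at both loci (fixed same allele); p3 polymorphic
  x <- matrix(c(20, 20, 10,
                20, 20, 5), 3, 2, dimnames = list(sites, c("l1", "l2")))
  n <- matrix(20, 3, 2, dimnames = dimnames(x))
  expect_warning(d <- pairwise_fst(biallelic_counts(x, n)), "monomorphic")
  expect_equal(d["p1", "p2"], 0)

  expect_error(pairwise_fst(biallelic_counts(
    matrix(c(1, 1), 1, 2, dimnames = list("p1", c("l1", "l2"))),
    matrix(1, 1, 2, dimnames = list("p1", c("l1", "l2"))))), "2 sampled")

  # permuting site order permutes the matrix consistently; theta <= 1 always
  b <- tiny_counts(S = 5, L = 8, seed = 21)
  d1 <- pairwise_fst(b)
  pm <- c(3, 1, 5, 2, 4)
  bp <- biallelic_counts(b$x[pm, ], b$n[pm, ])
  d2 <- pairwise_fst(bp)
  expect_equal(unclass(d2), unclass(d1)[pm, pm], ignore_attr = TRUE,
               tolerance = 1e-14)
  for (seed in 1:10)
    expect_true(all(dm_pairs(pairwise_fst(tiny_counts(S = 4, L = 5,
                                                      seed = seed))) <= 1))
})

test_that("Rousset transform is D/(1-D), strictly monotone, and guards D >= 1", {
  d <- sym_dist(c(0, 0.5, -0.02, 0.2, 0.3, 0.1), paste0("s", 1:4))
  r <- rousset_transform(d)
  expect_equal(dm_kind(r), "genetic_rousset")
  expect_equal(r[2, 1], 0)
  expect_equal(r[3, 1], 1)
  expect_equal(r[4, 1], -0.02 / 1.02)
  # strict monotonicity on random values below 1
  set.seed(4)
  v <- sort(runif(20, -0.1, 0.9))
  tv <- v / (1 - v)
  expect_true(all(diff(tv) > 0))
  dbad <- sym_dist(c(0.2, 1.3, 0.1, 0.4, 0.2, 0.5), paste0("s", 1:4))
  expect_error(rousset_transform(dbad), "s1-s3|s3-s1")
})

test_that("great-circle distances match the longhand haversine oracle", {
  s <- site_table(c("a", "b"), c(34, 36), c(-118, -115))
  d <- great_circle_matrix(s)
  expect_equal(d[1, 2], 352.689791600833, tolerance = 1e-9)
  # antipodal points on the equator sit pi * radius apart
  s2 <- site_table(c("a", "b"), c(0, 0), c(0, 180))
  expect_equal(great_circle_matrix(s2)[1, 2], pi * 6378.388, tolerance = 1e-9)
  # identical coordinates -> 0
  s3 <- site_table(c("a", "b"), c(10, 10), c(20, 20))
  expect_equal(great_circle_matrix(s3)[1, 2], 0)
  # custom radius scales linearly
  expect_equal(great_circle_matrix(s, radius_km = 6371)[1, 2],
               352.689791600833 * 6371 / 6378.388, tolerance = 1e-9)
})

test_that("great-circle matrices are symmetric and satisfy the triangle inequality", {
  for (seed in 1:5) {
    s <- simulate_sites(6, seed = seed)
    m <- unclass(great_circle_matrix(s))
    expect_equal(m, t(m), tolerance = 1e-12)
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-6)
  }
})

test_that("log10 geographic distance transforms off-diagonals and rejects duplicates", {
  s <- site_table(paste0("s", 1:4), c(0, 0, 0, 1), c(0, 0.9, 9, 9))
  d <- great_circle_matrix(s)
  ld <- log10_geo(d)
  expect_equal(unclass(ld)[lower.tri(ld)], log10(unclass(d)[lower.tri(d)]),
               tolerance = 1e-12)
  expect_equal(diag(unclass(ld)), rep(0, 4), ignore_attr = TRUE)
  m <- matrix(c(0, 100, 1, 100, 0, 10, 1, 10, 0), 3, 3)
  lm <- log10_geo(dist_matrix(m, "geo_km"))
  expect_equal(lm[2, 1], 2)
  expect_equal(lm[3, 1], 0)
  sdup <- site_table(paste0("s", 1:4), c(0, 0, 1, 2), c(0, 0, 1, 2))
  expect_error(log10_geo(great_circle_matrix(sdup)), "duplicate")
})

test_that("climate PCA distance preserves Euclidean geometry and honors component cuts", {
  set.seed(11)
  S <- 5
  cl <- matrix(rnorm(S * 19), S, 19)
  s <- site_table(paste0("s", 1:S), runif(S, 30, 35), runif(S, -120, -115),
                  climate = cl)
  # all components: equals Euclidean distance on the centered raw data
  d <- climate_pca_distance(s)
  dc <- as.matrix(dist(scale(cl, center = TRUE, scale = FALSE)))
  expect_equal(unclass(d), dc, tolerance = 1e-8, ignore_attr = TRUE)

  # retained components: longhand eigendecomposition + projection oracle
  d2 <- climate_pca_distance(s, n_components = 2)
  X <- scale(cl, center = TRUE, scale = FALSE)
  eg <- eigen(cov(X))
  scores <- X %*% eg$vectors[, 1:2]
  expect_equal(unclass(d2), as.matrix(dist(scores)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # identical climate -> zero distance
  s0 <- site_table(c("a", "b"), c(1, 2), c(1, 2),
                   climate = rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(max(abs(climate_pca_distance(s0))), 0)

  # invariance to adding a constant to a column; scaling guards constants
  cl2 <- cl
  cl2[, 3] <- cl2[, 3] + 100
  s2 <- site_table(s$site_id, s$lat, s$lon, climate = cl2)
  expect_equal(unclass(climate_pca_distance(s2)), unclass(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  cl3 <- cl
  cl3[, 1] <- 7
  s3 <- site_table(s$site_id, s$lat, s$lon, climate = cl3)
  expect_error(climate_pca_distance(s3, scale. = TRUE), "constant")
})

test_that("distance standardization gives unit off-diagonal spread", {
  d <- sym_dist(runif(10, 1, 5), paste0("s", 1:5), "geo_km")
  m <- standardize_distance(d)
  expect_equal(sd(m[lower.tri(m)]), 1, tolerance = 1e-12)
  expect_equal(attr(m, "scale") * m[2, 1], d[2, 1], tolerance = 1e-12)
})
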