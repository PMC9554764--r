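# Spearman correlations among distance matrices, bootstrap intervals,
# and the publication-bias (file-drawer) check.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0)
    stop("zero rank variance; correlation undefined")
  cor(x, y, method = "spearman")
}

#' Correlate two distance matrices with bootstrap intervals
#'
#' The point estimate is the Spearman correlation of the S(S-1)/2 unordered
#' site-pair entries. Uncertainty comes from resampling those site-pair
#' observations with replacement (the rows of the long-format distance
#' table): percentile 50% and 95% intervals over `B` resamples, and a
#' one-sided bootstrap p-value for rho > 0,
#' `p = (1 + #\{rho*_b <= 0\}) / (B + 1)` (never exactly 0). A resample in
#' which either vector has no rank variance is redrawn; more than 10%
#' redraws is an error. Genetic matrices should be supplied pre-transformed
#' (`genetic_rousset`) and geographic matrices pre-logged (`geo_log10`).
#'
#' @param a,b `dist_matrix` objects over the same sites.
#' @param B number of bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @param label optional label naming the two matrices.
#' @return A `correlation_result`: list with `rho`, `ci50`, `ci95`, `p_boot`,
#'   `n_pairs`, `sig_positive` (p_boot < 0.05), `sig_nonzero` (95% interval
#'   excludes 0), `label`.
#' @export
correlate_pair <- function(a, b, B = 1000, seed = 1L,
                           label = paste(dm_kind(a), dm_kind(b), sep = "~")) {
  va <- dm_pairs(a); vb <- dm_pairs(b)
  if (length(va) != length(vb)) stop("matrices must share the site set")
  rho <- spearman_rho(va, vb)
  n <- length(va)
  set.seed(as.integer(seed))
  boot <- numeric(B)
  redraws <- 0L
  for (bb in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(rank(va[idx])) > 0 && sd(rank(vb[idx])) > 0) break
      redraws <- redraws + 1L
      if (redraws > 0.1 * B) stop("too many degenerate bootstrap resamples")
    }
    boot[bb] <- cor(va[idx], vb[idx], method = "spearman")
  }
  ci95 <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  ci50 <- unname(quantile(boot, c(0.25, 0.75), type = 7))
  p_boot <- (1 + sum(boot <= 0)) / (B + 1)
  structure(list(rho = rho, ci50 = ci50, ci95 = ci95, p_boot = p_boot,
                 n_pairs = n, B = B, redraws = redraws,
                 sig_positive = p_boot < 0.05,
                 sig_nonzero = ci95[1] > 0 || ci95[2] < 0,
                 label = label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: rho = %.3f [95%%: %.3f, %.3f] p_boot = %.4g%s (n = %d pairs)\n",
              x$label, x$rho, x$ci95[1], x$ci95[2], x$p_boot,
              if (x$sig_positive) " *" else "", x$n_pairs))
  invisible(x)
}

#' Distance-correlation battery for one host-associate pair
#'
#' Computes the five descriptive correlations of interest: host isolation by
#' distance (host genetic ~ geographic), host isolation by climate, associate
#' IBD, associate isolation by climate, and the focal host ~ associate
#' genetic correlation. Genetic matrices are Rousset-transformed and
#' geographic distance log10-transformed before correlating. Climate slots
#' are `NULL` when the pair carries no climate data.
#'
#' @param pair a validated [pair_dataset()].
#' @param B,seed bootstrap controls passed to [correlate_pair()].
#' @param geo,climate,host_gen,assoc_gen optional precomputed matrices
#'   (computed from the pair when omitted).
#' @return A named list of [correlate_pair()] results: `host_ibd`,
#'   `host_ibe`, `assoc_ibd`, `assoc_ibe`, `host_assoc` (climate entries NULL
#'   when unavailable), with attribute `pair_id`.
#' @export
correlation_battery <- function(pair, B = 1000, seed = 1L, geo = NULL,
                                climate = NULL, host_gen = NULL,
                                assoc_gen = NULL) {
  if (!isTRUE(pair$validated)) pair <- validate_pair(pair)
  if (is.null(geo)) geo <- log10_geo(great_circle_matrix(pair$sites))
  if (is.null(climate) && pair$has_climate)
    climate <- climate_pca_distance(pair$sites)
  gmat <- function(obj) {
    if (inherits(obj, "biallelic_counts")) pairwise_fst(obj) else obj
  }
  if (is.null(host_gen)) host_gen <- gmat(pair$host)
  if (is.null(assoc_gen)) assoc_gen <- gmat(pair$associate)
  hr <- rousset_transform(host_gen)
  ar <- rousset_transform(assoc_gen)
  res <- list(
    host_ibd = correlate_pair(hr, geo, B, seed, label = "host~geo"),
    host_ibe = if (pair$has_climate)
      correlate_pair(hr, climate, B, seed + 1L, label = "host~climate"),
    assoc_ibd = correlate_pair(ar, geo, B, seed + 2L, label = "associate~geo"),
    assoc_ibe = if (pair$has_climate)
      correlate_pair(ar, climate, B, seed + 3L, label = "associate~climate"),
    host_assoc = correlate_pair(ar, hr, B, seed + 4L, label = "associate~host"))
  attr(res, "pair_id") <- pair$pair_id
  res
}

#' Publication-bias (file-drawer) check
#'
#' Spearman correlation between per-study sample sizes (total number of
#' pairwise comparisons, S(S-1)/2) and the estimated correlation
#' coefficients, with a two-sided asymptotic p-value (t approximation). A
#' significant negative correlation is consistent with the file-drawer
#' effect: small studies finding weak effects going unpublished.
#'
#' @param effects numeric vector of per-pair correlation estimates.
#' @param sizes numeric vector of per-pair site-pair counts.
#' @return list with `rho`, `p`, and `file_drawer_flag` (rho < 0 and p < 0.05).
#' @export
publication_bias_test <- function(effects, sizes) {
  if (length(effects) != length(sizes)) stop("effects and sizes must align")
  if (length(effects) < 4) stop("need at least 4 pairs")
  if (sd(rank(effects)) == 0 || sd(rank(sizes)) == 0)
    stop("degenerate (all-tied) input")
  ct <- suppressWarnings(cor.test(sizes, effects, method = "spearman",
                                  exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p = ct$p.value,
       file_drawer_flag = rho < 0 && ct$p.value < 0.05)
}
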