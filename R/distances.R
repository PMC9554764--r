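# Genetic, geographic, and climatic distance construction.

#' Recode multiallelic loci as biallelic pseudoloci
#'
#' Markers with more than two alleles (SSRs, AFLP phenotypes scored as
#' alleles, multiallelic SNPs) are recoded so that each allele of a k-allele
#' locus (k >= 3) becomes its own biallelic pseudolocus, allele a vs. not-a.
#' A locus with alleles A, B, C therefore yields three pseudoloci A/notA,
#' B/notB, C/notC, and for every site the focal counts of those pseudoloci
#' sum to the site's sample size at the original locus. Biallelic loci pass
#' through as a single pseudolocus whose focal allele is the
#' lexicographically first allele label.
#'
#' @param g a [multiallelic_genotypes()] object.
#' @return A [biallelic_counts()] object; pseudoloci are labelled
#'   `<locus>.<allele>` (multiallelic) or `<locus>` (biallelic), with
#'   `origin_locus` recording provenance. Loci with zero copies at every site
#'   are dropped with a warning.
#' @export
recode_pseudoloci <- function(g) {
  stopifnot(inherits(g, "multiallelic_genotypes"))
  xs <- list(); ns <- list(); org <- character(0)
  for (l in g$loci) {
    m <- g$counts[[l]]
    tot <- rowSums(m)
    if (all(tot == 0)) {
      warning(sprintf("locus %s has zero copies at every site; dropped", l))
      next
    }
    k <- ncol(m)
    if (k <= 2) {
      a <- sort(colnames(m))[1L]
      xs[[length(xs) + 1L]] <- m[, a]
      ns[[length(ns) + 1L]] <- tot
      names(xs)[length(xs)] <- l
      org <- c(org, l)
    } else {
      for (a in colnames(m)) {
        xs[[length(xs) + 1L]] <- m[, a]
        ns[[length(ns) + 1L]] <- tot
        names(xs)[length(xs)] <- paste(l, a, sep = ".")
        org <- c(org, l)
      }
    }
  }
  if (!length(xs)) stop("no informative loci after recoding")
  xm <- do.call(cbind, xs)
  nm <- do.call(cbind, ns)
  dimnames(nm) <- dimnames(xm)
  biallelic_counts(xm, nm, origin_locus = org)
}

# Per-pseudolocus Weir-Hill variance components for one site pair.
# Returns numerator (MSP - MSG) and denominator (MSP + (n_c - 1) MSG) terms.
fst_components <- function(x1, x2, n1, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  list(num = msp - msg, den = msp + (nc - 1) * msg)
}

#' Pairwise multilocus FST (Weir-Hill two-population moment estimator)
#'
#' For each pair of sites, computes the ratio-of-sums moment estimate of
#' theta from per-pseudolocus variance components: with allele-copy sizes
#' n_i, n_j and sample frequencies p_i, p_j at one pseudolocus,
#' `MSP = n_i (p_i - pbar)^2 + n_j (p_j - pbar)^2` (1 df between
#' populations), `MSG = (n_i p_i (1 - p_i) + n_j p_j (1 - p_j)) / (n_i + n_j - 2)`
#' (within-population mean squares), `n_c = (n_i + n_j) - (n_i^2 + n_j^2) /
#' (n_i + n_j)`, and the multilocus estimate is
#' `theta = sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG)` over pseudoloci.
#' Estimates can be negative (sampling noise around zero differentiation) and
#' are retained unclamped; theta <= 1 always. A site pair at which every
#' pseudolocus is monomorphic across both sites has an undefined (0/0)
#' estimate and is set to 0 with a warning, keeping the matrix complete.
#'
#' @param b a [biallelic_counts()] object; every site needs at least 2
#'   sampled copies at each pseudolocus.
#' @return A genetic [dist_matrix()] of pairwise theta estimates.
#' @export
pairwise_fst <- function(b) {
  stopifnot(inherits(b, "biallelic_counts"))
  S <- length(b$sites)
  if (any(b$n < 2)) stop("every site x pseudolocus needs >= 2 sampled copies")
  out <- matrix(0, S, S, dimnames = list(b$sites, b$sites))
  mono <- character(0)
  for (i in seq_len(S - 1L)) {
    for (j in seq.int(i + 1L, S)) {
      cmp <- fst_components(b$x[i, ], b$x[j, ], b$n[i, ], b$n[j, ])
      den <- sum(cmp$den)
      if (den <= 0) {
        mono <- c(mono, paste(b$sites[i], b$sites[j], sep = "-"))
        th <- 0
      } else th <- sum(cmp$num) / den
      out[i, j] <- out[j, i] <- th
    }
  }
  if (length(mono))
    warning("monomorphic site pair(s) set to FST 0: ",
            paste(mono, collapse = ", "))
  dist_matrix(out, kind = "genetic")
}

#' Rousset linearization of genetic distance
#'
#' Elementwise `D / (1 - D)`, the standard linearizing transform of FST for
#' distance regressions; strictly increasing, maps 0 to 0, and applies
#' unchanged to negative moment estimates. Entries at or above 1 (possible
#' for distances on other scales, e.g. Nei's D) are an error naming the
#' offending site pair: such matrices must be rescaled before transformation.
#'
#' @param d a genetic [dist_matrix()] with all entries `< 1`.
#' @return A [dist_matrix()] of kind `genetic_rousset`.
#' @export
rousset_transform <- function(d) {
  stopifnot(inherits(d, "dist_matrix"))
  m <- unclass(d)
  bad <- which(m >= 1 & row(m) != col(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("genetic distance >= 1 for site pair %s-%s; rescale before transforming",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  out <- m / (1 - m)
  diag(out) <- 0
  dist_matrix(out, kind = "genetic_rousset")
}

#' Great-circle distance matrix between sampling sites
#'
#' Haversine great-circle distances in kilometers on a sphere of configurable
#' radius. The default radius, 6378.388 km (the international ellipsoid's
#' equatorial radius, the customary default of classic geographic-distance
#' tooling), is exposed so reproductions against other toolchains can match
#' their sphere.
#'
#' @param s a [site_table()].
#' @param radius_km sphere radius in km.
#' @return A [dist_matrix()] of kind `geo_km`.
#' @export
great_circle_matrix <- function(s, radius_km = 6378.388) {
  stopifnot(inherits(s, "site_table"))
  p <- cbind(s$lon, s$lat)
  m <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = radius_km))
  dimnames(m) <- list(s$site_id, s$site_id)
  dist_matrix(m, kind = "geo_km")
}

#' Base-10 logarithm of geographic distances
#'
#' Elementwise log10 of the off-diagonal entries; the diagonal stays 0.
#' Duplicate coordinates (off-diagonal zeros) are an error — jitter the
#' coordinates or merge the sites.
#'
#' @param d a [dist_matrix()] of kind `geo_km`.
#' @return A [dist_matrix()] of kind `geo_log10`.
#' @export
log10_geo <- function(d) {
  stopifnot(inherits(d, "dist_matrix"), dm_kind(d) == "geo_km")
  m <- unclass(d)
  off <- row(m) != col(m)
  if (any(m[off] <= 0))
    stop("zero off-diagonal geographic distance (duplicate coordinates); jitter or merge sites")
  out <- m
  out[off] <- log10(m[off])
  diag(out) <- 0
  # log10 can be negative (sub-km distances) and breaks exact symmetry only
  # through the matrix copy, so rebuild via constructor for the checks
  dist_matrix(out, kind = "geo_log10")
}

#' Climatic distance in principal-component space
#'
#' Principal components of the site x variable climate matrix
#' (column-centered; optional scaling to unit variance, default off), then
#' Euclidean distance between site scores on the retained components. With
#' all components retained the rotation is orthogonal, so distances equal
#' Euclidean distances on the centered (or centered+scaled) raw data.
#'
#' @param s a [site_table()] carrying climate data for all sites.
#' @param n_components number of leading components to retain; `NULL` (all)
#'   by default.
#' @param scale. logical; scale columns to unit variance before PCA.
#' @return A [dist_matrix()] of kind `climate`.
#' @export
climate_pca_distance <- function(s, n_components = NULL, scale. = FALSE) {
  cl <- site_climate(s)
  if (is.null(cl)) stop("site table carries no climate data")
  if (nrow(cl) < 2) stop("need >= 2 sites")
  if (scale. && any(apply(cl, 2, sd) == 0))
    stop("constant climate column with scaling on")
  pc <- prcomp(cl, center = TRUE, scale. = scale.)
  k <- if (is.null(n_components)) ncol(pc$x) else min(n_components, ncol(pc$x))
  m <- as.matrix(dist(pc$x[, seq_len(k), drop = FALSE]))
  dimnames(m) <- list(s$site_id, s$site_id)
  dist_matrix(m, kind = "climate")
}

#' Standardize a distance matrix to unit off-diagonal spread
#'
#' Divides all entries by the standard deviation of the off-diagonal
#' (site-pair) entries, so isolating effects estimated per unit distance are
#' comparable across factors and across host-associate pairs.
#'
#' @param d a `dist_matrix` or square matrix.
#' @return The scaled matrix with attribute `scale` (the divisor).
#' @export
standardize_distance <- function(d) {
  m <- unclass(d)
  v <- m[lower.tri(m)]
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("degenerate distance matrix (zero spread)")
  out <- m / s
  attr(out, "scale") <- s
  out
}
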