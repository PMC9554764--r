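# Synthetic host-associate study generator.
#
# Generates collections with known, planted isolation structure: host allele
# frequencies covary over geography (and climate); associate frequencies
# additionally covary with the host's *realized* genetic distance matrix, so
# the planted isolation-by-host signal is exactly the quantity the analysis
# pipeline can observe.

#' Simulate a sampling-site table with spatially autocorrelated climate
#'
#' Sites are placed uniformly in a square of side `extent_km` (projected to
#' plausible WGS84 coordinates around a configurable anchor). Climate
#' variables are built from a small number of latent Gaussian-process fields
#' over the site coordinates (squared-exponential kernel with range
#' `spatial_range_km`) plus independent noise, linearly mixed into
#' `n_climate_vars` columns to mimic the strong inter-variable correlation of
#' Bioclim data.
#'
#' @param S number of sites (>= 4).
#' @param extent_km side of the sampling square, km.
#' @param n_climate_vars number of climate columns (default 19).
#' @param spatial_range_km GP range of the climate fields.
#' @param seed integer seed.
#' @param anchor c(lat, lon) of the square's corner.
#' @param n_latent number of latent climate fields mixed into the columns.
#' @param min_sep_km minimum pairwise site separation; closer draws are
#'   rejected and redrawn (sites a few hundred meters apart are not
#'   geographically distinct populations, and duplicate coordinates break
#'   log-distance).
#' @return A [site_table()] with climate; the mixing matrix is attached as
#'   attribute `climate_mixing` for reproducibility.
#' @export
simulate_sites <- function(S, extent_km = 200, n_climate_vars = 19,
                           spatial_range_km = extent_km / 3, seed = 1L,
                           anchor = c(35, -110), n_latent = 5,
                           min_sep_km = 1) {
  if (S < 4) stop("S must be >= 4")
  set.seed(as.integer(seed))
  xy <- matrix(runif(2 * S, 0, extent_km), S, 2)
  for (tries in 1:200) {
    close_pairs <- which(as.matrix(dist(xy)) < min_sep_km &
                           upper.tri(diag(S)), arr.ind = TRUE)
    if (!nrow(close_pairs)) break
    redo <- unique(close_pairs[, 1])
    xy[redo, ] <- matrix(runif(2 * length(redo), 0, extent_km),
                         length(redo), 2)
  }
  lat <- anchor[1] + xy[, 2] / 111.32
  lon <- anchor[2] + xy[, 1] / (111.32 * cos(anchor[1] * pi / 180))
  s0 <- site_table(sprintf("s%02d", seq_len(S)), lat, lon)
  dkm <- unclass(great_circle_matrix(s0))
  Kc <- exp(-(dkm / spatial_range_km)^2) + diag(1e-8, S)
  Rc <- chol(Kc)
  Zl <- crossprod(Rc, matrix(rnorm(S * n_latent), S, n_latent))
  W <- matrix(rnorm(n_latent * n_climate_vars), n_latent, n_climate_vars)
  shift <- rnorm(n_climate_vars, 0, 2)
  climate <- Zl %*% W +
    matrix(rnorm(S * n_climate_vars, 0, 0.3), S, n_climate_vars) +
    matrix(shift, S, n_climate_vars, byrow = TRUE)
  out <- site_table(s0$site_id, lat, lon, climate = climate)
  attr(out, "climate_mixing") <- W
  out
}

#' Simulate biallelic counts from the covariance-isolation model
#'
#' Draws per-locus global frequencies `mu_l` from `mu_dist`, latent site
#' frequencies `theta_l ~ MVN(mu_l, mu_l (1 - mu_l) Omega(params))` over the
#' supplied standardized distances, clamps to \[0, 1\], and samples binomial
#' counts.
#'
#' @param sites site labels (character) or a [site_table()].
#' @param D standardized geographic distance matrix.
#' @param E_list list of standardized ecological distance matrices.
#' @param params alpha parameters (list: `alpha0`, `alphaD`, `alphaE`,
#'   `alpha2`), see [build_covariance()].
#' @param L number of pseudoloci.
#' @param copies_per_site sampled allele copies per site (default 40,
#'   i.e. 20 diploids, the scale of typical SSR studies).
#' @param mu_dist function of L returning global frequencies (default
#'   uniform on (0.1, 0.9)).
#' @param seed integer seed.
#' @return A [biallelic_counts()] object.
#' @export
simulate_species_counts <- function(sites, D, E_list = list(), params,
                                    L = 50, copies_per_site = 40,
                                    mu_dist = function(L) runif(L, 0.1, 0.9),
                                    seed = 1L) {
  if (inherits(sites, "site_table")) sites <- sites$site_id
  S <- length(sites)
  Om <- build_covariance(params, D, E_list)
  R <- chol(Om)
  set.seed(as.integer(seed))
  mu <- mu_dist(L)
  Z <- crossprod(R, matrix(rnorm(S * L), S, L))
  theta <- Z * matrix(sqrt(mu * (1 - mu)), S, L, byrow = TRUE) +
    matrix(mu, S, L, byrow = TRUE)
  f <- pmin(pmax(theta, 0), 1)
  n <- matrix(copies_per_site, S, L,
              dimnames = list(sites, paste0("ps", seq_len(L))))
  x <- matrix(rbinom(S * L, copies_per_site, f), S, L, dimnames = dimnames(n))
  biallelic_counts(x, n)
}

# multiallelic (SSR-like) genotypes: spatially correlated logistic-normal
# allele frequencies, multinomial sampling
simulate_ssr_genotypes <- function(sites, D, n_loci = 10, n_alleles = 3,
                                   copies_per_site = 40, sd_site = 0.8,
                                   seed = 1L) {
  if (inherits(sites, "site_table")) sites <- sites$site_id
  S <- length(sites)
  K <- exp(-pmax(unclass(D), 0)) + diag(1e-8, S)
  R <- chol(K)
  set.seed(as.integer(seed))
  counts <- list()
  for (l in seq_len(n_loci)) {
    base <- log(rgamma(n_alleles, 1, 1) + 0.1)
    G <- crossprod(R, matrix(rnorm(S * n_alleles), S, n_alleles)) * sd_site
    eta <- sweep(G, 2, base, `+`)
    P <- exp(eta) / rowSums(exp(eta))
    m <- t(vapply(seq_len(S), function(i)
      rmultinom(1, copies_per_site, P[i, ])[, 1], numeric(n_alleles)))
    dimnames(m) <- list(sites, LETTERS[seq_len(n_alleles)])
    counts[[paste0("ssr", l)]] <- m
  }
  multiallelic_genotypes(counts)
}

#' Default configuration for one simulated host-associate pair
#'
#' @param pair_id pair label.
#' @param S sites; `L` pseudoloci per species; `copies_per_site` allele
#'   copies sampled per site.
#' @param interaction_type `"antagonist"` or `"mutualist"`.
#' @param extent_km,spatial_range_km sampling-design geometry.
#' @param host_params,assoc_params alpha parameters of the generating
#'   covariance model; `assoc_params$alphaE` is `c(clim, host)` - the second
#'   entry is the planted isolation-by-host effect.
#' @param distances_only drop genotypes, keep only genetic distance matrices
#'   (emulating studies that published distances, not genotypes).
#' @param no_climate strip climate from the site table (the data are still
#'   generated with a climate signal the analyst cannot see).
#' @param ssr_mode generate multiallelic SSR-style genotypes (recoded to
#'   pseudoloci for analysis; the raw genotypes are returned too).
#' @param seed integer seed.
#' @param L,copies_per_site see above.
#' @return config list for [simulate_pair()].
#' @export
pair_config <- function(pair_id = "pair1", S = 10, L = 50,
                        copies_per_site = 40,
                        interaction_type = "mutualist", extent_km = 200,
                        spatial_range_km = extent_km / 3,
                        host_params = list(alpha0 = 10, alphaD = 0.4,
                                           alphaE = 0.1, alpha2 = 1),
                        assoc_params = list(alpha0 = 10, alphaD = 0.15,
                                            alphaE = c(0.1, 0.5), alpha2 = 1),
                        distances_only = FALSE, no_climate = FALSE,
                        ssr_mode = FALSE, seed = 1L) {
  as.list(environment())
}

#' Simulate one host-associate pair with planted isolation effects
#'
#' Simulates host genotypes over geography and climate, computes the host's
#' realized FST matrix, then simulates associate genotypes whose covariance
#' decays with geography, climate, and that host FST matrix - the planted
#' isolation-by-host channel. Optional degraded variants mirror the
#' heterogeneity of compiled literature data: distances-only, no-climate,
#' and SSR-mode (multiallelic markers that require pseudolocus recoding).
#'
#' @param config list from [pair_config()].
#' @return list with `pair` (a validated [pair_dataset()]), `truth`
#'   (generating parameters and seeds), and in SSR mode `genotypes` (the raw
#'   multiallelic objects).
#' @export
simulate_pair <- function(config = pair_config()) {
  cf <- config
  sites <- simulate_sites(cf$S, cf$extent_km, 19, cf$spatial_range_km,
                          seed = cf$seed)
  geo <- great_circle_matrix(sites)
  Dstd <- standardize_distance(geo)
  clim <- climate_pca_distance(sites)
  Eclim <- standardize_distance(clim)
  # A realized host FST matrix is not guaranteed to yield a positive-definite
  # exp(-alpha * H) covariance (FST matrices are not conditionally negative
  # definite in general). When that happens, redraw the host genotypes - the
  # generating model itself only admits PD configurations.
  genotypes <- NULL
  assoc <- NULL
  for (attempt in 0:20) {
    hseed <- cf$seed + 1L + 1000L * attempt
    if (cf$ssr_mode) {
      hg <- simulate_ssr_genotypes(sites, Dstd,
                                   copies_per_site = cf$copies_per_site,
                                   seed = hseed)
      host <- recode_pseudoloci(hg)
      genotypes <- list(host = hg)
    } else {
      host <- simulate_species_counts(sites, Dstd, list(clim = Eclim),
                                      params = cf$host_params,
                                      L = cf$L,
                                      copies_per_site = cf$copies_per_site,
                                      seed = hseed)
    }
    host_fst <- pairwise_fst(host)
    hf <- unclass(host_fst)
    hf[hf < 0] <- 0
    Ehost <- standardize_distance(hf)
    assoc <- tryCatch(
      simulate_species_counts(sites, Dstd, list(clim = Eclim, host = Ehost),
                              params = cf$assoc_params, L = cf$L,
                              copies_per_site = cf$copies_per_site,
                              seed = cf$seed + 2L),
      error = function(e) NULL)
    if (!is.null(assoc)) break
  }
  if (is.null(assoc))
    stop("could not reach a positive-definite host configuration in 20 redraws")
  truth <- list(pair_id = cf$pair_id, host_params = cf$host_params,
                assoc_params = cf$assoc_params,
                alphaE_host = cf$assoc_params$alphaE[2],
                seed = cf$seed, host_seed = hseed, config = cf)
  host_obj <- host
  assoc_obj <- assoc
  if (cf$distances_only) {
    host_obj <- host_fst
    assoc_obj <- pairwise_fst(assoc)
  }
  if (cf$no_climate)
    sites <- site_table(sites$site_id, sites$lat, sites$lon)
  pair <- validate_pair(pair_dataset(cf$pair_id, cf$interaction_type,
                                     host_obj, assoc_obj, sites))
  out <- list(pair = pair, truth = truth)
  if (!is.null(genotypes)) out$genotypes <- genotypes
  out
}

#' Default design of a simulated study collection
#'
#' The structural skeleton of a 20-pair compiled collection: per-pair site
#' counts spanning 4-45, seven antagonistic interactions, seven
#' distance-only pairs (genotypes unavailable; only one of the
#' genotype-bearing pairs antagonistic), four pairs without usable climate,
#' and four close-relative groups tying pairs that share associate taxa.
#'
#' @return data.frame with columns `pair_id`, `S`, `interaction_type`,
#'   `distances_only`, `no_climate`, `relative_group`.
#' @export
collection_design <- function() {
  data.frame(
    pair_id = sprintf("p%02d", 1:20),
    S = c(6, 4, 30, 24, 8, 14, 45, 17, 28, 11, 10, 10, 8, 14, 9, 5, 7, 9, 13, 10),
    interaction_type = c("antagonist", "antagonist", "mutualist", "mutualist",
                         "antagonist", "mutualist", "mutualist", "mutualist",
                         "mutualist", "antagonist", "antagonist", "antagonist",
                         "antagonist", "mutualist", "mutualist", "mutualist",
                         "mutualist", "mutualist", "mutualist", "mutualist"),
    distances_only = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                       FALSE, FALSE, FALSE, FALSE),
    no_climate = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE),
    relative_group = c(NA, NA, NA, NA, NA, NA, "macropis", "macropis", NA,
                       "arceuthobium", "arceuthobium", NA, NA, NA, NA,
                       "crematogaster", "crematogaster", NA, "tegeticula",
                       "tegeticula"),
    stringsAsFactors = FALSE)
}

#' Simulate a collection of host-associate pairs
#'
#' Generates `n_pairs` studies on the default (or a supplied) design, with
#' interaction-type-dependent planted effects: antagonists draw their
#' isolation-by-host effect `alphaE_host` from a larger-mean distribution
#' than mutualists, and mutualists draw a larger geographic effect -
#' emulating the contrast the analysis stages are meant to detect.
#'
#' @param n_pairs number of pairs (default 20).
#' @param n_antagonist number of antagonistic pairs (default 7; only used
#'   when deviating from the default design).
#' @param seed integer seed.
#' @param design optional design data.frame (see [collection_design()]).
#' @param L pseudoloci per species; `copies_per_site` as in
#'   [simulate_species_counts()].
#' @param alphaE_host_mean named vector: mean planted isolation-by-host
#'   effect per interaction type (log-normal draws around these with sdlog
#'   0.4).
#' @param alphaD_mean named vector: mean planted geographic effect per type.
#' @param copies_per_site allele copies per site.
#' @return list with `pairs` (validated pair datasets), `truths`, `design`.
#' @export
simulate_collection <- function(n_pairs = 20, n_antagonist = 7, seed = 1L,
                                design = NULL, L = 50, copies_per_site = 40,
                                alphaE_host_mean = c(antagonist = 0.5,
                                                     mutualist = 0.15),
                                alphaD_mean = c(antagonist = 0.1,
                                                mutualist = 0.3)) {
  if (is.null(design)) {
    design <- collection_design()
    if (n_pairs != 20 || n_antagonist != 7) {
      if (n_antagonist > n_pairs) stop("n_antagonist must be <= n_pairs")
      idx <- rep(seq_len(20), length.out = n_pairs)
      design <- design[idx, , drop = FALSE]
      design$pair_id <- sprintf("p%02d", seq_len(n_pairs))
      design$relative_group <- NA_character_
      design$interaction_type <- rep("mutualist", n_pairs)
      design$interaction_type[seq_len(n_antagonist)] <- "antagonist"
    }
  }
  set.seed(as.integer(seed))
  pair_seeds <- seed + 7919L * seq_len(nrow(design))
  draw_sd <- 0.4
  pairs <- vector("list", nrow(design))
  truths <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ty <- design$interaction_type[i]
    set.seed(pair_seeds[i])
    aE_host <- rlnorm(1, log(alphaE_host_mean[[ty]]), draw_sd)
    aD <- rlnorm(1, log(alphaD_mean[[ty]]), draw_sd)
    aE_clim <- rlnorm(1, log(0.1), draw_sd)
    cf <- pair_config(
      pair_id = design$pair_id[i], S = design$S[i], L = L,
      copies_per_site = copies_per_site, interaction_type = ty,
      assoc_params = list(alpha0 = 10, alphaD = aD,
                          alphaE = c(aE_clim, aE_host), alpha2 = 1),
      distances_only = design$distances_only[i],
      no_climate = design$no_climate[i], seed = pair_seeds[i])
    sim <- simulate_pair(cf)
    sim$pair$relative_group <- design$relative_group[i]
    pairs[[i]] <- sim$pair
    truths[[i]] <- sim$truth
  }
  names(pairs) <- design$pair_id
  names(truths) <- design$pair_id
  list(pairs = pairs, truths = truths, design = design, seed = seed)
}
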