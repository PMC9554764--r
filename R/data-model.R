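# Shared data types, readers/writers, and validation.
#
# All containers are plain-R structures with light S3 classes:
#   site_table           data.frame (site_id, lat, lon) + optional climate matrix
#   multiallelic_genotypes  per-locus site x allele count matrices
#   biallelic_counts     site x pseudolocus focal (x) and total (n) count matrices
#   dist_matrix          labelled symmetric matrix with a kind tag
#   pair_dataset         one host-associate study
# Site order is canonical (first appearance) and enforced across all matrices.

DIST_KINDS <- c("geo_km", "geo_log10", "climate", "genetic", "genetic_rousset")

#' Construct a site table
#'
#' A site table holds the shared sampling sites of a host-associate pair:
#' unique site labels, WGS84 coordinates in decimal degrees, and optionally a
#' per-site climate matrix (default expectation: 19 Bioclim-style variables,
#' but any fixed number of real-valued columns is accepted).
#'
#' @param site_id character vector of unique site labels.
#' @param lat,lon numeric, decimal degrees; `lat` in \[-90, 90\], `lon` in
#'   \[-180, 180\].
#' @param climate optional numeric matrix (or data.frame) with one row per
#'   site, in site order, holding climate variables.
#' @return A `site_table`: a data.frame with columns `site_id`, `lat`, `lon`
#'   and, when supplied, the climate matrix in `attr(, "climate")` with
#'   rownames equal to `site_id`.
#' @export
site_table <- function(site_id, lat, lon, climate = NULL) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("site_ids must be unique")
  if (length(lat) != length(site_id) || length(lon) != length(site_id))
    stop("site_id, lat, lon must have equal length")
  if (anyNA(lat) || anyNA(lon)) stop("missing lat/lon not allowed")
  if (any(lat < -90 | lat > 90)) stop("lat outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("lon outside [-180, 180]")
  out <- data.frame(site_id = site_id, lat = as.numeric(lat),
                    lon = as.numeric(lon), stringsAsFactors = FALSE)
  if (!is.null(climate)) {
    climate <- as.matrix(climate)
    storage.mode(climate) <- "double"
    if (nrow(climate) != length(site_id))
      stop("climate must have one row per site")
    if (anyNA(climate)) stop("climate values must be complete")
    rownames(climate) <- site_id
    if (is.null(colnames(climate)))
      colnames(climate) <- paste0("bio", seq_len(ncol(climate)))
    attr(out, "climate") <- climate
  }
  class(out) <- c("site_table", "data.frame")
  out
}

#' @export
print.site_table <- function(x, ...) {
  cl <- attr(x, "climate")
  cat(sprintf("Site table: %d sites%s\n", nrow(x),
              if (is.null(cl)) " (no climate)"
              else sprintf(", %d climate variables", ncol(cl))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more sites\n", nrow(x) - 6))
  invisible(x)
}

#' Extract the climate matrix of a site table
#' @param s a `site_table`.
#' @return numeric matrix, or NULL when the table carries no climate data.
#' @export
site_climate <- function(s) attr(s, "climate")

#' Construct a multiallelic genotype container
#'
#' Raw per-site, per-locus allele-copy counts (ploidy-summed) before
#' pseudolocus recoding. Stored as one site x allele integer matrix per locus.
#'
#' @param counts named list, one element per locus, each a site x allele
#'   matrix of nonnegative integer allele-copy counts with identical rownames
#'   (the sites) across loci.
#' @return A `multiallelic_genotypes` object.
#' @export
multiallelic_genotypes <- function(counts) {
  if (!length(counts)) stop("no loci")
  if (is.null(names(counts))) names(counts) <- paste0("L", seq_along(counts))
  sites <- rownames(counts[[1L]])
  if (is.null(sites)) stop("allele-count matrices must have site rownames")
  for (nm in names(counts)) {
    m <- counts[[nm]]
    if (!identical(rownames(m), sites))
      stop("all loci must share the same ordered site list")
    if (any(m < 0) || any(m != round(m)))
      stop(sprintf("locus %s: counts must be nonnegative integers", nm))
    if (is.null(colnames(m)))
      colnames(m) <- paste0("a", seq_len(ncol(m)))
    storage.mode(counts[[nm]]) <- "double"
    colnames(counts[[nm]]) <- colnames(m)
  }
  structure(list(counts = counts, sites = sites, loci = names(counts)),
            class = "multiallelic_genotypes")
}

#' @export
print.multiallelic_genotypes <- function(x, ...) {
  k <- vapply(x$counts, ncol, 0L)
  cat(sprintf("Multiallelic genotypes: %d sites x %d loci (%d-%d alleles/locus)\n",
              length(x$sites), length(x$loci), min(k), max(k)))
  invisible(x)
}

#' Read a long-format genotype CSV
#'
#' Expects columns `site_id, locus, allele, count`; counts are allele copies
#' (ploidy-summed). Site and locus order is the order of first appearance.
#'
#' @param path path to a CSV file.
#' @return A [multiallelic_genotypes()] object.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("no records in ", path)
  need <- c("site_id", "locus", "allele", "count")
  if (!all(need %in% names(d)))
    stop("genotype CSV needs columns: ", paste(need, collapse = ", "))
  if (any(d$count < 0)) stop("negative counts in ", path)
  if (any(d$count != round(d$count))) stop("non-integer counts in ", path)
  key <- paste(d$site_id, d$locus, d$allele, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (site, locus, allele) rows in ", path)
  sites <- unique(as.character(d$site_id))
  loci <- unique(as.character(d$locus))
  counts <- lapply(loci, function(l) {
    dl <- d[d$locus == l, , drop = FALSE]
    alleles <- unique(as.character(dl$allele))
    m <- matrix(0, length(sites), length(alleles),
                dimnames = list(sites, alleles))
    m[cbind(as.character(dl$site_id), as.character(dl$allele))] <- dl$count
    m
  })
  names(counts) <- loci
  multiallelic_genotypes(counts)
}

#' Write genotypes as long-format CSV
#' @param g a `multiallelic_genotypes` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  rows <- do.call(rbind, lapply(g$loci, function(l) {
    m <- g$counts[[l]]
    data.frame(site_id = rep(rownames(m), ncol(m)),
               locus = l,
               allele = rep(colnames(m), each = nrow(m)),
               count = as.vector(m), stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct biallelic (pseudolocus) counts
#'
#' The working genotype representation for FST estimation and the covariance
#' model: per site and pseudolocus, the count `x` of the focal allele and the
#' total number `n` of sampled allele copies.
#'
#' @param x,n numeric matrices (sites x pseudoloci) with identical dimnames;
#'   `0 <= x <= n` elementwise.
#' @param origin_locus optional character vector recording, per pseudolocus,
#'   the multiallelic locus it was recoded from (defaults to the pseudolocus
#'   label itself).
#' @return A `biallelic_counts` object.
#' @export
biallelic_counts <- function(x, n, origin_locus = NULL) {
  x <- as.matrix(x); n <- as.matrix(n)
  storage.mode(x) <- "double"
  storage.mode(n) <- "double"
  if (!identical(dim(x), dim(n))) stop("x and n must have identical shape")
  if (is.null(rownames(x))) stop("x needs site rownames")
  if (is.null(colnames(x))) colnames(x) <- paste0("ps", seq_len(ncol(x)))
  dimnames(n) <- dimnames(x)
  if (any(n < 0)) stop("n must be nonnegative")
  if (any(x < 0) || any(x > n)) stop("need 0 <= x <= n elementwise")
  if (is.null(origin_locus)) origin_locus <- colnames(x)
  if (length(origin_locus) != ncol(x))
    stop("origin_locus must have one entry per pseudolocus")
  structure(list(x = x, n = n, sites = rownames(x),
                 pseudoloci = colnames(x),
                 origin_locus = as.character(origin_locus)),
            class = "biallelic_counts")
}

#' @export
print.biallelic_counts <- function(x, ...) {
  cat(sprintf("Biallelic counts: %d sites x %d pseudoloci (from %d loci)\n",
              length(x$sites), length(x$pseudoloci),
              length(unique(x$origin_locus))))
  invisible(x)
}

#' Write biallelic counts as long-format CSV
#' @param b a `biallelic_counts` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_biallelic <- function(b, path) {
  rows <- data.frame(site_id = rep(b$sites, length(b$pseudoloci)),
                     pseudolocus = rep(b$pseudoloci, each = length(b$sites)),
                     origin_locus = rep(b$origin_locus, each = length(b$sites)),
                     x = as.vector(b$x), n = as.vector(b$n),
                     stringsAsFactors = FALSE)
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read biallelic counts from long-format CSV
#' @param path CSV with columns site_id, pseudolocus, origin_locus, x, n.
#' @return A [biallelic_counts()] object.
#' @export
read_biallelic <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  sites <- unique(as.character(d$site_id))
  ps <- unique(as.character(d$pseudolocus))
  xm <- matrix(NA_real_, length(sites), length(ps), dimnames = list(sites, ps))
  nm <- xm
  xm[cbind(as.character(d$site_id), as.character(d$pseudolocus))] <- d$x
  nm[cbind(as.character(d$site_id), as.character(d$pseudolocus))] <- d$n
  if (anyNA(xm) || anyNA(nm)) stop("incomplete site x pseudolocus grid in ", path)
  org <- d$origin_locus[match(ps, d$pseudolocus)]
  biallelic_counts(xm, nm, origin_locus = org)
}

#' Construct a labelled distance matrix
#'
#' @param values square numeric matrix, symmetric to 1e-9, zero diagonal
#'   (genetic kinds define the diagonal as 0); rownames are the site labels.
#' @param kind one of `"geo_km"`, `"geo_log10"`, `"climate"`, `"genetic"`,
#'   `"genetic_rousset"`.
#' @param sites optional site labels overriding the dimnames.
#' @return A `dist_matrix`: the matrix with class and `kind` attributes.
#' @export
dist_matrix <- function(values, kind, sites = NULL) {
  kind <- match.arg(kind, DIST_KINDS)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (!is.null(sites)) dimnames(values) <- list(sites, sites)
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("s", seq_len(nrow(values))),
                             paste0("s", seq_len(nrow(values))))
  colnames(values) <- rownames(values)
  if (max(abs(values - t(values))) > 1e-9) stop("matrix not symmetric")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > 1e-9) stop("nonzero diagonal")
  diag(values) <- 0
  if (kind == "geo_km" && any(values < 0)) stop("geo_km distances must be >= 0")
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix [%s]: %d sites\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Kind tag of a distance matrix
#' @param d a `dist_matrix`.
#' @return character scalar.
#' @export
dm_kind <- function(d) attr(d, "kind")

#' Lower-triangle (site-pair) vector of a distance matrix
#' @param d a `dist_matrix` or plain square matrix.
#' @return numeric vector of the S(S-1)/2 unordered site-pair entries.
#' @export
dm_pairs <- function(d) {
  m <- unclass(d)
  m[lower.tri(m)]
}

#' Read a square labelled distance matrix CSV
#'
#' The first column holds row labels and must match the header labels in
#' order. Near-asymmetries below 1e-6 are symmetrized by averaging; larger
#' ones are an error, as is a diagonal away from zero by more than 1e-9.
#'
#' @param path CSV path.
#' @param kind kind tag to attach (the file does not carry it).
#' @return A [dist_matrix()].
#' @export
read_dist_matrix <- function(path, kind = "genetic") {
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square: ", path)
  if (!identical(rownames(m), colnames(m)))
    stop("row/column labels disagree in ", path)
  asym <- max(abs(m - t(m)))
  if (asym >= 1e-6)
    stop(sprintf("matrix asymmetry %.3g exceeds 1e-6 in %s", asym, path))
  m <- (m + t(m)) / 2
  if (max(abs(diag(m))) > 1e-9) stop("nonzero diagonal in ", path)
  diag(m) <- 0
  dist_matrix(m, kind = kind)
}

#' Write a distance matrix as labelled CSV
#' @param d a `dist_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path) {
  m <- as.data.frame(unclass(d))
  write.csv(m, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Assemble one host-associate study
#'
#' A pair dataset bundles everything one study contributes: host and
#' associate genetic data (either genotype counts or, for distance-only
#' studies, a precomputed genetic distance matrix), the shared sites, and the
#' interaction-type label used for subgroup meta-analysis.
#'
#' @param pair_id character label.
#' @param interaction_type `"antagonist"` or `"mutualist"`.
#' @param host,associate each either a [biallelic_counts()] object or a
#'   genetic [dist_matrix()].
#' @param sites a [site_table()] in canonical order.
#' @param notes optional provenance notes.
#' @return A `pair_dataset` (unvalidated; see [validate_pair()]).
#' @export
pair_dataset <- function(pair_id, interaction_type, host, associate, sites,
                         notes = NULL) {
  interaction_type <- match.arg(interaction_type, c("antagonist", "mutualist"))
  structure(list(pair_id = as.character(pair_id),
                 interaction_type = interaction_type,
                 host = host, associate = associate, sites = sites,
                 has_climate = !is.null(site_climate(sites)),
                 notes = notes),
            class = "pair_dataset")
}

species_sites <- function(obj) {
  if (inherits(obj, "biallelic_counts")) obj$sites else rownames(obj)
}

has_genotypes <- function(pair) {
  inherits(pair$host, "biallelic_counts") &&
    inherits(pair$associate, "biallelic_counts")
}

#' Validate a pair dataset
#'
#' Checks that host and associate reference the identical ordered site list,
#' that there are at least four geographically distinct sites, and records
#' which analysis stages the pair supports: every valid pair supports the
#' correlation and regression stages; only genotype-bearing pairs (both
#' species with allele counts, not just distance matrices) support the
#' covariance model.
#'
#' @param pair a [pair_dataset()].
#' @return The pair with attributes `validated = TRUE` and `stages` (character
#'   vector). Idempotent.
#' @export
validate_pair <- function(pair) {
  stopifnot(inherits(pair, "pair_dataset"))
  sites <- pair$sites$site_id
  if (length(sites) < 4)
    stop(sprintf("pair %s: fewer than 4 sites", pair$pair_id))
  for (role in c("host", "associate")) {
    sp <- species_sites(pair[[role]])
    if (!identical(sp, sites))
      stop(sprintf("pair %s: %s site list does not match the site table",
                   pair$pair_id, role))
  }
  stages <- c("correlations", "regression")
  if (has_genotypes(pair)) stages <- c(stages, "covariance-model")
  pair$stages <- stages
  pair$validated <- TRUE
  pair
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("Pair %s (%s): %d sites; host=%s, associate=%s; climate=%s\n",
              x$pair_id, x$interaction_type, nrow(x$sites),
              if (inherits(x$host, "biallelic_counts")) "genotypes" else "distances",
              if (inherits(x$associate, "biallelic_counts")) "genotypes" else "distances",
              if (isTRUE(x$has_climate)) "yes" else "no"))
  invisible(x)
}

#' Write a site table (with climate, if present) as CSV
#' @param s a `site_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(s, path) {
  d <- as.data.frame(s)
  cl <- site_climate(s)
  if (!is.null(cl)) d <- cbind(d, as.data.frame(cl))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site table CSV
#' @param path CSV with columns site_id, lat, lon and optional climate columns.
#' @return A [site_table()].
#' @export
read_site_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  clim_cols <- setdiff(names(d), c("site_id", "lat", "lon"))
  climate <- if (length(clim_cols)) as.matrix(d[clim_cols]) else NULL
  site_table(d$site_id, d$lat, d$lon, climate = climate)
}
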