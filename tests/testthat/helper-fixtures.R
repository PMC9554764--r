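# Fixtures are built in code; nothing is read from disk except temp files
# written by the tests themselves.

# labeled symmetric distance matrix from a lower-triangle vector
sym_dist <- function(v, sites, kind = "genetic") {
  S <- length(sites)
  M <- matrix(0, S, S, dimnames = list(sites, sites))
  M[lower.tri(M)] <- v
  M <- M + t(M)
  dist_matrix(M, kind)
}

# small multiallelic genotype object: one triallelic + one biallelic locus
tiny_genotypes <- function(sites = c("a", "b", "c", "d")) {
  tri <- matrix(c(3, 1, 0,
                  0, 4, 0,
                  2, 1, 1,
                  1, 1, 2), 4, 3, byrow = TRUE,
                dimnames = list(sites, c("A", "B", "C")))
  bi <- matrix(c(6, 2,
                 5, 3,
                 1, 7,
                 4, 4), 4, 2, byrow = TRUE,
               dimnames = list(sites, c("G", "T")))
  multiallelic_genotypes(list(ssr1 = tri, snp1 = bi))
}

# deterministic biallelic counts with differentiation between site groups
tiny_counts <- function(S = 4, L = 6, n = 20, seed = 7) {
  set.seed(seed)
  sites <- paste0("s", seq_len(S))
  p <- matrix(runif(S * L, 0.2, 0.8), S, L)
  x <- matrix(rbinom(S * L, n, p), S, L,
              dimnames = list(sites, paste0("ps", seq_len(L))))
  biallelic_counts(x, matrix(n, S, L, dimnames = dimnames(x)))
}

# quick 4-site site table with climate
tiny_sites <- function(seed = 5, S = 4, climate = TRUE) {
  set.seed(seed)
  cl <- if (climate) matrix(rnorm(S * 3), S, 3) else NULL
  site_table(paste0("s", seq_len(S)),
             lat = 34 + runif(S), lon = -118 + runif(S), climate = cl)
}

# independent longhand transcription of the two-population variance-component
# estimator, used as the FST oracle (kept deliberately separate from the
# package's implementation)
oracle_theta <- function(x1, x2, n1, n2) {
  num <- den <- 0
  for (l in seq_along(x1)) {
    p1 <- x1[l] / n1[l]; p2 <- x2[l] / n2[l]
    pb <- (n1[l] * p1 + n2[l] * p2) / (n1[l] + n2[l])
    msp <- n1[l] * (p1 - pb)^2 + n2[l] * (p2 - pb)^2
    msg <- (n1[l] * p1 * (1 - p1) + n2[l] * p2 * (1 - p2)) / (n1[l] + n2[l] - 2)
    nc <- (n1[l] + n2[l]) - (n1[l]^2 + n2[l]^2) / (n1[l] + n2[l])
    num <- num + msp - msg
    den <- den + msp + (nc - 1) * msg
  }
  num / den
}
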