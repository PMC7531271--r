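# Small in-code fixtures.

# build a one-locus-per-string dataset from genotype strings like
# "0/0 0/1 1/1" (one string per population per locus is overkill here; this
# helper covers the single-locus worked examples)
toy_dataset <- function(..., type = "snp") {
  pops <- list(...)
  pop <- rep(sprintf("pop%d", seq_along(pops)), vapply(pops, function(s) {
    length(strsplit(trimws(s), "\\s+")[[1]])
  }, 1L))
  calls <- unlist(lapply(pops, function(s) strsplit(trimws(s), "\\s+")[[1]]))
  parts <- strsplit(calls, "/", fixed = TRUE)
  num <- function(k) suppressWarnings(as.integer(vapply(parts, `[`, "", k)))
  genotype_dataset(pop, cbind(num(1)), cbind(num(2)), type = type)
}

# random small dataset with missingness; biallelic by default,
# microsatellite-like with `alleles` > 2
random_dataset <- function(seed, n_pops = 3, n_ind = 5, n_loci = 10,
                           alleles = 2, miss = 0.1) {
  set.seed(seed)
  N <- n_pops * n_ind
  pop <- rep(sprintf("pop%d", seq_len(n_pops)), each = n_ind)
  codes <- if (alleles == 2) 0:1 else 100 + seq_len(alleles)
  draw <- function() {
    m <- matrix(sample(codes, N * n_loci, replace = TRUE), N, n_loci)
    m[matrix(runif(N * n_loci) < miss, N, n_loci)] <- NA
    m
  }
  a1 <- draw(); a2 <- draw()
  # missing calls are whole-genotype: blank both copies where either is NA
  na <- is.na(a1) | is.na(a2)
  a1[na] <- NA; a2[na] <- NA
  genotype_dataset(pop, a1, a2, type = if (alleles == 2) "snp" else "microsat")
}

# a tiny hierarchical model that simulates quickly
small_model <- function(regime = "high", seed = 1, ...) {
  build_hierarchical_model(regime, n_old = 3, n_young = 3,
                           ne_old = 500, ne_young = 500 / 1.5,
                           t_split = 2000, t_ancestral = 14000,
                           seed = seed, ...)
}

# planar metadata for an arbitrary dataset (when a generated landscape is
# not needed)
fake_metadata <- function(dataset, seed = 1) {
  set.seed(seed)
  ids <- if (inherits(dataset, "genotype_dataset")) levels(dataset$pop)
         else dataset$pop_ids
  P <- length(ids)
  md <- data.frame(pop_id = ids, x = runif(P, 0, 10), y = runif(P, 0, 10),
                   env_1 = rnorm(P), env_2 = rnorm(P), env_3 = rnorm(P))
  attr(md, "planar") <- TRUE
  md$pc1 <- as.numeric(env_pc1(md[, c("env_1", "env_2", "env_3")]))
  cd <- centroid_distances(md)
  md$dist_geo_centroid <- cd$geographic
  md$dist_niche_centroid <- cd$niche
  md
}
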