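#' Simulate ascertained SNP genotypes under a demographic model
#'
#' Each locus is an independent structured-coalescent genealogy of all
#' sampled haplotypes (island migration within epochs, young demes fusing
#' into the old cluster at `t_split`, all demes fusing at `t_ancestral`)
#' carrying exactly one segregating mutation, so every locus is polymorphic
#' in the total sample. Genealogies are weighted by total branch length and
#' the mutation placed uniformly along the tree, which reproduces the
#' infinite-sites ascertained frequency spectrum (P(i derived copies)
#' proportional to 1/i in a panmictic sample).
#'
#' Haplotypes are paired into diploids within each deme; with probability
#' equal to the deme's inbreeding coefficient F an individual's second
#' haplotype is an identical-by-descent copy of its first (so a deme with
#' F = 1 is homozygous at every locus).
#'
#' @param model a [build_hierarchical_model()] object.
#' @param n_loci number of SNP loci.
#' @param n_diploids_per_pop diploid individuals sampled per deme.
#' @param seed integer seed (drives both the inbreeding draws and the
#'   coalescent simulation).
#' @return a [genotype_dataset()] with 0/1 allele calls.
#' @export
simulate_snp_genotypes <- function(model, n_loci, n_diploids_per_pop = 15L,
                                   seed = 1L) {
  stopifnot(inherits(model, "demographic_model"))
  if (n_loci < 1L || n_diploids_per_pop < 1L)
    stop("need at least one locus and one diploid per population")
  prep <- prepare_haplotypes(model, n_diploids_per_pop, seed)
  mig <- migration_matrices(model)
  hap <- cpp_sim_snp(as.integer(n_loci), prep$deme_of_hap, model$ne,
                     mig$epoch1, mig$epoch2,
                     model$t_split, model$t_ancestral,
                     model$cluster == "young", 0L,
                     lambda_target = 25, cmax = 110L)
  assemble_dataset(prep, hap, "snp")
}

#' Simulate microsatellite genotypes under a demographic model
#'
#' Same genealogies as [simulate_snp_genotypes()]; mutations occur as a
#' Poisson process along branches at rate `mutation_rate` per generation and
#' follow the stepwise mutation model (+-1 repeat with equal probability)
#' from a root repeat count, yielding multi-allelic integer alleles. No
#' ascertainment is applied, so loci can be monomorphic when mutations are
#' rare.
#'
#' @inheritParams simulate_snp_genotypes
#' @param mutation_rate per-generation, per-lineage mutation rate (>= 0).
#' @param root_state ancestral repeat count.
#' @return a [genotype_dataset()] of type `"microsat"`.
#' @export
simulate_microsat_genotypes <- function(model, n_loci, mutation_rate,
                                        n_diploids_per_pop = 15L, seed = 1L,
                                        root_state = 100L) {
  stopifnot(inherits(model, "demographic_model"))
  if (mutation_rate < 0) stop("mutation_rate must be non-negative")
  prep <- prepare_haplotypes(model, n_diploids_per_pop, seed)
  mig <- migration_matrices(model)
  hap <- cpp_sim_microsat(as.integer(n_loci), prep$deme_of_hap, model$ne,
                          mig$epoch1, mig$epoch2,
                          model$t_split, model$t_ancestral,
                          model$cluster == "young", 0L,
                          mutation_rate, as.integer(root_state))
  assemble_dataset(prep, hap, "microsat")
}

# Decide per-individual identity-by-descent copies up front so only distinct
# haplotypes are simulated; copies are expanded afterwards. Polymorphism among
# distinct haplotypes is preserved by the expansion, so SNP ascertainment in
# the total sample is unaffected.
prepare_haplotypes <- function(model, n_ind, seed) {
  set.seed(as.integer(seed))
  nd <- model$n_demes
  deme_of_ind <- rep(seq_len(nd), each = n_ind)
  ibd <- stats::runif(length(deme_of_ind)) < model$f[deme_of_ind]
  n_hap_of_ind <- ifelse(ibd, 1L, 2L)
  deme_of_hap <- rep(deme_of_ind, n_hap_of_ind)
  first_hap <- cumsum(n_hap_of_ind) - n_hap_of_ind + 1L
  list(deme_of_ind = deme_of_ind, ibd = ibd,
       deme_of_hap = as.integer(deme_of_hap - 1L),  # 0-based for C++
       first_hap = first_hap, n_ind = n_ind)
}

assemble_dataset <- function(prep, hap, type) {
  a1 <- hap[prep$first_hap, , drop = FALSE]
  second <- ifelse(prep$ibd, prep$first_hap, prep$first_hap + 1L)
  a2 <- hap[second, , drop = FALSE]
  pop <- factor(sprintf("pop%02d", prep$deme_of_ind),
                levels = sprintf("pop%02d", sort(unique(prep$deme_of_ind))))
  genotype_dataset(pop, a1, a2, type = type)
}

#' Generate per-population landscape metadata with known ground truth
#'
#' Places the demes on a plane (one spatial centre per genetic cluster),
#' derives `k_env` environmental variables as linear spatial gradients plus
#' noise, and computes the first environmental principal component and
#' distances to the geographic and niche centroids. Three modes control the
#' planted ground truth:
#'
#' * `"island"`: the demographic model is returned unchanged.
#' * `"ibd"`: within-cluster migration is rescaled so that
#'   `m_ij` is proportional to `exp(-d_ij / sigma)` (per-deme totals kept),
#'   planting true isolation by distance; `sigma = Inf` recovers island mode.
#' * `"cah"`: per-deme effective sizes are scaled down with distance from the
#'   geographic centroid (`Ne * exp(-lambda * d / max(d))`), planting a true
#'   central-abundance gradient (Spearman correlation between Ne and centroid
#'   distance is exactly -1).
#'
#' @param model a `demographic_model`.
#' @param mode one of `"island"`, `"ibd"`, `"cah"`.
#' @param seed integer seed.
#' @param k_env number of environmental variables.
#' @param sigma isolation-by-distance length scale (planar units); defaults
#'   to half the mean within-cluster distance.
#' @param lambda central-abundance strength.
#' @return a list with elements `metadata` (data frame: `pop_id`, `x`, `y`,
#'   `env_1..k`, `pc1`, `dist_geo_centroid`, `dist_niche_centroid`, with
#'   attribute `planar = TRUE`) and `model` (possibly modified).
#' @export
generate_landscape <- function(model, mode = c("island", "ibd", "cah"),
                               seed = 1L, k_env = 3L, sigma = NULL,
                               lambda = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "demographic_model"))
  set.seed(as.integer(seed))
  nd <- model$n_demes
  centers <- rbind(old = c(0, 0), young = c(8, 0))
  xy <- centers[as.character(model$cluster), , drop = FALSE] +
    matrix(stats::rnorm(2 * nd, 0, 2), nd, 2)
  colnames(xy) <- c("x", "y")

  # environmental gradients: linear in space plus independent noise
  env <- sapply(seq_len(k_env), function(j) {
    b <- stats::rnorm(2)
    drop(xy %*% b) + stats::rnorm(nd, 0, 0.5)
  })
  colnames(env) <- sprintf("env_%d", seq_len(k_env))

  md <- data.frame(pop_id = model$deme_ids, x = xy[, 1], y = xy[, 2], env,
                   stringsAsFactors = FALSE)
  attr(md, "planar") <- TRUE
  md$pc1 <- env_pc1(env)
  cd <- centroid_distances(md)
  md$dist_geo_centroid <- cd$geographic
  md$dist_niche_centroid <- cd$niche

  if (mode == "ibd") {
    d <- as.matrix(stats::dist(xy))
    if (is.null(sigma)) {
      same <- outer(model$cluster, model$cluster, "==") & d > 0
      sigma <- mean(d[same]) / 2
    }
    model$mig_within_weights <- exp(-d / sigma)
  } else if (mode == "cah") {
    # deterministic central-abundance ground truth: Ne is a strictly
    # decreasing function of centroid distance (replaces the jittered sizes,
    # so Spearman cor(Ne, distance) = -1 by construction)
    dmax <- max(md$dist_geo_centroid)
    model$ne <- mean(model$ne) * exp(-lambda * md$dist_geo_centroid / dmax)
  }
  list(metadata = md, model = model)
}

#' Plant environment-associated cline loci in a SNP dataset
#'
#' Deforms the allele frequencies of selected loci towards a logistic cline
#' in an environmental variable: in population p the planted derived-allele
#' frequency becomes `plogis(intercept + slope * z_p)` with `z` the
#' standardized environmental value, and genotypes at those loci are redrawn
#' binomially at those frequencies (Hardy-Weinberg within populations).
#' Planted locus ids are recorded so true and false positives are countable
#' in outlier-detection experiments.
#'
#' @param dataset a SNP [genotype_dataset()].
#' @param env numeric environmental value per population (in
#'   `levels(dataset$pop)` order), e.g. the PC1 column of a landscape.
#' @param loci locus indices or ids to plant; or a count `n` to pick at random.
#' @param slope,intercept cline parameters on the logit scale.
#' @param seed integer seed.
#' @return the dataset with redrawn genotypes; planted locus ids in
#'   `attr(, "planted")`.
#' @export
plant_cline_loci <- function(dataset, env, loci = 20L, slope = 3,
                             intercept = 0, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"), dataset$type == "snp")
  if (length(env) != n_pops(dataset))
    stop("need one environmental value per population")
  set.seed(as.integer(seed))
  if (length(loci) == 1L && is.numeric(loci) && loci < length(dataset$loci))
    loci <- sample(length(dataset$loci), loci)
  if (is.character(loci)) loci <- match(loci, dataset$loci)
  z <- as.numeric(scale(env))
  q <- stats::plogis(intercept + slope * z)   # per-pop target frequency
  qi <- q[as.integer(dataset$pop)]            # per-individual
  n <- length(dataset$pop)
  for (l in loci) {
    dataset$a1[, l] <- as.integer(stats::runif(n) < qi)
    dataset$a2[, l] <- as.integer(stats::runif(n) < qi)
  }
  attr(dataset, "planted") <- dataset$loci[loci]
  dataset
}
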