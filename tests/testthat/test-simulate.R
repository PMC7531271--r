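test_that("SNP simulation has the declared dimensions and codes", {
  m <- build_hierarchical_model("high", seed = 3)
  d <- simulate_snp_genotypes(m, 40, 15, seed = 1)
  expect_equal(unname(dim(d)), c(50L, 50L * 15L, 40L))
  expect_true(all(d$a1 %in% 0:1) && all(d$a2 %in% 0:1))
  expect_equal(levels(d$pop), m$deme_ids)
})

test_that("every ascertained SNP locus is polymorphic in the total sample", {
  m <- small_model(seed = 2)
  d <- simulate_snp_genotypes(m, 300, 8, seed = 5)
  counts <- colSums(d$a1) + colSums(d$a2)
  expect_true(all(counts > 0 & counts < 2 * nrow(d$a1)))
})

test_that("simulation is bit-identical under a fixed (config, seed)", {
  m <- small_model(seed = 4)
  d1 <- simulate_snp_genotypes(m, 50, 6, seed = 99)
  d2 <- simulate_snp_genotypes(m, 50, 6, seed = 99)
  expect_identical(d1, d2)
  d3 <- simulate_snp_genotypes(m, 50, 6, seed = 100)
  expect_false(identical(d1$a1, d3$a1))
})

test_that("inbreeding F = 1 makes every individual homozygous", {
  m <- small_model(seed = 6)
  m$f[] <- 1
  d <- simulate_snp_genotypes(m, 60, 5, seed = 2)
  expect_true(all(d$a1 == d$a2))
})

test_that("single-deme ascertained SFS matches the 1/i closed form", {
  # 2 diploids = 4 haplotypes; ascertained spectrum P(i) = (1/i)/H_3 gives
  # E[1 - sum p-hat^2] = 4.5/11; Monte-Carlo check at 2e4 loci (3 sigma)
  m <- build_hierarchical_model("high", n_old = 1, n_young = 0,
                                ne_old = 1000, f_sd = 0, seed = 1)
  d <- simulate_snp_genotypes(m, 2e4, 2, seed = 7)
  p <- (colSums(d$a1) + colSums(d$a2)) / 4
  h <- mean(1 - p^2 - (1 - p)^2)
  se <- stats::sd(1 - p^2 - (1 - p)^2) / sqrt(2e4)
  expect_lt(abs(h - 4.5 / 11), 3 * se + 1e-4)
})

test_that("unreachable common ancestor is rejected", {
  m <- small_model(seed = 1, jitter_cv = 0)
  m$m_within[] <- 0; m$m_between[] <- 0
  m$t_split <- Inf; m$t_ancestral <- Inf  # no fusion events either
  expect_error(simulate_snp_genotypes(m, 5, 3, seed = 1), "ancestor")
})

test_that("microsatellite mode: dimensions, SMM alleles, zero-rate limit", {
  m <- small_model(seed = 8)
  d <- simulate_microsat_genotypes(m, 22, mutation_rate = 5e-4,
                                   n_diploids_per_pop = 6, seed = 3)
  expect_equal(unname(dim(d))[3], 22L)
  expect_equal(d$type, "microsat")
  expect_true(all(d$a1 > 0))
  n_alleles <- sapply(seq_len(22), function(l) length(unique(c(d$a1[, l], d$a2[, l]))))
  expect_true(all(n_alleles >= 1))
  expect_gt(mean(n_alleles), 1)  # mutation actually generates variation

  d0 <- simulate_microsat_genotypes(m, 10, mutation_rate = 0,
                                    n_diploids_per_pop = 4, seed = 3)
  expect_true(all(d0$a1 == 100 & d0$a2 == 100))  # all loci monomorphic
})

test_that("microsat Hs approaches the stepwise-mutation equilibrium", {
  # single panmictic deme: equilibrium gene diversity 1 - 1/sqrt(1 + 8 Ne mu)
  ne <- 800; mu <- 8e-4   # 8 Ne mu = 5.12 -> ~0.6
  m <- build_hierarchical_model("high", n_old = 1, n_young = 0,
                                ne_old = ne, f_sd = 0, jitter_cv = 0, seed = 1)
  d <- simulate_microsat_genotypes(m, 400, mutation_rate = mu,
                                   n_diploids_per_pop = 15, seed = 11)
  hs <- basic_stats(d)$mean_hs
  expected <- 1 - 1 / sqrt(1 + 8 * ne * mu)
  expect_lt(abs(hs - expected), 0.05)
})

test_that("pooling preserves counts and loses only individual identity", {
  d <- toy_dataset("0/0 0/1")
  pf <- pool_frequencies(d)
  expect_equal(unname(pf$counts[["0"]][1, 1]), 3)
  expect_equal(unname(pf$counts[["1"]][1, 1]), 1)

  ds <- random_dataset(21, n_pops = 4, n_ind = 6, n_loci = 12, miss = 0.15)
  f_direct <- allele_frequencies(ds)
  f_pooled <- allele_frequencies(pool_frequencies(ds))
  expect_equal(f_pooled$p, f_direct$p)
  expect_equal(f_pooled$tot, f_direct$tot)

  # all-missing cell records total 0
  dm <- random_dataset(3, n_pops = 2, n_ind = 3, n_loci = 2, miss = 0)
  dm$a1[dm$pop == "pop1", 1] <- NA
  dm$a2[dm$pop == "pop1", 1] <- NA
  pf2 <- pool_frequencies(dm)
  expect_equal(unname(pf2$tot["pop1", 1]), 0)
})

test_that("landscape modes plant the advertised ground truth", {
  m <- build_hierarchical_model("high", n_old = 10, n_young = 10, seed = 2)
  isl <- generate_landscape(m, "island", seed = 3)
  expect_null(isl$model$mig_within_weights)
  expect_equal(isl$model$ne, m$ne)
  expect_true(all(c("pop_id", "x", "y", "env_1", "pc1",
                    "dist_geo_centroid", "dist_niche_centroid")
                  %in% names(isl$metadata)))

  # sigma -> Inf reduces IBD weighting to the island model
  ibd_inf <- generate_landscape(m, "ibd", seed = 3, sigma = Inf)
  w <- ibd_inf$model$mig_within_weights
  mats_isl <- popsampling:::migration_matrices(isl$model)
  mats_ibd <- popsampling:::migration_matrices(ibd_inf$model)
  expect_equal(mats_ibd$epoch1, mats_isl$epoch1, tolerance = 1e-12)

  # finite sigma: nearer demes get more migration
  ibd <- generate_landscape(m, "ibd", seed = 3)
  mats <- popsampling:::migration_matrices(ibd$model)
  expect_false(isTRUE(all.equal(mats$epoch1, mats_isl$epoch1)))
  expect_equal(rowSums(mats$epoch1), rowSums(mats_isl$epoch1), tolerance = 1e-12)

  # cah: Ne decreases monotonically with centroid distance (Spearman -1)
  cah <- generate_landscape(m, "cah", seed = 3)
  expect_equal(unname(stats::cor(cah$model$ne, cah$metadata$dist_geo_centroid,
                                 method = "spearman")), -1)
  expect_error(generate_landscape(m, "volcano"))
})

test_that("planted cline loci track the environment", {
  m <- build_hierarchical_model("high", n_old = 8, n_young = 8, seed = 5)
  ls <- generate_landscape(m, "island", seed = 5)
  d <- simulate_snp_genotypes(ls$model, 50, 8, seed = 5)
  pd <- plant_cline_loci(d, ls$metadata$pc1, loci = 5, slope = 4, seed = 9)
  planted <- attr(pd, "planted")
  expect_length(planted, 5)
  ft <- allele_frequencies(pd)
  rs <- abs(apply(ft$p, 2, stats::cor, y = ls$metadata$pc1))
  expect_gt(min(rs[match(planted, d$loci)]), 0.6)
})
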