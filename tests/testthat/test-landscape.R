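test_that("env_pc1: perfect correlation, 1-D identity, eigen oracle", {
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 5)
  sc <- env_pc1(x)
  expect_equal(attr(sc, "var_explained"), 1)

  # data one-dimensional along a variable: scores equal the scaled values
  # up to sign (PCA on the correlation matrix)
  set.seed(1)
  y <- cbind(v = rnorm(6), w = rep(0.5, 6) + rnorm(6) * 1e-14)
  expect_warning(env_pc1(cbind(y, z = rep(1, 6))), "zero-variance")

  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(5 * 19), 5, 19)
    colnames(m) <- paste0("b", 1:19)
    expect_equal(as.numeric(env_pc1(m)), as.numeric(oracle_pc1(m)),
                 tolerance = 1e-8)
  }
  expect_error(env_pc1(matrix(rnorm(4), 2, 2)), "three populations")
})

test_that("distance matrices: haversine, planar, environmental", {
  md <- data.frame(pop_id = c("a", "b"), lon = c(0, 0), lat = c(0, 90),
                   pc1 = c(1.0, -0.5))
  gen <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  dm <- distance_matrices(md, gen)
  expect_equal(unname(dm$geographic[1, 2]), 10007.5, tolerance = 1e-4)
  expect_equal(unname(dm$environmental[1, 2]), 1.5)
  expect_equal(diag(dm$geographic), c(a = 0, b = 0))

  # identical coordinates -> zero distance
  md2 <- data.frame(pop_id = c("a", "b"), lon = c(10, 10), lat = c(-5, -5),
                    pc1 = c(0, 0))
  expect_equal(unname(distance_matrices(md2, gen)$geographic[1, 2]), 0)

  # planar synthetic coordinates use Euclidean distance
  md3 <- data.frame(pop_id = c("a", "b"), x = c(0, 3), y = c(0, 4),
                    pc1 = c(0, 1))
  attr(md3, "planar") <- TRUE
  expect_equal(unname(distance_matrices(md3, gen)$geographic[1, 2]), 5)

  expect_error(distance_matrices(md[1, ], gen), "mismatch")

  # square CSV round trip with pop-id headers
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(dm$geographic, path)
  expect_equal(read_distance_csv(path), dm$geographic, tolerance = 1e-9)
})

test_that("haversine agrees with the geosphere implementation", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  lon <- runif(6, -120, 40); lat <- runif(6, -50, 60)
  ours <- popsampling:::haversine_km(lon[1], lat[1], lon[-1], lat[-1])
  ref <- geosphere::distHaversine(c(lon[1], lat[1]), cbind(lon[-1], lat[-1]),
                                  r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("MRM recovers constructed coefficients exactly", {
  set.seed(3)
  n <- 8
  xy <- matrix(rnorm(2 * n), n, 2)
  geo <- as.matrix(dist(xy))
  env <- abs(outer(rnorm(n), rnorm(n), "-"))
  gen <- 0.5 * geo + 0 * env
  fit <- mrm(gen, geo, env, n_permutations = 100, seed = 1)
  expect_equal(unname(fit$coefficients["geographic"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["environmental"]), 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lte(fit$p_values["geographic"], 0.05)

  zero <- mrm(matrix(0, n, n), geo, env, n_permutations = 10, seed = 1)
  expect_equal(unname(zero$coefficients), c(0, 0, 0), tolerance = 1e-12)

  expect_error(mrm(gen, geo, geo * 2), "collinear")
  expect_error(mrm(gen[1:3, 1:3], geo[1:3, 1:3], env[1:3, 1:3]), "four")
})

test_that("single-predictor MRM equals OLS on the unfolded distances", {
  set.seed(4)
  n <- 7
  geo <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
  gen <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
  fit <- mrm(gen, geo_dist = geo, n_permutations = 0)
  y <- gen[lower.tri(gen)]
  X <- cbind(1, geo[lower.tri(geo)])
  expect_equal(unname(fit$coefficients), unname(oracle_ols(y, X)),
               tolerance = 1e-10)
})

test_that("MRM permutation p-values are invariant to population relabeling", {
  set.seed(5)
  n <- 9
  geo <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
  env <- as.matrix(dist(rnorm(n)))
  gen <- 0.2 * geo + 0.1 * env + as.matrix(dist(rnorm(n))) * 0.05
  f1 <- mrm(gen, geo, env, n_permutations = 200, seed = 8)
  ord <- sample(n)
  f2 <- mrm(gen[ord, ord], geo[ord, ord], env[ord, ord],
            n_permutations = 200, seed = 8)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # the permutation null is label-exchangeable, so p-values agree up to
  # Monte-Carlo noise (binomial sd ~ sqrt(p(1-p)/200))
  expect_true(all(abs(f1$p_values - f2$p_values) <
                    4 * sqrt(pmax(f1$p_values * (1 - f1$p_values), 0.01) / 200)))
})

test_that("centroid distances match a brute-force mean-and-norm oracle", {
  md <- data.frame(pop_id = c("a", "b"), x = c(0, 2), y = c(0, 0),
                   env_1 = c(1, 2), env_2 = c(2, 1))
  attr(md, "planar") <- TRUE
  cd <- centroid_distances(md)
  expect_equal(cd$geographic, c(1, 1))

  same <- data.frame(pop_id = c("a", "b", "c"), x = rep(1, 3), y = rep(2, 3),
                     env_1 = rep(0.3, 3), env_2 = rep(4, 3))
  attr(same, "planar") <- TRUE
  cds <- centroid_distances(same)
  expect_equal(cds$geographic, rep(0, 3))

  set.seed(6)
  md5 <- fake_metadata(random_dataset(8, n_pops = 5, n_ind = 2, n_loci = 2))
  cd5 <- centroid_distances(md5)
  xy <- cbind(md5$x, md5$y)
  ctr <- colMeans(xy)
  expect_equal(cd5$geographic,
               sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
  # niche distances: Euclidean in the first two scaled PCs
  pr <- prcomp(md5[, c("env_1", "env_2", "env_3")], scale. = TRUE)
  pc <- pr$x[, 1:2]
  nc <- colMeans(pc)
  expect_equal(cd5$niche,
               unname(sqrt((pc[, 1] - nc[1])^2 + (pc[, 2] - nc[2])^2)))
})

test_that("CAH regression: exact recovery, degenerate inputs", {
  d <- seq(0, 5, length.out = 8)
  hs <- 0.5 - 0.1 * d
  fit <- cah_regression(hs, d, "geographic")
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- cah_regression(rep(0.4, 8), d, "niche")
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(cah_regression(hs, rep(1, 8)), "zero variance")
  expect_error(cah_regression(hs[1:2], d[1:2]), "three populations")
})

test_that("ibd-mode synthetic data are recovered by MRM with power", {
  # single-cluster model with distance-decayed migration; at this reduced
  # scale (14 demes, 900 loci, 10 diploids) the geographic signal should be
  # positive essentially always and significant in most seeds
  hits_beta <- hits_p <- 0
  for (seed in 1:10) {
    m <- build_hierarchical_model("high", n_old = 14, n_young = 0,
                                  ne_old = 1000, t_split = 5000,
                                  t_ancestral = 40000, m_within = 0.0015,
                                  seed = seed)
    ls <- generate_landscape(m, "ibd", seed = seed, sigma = 0.8)
    d <- simulate_snp_genotypes(ls$model, 900, 10, seed = seed)
    dm <- distance_matrices(ls$metadata, pairwise_fst(d, "wc"))
    fit <- mrm(dm, n_permutations = 199, seed = seed)
    hits_beta <- hits_beta + (fit$coefficients[["geographic"]] > 0)
    hits_p <- hits_p + (fit$p_values[["geographic"]] < 0.05)
  }
  expect_gte(hits_beta, 9)
  expect_gte(hits_p, 8)
})

test_that("cah-mode synthetic data yield a negative diversity-distance slope", {
  m <- build_hierarchical_model("high", n_old = 12, n_young = 12,
                                ne_old = 2000, ne_young = 2000 / 1.5,
                                t_split = 4000, t_ancestral = 30000,
                                seed = 21)
  ls <- generate_landscape(m, "cah", seed = 21, lambda = 2.5)
  d <- simulate_snp_genotypes(ls$model, 600, 10, seed = 21)
  hs_pop <- basic_stats(d)$per_pop$mean_hs
  fit <- cah_regression(hs_pop, ls$metadata$dist_geo_centroid, "geographic")
  expect_lt(fit$slope, 0)
})
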