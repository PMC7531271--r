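test_that("locus FST scan: flat frequencies, planted maximum, oracle", {
  # identical frequencies everywhere -> global theta ~ 0
  set.seed(1)
  g <- matrix(rep(c(0L, 0L, 1L, 1L), 20), 4, 20)
  d <- genotype_dataset(rep(c("a", "b"), each = 2), g, g[4:1, , drop = FALSE])
  scan <- locus_fst_scan(d)
  expect_lt(abs(scan$global), 0.05)

  # a locus fixed for alternative alleles between clusters attains the max
  d2 <- random_dataset(9, n_pops = 4, n_ind = 6, n_loci = 25, miss = 0)
  d2$a1[, 13] <- d2$a2[, 13] <- as.integer(d2$pop %in% c("pop1", "pop2"))
  scan2 <- locus_fst_scan(d2)
  expect_equal(scan2$max_locus, d2$loci[13])
  expect_equal(scan2$max, 1)
})

test_that("differentiation test: p floor, planted locus, skipped status", {
  d <- random_dataset(10, n_pops = 5, n_ind = 8, n_loci = 40, miss = 0)
  d$a1[, 7] <- d$a2[, 7] <- as.integer(d$pop %in% c("pop1", "pop2"))
  res <- fst_outlier_test(d, n_null = 200, seed = 2)
  expect_equal(res$status, "ok")
  expect_equal(min(res$table$p, na.rm = TRUE), 1 / 201)
  expect_equal(which.min(res$table$p), 7L)
  expect_true(all(res$table$p >= 1 / 201, na.rm = TRUE))

  # q-values are monotone in the p-value ranks
  tab <- res$table[order(res$table$p), ]
  expect_true(all(diff(tab$q) >= -1e-12))
})

test_that("null-simulated data produce approximately zero flags (FDR control)", {
  # simulate straight from the beta-binomial null itself
  set.seed(42)
  P <- 12; L <- 500; theta <- 0.15; n_hap <- 30L
  pbar <- runif(L, 0.05, 0.95)
  al <- pbar * (1 - theta) / theta
  be <- (1 - pbar) * (1 - theta) / theta
  cnt1 <- sapply(seq_len(L), function(l) {
    rbinom(P, n_hap, rbeta(P, al[l], be[l]))
  })
  cnt0 <- matrix(n_hap, P, L) - cnt1
  ids <- sprintf("p%02d", 1:P)
  loci <- sprintf("L%03d", 1:L)
  dimnames(cnt0) <- dimnames(cnt1) <- list(ids, loci)
  pool <- structure(list(counts = list(`0` = cnt0, `1` = cnt1),
                         tot = cnt0 + cnt1, alleles = c(0L, 1L),
                         pop_ids = ids, loci = loci, type = "snp"),
                    class = "pool_dataset")
  res <- fst_outlier_test(pool, n_null = 400, seed = 3)
  expect_equal(res$status, "ok")
  expect_lte(sum(res$table$q < 0.05, na.rm = TRUE), 2)

  # association test calibration under a permuted-label null
  env <- rnorm(P)
  assoc <- env_association_test(pool, env, n_permutations = 300, seed = 4)
  expect_lte(sum(assoc$table$q < 0.05, na.rm = TRUE), 2)
})

test_that("association test: perfect cline is minimal, constant env errors", {
  d <- random_dataset(11, n_pops = 8, n_ind = 10, n_loci = 30, miss = 0)
  env <- seq(-1, 1, length.out = 8)
  # frequencies exactly linear in env at locus 5
  for (p in 1:8) {
    rows <- which(d$pop == sprintf("pop%d", p))
    q <- 0.1 + 0.8 * (env[p] + 1) / 2
    k <- round(q * 10)
    d$a1[rows, 5] <- rep(c(1L, 0L), c(k, 10 - k))
    d$a2[rows, 5] <- rep(c(1L, 0L), c(k, 10 - k))
  }
  res <- env_association_test(d, env, n_permutations = 200, seed = 5)
  expect_equal(which.min(res$table$p), 5L)
  expect_equal(min(res$table$p), 1 / 201)
  expect_error(env_association_test(d, rep(1, 8)), "constant")
  expect_error(env_association_test(d, env[1:3]), "one environmental value")
})

test_that("detect_outliers flags the planted cline and honours thresholds", {
  m <- build_hierarchical_model("high", n_old = 10, n_young = 10,
                                ne_old = 1000, ne_young = 1000 / 1.5,
                                t_split = 2000, t_ancestral = 14000, seed = 31)
  ls <- generate_landscape(m, "island", seed = 31)
  d <- simulate_snp_genotypes(ls$model, 120, 8, seed = 31)
  pd <- plant_cline_loci(d, ls$metadata$pc1, loci = 3, slope = 5, seed = 32)
  planted <- attr(pd, "planted")
  # null sizes must keep the attainable q floor (~ p_floor * L / k) below
  # the threshold: with 120 loci and 3 planted, 2000 nulls give q ~ 0.02
  res <- detect_outliers(pd, ls$metadata$pc1, q_threshold = 0.05,
                         n_null = 2000, n_permutations = 2000, seed = 33)
  expect_gte(length(intersect(res$outliers, planted)), 2)
  expect_true(is.finite(res$max_fst))

  # empty rejection region at q_threshold = 0
  res0 <- detect_outliers(pd, ls$metadata$pc1, q_threshold = 0,
                          n_null = 100, n_permutations = 100, seed = 33)
  expect_equal(res0$n_outliers, 0L)
  expect_true(is.finite(res0$max_fst))  # max FST still reported
})

test_that("population-count experiment bookkeeping", {
  m <- build_hierarchical_model("high", n_old = 6, n_young = 6,
                                ne_old = 800, ne_young = 800 / 1.5,
                                t_split = 2000, t_ancestral = 14000, seed = 41)
  ls <- generate_landscape(m, "island", seed = 41)
  d <- simulate_snp_genotypes(ls$model, 80, 6, seed = 41)
  pd <- plant_cline_loci(d, ls$metadata$pc1, loci = 4, slope = 5, seed = 42)

  # reps = 1, level = all: the intersection is that replicate's outlier set
  ex <- population_count_experiment(pd, ls$metadata, levels = "all",
                                    reps = 1L, n_loci = 80,
                                    n_null = 150, n_permutations = 150,
                                    seed = 43)
  expect_equal(nrow(ex$table), 1)
  expect_setequal(ex$intersections[["12"]], ex$outlier_sets[["12"]][[1]])
  expect_setequal(ex$global_intersection, ex$intersections[["12"]])

  # disjoint outlier sets -> empty intersection
  expect_equal(Reduce(intersect, list(c("a", "b"), c("c"))), character(0))
  expect_error(population_count_experiment(pd, ls$metadata, levels = 40,
                                           reps = 1, n_loci = 10, seed = 1),
               "levels")
})
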