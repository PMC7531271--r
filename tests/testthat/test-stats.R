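test_that("allele frequencies handle direct, degenerate and pooled input", {
  d <- toy_dataset("0/0 0/1 1/1 0/1")
  ft <- allele_frequencies(d)
  expect_equal(unname(ft$p[1, 1]), 0.5)
  expect_equal(unname(ft$n[1, 1]), 4)

  d2 <- toy_dataset("./. ./.")
  ft2 <- allele_frequencies(toy_dataset("0/1 ./."))
  expect_equal(unname(ft2$n[1, 1]), 1)

  pool <- pool_frequencies(toy_dataset("0/0 0/1"))
  ftp <- allele_frequencies(pool)
  expect_equal(unname(ftp$p[1, 1]), 0.25)

  # all-missing (locus, pop): n = 0 and undefined frequency
  dm <- toy_dataset("./. ./.")
  ftm <- allele_frequencies(dm)
  expect_equal(unname(ftm$n[1, 1]), 0)
  expect_true(is.na(ftm$p[1, 1]))
})

test_that("worked single-population examples match the Nei formulas", {
  s <- basic_stats(toy_dataset("0/0 0/1 1/1 0/1"))
  expect_equal(unname(s$ho[1, 1]), 0.5)
  expect_equal(unname(s$hs[1, 1]), 0.58333, tolerance = 1e-5)
  expect_equal(unname(s$fis[1, 1]), 0.142857, tolerance = 1e-5)
  expect_equal(unname(s$fis[1, 1]), 1 - 0.5 / ((4 / 3) * 0.4375), tolerance = 1e-12)

  s2 <- basic_stats(toy_dataset("0/1 0/1"))
  expect_equal(unname(s2$ho[1, 1]), 1)
  expect_equal(unname(s2$hs[1, 1]), 0.5)
  expect_equal(unname(s2$fis[1, 1]), -1)

  # monomorphic cell: Ho = Hs = 0, FIS undefined and counted
  s3 <- basic_stats(toy_dataset("0/0 0/0"))
  expect_equal(unname(s3$ho[1, 1]), 0)
  expect_equal(unname(s3$hs[1, 1]), 0)
  expect_true(is.na(s3$fis[1, 1]))
  expect_equal(s3$per_pop$nan_fis, 1)
})

test_that("statistics equal the per-term oracle on random datasets", {
  for (seed in 1:20) {
    alleles <- if (seed %% 3 == 0) 4 else 2
    d <- random_dataset(seed, n_pops = sample(2:5, 1), n_ind = sample(2:6, 1),
                        n_loci = 20, alleles = alleles, miss = 0.15)
    s <- basic_stats(d)
    o <- oracle_basic_stats(d)
    expect_equal(s$ho, o$ho, tolerance = 1e-10)
    expect_equal(s$hs, o$hs, tolerance = 1e-10)
    expect_equal(s$fis, o$fis, tolerance = 1e-10)
    expect_equal(unname(s$ht), unname(o$ht), tolerance = 1e-10)
    expect_equal(unname(s$fst_locus), unname(o$fst_locus), tolerance = 1e-10)
    expect_equal(s$fst_ratio, o$fst_ratio, tolerance = 1e-10)
  }
})

test_that("pooled data mark Ho/FIS unavailable, never zero", {
  d <- random_dataset(5, n_pops = 3, n_ind = 6, n_loci = 8, miss = 0)
  pool <- pool_frequencies(d)
  s <- basic_stats(pool)
  expect_true(all(is.na(s$ho)))
  expect_true(all(is.na(s$fis)))
  expect_true(is.na(s$mean_fis))
  expect_true(s$pooled)
  # pooled Hs uses n = haploid count / 2 without the Ho term
  ft <- allele_frequencies(pool)
  n11 <- ft$tot[1, 1] / 2
  sumsq <- sum(sapply(ft$freq, function(f) f[1, 1]^2))
  expect_equal(unname(s$hs[1, 1]), n11 / (n11 - 1) * (1 - sumsq))
})

test_that("negative FST values are reported as computed, not clamped", {
  found_neg <- FALSE
  for (seed in 1:40) {
    d <- random_dataset(seed + 100, n_pops = 2, n_ind = 3, n_loci = 4, miss = 0)
    s <- basic_stats(d)
    if (any(s$fst_locus < 0, na.rm = TRUE)) found_neg <- TRUE
  }
  expect_true(found_neg)
})

test_that("FST and pairwise FST require two populations", {
  d <- toy_dataset("0/0 0/1 1/1")
  expect_error(global_fst(d), "two populations")
  expect_error(pairwise_fst(d), "two populations")
})

test_that("pairwise WC theta: complete differentiation and self-identity", {
  d <- toy_dataset("0/0 0/0 0/0", "1/1 1/1 1/1")
  th <- pairwise_fst(d, "wc")
  expect_equal(unname(th[1, 2]), 1)
  expect_equal(diag(th), c(pop1 = 0, pop2 = 0))

  # a population duplicated: the corrected estimator has a small negative
  # bias of order -1/(2(n-1)) that vanishes with sample size
  for (n_ind in c(6, 200)) {
    dd <- random_dataset(7, n_pops = 1, n_ind = n_ind, n_loci = 30, miss = 0)
    d2 <- genotype_dataset(rep(c("a", "b"), each = n_ind),
                           rbind(dd$a1, dd$a1), rbind(dd$a2, dd$a2))
    th2 <- pairwise_fst(d2, "wc")
    expect_lte(th2[1, 2], 0)
    expect_lt(abs(th2[1, 2]), 1 / (n_ind - 1))
  }
})

test_that("pairwise and per-locus WC theta match the 1984 per-term oracle", {
  # pooled 2-pop, 1-locus count example: 8/8 vs 4/8 derived of 8 chromosomes
  cnt1 <- matrix(c(0L, 4L), 2, 1, dimnames = list(c("a", "b"), "l1"))
  cnt0 <- matrix(c(8L, 4L), 2, 1, dimnames = list(c("a", "b"), "l1"))
  pool <- structure(list(counts = list(`0` = cnt0, `1` = cnt1),
                         tot = cnt0 + cnt1, alleles = c(0L, 1L),
                         pop_ids = c("a", "b"), loci = "l1", type = "snp"),
                    class = "pool_dataset")
  th <- pairwise_fst(pool, "wc")
  expect_equal(unname(th[1, 2]),
               oracle_wc_theta_counts(c(8, 4), c(8, 8)), tolerance = 1e-12)

  for (seed in 1:10) {
    d <- random_dataset(seed + 50, n_pops = 4, n_ind = 5, n_loci = 15,
                        miss = 0.1)
    th <- pairwise_fst(d, "wc")
    expect_true(isSymmetric(th))
    o12 <- oracle_wc_theta(d, c("pop1", "pop2"))$theta
    expect_equal(unname(th["pop1", "pop2"]), o12, tolerance = 1e-10)
    scan <- locus_fst_scan(d)
    o <- oracle_wc_theta(d)
    expect_equal(unname(scan$theta), o$per_locus, tolerance = 1e-10)
    expect_equal(scan$global, o$theta, tolerance = 1e-10)
  }
})

test_that("Nei pairwise FST equals the pair-restricted basic_stats ratio", {
  d <- random_dataset(31, n_pops = 3, n_ind = 5, n_loci = 12, miss = 0.1)
  th <- pairwise_fst(d, "nei")
  sub <- popsampling:::subset_pops(d, c("pop1", "pop3"))
  s <- basic_stats(sub)
  expect_equal(unname(th["pop1", "pop3"]), s$fst_ratio, tolerance = 1e-10)
  expect_equal(diag(th), c(pop1 = 0, pop2 = 0, pop3 = 0))
})

test_that("statistics survive a VCF round trip unchanged", {
  d <- random_dataset(77, n_pops = 3, n_ind = 5, n_loci = 10, miss = 0.1)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(d, path)
  d2 <- load_genotypes(path, "vcf")
  s1 <- basic_stats(d)
  s2 <- basic_stats(d2)
  expect_equal(s2$hs, s1$hs, tolerance = 1e-12)
  expect_equal(s2$fst_ratio, s1$fst_ratio, tolerance = 1e-12)
})

test_that("FIS/NaN correlation: construction, degeneracy and errors", {
  tab <- data.frame(mean_fis = -(1:10), nan_fis = 1:10)
  r <- fis_nan_correlation(tab)
  expect_equal(r$estimate, -1)

  const <- data.frame(mean_fis = rnorm(5), nan_fis = rep(2, 5))
  rc <- fis_nan_correlation(const)
  expect_true(is.na(rc$estimate))
  expect_match(rc$status, "zero variance")

  expect_error(fis_nan_correlation(data.frame(mean_fis = 1:2, nan_fis = 1:2)),
               "three replicates")
  expect_error(fis_nan_correlation(data.frame(a = 1)), "columns")
})
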