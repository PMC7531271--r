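# Naive per-term reference implementations, written directly from the
# textbook formulas with explicit loops. They deliberately share no code
# with the package internals.

# Nei (1987) / Nei & Chesser (1983) statistics, one locus and population at
# a time. Works for any integer allele coding; `NA` alleles are missing.
oracle_basic_stats <- function(dataset) {
  pops <- levels(dataset$pop)
  L <- length(dataset$loci)
  P <- length(pops)
  ho <- hs <- fis <- n <- matrix(NA_real_, P, L, dimnames = list(pops, dataset$loci))
  freqs <- vector("list", L)
  for (l in seq_len(L)) {
    freqs[[l]] <- list()
    for (p in seq_len(P)) {
      rows <- which(dataset$pop == pops[p])
      a1 <- dataset$a1[rows, l]; a2 <- dataset$a2[rows, l]
      keep <- !is.na(a1) & !is.na(a2)
      a1 <- a1[keep]; a2 <- a2[keep]
      nn <- length(a1)
      n[p, l] <- nn
      if (nn == 0) next
      alleles <- c(a1, a2)
      tab <- table(alleles) / (2 * nn)
      freqs[[l]][[p]] <- tab
      ho_pl <- sum(a1 != a2) / nn
      ho[p, l] <- ho_pl
      if (nn >= 2) {
        hs[p, l] <- nn / (nn - 1) * (1 - sum(tab^2) - ho_pl / (2 * nn))
        if (hs[p, l] != 0) fis[p, l] <- 1 - ho_pl / hs[p, l]
      }
    }
  }
  ht <- fst <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    with_data <- which(n[, l] > 0)
    s <- length(with_data)
    if (s < 2) next
    all_alleles <- sort(unique(unlist(lapply(freqs[[l]][with_data], names))))
    pbar <- sapply(all_alleles, function(a) {
      mean(sapply(with_data, function(p) {
        f <- freqs[[l]][[p]]
        if (a %in% names(f)) f[[a]] else 0
      }))
    })
    nh <- s / sum(1 / n[with_data, l])
    hs_def <- hs[with_data, l]
    if (all(is.na(hs_def))) next
    hs_bar <- mean(hs_def[!is.na(hs_def)])
    ho_def <- ho[with_data, l]; ho_bar <- mean(ho_def[!is.na(ho_def)])
    ht[l] <- 1 - sum(pbar^2) + hs_bar / (nh * s) - ho_bar / (2 * nh * s)
    fst[l] <- (ht[l] - hs_bar) / ht[l]
  }
  hsbar_loc <- sapply(seq_len(L), function(l) {
    v <- hs[n[, l] > 0, l]; v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  list(ho = ho, hs = hs, fis = fis, n = n, ht = ht, fst_locus = fst,
       fst_ratio = sum(ht - hsbar_loc, na.rm = TRUE) / sum(ht, na.rm = TRUE))
}

# Weir & Cockerham (1984) theta for biallelic genotype data over a set of
# populations, per-term per-locus, multilocus ratio of sums.
oracle_wc_theta <- function(dataset, pops = levels(dataset$pop)) {
  num <- den <- 0
  per_locus <- rep(NA_real_, length(dataset$loci))
  for (l in seq_along(dataset$loci)) {
    ni <- pi <- hi <- c()
    for (p in pops) {
      rows <- which(dataset$pop == p)
      a1 <- dataset$a1[rows, l]; a2 <- dataset$a2[rows, l]
      keep <- !is.na(a1) & !is.na(a2)
      a1 <- a1[keep]; a2 <- a2[keep]
      if (!length(a1)) next
      ni <- c(ni, length(a1))
      pi <- c(pi, mean(c(a1, a2) == 1))
      hi <- c(hi, mean(a1 != a2))
    }
    r <- length(ni)
    if (r < 2) next
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    # both alleles contribute symmetric components for a biallelic locus
    num <- num + 2 * a
    den <- den + 2 * (a + b + cc)
    if (a + b + cc != 0) per_locus[l] <- a / (a + b + cc)
  }
  list(theta = if (den != 0) num / den else NA_real_, per_locus = per_locus)
}

# haploid (allele-count) analogue, one locus, from counts of the derived
# allele `cnt` out of `tot` haploid copies per population
oracle_wc_theta_counts <- function(cnt, tot) {
  keep <- tot > 0
  cnt <- cnt[keep]; tot <- tot[keep]
  r <- length(tot)
  p <- cnt / tot
  tt <- sum(tot)
  pw <- sum(tot * p) / tt
  msp <- sum(tot * (p - pw)^2) / (r - 1)
  msg <- sum(tot * p * (1 - p)) / sum(tot - 1)
  nc <- (tt - sum(tot^2) / tt) / (r - 1)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# plain eigen-decomposition PC1 (correlation matrix), sign fixed like the
# package's convention
oracle_pc1 <- function(x) {
  x <- scale(as.matrix(x))
  ev <- eigen(stats::cov(x))
  v <- ev$vectors[, 1]
  v <- v * sign(v[which.max(abs(v))])
  drop(x %*% v)
}

oracle_ols <- function(y, X) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}
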