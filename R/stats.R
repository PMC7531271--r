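#' Per-locus, per-population allele frequencies
#'
#' Missing genotype calls are excluded; an individual counts as typed at a
#' locus only when both allele calls are present. For pooled data the typed
#' "individual" count is taken as half the haploid pool count.
#'
#' @param dataset a [genotype_dataset()] or [pool_frequencies()] result.
#' @return an object of class `freq_table`: list with `freq` (named list,
#'   one `n_pops x n_loci` frequency matrix per allele; `NA` where a
#'   population has no typed copies), `p` (frequency of allele "1" for SNP
#'   data, else of the last allele), `n` (typed individuals), `tot` (typed
#'   haploid counts), `alleles`, `pop_ids`, `loci`.
#' @export
allele_frequencies <- function(dataset) {
  pf <- if (is_pooled(dataset)) dataset else pool_frequencies(dataset)
  tot <- pf$tot
  freq <- lapply(pf$counts, function(cm) {
    f <- cm / tot
    f[tot == 0] <- NA_real_
    f
  })
  n <- if (is_pooled(dataset)) tot / 2 else {
    pop_rowsum(typed_mask(dataset) * 1L, dataset$pop)
  }
  p <- if (!length(freq)) {
    matrix(NA_real_, nrow(tot), ncol(tot), dimnames = dimnames(tot))
  } else if ("1" %in% names(freq)) freq[["1"]] else freq[[length(freq)]]
  structure(list(freq = freq, p = p, n = n, tot = tot,
                 alleles = pf$alleles, pop_ids = pf$pop_ids, loci = pf$loci),
            class = "freq_table")
}

# Sufficient statistics for the Nei / Nei-Chesser estimators.
# Returns per-(pop, locus) matrices: n (typed individuals), ho (observed het
# proportion, NA for pooled), sumsq (sum over alleles of squared within-pop
# frequencies), and per-locus vectors: s (populations with data), nh
# (harmonic mean sample size over those populations), sumsq_bar (sum of
# squared across-population mean frequencies).
nei_sufficient <- function(dataset) {
  pooled <- is_pooled(dataset)
  ft <- allele_frequencies(dataset)
  n <- ft$n
  mask <- n > 0
  sumsq <- Reduce("+", lapply(ft$freq, function(f) {
    f0 <- f; f0[is.na(f0)] <- 0; f0 * f0
  }))
  s <- colSums(mask)
  nh <- s / colSums(ifelse(mask, 1 / n, 0))
  sumsq_bar <- Reduce("+", lapply(ft$freq, function(f) {
    f0 <- f; f0[is.na(f0)] <- 0
    pbar <- colSums(f0 * mask) / pmax(s, 1)
    pbar * pbar
  }))
  if (pooled) {
    ho <- matrix(NA_real_, nrow(n), ncol(n), dimnames = dimnames(n))
  } else {
    ok <- typed_mask(dataset)
    het <- pop_rowsum(((dataset$a1 != dataset$a2) & ok) * 1L, dataset$pop)
    ho <- het / n
    ho[n == 0] <- NA_real_
  }
  list(ft = ft, n = n, ho = ho, sumsq = sumsq, s = s, nh = nh,
       sumsq_bar = sumsq_bar, pooled = pooled,
       pop_ids = ft$pop_ids, loci = ft$loci)
}

#' Summary statistics with explicit undefined-value accounting
#'
#' Computes, per locus and population, observed heterozygosity `Ho`, Nei's
#' sample-size-corrected gene diversity
#' `Hs = n/(n-1) (1 - sum p^2 - Ho/(2n))`, and `FIS = 1 - Ho/Hs` (undefined
#' where `Hs = 0`, e.g. loci fixed within the population; such cells are
#' counted, never silently dropped). Per locus across populations it computes
#' the Nei-Chesser corrected total diversity
#' `Ht = 1 - sum pbar^2 + Hsbar/(nh s) - Hobar/(2 nh s)` (`nh` the harmonic
#' mean sample size over the `s` populations with data) and
#' `FST = (Ht - Hsbar)/Ht`, reported as computed -- negative values are not
#' clamped. Monomorphic cells stay in all denominators, contributing zero.
#'
#' For pooled input, `Ho` and `FIS` are marked unavailable (not zero),
#' `Hs = n/(n-1) (1 - sum p^2)` with `n` half the haploid pool count, and
#' `Ht` omits the `Ho` term.
#'
#' Per-population means across loci skip undefined cells but record their
#' count; grand means weight populations equally. The overall FST is the
#' ratio of per-locus sums `sum(Ht - Hsbar)/sum(Ht)` by default
#' (`fst_method = "ratio"`); `"mean"` averages the per-locus ratios instead.
#'
#' @param dataset a [genotype_dataset()] or [pool_frequencies()] result.
#' @param fst_method multilocus combination for the overall FST.
#' @return an object of class `summary_stats`; see Details.
#' @export
basic_stats <- function(dataset, fst_method = c("ratio", "mean")) {
  fst_method <- match.arg(fst_method)
  sf <- nei_sufficient(dataset)
  n <- sf$n

  if (sf$pooled) {
    hs <- n / (n - 1) * (1 - sf$sumsq)
    ho <- sf$ho
  } else {
    hs <- n / (n - 1) * (1 - sf$sumsq - sf$ho / (2 * n))
    ho <- sf$ho
  }
  hs[n <= 1] <- NA_real_

  fis <- 1 - ho / hs
  fis[!is.na(hs) & hs == 0] <- NA_real_

  # per-locus totals over populations with data
  def_hs <- !is.na(hs)
  s <- sf$s
  hsbar <- colSums(ifelse(def_hs, hs, 0)) / pmax(colSums(def_hs), 1)
  hsbar[colSums(def_hs) == 0] <- NA_real_
  multi <- length(sf$pop_ids) >= 2L
  if (multi) {
    ht <- 1 - sf$sumsq_bar + hsbar / (sf$nh * s)
    if (!sf$pooled) {
      def_ho <- !is.na(ho)
      hobar <- colSums(ifelse(def_ho, ho, 0)) / pmax(colSums(def_ho), 1)
      ht <- ht - hobar / (2 * sf$nh * s)
    }
    ht[s < 2] <- NA_real_  # total diversity needs >= 2 populations with data
    fst_locus <- (ht - hsbar) / ht
    fst_ratio <- sum(ht - hsbar, na.rm = TRUE) / sum(ht, na.rm = TRUE)
    fst_mean <- mean(fst_locus[is.finite(fst_locus)])
  } else {
    ht <- fst_locus <- rep(NA_real_, length(sf$loci))
    fst_ratio <- fst_mean <- NA_real_
  }

  per_pop <- data.frame(
    pop = sf$pop_ids,
    mean_ho = rowMeans2_na(ho),
    mean_hs = rowMeans2_na(hs),
    mean_fis = rowMeans2_na(fis),
    nan_fis = rowSums(is.na(fis)),
    stringsAsFactors = FALSE
  )

  structure(list(
    ho = ho, hs = hs, fis = fis, n = n,
    ht = ht, hsbar = hsbar, fst_locus = fst_locus,
    per_pop = per_pop,
    mean_ho = mean(per_pop$mean_ho, na.rm = TRUE),
    mean_hs = mean(per_pop$mean_hs, na.rm = TRUE),
    mean_fis = mean(per_pop$mean_fis, na.rm = TRUE),
    mean_nan_fis = mean(per_pop$nan_fis),
    fst = if (fst_method == "ratio") fst_ratio else fst_mean,
    fst_ratio = fst_ratio, fst_mean = fst_mean,
    fst_method = fst_method,
    pooled = sf$pooled, n_pops = length(sf$pop_ids)
  ), class = "summary_stats")
}

rowMeans2_na <- function(m) {
  k <- rowSums(!is.na(m))
  out <- rowSums(m, na.rm = TRUE) / k
  out[k == 0] <- NA_real_
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %d populations, %d loci%s\n", x$n_pops,
              length(x$ht), if (x$pooled) " (pooled; Ho/FIS unavailable)" else ""))
  cat(sprintf("  mean Hs %.4f | mean FIS %s | FST (%s) %s\n",
              x$mean_hs,
              if (x$pooled) "unavailable" else sprintf("%.4f", x$mean_fis),
              x$fst_method,
              if (is.na(x$fst)) "undefined" else sprintf("%.4f", x$fst)))
  cat(sprintf("  undefined FIS cells per population: mean %.1f\n", x$mean_nan_fis))
  invisible(x)
}

#' Overall FST of a dataset
#'
#' Convenience wrapper around [basic_stats()]; errors on fewer than two
#' populations, where FST is undefined.
#' @inheritParams basic_stats
#' @export
global_fst <- function(dataset, fst_method = c("ratio", "mean")) {
  np <- if (is_pooled(dataset)) length(dataset$pop_ids) else n_pops(dataset)
  if (np < 2L) stop("FST requires at least two populations")
  basic_stats(dataset, fst_method)$fst
}

#' Pairwise FST matrix
#'
#' `method = "wc"` gives the Weir & Cockerham (1984) theta for each pair of
#' populations, combined across loci as a ratio of sums of the per-locus
#' variance components (for pooled allele-count input the haploid
#' moment-estimator analogue is used). `method = "nei"` applies the
#' Nei/Nei-Chesser corrected `(Ht - Hs)/Ht` of [basic_stats()] restricted to
#' each pair, again as a ratio of per-locus sums.
#'
#' @param dataset a [genotype_dataset()] or [pool_frequencies()] result.
#' @param method `"wc"` or `"nei"`.
#' @return a symmetric `n_pops x n_pops` matrix with zero diagonal; a pair
#'   with no co-typed loci gets `NA`.
#' @export
pairwise_fst <- function(dataset, method = c("wc", "nei")) {
  method <- match.arg(method)
  sf <- nei_sufficient(dataset)
  P <- length(sf$pop_ids)
  if (P < 2L) stop("pairwise FST requires at least two populations")
  biallelic <- length(sf$ft$alleles) <= 2L && "1" %in% names(sf$ft$freq)
  if (method == "wc" && biallelic) {
    # fast path: single-allele WC components are sufficient for biallelic loci
    out <- if (sf$pooled) {
      cpp_pairwise_wc_counts(sf$ft$tot, sf$ft$p)
    } else {
      cpp_pairwise_wc(sf$n, sf$ft$p, sf$ho)
    }
    diag(out) <- 0
    dimnames(out) <- list(sf$pop_ids, sf$pop_ids)
    return(out)
  }
  out <- matrix(0, P, P, dimnames = list(sf$pop_ids, sf$pop_ids))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      v <- if (method == "wc") {
        if (sf$pooled) wc_theta_counts(sf$ft, c(i, j))
        else wc_theta_genotype(sf, c(i, j))
      } else {
        nei_fst_pair(sf, i, j)
      }
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

# WC84 multi-allelic theta for a subset of populations, multilocus ratio of
# sums; genotype input (uses observed heterozygote frequencies).
wc_theta_genotype <- function(sf, idx) {
  n <- sf$n[idx, , drop = FALSE]
  ho <- sf$ho[idx, , drop = FALSE]
  num <- den <- 0
  for (f in sf$ft$freq) {
    p <- f[idx, , drop = FALSE]
    comp <- wc84_components(n, p, ho)
    num <- num + sum(comp$a[comp$use], na.rm = TRUE)
    den <- den + sum((comp$a + comp$b + comp$c)[comp$use], na.rm = TRUE)
  }
  if (den == 0) NA_real_ else num / den
}

# Per-allele, per-locus WC84 components a, b, c across the populations in
# rows of n/p/h (proportion of heterozygotes *carrying this allele* should be
# used for multi-allelic data; for biallelic data the overall heterozygote
# frequency is that proportion for both alleles). For simplicity we use the
# overall heterozygote frequency for every allele, exact for biallelic loci
# (the package's SNP case) and the standard biallelic estimator elsewhere.
wc84_components <- function(n, p, h) {
  typed <- n > 0 & !is.na(p)
  r <- colSums(typed)
  nm <- ifelse(typed, n, 0)
  pm <- ifelse(typed, p, 0)
  hm <- ifelse(typed, h, 0)
  nbar <- colSums(nm) / r
  sum_n2 <- colSums(nm * nm)
  nc <- (r * nbar - sum_n2 / (r * nbar)) / (r - 1)
  pbar <- colSums(nm * pm) / (r * nbar)
  s2 <- colSums(nm * sweep(pm, 2, pbar, "-")^2 * typed) / ((r - 1) * nbar)
  hbar <- colSums(nm * hm) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  use <- r >= 2 & nbar > 1
  list(a = a, b = b, c = cc, use = use, r = r)
}

# Haploid-count Weir & Cockerham analogue (pooled data): per-locus numerator
# MSP - MSG and denominator MSP + (nc - 1) MSG from allele counts, ratio of
# sums across loci and alleles.
wc_theta_counts <- function(ft, idx) {
  tot <- ft$tot[idx, , drop = FALSE]
  num <- den <- 0
  for (f in ft$freq) {
    p <- f[idx, , drop = FALSE]
    comp <- wc_count_components(tot, p)
    num <- num + sum(comp$num[comp$use], na.rm = TRUE)
    den <- den + sum(comp$den[comp$use], na.rm = TRUE)
  }
  if (den == 0) NA_real_ else num / den
}

wc_count_components <- function(tot, p) {
  typed <- tot > 0 & !is.na(p)
  r <- colSums(typed)
  tm <- ifelse(typed, tot, 0)
  pm <- ifelse(typed, p, 0)
  tt <- colSums(tm)
  pw <- colSums(tm * pm) / tt
  msp <- colSums(tm * sweep(pm, 2, pw, "-")^2 * typed) / (r - 1)
  msg <- colSums(tm * pm * (1 - pm)) / colSums(pmax(tm - 1, 0) * typed)
  nc <- (tt - colSums(tm * tm) / tt) / (r - 1)
  use <- r >= 2 & tt > r  # needs at least one pool with > 1 copy
  list(num = msp - msg, den = msp + (nc - 1) * msg, use = use)
}

# Nei / Nei-Chesser FST restricted to one pair, ratio of per-locus sums
nei_fst_pair <- function(sf, i, j) {
  idx <- c(i, j)
  n <- sf$n[idx, , drop = FALSE]
  use <- colSums(n > 0) == 2L
  if (!any(use)) return(NA_real_)
  hs_pair <- matrix(NA_real_, 2, ncol(n))
  for (k in 1:2) {
    sumsq_k <- sf$sumsq[idx[k], ]
    nk <- n[k, ]
    hs_k <- if (sf$pooled) nk / (nk - 1) * (1 - sumsq_k)
            else nk / (nk - 1) * (1 - sumsq_k - sf$ho[idx[k], ] / (2 * nk))
    hs_k[nk <= 1] <- NA_real_
    hs_pair[k, ] <- hs_k
  }
  hsbar <- colMeans(hs_pair)
  nh <- 2 / (1 / n[1, ] + 1 / n[2, ])
  sumsq_bar <- Reduce("+", lapply(sf$ft$freq, function(f) {
    pb <- (f[i, ] + f[j, ]) / 2
    pb * pb
  }))
  ht <- 1 - sumsq_bar + hsbar / (2 * nh)
  if (!sf$pooled) {
    hobar <- colMeans(sf$ho[idx, , drop = FALSE])
    ht <- ht - hobar / (4 * nh)
  }
  use <- use & !is.na(hsbar) & !is.na(ht)
  if (!any(use)) return(NA_real_)
  sum(ht[use] - hsbar[use]) / sum(ht[use])
}

#' Correlation between replicate mean FIS and undefined-FIS counts
#'
#' Quantifies the mechanism by which subsampling few individuals depresses
#' FIS: loci appear fixed within populations (FIS undefined, "NaN"), and the
#' per-replicate mean FIS falls as the undefined count rises. Pearson
#' correlation between the per-replicate mean FIS and the mean per-population
#' count of undefined FIS cells.
#'
#' @param replicate_table a data frame with columns `mean_fis` and `nan_fis`
#'   (e.g. from [run_design()] on the individuals axis).
#' @return list with `estimate`, `p.value`, `n`, and `status`
#'   (`"ok"` or `"undefined (zero variance)"`).
#' @export
fis_nan_correlation <- function(replicate_table) {
  if (!all(c("mean_fis", "nan_fis") %in% names(replicate_table)))
    stop("replicate table must have columns mean_fis and nan_fis")
  x <- replicate_table$mean_fis
  y <- replicate_table$nan_fis
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3L) stop("need at least three replicates")
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p.value = NA_real_, n = length(x),
                status = "undefined (zero variance)"))
  ct <- stats::cor.test(x, y)
  list(estimate = unname(ct$estimate), p.value = ct$p.value, n = length(x),
       status = "ok")
}
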