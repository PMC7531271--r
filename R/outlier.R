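#' Per-locus FST scan
#'
#' Per-locus Weir-Cockerham theta across all populations plus the multilocus
#' global theta (ratio of sums of the per-locus variance components).
#' Genotype data use the full WC84 estimator; pooled data the haploid
#' allele-count analogue. Loci monomorphic (or untyped in fewer than two
#' populations) in the data at hand get `NA` and are excluded from the
#' maximum.
#'
#' @param dataset a [genotype_dataset()] or [pool_frequencies()] result.
#' @return list of class `fst_scan`: `theta` (named per-locus vector),
#'   `global`, `max` (largest defined per-locus theta), `max_locus`.
#' @export
locus_fst_scan <- function(dataset) {
  sf <- nei_sufficient(dataset)
  if (length(sf$pop_ids) < 2L) stop("FST requires at least two populations")
  num <- den <- 0
  if (sf$pooled) {
    for (f in sf$ft$freq) {
      comp <- wc_count_components(sf$ft$tot, f)
      num <- num + ifelse(comp$use, comp$num, 0)
      den <- den + ifelse(comp$use, comp$den, 0)
    }
  } else {
    for (f in sf$ft$freq) {
      comp <- wc84_components(sf$n, f, sf$ho)
      num <- num + ifelse(comp$use, comp$a, 0)
      den <- den + ifelse(comp$use, comp$a + comp$b + comp$c, 0)
    }
  }
  theta <- num / den
  theta[den == 0] <- NA_real_
  # a locus monomorphic in the subsample has zero variance components
  mono <- apply_mono_mask(sf)
  theta[mono] <- NA_real_
  names(theta) <- sf$loci
  gl <- sum(num[!mono], na.rm = TRUE) / sum(den[!mono], na.rm = TRUE)
  ok <- which(is.finite(theta))
  structure(list(theta = theta, global = gl,
                 max = if (length(ok)) max(theta[ok]) else NA_real_,
                 max_locus = if (length(ok)) sf$loci[ok[which.max(theta[ok])]]
                             else NA_character_),
            class = "fst_scan")
}

# loci with a single allele across the pooled sample at hand
apply_mono_mask <- function(sf) {
  present <- lapply(sf$ft$freq, function(f) colSums(f > 0, na.rm = TRUE) > 0)
  Reduce("+", present) < 2
}

#' Parametric FST outlier test
#'
#' For each locus, differentiation is measured by the allele-count
#' Weir-Cockerham theta. The null distribution is parametric: given the
#' locus's pooled allele frequency `pbar` and the multilocus global theta,
#' population frequencies are drawn from
#' `Beta(pbar (1 - theta)/theta, (1 - pbar)(1 - theta)/theta)` (the
#' beta-approximation to the migration-drift equilibrium implied by the
#' genome-wide differentiation), allele counts re-drawn binomially at the
#' observed per-population sample sizes, and the locus theta recomputed.
#' `p = (1 + #{theta_null >= theta_obs}) / (n_null + 1)` (upper tail,
#' observed counted, so the smallest attainable p is `1/(n_null + 1)`);
#' q-values by Benjamini-Hochberg across tested loci.
#'
#' @param dataset a [genotype_dataset()] or [pool_frequencies()] result.
#' @param n_null null replicates per locus.
#' @param seed integer seed.
#' @return list of class `outlier_test`: data frame `table` (locus,
#'   theta, p, q), `global_theta`, `status` (`"ok"`, or `"skipped"` when the
#'   global theta is not in (0, 1), in which case p/q are NA).
#' @export
fst_outlier_test <- function(dataset, n_null = 10000L, seed = 1L) {
  sf <- nei_sufficient(dataset)
  ft <- sf$ft
  if (length(ft$alleles) > 2L)
    stop("the outlier test supports biallelic (SNP) data only")
  tot <- ft$tot                  # P x L haploid counts
  p <- ft$p                      # P x L derived-allele frequency
  obs <- theta_counts_vec(tot, p)
  gl <- obs$global
  L <- length(sf$loci)
  if (!is.finite(gl) || gl <= 0 || gl >= 1) {
    tab <- data.frame(locus = sf$loci, theta = obs$theta,
                      p = NA_real_, q = NA_real_)
    return(structure(list(table = tab, global_theta = gl,
                          status = "skipped (global theta outside (0,1))"),
                     class = "outlier_test"))
  }
  set.seed(as.integer(seed))
  pbar <- colSums(ifelse(tot > 0, tot * p, 0)) / colSums(tot)
  al <- pbar * (1 - gl) / gl
  be <- (1 - pbar) * (1 - gl) / gl
  P <- nrow(tot)
  R <- as.integer(n_null)
  # accumulate per-(locus, replicate) sufficient sums across populations
  s_t <- s_tp <- s_tp2 <- s_tpq <- s_t2 <- s_tm1 <- s_r <- 0
  for (pp in seq_len(P)) {
    tv <- tot[pp, ]                      # length L sample sizes
    q <- matrix(stats::rbeta(L * R, al, be), L, R)
    cnt <- matrix(stats::rbinom(L * R, tv, q), L, R)
    ph <- cnt / tv
    ph[tv == 0, ] <- 0
    typed <- as.numeric(tv > 0)
    s_t <- s_t + tv * typed
    s_t2 <- s_t2 + tv^2 * typed
    s_tm1 <- s_tm1 + pmax(tv - 1, 0) * typed
    s_r <- s_r + typed
    s_tp <- s_tp + tv * ph
    s_tp2 <- s_tp2 + tv * ph^2
    s_tpq <- s_tpq + tv * ph * (1 - ph)
  }
  # msp = [sum t p^2 - (sum t p)^2 / T] / (r - 1); msg = sum t p q / sum(t-1)
  pw2 <- s_tp^2 / s_t
  msp <- (s_tp2 - pw2) / (s_r - 1)
  msg <- s_tpq / s_tm1
  nc <- (s_t - s_t2 / s_t) / (s_r - 1)
  tnull <- (msp - msg) / (msp + (nc - 1) * msg)
  tnull[!is.finite(tnull)] <- 0        # monomorphic null draws carry no signal
  exceed <- rowSums(tnull >= obs$theta - 1e-12)
  pval <- (1 + exceed) / (R + 1)
  pval[!is.finite(obs$theta)] <- NA_real_
  qval <- stats::p.adjust(pval, "BH")
  tab <- data.frame(locus = sf$loci, theta = obs$theta, p = pval, q = qval)
  structure(list(table = tab, global_theta = gl, status = "ok"),
            class = "outlier_test")
}

# vectorized biallelic allele-count theta per locus + global (ratio of sums)
theta_counts_vec <- function(tot, p) {
  comp <- wc_count_components(tot, p)
  theta <- ifelse(comp$use, comp$num / comp$den, NA_real_)
  theta[comp$use & comp$den == 0] <- NA_real_
  pw <- colSums(ifelse(tot > 0, tot * p, 0)) / colSums(tot)
  mono <- !is.finite(pw) | pw <= 0 | pw >= 1
  theta[mono] <- NA_real_
  gl <- sum(comp$num[comp$use & !mono], na.rm = TRUE) /
    sum(comp$den[comp$use & !mono], na.rm = TRUE)
  list(theta = theta, global = gl)
}

#' Environmental-association outlier test
#'
#' Per-locus statistic: absolute Pearson correlation between population
#' derived-allele frequencies and an environmental value (typically the PC1
#' score). The null is generated by permuting the environmental vector over
#' populations, with the same permutations reused across loci;
#' `p = (1 + #{|r_null| >= |r_obs|}) / (n_permutations + 1)` and q-values by
#' Benjamini-Hochberg.
#'
#' @param freq_table an [allele_frequencies()] result (or a dataset, which
#'   is converted).
#' @param env per-population environmental values in `pop_ids` order.
#' @param n_permutations number of permutations.
#' @param seed integer seed.
#' @return list of class `outlier_test` with `table` (locus, r, p, q).
#' @export
env_association_test <- function(freq_table, env, n_permutations = 1000L,
                                 seed = 1L) {
  if (!inherits(freq_table, "freq_table"))
    freq_table <- allele_frequencies(freq_table)
  P <- length(freq_table$pop_ids)
  if (length(env) != P) stop("need one environmental value per population")
  if (stats::sd(env) == 0) stop("environmental variable is constant")
  X <- freq_table$p                      # P x L derived-allele frequencies
  robs <- abs(suppressWarnings(
    stats::cor(X, env, use = "pairwise.complete.obs")))[, 1]
  set.seed(as.integer(seed))
  R <- as.integer(n_permutations)
  perms <- replicate(R, sample.int(P))
  if (!anyNA(X)) {
    Z <- scale(X)                        # standardize loci columns
    Z[is.nan(Z)] <- 0                    # monomorphic: zero correlation
    E <- scale(matrix(env[perms], P, R))
    rnull <- abs(crossprod(Z, E)) / (P - 1)   # L x R
    exceed <- rowSums(rnull >= robs - 1e-12)
  } else {
    exceed <- rep(0L, ncol(X))
    for (k in seq_len(R)) {
      rk <- abs(suppressWarnings(
        stats::cor(X, env[perms[, k]], use = "pairwise.complete.obs")))[, 1]
      exceed <- exceed + (rk >= robs - 1e-12)
    }
  }
  pval <- (1 + exceed) / (R + 1)
  pval[!is.finite(robs)] <- NA_real_
  qval <- stats::p.adjust(pval, "BH")
  tab <- data.frame(locus = freq_table$loci, r = as.numeric(robs),
                    p = pval, q = qval)
  structure(list(table = tab, status = "ok"), class = "outlier_test")
}

#' Two-stage outlier-SNP detection
#'
#' A locus is flagged as an outlier when it passes both the differentiation
#' test ([fst_outlier_test()]) and the environmental-association test
#' ([env_association_test()]) at `q < q_threshold` -- the conservative
#' intersection rule. The result also records the maximum per-locus FST and
#' the outlier count, the quantities tracked by the population-count
#' experiment.
#'
#' @param dataset a [genotype_dataset()] or [pool_frequencies()] result
#'   (biallelic SNPs).
#' @param env per-population environmental values.
#' @param q_threshold q-value threshold for both tests.
#' @param n_null null replicates for the differentiation test.
#' @param n_permutations permutations for the association test.
#' @param seed integer seed.
#' @return list of class `outlier_result`: `table` (locus, theta, p/q of
#'   both tests, flag), `outliers` (flagged locus ids), `n_outliers`,
#'   `max_fst`, `max_fst_locus`, `global_theta`, `q_threshold`.
#' @export
detect_outliers <- function(dataset, env, q_threshold = 0.05,
                            n_null = 10000L, n_permutations = 1000L,
                            seed = 1L) {
  scan <- locus_fst_scan(dataset)
  dif <- fst_outlier_test(dataset, n_null = n_null, seed = seed)
  assoc <- env_association_test(dataset, env, n_permutations = n_permutations,
                                seed = seed + 1L)
  flag <- !is.na(dif$table$q) & !is.na(assoc$table$q) &
    dif$table$q < q_threshold & assoc$table$q < q_threshold
  tab <- data.frame(locus = dif$table$locus,
                    theta = scan$theta,
                    diff_p = dif$table$p, diff_q = dif$table$q,
                    assoc_r = assoc$table$r,
                    assoc_p = assoc$table$p, assoc_q = assoc$table$q,
                    flag = flag)
  structure(list(table = tab, outliers = tab$locus[flag],
                 n_outliers = sum(flag),
                 max_fst = scan$max, max_fst_locus = scan$max_locus,
                 global_theta = scan$global,
                 q_threshold = q_threshold,
                 diff_status = dif$status),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("outlier detection: %d loci, %d flagged at q < %g\n",
              nrow(x$table), x$n_outliers, x$q_threshold))
  cat(sprintf("  global theta %.4f; max locus FST %.4f (%s)\n",
              x$global_theta, x$max_fst, x$max_fst_locus))
  invisible(x)
}

#' Population-count outlier-detection experiment
#'
#' For each population-sampling level and replicate: subsample populations
#' (a single locus subsample of `n_loci` loci is drawn once, shared across
#' all levels and replicates), run [detect_outliers()], and record the
#' maximum per-locus FST, the outlier count and the outlier locus ids. The
#' experiment summarizes, per level, the loci flagged in every replicate
#' (cross-replicate intersection) and the loci flagged in all replicates of
#' all levels.
#'
#' @param dataset a SNP [genotype_dataset()] (or pooled counts).
#' @param metadata population metadata with a `pc1` column (or `env_*`).
#' @param levels population counts to test; the string `"all"` (or a count
#'   equal to the number of populations) runs the full set.
#' @param reps replicates per level.
#' @param n_loci loci subsampled once for the whole experiment (capped at
#'   the available loci).
#' @param q_threshold,n_null,n_permutations passed to [detect_outliers()].
#' @param seed integer seed.
#' @return list of class `experiment_table`: data frame `table` (level,
#'   replicate, max_fst, n_outliers), `outlier_sets` (nested list of locus
#'   ids), `intersections` (per-level), `global_intersection`.
#' @export
population_count_experiment <- function(dataset, metadata,
                                        levels = c(5, 10, 20, 30, "all"),
                                        reps = 10L, n_loci = 10000L,
                                        q_threshold = 0.05,
                                        n_null = 10000L,
                                        n_permutations = 1000L,
                                        seed = 1L) {
  P <- if (is_pooled(dataset)) length(dataset$pop_ids) else n_pops(dataset)
  lev <- ifelse(levels == "all", P, suppressWarnings(as.integer(levels)))
  if (anyNA(lev) || any(lev < 2) || any(lev > P))
    stop("levels must be population counts <= ", P, " (or \"all\")")
  set.seed(as.integer(seed))
  L <- length(dataset$loci)
  if (n_loci < L) {
    keep <- sort(sample.int(L, n_loci))
    dataset <- subset_loci(dataset, keep)
  }
  pc1 <- metadata_pc1(metadata)
  rows <- list()
  outlier_sets <- stats::setNames(vector("list", length(lev)), as.character(lev))
  k <- 0L
  for (li in seq_along(lev)) {
    sets <- vector("list", reps)
    for (r in seq_len(reps)) {
      k <- k + 1L
      rs <- replicate_seed(seed, k)
      des <- sampling_design("populations", lev[li], n_replicates = 1L,
                             seed = rs)
      sub <- draw_subsample(dataset, metadata, des, rs)
      env <- pc1[match(pop_ids_of(sub$dataset), metadata$pop_id)]
      det <- detect_outliers(sub$dataset, env, q_threshold = q_threshold,
                             n_null = n_null,
                             n_permutations = n_permutations, seed = rs)
      sets[[r]] <- det$outliers
      rows[[k]] <- data.frame(level = lev[li], replicate = r,
                              max_fst = det$max_fst,
                              n_outliers = det$n_outliers,
                              pops = paste(sub$units, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
    outlier_sets[[li]] <- sets
  }
  inter <- lapply(outlier_sets, function(sets) Reduce(intersect, sets))
  global_inter <- Reduce(intersect, inter)
  structure(list(table = do.call(rbind, rows),
                 outlier_sets = outlier_sets,
                 intersections = inter,
                 global_intersection = global_inter,
                 levels = lev, reps = reps,
                 n_loci = length(dataset$loci), seed = seed),
            class = "experiment_table")
}

pop_ids_of <- function(x) if (is_pooled(x)) x$pop_ids else pop_ids(x)
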