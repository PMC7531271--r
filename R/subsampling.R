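#' Declare a subsampling design
#'
#' One axis and level of the replicated subsampling experiment:
#' `"loci"` (number of loci kept), `"individuals"` (individuals kept per
#' population), `"populations"` (populations kept), or `"tradeoff"` (a joint
#' `(individuals per population, populations)` pair, e.g. few individuals in
#' many populations versus many individuals in few populations).
#'
#' @param axis one of `"loci"`, `"individuals"`, `"populations"`,
#'   `"tradeoff"`.
#' @param level sampling level: a single count, or for `"tradeoff"` a
#'   length-2 vector `c(individuals, populations)`.
#' @param n_replicates number of independent replicates (each re-sampled
#'   randomly and without replacement).
#' @param seed design seed; replicate `i` uses the deterministic seed
#'   [replicate_seed()]`(seed, i)` so any single replicate can be reproduced
#'   in isolation.
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(axis = c("loci", "individuals", "populations",
                                     "tradeoff"),
                            level, n_replicates = 1000L, seed = 1L) {
  axis <- match.arg(axis)
  if (axis == "tradeoff") {
    if (length(level) != 2L)
      stop("tradeoff level must be c(individuals, populations)")
  } else if (length(level) != 1L) {
    stop("level must be a single count")
  }
  if (any(level < 1L)) stop("levels must be positive")
  if (n_replicates < 1L) stop("need at least one replicate")
  structure(list(axis = axis, level = as.integer(level),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sampling_design")
}

#' Deterministic per-replicate seed
#'
#' A fixed affine hash of the design seed and replicate index (mod 2^31 - 1),
#' so replicate `i` of a design is individually reproducible without
#' replaying the preceding replicates.
#'
#' @param seed design seed.
#' @param i replicate index.
#' @export
replicate_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807 + 1) %% 2147483647)
}

#' Draw one subsample of a dataset (and its metadata)
#'
#' Uniform sampling without replacement on the design's axis. The
#' populations (and tradeoff) axes subset the metadata consistently;
#' precomputed metadata columns (PC1 scores, centroid distances) are kept as
#' computed on the full data, mirroring how reduced field campaigns would
#' reuse range-wide environmental summaries.
#'
#' @param dataset a [genotype_dataset()].
#' @param metadata optional population metadata data frame.
#' @param design a [sampling_design()].
#' @param replicate_seed integer seed for this draw.
#' @return list with `dataset`, `metadata` (NULL if not supplied) and
#'   `units` (the sampled unit ids).
#' @export
draw_subsample <- function(dataset, metadata = NULL, design,
                           replicate_seed = 1L) {
  stopifnot(inherits(design, "sampling_design"))
  if (design$axis %in% c("individuals", "tradeoff") && is_pooled(dataset))
    stop("the individuals axis requires genotype (not pooled) data")
  set.seed(as.integer(replicate_seed))
  md <- metadata
  units <- NULL
  switch(design$axis,
    loci = {
      L <- length(dataset$loci)
      if (design$level > L) stop("level exceeds available loci")
      keep <- sort(sample.int(L, design$level))
      units <- dataset$loci[keep]
      dataset <- subset_loci(dataset, keep)
    },
    individuals = {
      dataset <- sample_individuals(dataset, design$level)
      units <- dataset$ind
    },
    populations = {
      P <- n_pops(dataset)
      if (design$level > P) stop("level exceeds available populations")
      keep <- sort(sample.int(P, design$level))
      units <- pop_ids(dataset)[keep]
      dataset <- subset_pops(dataset, units)
      if (!is.null(md)) md <- md[md$pop_id %in% units, , drop = FALSE]
    },
    tradeoff = {
      P <- n_pops(dataset)
      if (design$level[2] > P) stop("level exceeds available populations")
      keep <- sort(sample.int(P, design$level[2]))
      units <- pop_ids(dataset)[keep]
      dataset <- subset_pops(dataset, units)
      dataset <- sample_individuals(dataset, design$level[1])
      if (!is.null(md)) md <- md[md$pop_id %in% units, , drop = FALSE]
    })
  if (!is.null(md)) attr(md, "planar") <- attr(metadata, "planar")
  list(dataset = dataset, metadata = md, units = units)
}

subset_loci <- function(dataset, idx) {
  genotype_dataset(dataset$pop,
                   dataset$a1[, idx, drop = FALSE],
                   dataset$a2[, idx, drop = FALSE],
                   loci = dataset$loci[idx], ind = dataset$ind,
                   type = dataset$type)
}

subset_pops <- function(dataset, pops) {
  keep <- dataset$pop %in% pops
  genotype_dataset(factor(dataset$pop[keep], levels = pops),
                   dataset$a1[keep, , drop = FALSE],
                   dataset$a2[keep, , drop = FALSE],
                   loci = dataset$loci, ind = dataset$ind[keep],
                   type = dataset$type)
}

sample_individuals <- function(dataset, k) {
  counts <- table(dataset$pop)
  if (any(counts < k))
    stop("population(s) with fewer than ", k, " individuals: ",
         paste(names(counts)[counts < k], collapse = ", "))
  keep <- unlist(lapply(split(seq_along(dataset$pop), dataset$pop),
                        function(ix) sort(sample(ix, k))), use.names = FALSE)
  keep <- sort(keep)
  genotype_dataset(dataset$pop[keep],
                   dataset$a1[keep, , drop = FALSE],
                   dataset$a2[keep, , drop = FALSE],
                   loci = dataset$loci, ind = dataset$ind[keep],
                   type = dataset$type)
}

#' Relative error of a subsample statistic
#'
#' `(x_est - x_sim) / x_est`, the deviation of a subsample statistic `x_sim`
#' from the full-data reference `x_est`, relative to the reference:
#' underestimates give positive error, overestimates negative. Undefined
#' (NA) when the reference is zero or not finite.
#'
#' @param x_est reference ("real"-data) statistic.
#' @param x_sim subsample statistic.
#' @export
relative_error <- function(x_est, x_sim) {
  out <- (x_est - x_sim) / x_est
  out[!is.finite(x_est) | x_est == 0] <- NA_real_
  out
}

#' Run a replicated subsampling design
#'
#' Draws `design$n_replicates` independent subsamples and computes the
#' selected statistic suite on each. Statistics undefined in a replicate are
#' recorded as `NA`, never aborting the run. The landscape statistics (MRM
#' coefficients via pairwise Weir-Cockerham FST, central-abundance slopes)
#' require `metadata`; MRM coefficients are computed without permutation
#' tests (point estimates only), as the design summaries only use their
#' values and signs.
#'
#' @param dataset a [genotype_dataset()].
#' @param metadata optional population metadata (required for `"mrm"` /
#'   `"cah"` statistics).
#' @param design a [sampling_design()].
#' @param suite character subset of `c("hs", "fis", "fst", "nan", "mrm",
#'   "cah")`; `"nan"` records the mean per-population *fraction* of loci with
#'   undefined FIS (the raw counts of [basic_stats()] divided by the number
#'   of loci in the subsample).
#' @param fst_method passed to [basic_stats()].
#' @return a `replicate_table` data frame: one row per replicate with the
#'   replicate index, its seed, the statistics, and the sampled unit ids in
#'   `attr(, "units")`.
#' @export
run_design <- function(dataset, metadata = NULL, design,
                       suite = c("hs", "fis", "fst", "nan"),
                       fst_method = "ratio") {
  stopifnot(inherits(design, "sampling_design"))
  bad <- setdiff(suite, c("hs", "fis", "fst", "nan", "mrm", "cah"))
  if (length(bad)) stop("unknown statistics: ", paste(bad, collapse = ", "))
  if (any(c("mrm", "cah") %in% suite) && is.null(metadata))
    stop("mrm/cah statistics require metadata")
  if ("fis" %in% suite && is_pooled(dataset))
    stop("FIS is unavailable for pooled data")
  rows <- vector("list", design$n_replicates)
  units <- vector("list", design$n_replicates)
  for (i in seq_len(design$n_replicates)) {
    rs <- replicate_seed(design$seed, i)
    sub <- draw_subsample(dataset, metadata, design, rs)
    units[[i]] <- sub$units
    rows[[i]] <- c(replicate = i, seed = rs,
                   compute_suite(sub$dataset, sub$metadata, suite, fst_method))
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "units") <- units
  attr(out, "design") <- design
  class(out) <- c("replicate_table", class(out))
  out
}

# the per-replicate statistic suite; NA for anything that fails or is
# undefined on this subsample
compute_suite <- function(dataset, metadata, suite, fst_method = "ratio") {
  out <- c()
  ss <- NULL
  if (any(c("hs", "fis", "fst", "nan", "cah") %in% suite))
    ss <- try(basic_stats(dataset, fst_method), silent = TRUE)
  grab <- function(expr) {
    v <- try(expr, silent = TRUE)
    if (inherits(v, "try-error") || !length(v)) NA_real_ else as.numeric(v)
  }
  if ("hs" %in% suite) out["mean_hs"] <- grab(ss$mean_hs)
  if ("fis" %in% suite) out["mean_fis"] <- grab(ss$mean_fis)
  if ("fst" %in% suite) out["fst"] <- grab(ss$fst)
  # undefined-FIS cells as a per-locus rate, so that replicate tables are
  # comparable across levels of the loci axis
  if ("nan" %in% suite) out["nan_fis"] <- grab(ss$mean_nan_fis / ncol(ss$hs))
  if ("mrm" %in% suite) {
    v <- try({
      fstm <- pairwise_fst(dataset, "wc")
      dm <- distance_matrices(metadata, fstm)
      fit <- mrm(dm, n_permutations = 0L)
      fit$coefficients[c("geographic", "environmental")]
    }, silent = TRUE)
    if (inherits(v, "try-error")) v <- c(NA_real_, NA_real_)
    out["mrm_geo"] <- v[1]; out["mrm_env"] <- v[2]
  }
  if ("cah" %in% suite) {
    v <- try({
      hs_pop <- ss$per_pop$mean_hs[match(metadata$pop_id, ss$per_pop$pop)]
      c(cah_regression(hs_pop, metadata$dist_geo_centroid, "geographic")$slope,
        cah_regression(hs_pop, metadata$dist_niche_centroid, "niche")$slope)
    }, silent = TRUE)
    if (inherits(v, "try-error")) v <- c(NA_real_, NA_real_)
    out["cah_geo"] <- v[1]; out["cah_niche"] <- v[2]
  }
  out
}

#' Summarize a replicate table against full-data reference statistics
#'
#' For each statistic: distribution summaries across replicates, the
#' relative error of the replicate mean, the mean of per-replicate relative
#' errors (both are reported since they answer slightly different
#' questions), the count of undefined replicates, and -- for association
#' statistics (`mrm_*`, `cah_*`) -- the sign-flip proportion: the fraction
#' of replicates whose coefficient has sign opposite to the reference.
#'
#' @param table a [run_design()] result.
#' @param reference named numeric vector (or list) of full-data statistics
#'   covering every statistic column in `table`.
#' @return a `design_summary` data frame, one row per statistic.
#' @export
summarize_replicates <- function(table, reference) {
  stat_cols <- setdiff(names(table), c("replicate", "seed"))
  reference <- unlist(reference)
  missing_ref <- setdiff(stat_cols, names(reference))
  if (length(missing_ref))
    stop("statistic absent from reference: ", paste(missing_ref, collapse = ", "))
  assoc <- grepl("^(mrm|cah)_", stat_cols)
  rows <- lapply(seq_along(stat_cols), function(k) {
    s <- stat_cols[k]
    x <- table[[s]]
    ref <- reference[[s]]
    ok <- is.finite(x)
    q <- if (any(ok)) stats::quantile(x[ok], c(0.025, 0.5, 0.975)) else rep(NA_real_, 3)
    per_rep_err <- relative_error(ref, x[ok])
    data.frame(
      statistic = s,
      reference = ref,
      mean = if (any(ok)) mean(x[ok]) else NA_real_,
      sd = if (sum(ok) > 1) stats::sd(x[ok]) else NA_real_,
      min = if (any(ok)) min(x[ok]) else NA_real_,
      max = if (any(ok)) max(x[ok]) else NA_real_,
      q025 = q[[1]], median = q[[2]], q975 = q[[3]],
      n_undefined = sum(!ok),
      rel_error_of_mean = if (any(ok)) relative_error(ref, mean(x[ok])) else NA_real_,
      mean_rel_error = if (any(ok)) mean(per_rep_err, na.rm = TRUE) else NA_real_,
      sign_flip = if (assoc[k] && is.finite(ref) && ref != 0)
        mean(x[ok] * ref < 0) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("design_summary", class(out))
  out
}
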