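#' Build a two-cluster hierarchical island model
#'
#' Constructs the demographic model used throughout the package: `n_old +
#' n_young` demes in two genetic clusters ("old" and "young"). Looking
#' backward in time, lineages migrate between demes at per-generation,
#' per-lineage emigration probabilities (`m_within` in total towards demes of
#' the same cluster, `m_between` towards the other cluster), all young demes
#' fuse into the first old deme `t_split` generations ago, and all remaining
#' demes fuse into that same deme `t_ancestral` generations ago.
#'
#' Between-deme heterogeneity is introduced by drawing each deme's effective
#' size and migration totals from truncated normal distributions (truncated at
#' zero) centred on the regime means with coefficient of variation
#' `jitter_cv`, and each deme's inbreeding coefficient as
#' `max(Normal(0, f_sd), 0)` (so `E[F]` is about `0.4 * f_sd`).
#'
#' @param regime gene-flow regime: `"high"` sets the between-cluster
#'   emigration total to `m_between`; `"low"` sets it to zero.
#' @param n_old,n_young number of demes in the old and young cluster.
#' @param ne_old,ne_young mean diploid effective sizes per deme. The young
#'   cluster default is `ne_old / 1.5`.
#' @param m_within mean per-lineage total emigration probability towards
#'   same-cluster demes (split uniformly across them).
#' @param m_between mean total emigration probability towards the other
#'   cluster under the high-flow regime.
#' @param t_split,t_ancestral fusion times in generations; must satisfy
#'   `0 < t_split < t_ancestral`.
#' @param f_sd scale of the per-deme inbreeding draw.
#' @param jitter_cv coefficient of variation of the per-deme parameter draws;
#'   `0` gives every deme exactly the regime mean.
#' @param seed integer seed; the model is fully reproducible from it.
#' @return an object of class `demographic_model`.
#' @examples
#' m <- build_hierarchical_model("high", seed = 1)
#' m$m_between_mean   # 1e-4
#' @export
build_hierarchical_model <- function(regime = c("high", "low"),
                                     n_old = 25L, n_young = 25L,
                                     ne_old = 5000, ne_young = 5000 / 1.5,
                                     m_within = 0.001, m_between = 1e-4,
                                     t_split = 20000, t_ancestral = 140000,
                                     f_sd = 0.05, jitter_cv = 0.10,
                                     seed = 1L) {
  regime <- match.arg(regime)
  if (n_old < 1L) stop("need at least one old deme (the fusion anchor)")
  if (!(t_split > 0 && t_ancestral > t_split))
    stop("fusion times must satisfy 0 < t_split < t_ancestral")
  if (ne_old <= 0 || ne_young <= 0) stop("effective sizes must be positive")
  if (m_within < 0 || m_within > 1 || m_between < 0 || m_between > 1)
    stop("migration probabilities must lie in [0, 1]")
  m_b <- if (regime == "high") m_between else 0

  n_demes <- n_old + n_young
  cluster <- factor(rep(c("old", "young"), c(n_old, n_young)),
                    levels = c("old", "young"))
  set.seed(as.integer(seed))
  ne_mean <- ifelse(cluster == "old", ne_old, ne_young)
  ne <- rtrunc_pos(n_demes, ne_mean, jitter_cv * ne_mean)
  mw <- rtrunc_pos(n_demes, m_within, jitter_cv * m_within)
  mb <- rtrunc_pos(n_demes, m_b, jitter_cv * m_b)
  f <- pmin(pmax(stats::rnorm(n_demes, 0, f_sd), 0), 1)
  if (any(mw + mb > 1)) stop("per-deme emigration totals exceed 1")

  structure(list(
    n_demes = n_demes,
    deme_ids = sprintf("pop%02d", seq_len(n_demes)),
    cluster = cluster,
    ne = ne, m_within = mw, m_between = mb, f = f,
    t_split = t_split, t_ancestral = t_ancestral,
    regime = regime, jitter_cv = jitter_cv, f_sd = f_sd,
    ne_old_mean = ne_old, ne_young_mean = ne_young,
    m_within_mean = m_within, m_between_mean = m_b,
    seed = as.integer(seed),
    mig_within_weights = NULL  # optional deme x deme weights (IBD landscapes)
  ), class = "demographic_model")
}

# truncated-normal draw, strictly positive unless the mean itself is zero;
# bounded redraws, then hard failure (mirrors the module error contract)
rtrunc_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- which(x <= 0 & mean > 0)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
  }
  if (any(x <= 0 & mean > 0)) stop("could not draw a positive parameter value")
  x[mean == 0] <- 0
  x
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Hierarchical island model (", x$regime, " between-cluster gene flow)\n",
      sep = "")
  cat("  demes:", x$n_demes, "(", sum(x$cluster == "old"), "old +",
      sum(x$cluster == "young"), "young )\n")
  cat(sprintf("  mean Ne: old %.0f, young %.0f; m_within %.2g, m_between %.2g\n",
              x$ne_old_mean, x$ne_young_mean, x$m_within_mean, x$m_between_mean))
  cat(sprintf("  fusions at %g and %g generations; jitter CV %.2f; E[F] ~ %.3f\n",
              x$t_split, x$t_ancestral, x$jitter_cv, x$f_sd / sqrt(2 * pi)))
  invisible(x)
}

# Backward emigration rate matrices for the two migration epochs.
# Row d gives lineage-in-deme-d rates towards each target deme: the deme's
# total within-cluster rate split across same-cluster demes (optionally with
# non-uniform weights, used by the isolation-by-distance landscape mode) and
# its total between-cluster rate split uniformly across the other cluster.
# The second epoch keeps only the old demes (young demes have fused).
migration_matrices <- function(model) {
  nd <- model$n_demes
  same <- outer(model$cluster, model$cluster, "==")
  diag(same) <- FALSE
  m1 <- matrix(0, nd, nd)
  w <- model$mig_within_weights
  for (d in seq_len(nd)) {
    s <- which(same[d, ])
    if (length(s)) {
      wt <- if (is.null(w)) rep(1, length(s)) else w[d, s]
      if (sum(wt) <= 0) wt <- rep(1, length(s))
      m1[d, s] <- model$m_within[d] * wt / sum(wt)
    }
    o <- which(!same[d, ] & seq_len(nd) != d)
    if (length(o)) m1[d, o] <- model$m_between[d] / length(o)
  }
  old <- model$cluster == "old"
  m2 <- matrix(0, nd, nd)
  for (d in which(old)) {
    s <- which(old & seq_len(nd) != d)
    if (length(s)) m2[d, s] <- model$m_within[d] / length(s)
  }
  list(epoch1 = m1, epoch2 = m2)
}

#' Serialize / restore a demographic model
#'
#' Models are plain lists and round-trip losslessly through YAML, so a run's
#' exact demography can be archived next to its results.
#'
#' @param model a `demographic_model`.
#' @param path file path.
#' @rdname model-io
#' @export
write_model <- function(model, path) {
  x <- unclass(model)
  x$cluster <- as.character(x$cluster)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname model-io
#' @export
read_model <- function(path) {
  x <- yaml::read_yaml(path)
  x$cluster <- factor(x$cluster, levels = c("old", "young"))
  if (!is.null(x$mig_within_weights))
    x$mig_within_weights <- matrix(unlist(x$mig_within_weights), x$n_demes, x$n_demes)
  structure(x, class = "demographic_model")
}
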