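#' First principal component of environmental variables
#'
#' PCA on the correlation matrix (variables centred and scaled, since
#' bioclimatic variables have heterogeneous units). Zero-variance variables
#' are dropped with a warning. The sign convention fixes the
#' largest-magnitude loading positive, so scores are reproducible across
#' subsets.
#'
#' @param env_matrix numeric matrix or data frame, populations x variables.
#' @return numeric vector of PC1 scores, one per population, with the
#'   proportion of variance explained in `attr(, "var_explained")`.
#' @export
env_pc1 <- function(env_matrix) {
  x <- as.matrix(env_matrix)
  if (nrow(x) < 3L) stop("need at least three populations")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least two (non-constant) variables")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  flip <- sign(load1[which.max(abs(load1))])
  scores <- pc$x[, 1] * flip
  attr(scores, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  scores
}

#' Geographic, environmental and genetic distance matrices
#'
#' Geographic distance is great-circle (haversine, km, Earth radius 6371 km)
#' for longitude/latitude metadata, Euclidean for planar synthetic
#' coordinates (`attr(metadata, "planar")` set, or `x`/`y` columns).
#' Environmental distance is the absolute difference of PC1 scores.
#' The genetic matrix (pairwise FST) is passed through unchanged; slightly
#' negative estimator-corrected values are preserved.
#'
#' @param metadata population metadata (data frame with `pop_id`,
#'   `lon`/`lat` or `x`/`y`, and a `pc1` column or `env_*` columns).
#' @param genetic pairwise FST matrix with pop ids as dimnames.
#' @return list of class `distance_matrices` with `geographic`,
#'   `environmental`, `genetic` (all symmetric, zero diagonal) and `pop_ids`.
#' @export
distance_matrices <- function(metadata, genetic) {
  ids <- metadata$pop_id
  gid <- rownames(genetic)
  if (is.null(gid)) stop("genetic distance matrix needs pop-id dimnames")
  missing_md <- setdiff(gid, ids)
  missing_gen <- setdiff(ids, gid)
  if (length(missing_md) || length(missing_gen))
    stop("population id mismatch; missing from metadata: ",
         paste(missing_md, collapse = ", "), "; missing from genetic: ",
         paste(missing_gen, collapse = ", "))
  metadata <- metadata[match(gid, ids), , drop = FALSE]

  geo <- if (is_planar(metadata)) {
    as.matrix(stats::dist(cbind(metadata$x, metadata$y)))
  } else {
    haversine_matrix(metadata$lon, metadata$lat)
  }
  pc1 <- metadata_pc1(metadata)
  env <- abs(outer(pc1, pc1, "-"))
  dimnames(geo) <- dimnames(env) <- dimnames(genetic)
  structure(list(geographic = geo, environmental = env, genetic = genetic,
                 pop_ids = gid),
            class = "distance_matrices")
}

is_planar <- function(metadata) {
  isTRUE(attr(metadata, "planar")) ||
    (all(c("x", "y") %in% names(metadata)) && !("lon" %in% names(metadata)))
}

metadata_pc1 <- function(metadata) {
  if ("pc1" %in% names(metadata)) return(metadata$pc1)
  env_cols <- grep("^env_", names(metadata), value = TRUE)
  if (!length(env_cols)) stop("metadata needs a pc1 column or env_* columns")
  as.numeric(env_pc1(metadata[, env_cols, drop = FALSE]))
}

# great-circle distance in km, spherical Earth of radius 6371 km
haversine_km <- function(lon1, lat1, lon2, lat2, radius = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- haversine_km(lon[i], lat[i], lon, lat)
  }
  (m + t(m)) / 2
}

#' Write / read a distance matrix as square CSV with pop-id headers
#'
#' @param m square matrix with pop-id dimnames (e.g. one component of a
#'   [distance_matrices()] result).
#' @param path file path.
#' @rdname distance-io
#' @export
write_distance_csv <- function(m, path) {
  df <- data.frame(pop_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname distance-io
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$pop_id
  m
}

#' Multiple regression on distance matrices
#'
#' Ordinary least squares of the unfolded lower triangle of the genetic
#' distance matrix on the unfolded geographic and environmental distances
#' (joint model: both predictors simultaneously). Significance is assessed
#' by permuting rows and columns of the response matrix jointly, refitting,
#' and taking `p = (1 + #{|b_perm| >= |b_obs|}) / (n_permutations + 1)` per
#' coefficient (the observed statistic counts as one permutation, so
#' `p >= 1/(n_permutations + 1)`). With `n_permutations = 0` only the
#' coefficients are returned.
#'
#' @param genetic_dist,geo_dist,env_dist square symmetric matrices over the
#'   same populations (or a [distance_matrices()] object as first argument).
#' @param n_permutations permutations of the response matrix.
#' @param seed integer seed for the permutations.
#' @return list of class `mrm_result`: `coefficients` (intercept, geographic,
#'   environmental), `r_squared`, `p_values`, `n_permutations`, `n_pops`.
#' @export
mrm <- function(genetic_dist, geo_dist = NULL, env_dist = NULL,
                n_permutations = 1000L, seed = 1L) {
  if (inherits(genetic_dist, "distance_matrices")) {
    geo_dist <- genetic_dist$geographic
    env_dist <- genetic_dist$environmental
    genetic_dist <- genetic_dist$genetic
  }
  n <- nrow(genetic_dist)
  if (n < 4L) stop("need at least four populations")
  lower <- lower.tri(genetic_dist)
  y <- genetic_dist[lower]
  preds <- list()
  if (!is.null(geo_dist)) preds$geographic <- geo_dist[lower]
  if (!is.null(env_dist)) preds$environmental <- env_dist[lower]
  if (!length(preds)) stop("at least one predictor matrix required")
  if (length(preds) == 2L &&
      abs(stats::cor(preds[[1]], preds[[2]])) > 1 - 1e-12)
    stop("predictor distance matrices are collinear")
  X <- cbind(intercept = 1, do.call(cbind, preds))
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  fitted <- X %*% beta
  ssr <- sum((fitted - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else ssr / sst
  p <- rep(NA_real_, length(beta))
  names(p) <- names(beta)
  if (n_permutations > 0L) {
    set.seed(as.integer(seed))
    yperm <- matrix(0, sum(lower), n_permutations)
    for (k in seq_len(n_permutations)) {
      ord <- sample.int(n)
      yperm[, k] <- genetic_dist[ord, ord][lower]
    }
    bperm <- qr.coef(qr_x, yperm)  # coefficients x permutations
    exceed <- abs(bperm) >= abs(beta) - 1e-12
    p <- (1 + rowSums(exceed)) / (n_permutations + 1)
    names(p) <- names(beta)
  }
  structure(list(coefficients = beta, r_squared = r2, p_values = p,
                 n_permutations = n_permutations, n_pops = n),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM over %d populations (%d permutations)\n",
              x$n_pops, x$n_permutations))
  out <- data.frame(estimate = x$coefficients, p = x$p_values)
  print(out)
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Distances to the geographic and niche centroids
#'
#' The geographic centroid is the coordinate-wise mean of the population
#' coordinates; the niche centroid is the mean in the space of the first two
#' environmental principal components (one PC if only one is available).
#' Distances are Euclidean in the respective space.
#'
#' @param metadata population metadata with coordinates and `env_*` columns
#'   (or precomputed `pc1`/`pc2`).
#' @return list with numeric vectors `geographic` and `niche` (one value per
#'   population, `metadata` row order).
#' @export
centroid_distances <- function(metadata) {
  if (nrow(metadata) < 2L) stop("need at least two populations")
  xy <- if (is_planar(metadata)) cbind(metadata$x, metadata$y)
        else cbind(metadata$lon, metadata$lat)
  ctr <- colMeans(xy)
  geo <- sqrt(rowSums(sweep(xy, 2, ctr)^2))

  env_cols <- grep("^env_", names(metadata), value = TRUE)
  x <- as.matrix(metadata[, env_cols, drop = FALSE])
  if (length(env_cols)) {
    v <- apply(x, 2, stats::var)
    x <- x[, v > 0, drop = FALSE]
  }
  pcs <- if (ncol(x) >= 2L) {
    pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    pr$x[, seq_len(min(2L, ncol(pr$x))), drop = FALSE]
  } else if (ncol(x) == 1L) {
    scale(x)
  } else if ("pc1" %in% names(metadata)) {
    cbind(metadata$pc1)
  } else {
    # fully degenerate environment: every population sits at the niche centre
    matrix(0, nrow(metadata), 1L)
  }
  nctr <- colMeans(pcs)
  niche <- sqrt(rowSums(sweep(pcs, 2, nctr)^2))
  list(geographic = geo, niche = niche)
}

#' Central-abundance regression
#'
#' Simple linear regression of per-population gene diversity on the distance
#' from the geographic or niche centroid. Under the central-abundance
#' hypothesis the slope is negative: diversity declines away from the centre
#' of the range or niche.
#'
#' @param hs_per_pop per-population mean gene diversity.
#' @param centroid_distance per-population centroid distances.
#' @param predictor label recorded in the result.
#' @return list of class `cah_result`: `slope`, `intercept`, `p_value`,
#'   `r_squared`, `predictor`, `n`.
#' @export
cah_regression <- function(hs_per_pop, centroid_distance,
                           predictor = c("geographic", "niche")) {
  predictor <- match.arg(predictor)
  keep <- is.finite(hs_per_pop) & is.finite(centroid_distance)
  if (sum(keep) < 3L) stop("need at least three populations")
  if (stats::sd(centroid_distance[keep]) == 0)
    stop("centroid distances have zero variance")
  fit <- stats::lm(hs_per_pop[keep] ~ centroid_distance[keep])
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  slope <- unname(stats::coef(fit)[2])
  pv <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = pv, r_squared = sm$r.squared,
                 predictor = predictor, n = sum(keep)),
            class = "cah_result")
}

#' @export
print.cah_result <- function(x, ...) {
  cat(sprintf("CAH regression (Hs ~ %s centroid distance, n = %d)\n",
              x$predictor, x$n))
  cat(sprintf("  slope %.5f, intercept %.4f, p = %.4g, R2 = %.3f\n",
              x$slope, x$intercept, x$p_value, x$r_squared))
  invisible(x)
}
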