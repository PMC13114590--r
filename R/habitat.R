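# Habitat clustering: pooled superpixel features -> frozen K-means model ->
# per-voxel habitat labels, with Davies-Bouldin K selection, PCA separability
# export and random-forest imputation of missing habitat feature blocks.

# k-means++ seeding on a feature matrix (rows = observations).
kmeanspp_seeds <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1, ] <- x[idx, ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- d2 / sum(d2)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

#' Fit the habitat cluster model
#'
#' K-means (k-means++ initialization, 10 restarts, Lloyd iterations) on
#' pooled superpixel features from the training lesions. Features are
#' z-scored with training statistics that are stored in the model, so the
#' same frozen standardization and centroids are applied unchanged to
#' validation and test lesions.
#'
#' @param features numeric matrix, pooled superpixels x 10 first-order
#'   statistics (see [superpixel_features()]).
#' @param K number of habitats.
#' @param seed RNG seed for initialization.
#' @param nstart number of k-means++ restarts (default 10).
#' @return An object of class `cluster_model`: `K`, `centroids` (K x 10, in
#'   standardized space), `feat_mean`, `feat_sd`, `seed`, and optionally a
#'   `db_curve` attached by [select_k()].
#' @export
fit_habitat_model <- function(features, K, seed = 1L, nstart = 10L) {
  features <- as.matrix(features)
  if (nrow(features) < K) stop("fewer superpixels than requested clusters K")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(features, 2, mu), 2, sdv, `/`)
  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (r in seq_len(nstart)) {
    init <- kmeanspp_seeds(z, K)
    km <- suppressWarnings(
      stats::kmeans(z, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(list(K = as.integer(K), centroids = unname(best$centers),
                 feat_mean = mu, feat_sd = sdv, seed = as.integer(seed),
                 inertia = best$tot.withinss, db_curve = NULL),
            class = "cluster_model")
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio `(s_i + s_j) / d_ij`, where
#' `s_i` is the mean Euclidean distance of cluster members to their centroid
#' and `d_ij` the distance between centroids. Smaller is better.
#'
#' @param features numeric matrix of observations.
#' @param assignments integer cluster labels (1..K), every cluster nonempty.
#' @return The DB index (single number).
#' @export
davies_bouldin <- function(features, assignments) {
  features <- as.matrix(features)
  ks <- sort(unique(assignments))
  K <- length(ks)
  if (K < 2L) stop("need at least 2 clusters")
  if (!all(seq_len(max(ks)) %in% ks)) stop("empty cluster in assignments")
  cent <- t(vapply(ks, function(k) colMeans(features[assignments == k, , drop = FALSE]),
                   numeric(ncol(features))))
  s <- vapply(ks, function(k) {
    m <- features[assignments == k, , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cent[k, ])^2)))
  }, numeric(1))
  db <- 0
  for (i in seq_len(K)) {
    rij <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (dij == 0) stop("duplicate centroids: DB index undefined")
      rij <- max(rij, (s[i] + s[j]) / dij)
    }
    db <- db + rij
  }
  db / K
}

#' Select the number of habitats by the Davies-Bouldin criterion
#'
#' Fits a cluster model for each candidate K and returns the K with minimal
#' DB index (ties break to the smallest K), plus the full curve. The index
#' is computed in the standardized feature space used for clustering.
#'
#' @param features pooled superpixel feature matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed.
#' @return List with `K` (selected), `db` (named numeric curve) and `models`.
#' @export
select_k <- function(features, k_range = 2:10, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < max(k_range)) stop("not enough superpixels for max K")
  db <- stats::setNames(numeric(length(k_range)), k_range)
  models <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    m <- fit_habitat_model(features, k_range[i], seed = seed)
    z <- sweep(sweep(features, 2, m$feat_mean), 2, m$feat_sd, `/`)
    a <- nearest_centroid(z, m$centroids)
    db[i] <- davies_bouldin(z, a)
    models[[i]] <- m
  }
  kbest <- k_range[which.min(db)]  # which.min takes the first (smallest K) on ties
  list(K = kbest, db = db, models = models)
}

nearest_centroid <- function(z, centroids) {
  d2 <- matrix(0, nrow(z), nrow(centroids))
  for (k in seq_len(nrow(centroids)))
    d2[, k] <- colSums((t(z) - centroids[k, ])^2)
  max.col(-d2, ties.method = "first")
}

#' Assign habitats to a lesion with a frozen cluster model
#'
#' Computes superpixel features, standardizes them with the model's stored
#' training statistics, maps each superpixel to its nearest centroid, and
#' propagates the habitat label to the member voxels. No re-fitting occurs,
#' so assignments are consistent across cohorts.
#'
#' @param vol_norm a z-normalized [ct_volume].
#' @param spmap a `superpixel_map` from [slic3d()].
#' @param model a `cluster_model` from [fit_habitat_model()].
#' @return An integer habitat label array (class `habitat_map`): 0 outside
#'   the lesion, 1..K inside; attribute `present` lists the habitats found.
#' @export
assign_habitats <- function(vol_norm, spmap, model) {
  stopifnot(inherits(model, "cluster_model"))
  f <- superpixel_features(vol_norm, spmap)
  z <- sweep(sweep(f, 2, model$feat_mean), 2, model$feat_sd, `/`)
  hab <- nearest_centroid(z, model$centroids)
  out <- array(0L, dim(spmap$labels))
  inm <- spmap$labels > 0
  out[inm] <- hab[spmap$labels[inm]]
  attr(out, "present") <- sort(unique(hab))
  class(out) <- "habitat_map"
  out
}

#' Impute missing habitat feature blocks
#'
#' Iterative random-forest imputation in the style of missForest: columns
#' with missing entries are initialized at their observed mean, then each is
#' refit on the remaining columns and re-predicted, looping until the
#' relative change in imputed values increases or `max_iter` is reached.
#'
#' @param table numeric matrix/data.frame, cases x features, with `NA` blocks
#'   for absent habitats.
#' @param ntree trees per forest (default 50).
#' @param max_iter maximum sweeps (default 5).
#' @param seed RNG seed.
#' @return List with `table` (completed matrix), `n_imputed_blocks` (count of
#'   case x habitat blocks that contained missing values) and `n_iter`.
#' @export
impute_missing_habitats <- function(table, ntree = 50L, max_iter = 5L, seed = 1L) {
  x <- as.matrix(table)
  miss <- is.na(x)
  if (!any(miss)) return(list(table = x, n_imputed_blocks = 0L, n_iter = 0L))
  if (any(colSums(!miss) == 0L))
    stop("feature missing in all cases; cannot impute")
  # count case x habitat blocks with missingness (columns named Habitat{k}_*)
  habs <- unique(sub("^(Habitat[0-9]+)_.*$", "\\1", grep("^Habitat[0-9]+_", colnames(x), value = TRUE)))
  nblocks <- 0L
  for (h in habs) {
    cols <- grep(paste0("^", h, "_"), colnames(x))
    nblocks <- nblocks + sum(rowSums(miss[, cols, drop = FALSE]) > 0L)
  }
  set.seed(seed)
  # mean initialization
  for (j in which(colSums(miss) > 0L))
    x[miss[, j], j] <- mean(x[!miss[, j], j])
  cols_miss <- order(colSums(miss), decreasing = FALSE)
  cols_miss <- cols_miss[colSums(miss)[cols_miss] > 0L]
  prev_err <- Inf; it <- 0L
  x_prev <- x
  repeat {
    it <- it + 1L
    for (j in cols_miss) {
      obs <- !miss[, j]
      rf <- randomForest::randomForest(x = x[obs, -j, drop = FALSE],
                                       y = x[obs, j], ntree = ntree)
      x[!obs, j] <- stats::predict(rf, x[!obs, -j, drop = FALSE])
    }
    err <- sum((x[miss] - x_prev[miss])^2) / max(sum(x[miss]^2), .Machine$double.eps)
    if (err >= prev_err || it >= max_iter) {
      if (err >= prev_err) x <- x_prev  # revert the diverging sweep
      break
    }
    prev_err <- err
    x_prev <- x
  }
  list(table = x, n_imputed_blocks = nblocks, n_iter = it)
}

#' 2D PCA projection of superpixel features
#'
#' First two principal components (covariance PCA on centered inputs), used
#' to inspect habitat separability. Callers pass features already
#' standardized with the cluster model's training statistics, so the
#' projection operates on the same space as the clustering.
#'
#' @param features numeric matrix (>= 3 rows).
#' @return List with `scores` (n x 2), `explained` (proportion of variance
#'   per retained component) and the full `sdev`.
#' @export
pca_projection <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need at least 3 observations")
  sdv <- apply(features, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) warning("dropping constant column(s) from the projection")
  p <- stats::prcomp(features[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ncomp <- min(2L, ncol(p$x))
  if (ncomp < 2L) warning("rank-deficient features: fewer than 2 components")
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(ncomp), drop = FALSE],
       explained = expl[seq_len(ncomp)], sdev = p$sdev)
}

# Serialize / restore a cluster model as plain JSON.
#' @rdname serialize_models
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  obj <- list(type = "cluster_model", version = 1L, K = model$K,
              centroids = model$centroids, feat_mean = model$feat_mean,
              feat_sd = model$feat_sd, seed = model$seed,
              inertia = model$inertia, db_curve = model$db_curve)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialize_models
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "cluster_model")
    stop("not a cluster model file")
  structure(list(K = as.integer(obj$K),
                 centroids = as.matrix(obj$centroids),
                 feat_mean = unlist(obj$feat_mean), feat_sd = unlist(obj$feat_sd),
                 seed = as.integer(obj$seed), inertia = obj$inertia,
                 db_curve = if (length(obj$db_curve)) unlist(obj$db_curve) else NULL),
            class = "cluster_model")
}
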