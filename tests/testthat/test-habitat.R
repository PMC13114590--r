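test_that("SLIC partitions a uniform cube into near-equal connected blocks", {
  set.seed(1)
  a <- array(rnorm(20^3, 0, 1e-6), c(20, 20, 20))  # essentially uniform
  v <- ct_volume(a)
  m <- array(TRUE, c(20, 20, 20))
  sp <- slic3d(v, m, n_superpixels = 50)
  expect_true(sp$n >= 1 && sp$n <= 50)
  expect_equal(sum(sp$labels > 0), sum(m))   # labels partition the mask
  expect_lt(max(sp$sizes) / min(sp$sizes), 4)
  # spatial connectivity of every superpixel
  lab <- sp$labels
  lab[lab == 0] <- NA_integer_
  z <- habitomics:::label_zones(lab)
  expect_equal(max(z, na.rm = TRUE), sp$n)
})

test_that("tiny masks degrade to one superpixel per voxel with a warning", {
  v <- ct_volume(array(rnorm(5^3), c(5, 5, 5)))
  m <- array(FALSE, c(5, 5, 5)); m[2:3, 2:3, 2] <- TRUE  # 8 voxels? no: 4
  m[2, 2, 3] <- TRUE
  expect_warning(sp <- slic3d(v, m, n_superpixels = 50), "per voxel")
  expect_equal(sp$n, sum(m))
})

test_that("low compactness follows intensity boundaries better than high", {
  set.seed(3)
  a <- array(0, c(16, 16, 8))
  a[1:8, , ] <- -1; a[9:16, , ] <- 1
  a <- a + array(rnorm(length(a), 0, 0.05), dim(a))
  v <- ct_volume(a); m <- array(TRUE, dim(a))
  straddle <- function(compactness) {
    sp <- slic3d(v, m, n_superpixels = 16, compactness = compactness)
    bad <- 0
    for (s in seq_len(sp$n)) {
      xs <- which(sp$labels == s, arr.ind = TRUE)[, 1]
      if (any(xs <= 8) && any(xs > 8)) bad <- bad + 1
    }
    bad
  }
  expect_lte(straddle(0.05), straddle(5))
})

test_that("superpixel statistics match hand computation and conventions", {
  v <- ct_volume(array(c(1, 2, 3, 4, rep(9, 4)), c(2, 2, 2)))
  sp <- structure(list(labels = array(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
                                      c(2, 2, 2)),
                       n = 2L, sizes = c(4L, 4L)), class = "superpixel_map")
  f <- superpixel_features(v, sp)
  expect_equal(f[1, "mean"], 2.5, ignore_attr = TRUE)
  expect_equal(f[1, "median"], 2.5, ignore_attr = TRUE)
  expect_equal(f[1, "variance"], 1.25, ignore_attr = TRUE)  # population
  expect_equal(f[1, "skewness"], 0, ignore_attr = TRUE)     # symmetric
  # constant superpixel conventions
  expect_equal(unname(f[2, c("variance", "skewness", "kurtosis", "entropy")]),
               c(0, 0, 0, 0))
  expect_equal(f[2, "min"], 9, ignore_attr = TRUE)
  expect_equal(f[2, "max"], 9, ignore_attr = TRUE)
})

test_that("K-means habitat model is deterministic and recovers blobs", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(300, 0), 30),
                 matrix(rnorm(300, 8), 30),
                 matrix(rnorm(300, -8), 30))
  truth <- rep(1:3, each = 30)
  m1 <- fit_habitat_model(blobs, K = 3, seed = 4)
  m2 <- fit_habitat_model(blobs, K = 3, seed = 4)
  expect_identical(m1$centroids, m2$centroids)
  z <- sweep(sweep(blobs, 2, m1$feat_mean), 2, m1$feat_sd, `/`)
  a <- habitomics:::nearest_centroid(z, m1$centroids)
  # adjusted Rand index against the construction
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); n2 <- choose(length(a), 2)
    (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
  }
  expect_gt(ari(a, truth), 0.95)
  expect_equal(fit_habitat_model(blobs, K = 1, seed = 1)$K, 1L)
  expect_error(fit_habitat_model(blobs[1:2, ], K = 5), "fewer superpixels")
})

test_that("Davies-Bouldin equals its closed form and the naive oracle", {
  # two clusters at centroid distance 10 with within-scatter 1 each
  x <- rbind(cbind(c(-1, 1, -1, 1) + 0, 0), cbind(c(9, 11, 9, 11), 0))
  a <- rep(1:2, each = 4)
  expect_equal(davies_bouldin(x, a), (1 + 1) / 10)
  set.seed(6)
  y <- matrix(rnorm(150), 50, 3)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(davies_bouldin(y, b), oracle_db(y, b))
  expect_error(davies_bouldin(x, rep(1, 8)), "at least 2 clusters")
  # duplicated centroids are a guarded error
  xx <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_error(davies_bouldin(xx, c(1, 1, 2, 2)), "duplicate centroids")
})

test_that("K selection returns the DB argmin with smallest-K tie-break", {
  set.seed(7)
  two <- rbind(matrix(rnorm(200, 0, 0.5), 20), matrix(rnorm(200, 6, 0.5), 20))
  sel <- select_k(two, k_range = 2:6, seed = 2)
  expect_equal(sel$K, 2L)
  expect_equal(names(sel$db), as.character(2:6))
  expect_equal(sel$K, as.integer(names(which.min(sel$db))))
})

test_that("frozen assignment is consistent and flags missing habitats", {
  set.seed(8)
  voi <- make_test_voi(8, side = 14)
  voln <- znormalize(voi$vol, voi$mask)
  sp <- slic3d(voln, voi$mask, n_superpixels = 30)
  f <- superpixel_features(voln, sp)
  cm <- fit_habitat_model(f, K = 3, seed = 1)
  hm <- assign_habitats(voln, sp, cm)
  expect_identical(unclass(hm)[voi$mask] > 0, rep(TRUE, sum(voi$mask)))
  expect_equal(sum(unclass(hm) > 0), sum(voi$mask))  # volumes conserved
  # serialized model reproduces identical assignments
  p <- tempfile(fileext = ".json")
  write_cluster_model(cm, p)
  cm2 <- read_cluster_model(p)
  hm2 <- assign_habitats(voln, sp, cm2)
  expect_identical(unclass(hm), unclass(hm2))
})

test_that("habitat maps recover the constructed phantom subregions", {
  # part-solid cases whose ground-glass shell is thick enough that all three
  # subregions exist at the superpixel resolution (CTR <= 0.7, diameter >=
  # 16 mm) and with mild intra-subregion texture; near-solid lesions have
  # sub-resolution rims that no 50-superpixel partition resolves, and strong
  # speckle heterogeneity moves superpixels across intensity clusters (the
  # habitat-reassignment effect noted for noisy acquisitions). Averaged over
  # three cohorts to damp K-means initialization variation.
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); n2 <- choose(length(a), 2)
    (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
  }
  spec <- preproc_spec()
  aris <- c()
  for (seed in 21:23) {
    cfg <- cohort_config(n_cases = 20, seed = seed,
                         part_solid_fraction = 1,
                         ctr_range = c(0.3, 0.7),
                         diameter_range = c(16, 28),
                         rim_texture_range = c(0.05, 0.2),
                         batch_noise_sd = rep(20, 5))
    co <- generate_cohort(cfg)
    prep <- lapply(co$cases, function(cs) {
      vol <- clip_window(cs$volume, spec)
      voln <- znormalize(vol, cs$lesion_mask)
      sp <- slic3d(voln, cs$lesion_mask)
      list(voln = voln, sp = sp, f = superpixel_features(voln, sp),
           truth = cs$subregion_truth, mask = cs$lesion_mask)
    })
    cm <- fit_habitat_model(do.call(rbind, lapply(prep, `[[`, "f")), K = 3,
                            seed = 2)
    aris <- c(aris, vapply(prep, function(p) {
      hm <- assign_habitats(p$voln, p$sp, cm)
      ari(unclass(hm)[p$mask], p$truth[p$mask])
    }, numeric(1)))
  }
  expect_gt(mean(aris), 0.6)
})

test_that("imputation beats mean fill and counts injected blocks exactly", {
  set.seed(9)
  n <- 82; latent <- rnorm(n)
  mk <- function(k) sapply(1:6, function(j) latent * (0.8 + 0.05 * j) +
                             rnorm(n, 0, 0.3) + k)
  x <- cbind(mk(1), mk(2), mk(3))
  colnames(x) <- paste0("Habitat", rep(1:3, each = 6), "_f", rep(1:6, 3))
  truth <- x
  drop_rows <- sample(n, 7)
  x[drop_rows, 7:12] <- NA  # habitat-2 block of 7 cases
  res <- impute_missing_habitats(x, seed = 1)
  expect_equal(res$n_imputed_blocks, 7L)
  rmse <- sqrt(mean((res$table[drop_rows, 7:12] - truth[drop_rows, 7:12])^2))
  meanfill <- sweep(array(0, c(7, 6)), 2, colMeans(truth[-drop_rows, 7:12]), `+`)
  rmse_mean <- sqrt(mean((meanfill - truth[drop_rows, 7:12])^2))
  expect_lt(rmse, rmse_mean)
  # no missing values: unchanged
  res0 <- impute_missing_habitats(truth)
  expect_identical(res0$table, truth)
  expect_equal(res0$n_imputed_blocks, 0L)
  # 24 blocks across a larger cohort are reported exactly
  set.seed(10)
  nn <- 313
  big <- cbind(mk2 <- matrix(rnorm(nn * 4), nn), matrix(rnorm(nn * 4), nn),
               matrix(rnorm(nn * 4), nn))
  colnames(big) <- paste0("Habitat", rep(1:3, each = 4), "_f", rep(1:4, 3))
  rows <- sample(nn, 24)
  habs <- sample(1:3, 24, replace = TRUE)
  for (q in 1:24) big[rows[q], (habs[q] - 1) * 4 + 1:4] <- NA
  resb <- impute_missing_habitats(big, ntree = 10, seed = 2)
  expect_equal(resb$n_imputed_blocks, 24L)
})

test_that("PCA projection matches an independent eigendecomposition", {
  set.seed(11)
  x <- matrix(rnorm(20 * 5), 20, 5)
  p <- pca_projection(x)
  z <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(z), symmetric = TRUE)
  expect_equal(sort(p$sdev^2), sort(ev$values), tolerance = 1e-10)
  expect_equal(abs(stats::cor(p$scores[, 1], z %*% ev$vectors[, 1])), 1,
               tolerance = 1e-8, ignore_attr = TRUE)
  # collinear data: PC1 explains ~ everything
  line <- cbind(1:20, 2 * (1:20) + rnorm(20, 0, 1e-8), 3 * (1:20))
  pl <- pca_projection(line)
  expect_gt(pl$explained[1], 0.999)
  # orthogonal rotation leaves explained variance unchanged
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  pr <- pca_projection(x %*% Q)
  expect_equal(sort(p$explained), sort(pr$explained), tolerance = 1e-8)
})
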