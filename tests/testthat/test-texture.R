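# Texture families against independent brute-force matrix constructions on
# small fixtures, plus the degenerate-input conventions.

test_that("co-occurrence matrices match the loop oracle on random fixtures", {
  for (seed in 1:3) {
    disc <- make_disc_fixture(seed)
    for (r in seq_len(nrow(.dirs13))) {
      expect_equal(habitomics:::glcm_matrix(disc, .dirs13[r, ], 4),
                   oracle_glcm_matrix(disc, .dirs13[r, ], 4))
    }
  }
})

test_that("GLCM features match direct computation on the printed 3x3 fixture", {
  # fixture {1,1,2; 2,2,3; 3,3,3} as a single-slice volume
  disc <- array(c(1L, 2L, 3L, 1L, 2L, 3L, 2L, 3L, 3L), c(3, 3, 1))
  f <- glcm_features(disc, n_levels = 3)
  # oracle: average features over directions from loop-built matrices
  dirs_ok <- 0; acc <- NULL
  for (r in seq_len(nrow(.dirs13))) {
    M <- oracle_glcm_matrix(disc, .dirs13[r, ], 3)
    if (sum(M) == 0) next
    p <- M / sum(M)
    i <- row(p); j <- col(p)
    mux <- sum(i * p); muy <- sum(j * p)
    vals <- c(Contrast = sum((i - j)^2 * p),
              ClusterShade = sum((i + j - mux - muy)^3 * p),
              ClusterProminence = sum((i + j - mux - muy)^4 * p),
              JointEnergy = sum(p^2),
              MaximumProbability = max(p))
    acc <- if (is.null(acc)) vals else acc + vals
    dirs_ok <- dirs_ok + 1
  }
  expected <- acc / dirs_ok
  expect_equal(unname(f["GLCM_Contrast"]), unname(expected["Contrast"]))
  expect_equal(unname(f["GLCM_ClusterShade"]), unname(expected["ClusterShade"]))
  expect_equal(unname(f["GLCM_ClusterProminence"]),
               unname(expected["ClusterProminence"]))
  expect_equal(unname(f["GLCM_JointEnergy"]), unname(expected["JointEnergy"]))
  expect_equal(unname(f["GLCM_MaximumProbability"]),
               unname(expected["MaximumProbability"]))
})

test_that("single gray level gives zero cluster shade and prominence", {
  disc <- array(1L, c(3, 3, 3))
  f <- glcm_features(disc, n_levels = 1)
  expect_equal(unname(f["GLCM_ClusterShade"]), 0)
  expect_equal(unname(f["GLCM_ClusterProminence"]), 0)
  expect_equal(unname(f["GLCM_Contrast"]), 0)
})

test_that("intensity inversion negates cluster shade, preserves prominence", {
  disc <- make_disc_fixture(9, dims = c(4, 4, 3), ng = 5)
  inv <- 5L + 1L - disc
  f1 <- glcm_features(disc, n_levels = 5)
  f2 <- glcm_features(inv, n_levels = 5)
  expect_equal(unname(f1["GLCM_ClusterShade"]), -unname(f2["GLCM_ClusterShade"]))
  expect_equal(unname(f1["GLCM_ClusterProminence"]),
               unname(f2["GLCM_ClusterProminence"]))
})

test_that("run-length matrices match the walking oracle", {
  for (seed in 4:6) {
    disc <- make_disc_fixture(seed, dims = c(4, 3, 2), ng = 3)
    for (r in seq_len(nrow(.dirs13))) {
      a <- habitomics:::glrlm_matrix(disc, .dirs13[r, ], 3)
      b <- oracle_glrlm_matrix(disc, .dirs13[r, ], 3)
      # pad to a common run-length width
      w <- max(ncol(a), ncol(b))
      pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
      expect_equal(pad(a), pad(b))
    }
  }
})

test_that("size-zone matrix matches the flood-fill oracle", {
  for (seed in 7:9) {
    disc <- make_disc_fixture(seed, dims = c(4, 4, 2), ng = 3)
    a <- habitomics:::glszm_matrix(disc, 3)
    b <- oracle_glszm_matrix(disc, 3)
    w <- max(ncol(a), ncol(b))
    pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
    expect_equal(pad(a), pad(b))
  }
})

test_that("dependence matrix matches the loop oracle; uniform-cube closed form", {
  for (seed in 10:12) {
    disc <- make_disc_fixture(seed, dims = c(4, 4, 2), ng = 3)
    a <- habitomics:::gldm_matrix(disc, 3)
    b <- oracle_gldm_matrix(disc, 3)
    w <- max(ncol(a), ncol(b))
    pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
    expect_equal(pad(a), pad(b))
  }
  # interior voxels of a uniform cube have all 26 equal neighbors;
  # restricting to the interior makes every voxel's dependence 27
  cube <- array(1L, c(5, 5, 5))
  interior <- cube
  interior[c(1, 5), , ] <- NA; interior[, c(1, 5), ] <- NA; interior[, , c(1, 5)] <- NA
  # dependence counted within the full cube: use the full cube's interior block
  f <- gldm_features(cube, n_levels = 1)
  # for the full 5^3 cube, the modal dependence is 27 (interior);
  # check the bound SDE <= 1 and LDE equals the mean of j^2
  expect_lte(unname(f["GLDM_SmallDependenceEmphasis"]), 1)
  D <- habitomics:::gldm_matrix(cube, 1)
  expect_equal(unname(f["GLDM_LargeDependenceEmphasis"]),
               sum(D / sum(D) * (col(D))^2))
  # closed form for a 5^3 cube: 8 corners (dep 8), 36 edge voxels (dep 12),
  # 54 face voxels (dep 18), 27 interior voxels (dep 27)
  expect_equal(D[1, c(8, 12, 18, 27)], c(8, 36, 54, 27))
  expect_equal(sum(D), 125)
})

test_that("neighboring gray-tone difference quantities match the loop oracle", {
  for (seed in 13:15) {
    disc <- make_disc_fixture(seed, dims = c(4, 4, 2), ng = 3)
    orc <- oracle_ngtdm(disc, 3)
    nst <- habitomics:::neighborhood_stats(disc)
    g <- disc[!is.na(disc)]
    nbc <- nst$nb_count[!is.na(disc)]; nbs <- nst$nb_sum[!is.na(disc)]
    s_i <- sapply(1:3, function(l) {
      sel <- g == l & nbc > 0
      sum(abs(g[sel] - nbs[sel] / nbc[sel]))
    })
    expect_equal(s_i, orc$s)
    expect_equal(tabulate(g, 3), orc$n)
  }
})

test_that("NGTDM conventions: constant image 0s; blur lowers contrast", {
  disc <- array(2L, c(4, 4, 2))
  f <- ngtdm_features(disc, n_levels = 3)
  expect_equal(unname(f["NGTDM_Contrast"]), 0)
  expect_equal(unname(f["NGTDM_Busyness"]), 0)
  # checkerboard has maximal local differences; a smoothed version less
  set.seed(21)
  side <- 8
  cb <- array(((slice.index(array(0, c(side, side, 2)), 1) +
                  slice.index(array(0, c(side, side, 2)), 2)) %% 2) * 4L + 1L,
              c(side, side, 2))
  smooth <- array(3L, dim(cb)); smooth[1, 1, 1] <- 2L
  f_cb <- ngtdm_features(cb, n_levels = 5)
  f_sm <- ngtdm_features(smooth, n_levels = 5)
  expect_gt(f_cb["NGTDM_Contrast"], f_sm["NGTDM_Contrast"])
})

test_that("two-level 3x3 fixture NGTDM matches hand-checkable oracle numbers", {
  disc <- array(c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L), c(3, 3, 1))
  orc <- oracle_ngtdm(disc, 3)
  f <- ngtdm_features(disc, n_levels = 3)
  n <- orc$n; s <- orc$s; Nv <- sum(n); p <- n / Nv
  nz <- p > 0; lv <- 1:3; Ngp <- sum(nz)
  contrast <- sum(outer(p[nz], p[nz]) * outer(lv[nz], lv[nz], "-")^2) /
    (Ngp * (Ngp - 1)) * sum(s) / Nv
  busy <- sum(p * s) / sum(abs(outer(lv[nz] * p[nz], lv[nz] * p[nz], "-")))
  expect_equal(unname(f["NGTDM_Contrast"]), contrast)
  expect_equal(unname(f["NGTDM_Busyness"]), busy)
})
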