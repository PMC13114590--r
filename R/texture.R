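# Texture-matrix machinery shared by the GLCM/GLRLM/GLSZM/GLDM/NGTDM feature
# families. All functions operate on a cropped integer gray-level array with
# NA outside the region of interest; gray levels are the 1..n_bins indices
# produced by discretize_fixed_bins().

.EPS <- 2.2e-16

# 13 unique 3D direction offsets (unit distance, up to sign).
texture_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# All 26 neighbor offsets.
neighbor_offsets <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE])
}

# Crop an array (plus parallel arrays) to the bounding box of non-NA voxels.
crop_to_mask <- function(disc) {
  ok <- which(!is.na(disc), arr.ind = TRUE)
  if (nrow(ok) == 0L) stop("empty region")
  rr <- range(ok[, 1]); rc <- range(ok[, 2]); rs <- range(ok[, 3])
  disc[rr[1]:rr[2], rc[1]:rc[2], rs[1]:rs[2], drop = FALSE]
}

# Overlapping index ranges of an array and its copy shifted by `off`.
# Returns list(a = index list for the anchor, b = for the neighbor).
shift_ranges <- function(dims, off) {
  a <- b <- vector("list", 3L)
  for (k in 1:3) {
    n <- dims[k]; o <- off[k]
    if (abs(o) >= n) return(NULL)
    if (o >= 0) { a[[k]] <- seq_len(n - o); b[[k]] <- seq_len(n - o) + o }
    else        { a[[k]] <- seq_len(n + o) - o; b[[k]] <- seq_len(n + o) }
  }
  list(a = a, b = b)
}

# Neighbor summaries in the 26-neighborhood: for every in-mask voxel, the
# number of equal-gray in-mask neighbors, the sum of neighbor gray values and
# the neighbor count. Used by GLDM (alpha = 0) and NGTDM.
neighborhood_stats <- function(disc) {
  dims <- dim(disc)
  inm <- !is.na(disc)
  eqc <- array(0L, dims); nbs <- array(0, dims); nbc <- array(0L, dims)
  for (r in seq_len(nrow(neighbor_offsets()))) {
    off <- neighbor_offsets()[r, ]
    sr <- shift_ranges(dims, off)
    if (is.null(sr)) next
    a <- disc[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE]
    b <- disc[sr$b[[1]], sr$b[[2]], sr$b[[3]], drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    eq <- both & (a == b)
    eqc[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
      eqc[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE] + eq
    addb <- ifelse(both, b, 0)
    nbs[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
      nbs[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE] + addb
    nbc[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
      nbc[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE] + both
  }
  list(eq_count = eqc, nb_sum = nbs, nb_count = nbc, in_mask = inm)
}

# ---- gray-level co-occurrence -------------------------------------------

# Symmetric co-occurrence count matrix for one direction.
glcm_matrix <- function(disc, off, n_levels) {
  dims <- dim(disc)
  sr <- shift_ranges(dims, off)
  if (is.null(sr)) return(matrix(0, n_levels, n_levels))
  a <- disc[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE]
  b <- disc[sr$b[[1]], sr$b[[2]], sr$b[[3]], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  ai <- a[keep]; bi <- b[keep]
  m <- matrix(0, n_levels, n_levels)
  if (length(ai)) {
    t1 <- tabulate((bi - 1L) * n_levels + ai, nbins = n_levels * n_levels)
    m <- matrix(t1, n_levels, n_levels)
    m <- m + t(m)  # symmetric
  }
  m
}

glcm_features_from_matrix <- function(P) {
  Ng <- nrow(P)
  s <- sum(P)
  if (s <= 0) return(NULL)
  p <- P / s
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  lv <- seq_len(Ng)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sdx <- sqrt(sum((lv - mux)^2 * px)); sdy <- sqrt(sum((lv - muy)^2 * py))
  # diagonal / cross-diagonal distributions
  kd <- abs(i - j)
  pdm <- vapply(0:(Ng - 1), function(k) sum(p[kd == k]), numeric(1))
  ks <- i + j
  pds <- vapply(2:(2 * Ng), function(k) sum(p[ks == k]), numeric(1))
  kdv <- 0:(Ng - 1); ksv <- 2:(2 * Ng)
  da <- sum(kdv * pdm)
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(p[p > 0] * log2(p[p > 0]))
  pxy <- outer(px, py)
  HXY1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0] + .EPS))
  HXY2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  corr <- if (sdx > .EPS && sdy > .EPS)
    (sum(i * j * p) - mux * muy) / (sdx * sdy) else 1
  # maximal correlation coefficient: sqrt of the second-largest eigenvalue of
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px_i py_k)
  mcc <- 1
  if (sdx > .EPS) {
    A <- p / pmax(px, .EPS)        # rows divided by px_i
    B <- t(p) / pmax(py, .EPS)     # B[k, j] = p(j, k) / py_k
    Q <- A %*% B
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(ev) >= 2 && ev[2] > 0) sqrt(min(max(ev[2], 0), 1)) else 0
  }
  c(
    Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdm[pdm > 0] * log2(pdm[pdm > 0])),
    DifferenceVariance = sum((kdv - da)^2 * pdm),
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j)^2) / Ng^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(p[i != j] / ((i - j)[i != j])^2),
    MaximumProbability = max(p),
    SumEntropy = -sum(pds[pds > 0] * log2(pds[pds > 0])),
    SumSquares = sum((i - mux)^2 * p),
    MCC = mcc
  )
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices over the 13 unique 3D directions at
#' distance 1; feature values are averaged across directions.
#'
#' @param disc integer gray-level array (NA outside the region).
#' @param n_levels number of gray levels (default: observed maximum).
#' @return Named numeric vector of 23 GLCM features (the SumAverage
#'   co-occurrence statistic is excluded from the catalog; see
#'   [feature_catalog()]).
#' @export
glcm_features <- function(disc, n_levels = max(disc, na.rm = TRUE)) {
  disc <- crop_to_mask(disc)
  dirs <- texture_directions()
  acc <- NULL; nd <- 0L
  for (r in seq_len(nrow(dirs))) {
    M <- glcm_matrix(disc, dirs[r, ], n_levels)
    f <- glcm_features_from_matrix(M)
    if (is.null(f)) next
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no valid co-occurrence pairs in any direction")
  out <- acc / nd
  names(out) <- paste0("GLCM_", names(out))
  out
}

# ---- gray-level run length ----------------------------------------------

# Run-length count matrix (n_levels x max run length) for one direction.
glrlm_matrix <- function(disc, off, n_levels) {
  dims <- dim(disc)
  inm <- !is.na(disc)
  # predecessor gray value (NA when out of bounds)
  pred <- array(NA_integer_, dims)
  sr <- shift_ranges(dims, -off)
  if (!is.null(sr)) {
    pred[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
      disc[sr$b[[1]], sr$b[[2]], sr$b[[3]]]
  }
  starts <- which(inm & (is.na(pred) | pred != disc), arr.ind = TRUE)
  if (nrow(starts) == 0L) return(matrix(0, n_levels, 1))
  g <- disc[starts]
  len <- rep(1L, nrow(starts))
  pos <- starts
  alive <- rep(TRUE, nrow(starts))
  while (any(alive)) {
    nxt <- pos[alive, , drop = FALSE] +
      matrix(off, sum(alive), 3, byrow = TRUE)
    inside <- nxt[, 1] >= 1 & nxt[, 1] <= dims[1] &
      nxt[, 2] >= 1 & nxt[, 2] <= dims[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= dims[3]
    cont <- inside
    if (any(inside)) {
      vals <- disc[nxt[inside, , drop = FALSE]]
      cont[inside] <- !is.na(vals) & vals == g[alive][inside]
    }
    idx <- which(alive)
    len[idx[cont]] <- len[idx[cont]] + 1L
    pos[idx[cont], ] <- nxt[cont, , drop = FALSE]
    alive[idx[!cont]] <- FALSE
  }
  lmax <- max(len)
  m <- matrix(0, n_levels, lmax)
  for (k in seq_along(g)) m[g[k], len[k]] <- m[g[k], len[k]] + 1
  m
}

rlm_style_features <- function(R, n_voxels, prefix, run_word) {
  Nr <- sum(R)
  p <- R / Nr
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pg <- rowSums(R); pr <- colSums(R)
  vals <- c(
    sum(p / j^2),                      # short emphasis
    sum(p * j^2),                      # long emphasis
    sum(pg^2) / Nr,                    # gray-level non-uniformity
    sum(pg^2) / Nr^2,                  # ... normalized
    sum(pr^2) / Nr,                    # run/zone non-uniformity
    sum(pr^2) / Nr^2,                  # ... normalized
    Nr / n_voxels,                     # percentage
    sum((i - mu_i)^2 * p),             # gray-level variance
    sum((j - mu_j)^2 * p),             # run/zone variance
    -sum(p[p > 0] * log2(p[p > 0])),   # entropy
    sum(p / i^2),
    sum(p * i^2),
    sum(p / (i^2 * j^2)),
    sum(p * i^2 / j^2),
    sum(p * j^2 / i^2),
    sum(p * i^2 * j^2)
  )
  names(vals) <- paste0(prefix, c(
    paste0("Short", run_word, "Emphasis"), paste0("Long", run_word, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(run_word, "LengthNonUniformity"),
    paste0(run_word, "LengthNonUniformityNormalized"),
    paste0(run_word, "Percentage"),
    "GrayLevelVariance", paste0(run_word, "Variance"),
    paste0(run_word, "Entropy"),
    paste0("LowGrayLevel", run_word, "Emphasis"),
    paste0("HighGrayLevel", run_word, "Emphasis"),
    paste0("Short", run_word, "LowGrayLevelEmphasis"),
    paste0("Short", run_word, "HighGrayLevelEmphasis"),
    paste0("Long", run_word, "LowGrayLevelEmphasis"),
    paste0("Long", run_word, "HighGrayLevelEmphasis")
  ))
  vals
}

#' Gray-level run-length (GLRLM) features
#'
#' Run-length matrices over the 13 unique 3D directions; feature values are
#' averaged across directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 GLRLM features.
#' @export
glrlm_features <- function(disc, n_levels = max(disc, na.rm = TRUE)) {
  disc <- crop_to_mask(disc)
  np <- sum(!is.na(disc))
  dirs <- texture_directions()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    R <- glrlm_matrix(disc, dirs[r, ], n_levels)
    f <- rlm_style_features(R, np, "", "Run")
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / nrow(dirs)
  names(out) <- paste0("GLRLM_", names(out))
  out
}

# ---- gray-level size zone ------------------------------------------------

# 26-connected components of iso-intensity zones. Adjacent equal-gray voxel
# pairs are collected by array shifts over the 13 unique directions and the
# components come from the resulting undirected graph. Returns an integer
# array of zone ids (NA outside mask).
label_zones <- function(disc) {
  dims <- dim(disc)
  inm <- !is.na(disc)
  nvox <- sum(inm)
  id <- array(NA_integer_, dims)
  id[inm] <- seq_len(nvox)
  lin <- array(seq_along(disc), dims)
  edges <- vector("list", 13L)
  dirs <- texture_directions()
  for (r in seq_len(nrow(dirs))) {
    sr <- shift_ranges(dims, dirs[r, ])
    if (is.null(sr)) next
    a <- disc[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE]
    b <- disc[sr$b[[1]], sr$b[[2]], sr$b[[3]], drop = FALSE]
    keep <- !is.na(a) & !is.na(b) & a == b
    if (!any(keep)) next
    ia <- lin[sr$a[[1]], sr$a[[2]], sr$a[[3]], drop = FALSE][keep]
    ib <- lin[sr$b[[1]], sr$b[[2]], sr$b[[3]], drop = FALSE][keep]
    edges[[r]] <- rbind(id[ia], id[ib])
  }
  el <- do.call(cbind, edges)
  memb <- if (is.null(el)) seq_len(nvox) else {
    g <- igraph::make_graph(as.vector(el), n = nvox, directed = FALSE)
    igraph::components(g)$membership
  }
  z <- array(NA_integer_, dims)
  z[inm] <- as.integer(memb)
  z
}

glszm_matrix <- function(disc, n_levels) {
  zones <- label_zones(disc)
  inm <- !is.na(disc)
  zid <- zones[inm]; g <- disc[inm]
  zs <- tabulate(zid)
  zg <- g[match(seq_along(zs), zid)]  # gray level of each zone
  smax <- max(zs)
  m <- matrix(0, n_levels, smax)
  for (k in seq_along(zs)) m[zg[k], zs[k]] <- m[zg[k], zs[k]] + 1
  m
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are 26-connected components of equal gray level; the size-zone
#' matrix is direction-free.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 GLSZM features.
#' @export
glszm_features <- function(disc, n_levels = max(disc, na.rm = TRUE)) {
  disc <- crop_to_mask(disc)
  np <- sum(!is.na(disc))
  S <- glszm_matrix(disc, n_levels)
  out <- rlm_style_features(S, np, "", "Zone")
  # conventional GLSZM naming uses Area for size emphasis
  names(out) <- sub("^ShortZone", "SmallArea", names(out))
  names(out) <- sub("^LongZone", "LargeArea", names(out))
  names(out) <- sub("ZoneLengthNonUniformity", "SizeZoneNonUniformity", names(out))
  names(out) <- sub("^ZonePercentage", "ZonePercentage", names(out))
  names(out) <- sub("ShortZoneLowGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis", names(out))
  names(out) <- paste0("GLSZM_", names(out))
  out
}

# ---- gray-level dependence ----------------------------------------------

gldm_matrix <- function(disc, n_levels, nstats = NULL) {
  if (is.null(nstats)) nstats <- neighborhood_stats(disc)
  inm <- nstats$in_mask
  dep <- nstats$eq_count[inm] + 1L   # dependence includes the center voxel
  g <- disc[inm]
  dmax <- max(dep)
  m <- matrix(0, n_levels, dmax)
  t1 <- tabulate((dep - 1L) * n_levels + g, nbins = n_levels * dmax)
  matrix(t1, n_levels, dmax)
}

#' Gray-level dependence (GLDM) features
#'
#' Dependence counts use the 26-neighborhood at distance 1 with similarity
#' tolerance alpha = 0 (exact gray-level equality); the dependence of a voxel
#' is 1 plus its number of equal-gray neighbors.
#'
#' @inheritParams glcm_features
#' @param nstats optional precomputed [neighborhood_stats()] result.
#' @return Named numeric vector of 14 GLDM features.
#' @export
gldm_features <- function(disc, n_levels = max(disc, na.rm = TRUE), nstats = NULL) {
  if (is.null(nstats)) disc <- crop_to_mask(disc)
  D <- gldm_matrix(disc, n_levels, nstats = nstats)
  Nz <- sum(D)
  p <- D / Nz
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pg <- rowSums(D); pd <- colSums(D)
  out <- c(
    SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    DependenceNonUniformity = sum(pd^2) / Nz,
    DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
  names(out) <- paste0("GLDM_", names(out))
  out
}

# ---- neighboring gray-tone difference -----------------------------------

#' Neighboring gray-tone difference (NGTDM) features
#'
#' The NGTD matrix records, per gray level, the summed absolute difference
#' between each voxel's gray level and the mean of its in-mask
#' 26-neighborhood. Degenerate denominators yield 0 (Coarseness yields 1e6).
#'
#' @inheritParams gldm_features
#' @return Named numeric vector of 5 NGTDM features.
#' @export
ngtdm_features <- function(disc, n_levels = max(disc, na.rm = TRUE), nstats = NULL) {
  if (is.null(nstats)) {
    disc <- crop_to_mask(disc)
    nstats <- neighborhood_stats(disc)
  }
  inm <- nstats$in_mask
  g <- disc[inm]
  nbc <- nstats$nb_count[inm]
  nbs <- nstats$nb_sum[inm]
  has_nb <- nbc > 0
  diffv <- numeric(length(g))
  diffv[has_nb] <- abs(g[has_nb] - nbs[has_nb] / nbc[has_nb])
  Nvp <- length(g)
  n_i <- tabulate(g, nbins = n_levels)
  s_i <- vapply(seq_len(n_levels), function(l) sum(diffv[g == l]), numeric(1))
  p_i <- n_i / Nvp
  nz <- which(p_i > 0)
  Ngp <- length(nz)
  lv <- seq_len(n_levels)
  contrast <- 0
  if (Ngp > 1) {
    pp <- outer(p_i[nz], p_i[nz])
    dd <- outer(lv[nz], lv[nz], "-")^2
    contrast <- sum(pp * dd) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  }
  # denominator is the full double sum over gray-level pairs with p > 0
  busy_den <- sum(abs(outer(lv[nz] * p_i[nz], lv[nz] * p_i[nz], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  complexity <- 0
  if (Ngp > 1) {
    pi_ <- p_i[nz]; si_ <- s_i[nz]; li <- lv[nz]
    num <- outer(li, li, function(a, b) abs(a - b))
    wgt <- outer(pi_ * si_, pi_ * si_, "+") / outer(pi_, pi_, "+")
    complexity <- sum(num * wgt) / Nvp
  }
  strength <- 0
  if (sum(s_i) > 0 && Ngp > 1) {
    pi_ <- p_i[nz]; li <- lv[nz]
    strength <- sum(outer(pi_, pi_, "+") * outer(li, li, "-")^2) / sum(s_i)
  }
  coarse_den <- sum(p_i * s_i)
  out <- c(
    Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Contrast = contrast,
    Busyness = busyness,
    Complexity = complexity,
    Strength = strength
  )
  names(out) <- paste0("NGTDM_", names(out))
  out
}
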