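#' First-order intensity features
#'
#' Eighteen histogram/intensity statistics computed on the raw masked values;
#' Entropy and Uniformity use the fixed-bin discretization.
#'
#' @param values numeric vector of masked raw intensities.
#' @param bins integer vector of gray-level bins for the same voxels.
#' @param voxel_volume volume of a single voxel in mm^3 (for TotalEnergy).
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(values, bins, voxel_volume = 1) {
  v <- as.numeric(values)
  n <- length(v)
  if (n < 1L) stop("empty value vector")
  pk <- tabulate(bins, nbins = max(bins)) / n
  pk <- pk[pk > 0]
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  q <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  inr <- v[v >= q[1] & v <= q[4]]
  out <- c(
    Energy = sum(v^2),
    TotalEnergy = voxel_volume * sum(v^2),
    Entropy = -sum(pk * log2(pk)),
    Minimum = min(v),
    Percentile10 = q[1],
    Percentile90 = q[4],
    Maximum = max(v),
    Mean = mu,
    Median = stats::median(v),
    InterquartileRange = q[3] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = if (length(inr)) mean(abs(inr - mean(inr))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pk^2)
  )
  names(out) <- paste0("firstorder_", names(out))
  out
}

#' Shape features
#'
#' Fourteen 3D morphology descriptors computed on the voxel grid: volumes,
#' surface area from exposed voxel faces, sphericity, maximum diameters and
#' principal-axis lengths. Mesh quantities are voxel-face approximations.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  n <- sum(mask)
  if (n < 1L) stop("empty mask")
  voxvol <- prod(spacing)
  dims <- dim(mask)
  # surface area: faces of mask voxels not shared with another mask voxel
  face_areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2])
  area <- 0
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- s
      sr <- shift_ranges(dims, off)
      nb <- array(FALSE, dims)
      if (!is.null(sr))
        nb[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
          mask[sr$b[[1]], sr$b[[2]], sr$b[[3]]]
      area <- area + sum(mask & !nb) * face_areas[ax]
    }
  }
  vol <- n * voxvol
  coords <- which(mask, arr.ind = TRUE)
  phys <- sweep(coords, 2, spacing, `*`)
  # surface voxels: at least one exposed face (6-neighborhood)
  surf <- mask
  inner <- mask
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- s
      sr <- shift_ranges(dims, off)
      nb <- array(FALSE, dims)
      if (!is.null(sr))
        nb[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
          mask[sr$b[[1]], sr$b[[2]], sr$b[[3]]]
      inner <- inner & nb
    }
  }
  surf <- mask & !inner
  sc <- which(surf, arr.ind = TRUE)
  sphys <- sweep(sc, 2, spacing, `*`)
  max_pair_dist <- function(m) {
    if (nrow(m) < 2L) return(0)
    if (nrow(m) > 2000L) m <- m[seq(1, nrow(m), length.out = 2000L), , drop = FALSE]
    g <- tcrossprod(m)
    sq <- diag(g)
    d2 <- outer(sq, sq, "+") - 2 * g
    sqrt(max(d2, 0))
  }
  d3 <- max_pair_dist(sphys)
  plane_diam <- function(drop_ax) {
    keep <- setdiff(1:3, drop_ax)
    mx <- 0
    for (sl in unique(sc[, drop_ax])) {
      m <- sphys[sc[, drop_ax] == sl, keep, drop = FALSE]
      mx <- max(mx, max_pair_dist(m))
    }
    mx
  }
  # principal axes from the physical coordinate covariance
  if (n >= 2) {
    cv <- stats::cov(phys)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  out <- c(
    MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = plane_diam(3),
    Maximum2DDiameterColumn = plane_diam(1),
    Maximum2DDiameterRow = plane_diam(2),
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
  names(out) <- paste0("shape_", names(out))
  out
}

#' The radiomic feature catalog
#'
#' Whole-lesion extraction emits 106 named features: 14 shape, 18 first-order,
#' 23 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM. The co-occurrence
#' SumAverage statistic is excluded (it duplicates a linear combination of
#' JointAverage under matrix symmetry), which is what brings the co-occurrence
#' family to 23 and the total to 106; the exclusion is an explicit catalog
#' entry. The per-habitat catalog keeps all non-shape families plus
#' `shape_VoxelVolume` (93 features per habitat).
#'
#' @param per_habitat if TRUE, return the 93-feature per-habitat subset.
#' @return data.frame with columns `name` and `family`.
#' @export
feature_catalog <- function(per_habitat = FALSE) {
  fo <- paste0("firstorder_", c(
    "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
    "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
    "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"))
  sh <- paste0("shape_", c(
    "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
    "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
    "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness"))
  glcm <- paste0("GLCM_", c(
    "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
    "MaximumProbability", "SumEntropy", "SumSquares", "MCC"))
  glrlm <- paste0("GLRLM_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
    "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LongRunHighGrayLevelEmphasis"))
  glszm <- paste0("GLSZM_", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
    "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LargeAreaHighGrayLevelEmphasis"))
  gldm <- paste0("GLDM_", c(
    "SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis"))
  ngtdm <- paste0("NGTDM_", c(
    "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"))
  if (per_habitat) {
    nm <- c("shape_VoxelVolume", fo, glcm, glrlm, glszm, gldm, ngtdm)
  } else {
    nm <- c(sh, fo, glcm, glrlm, glszm, gldm, ngtdm)
  }
  data.frame(name = nm,
             family = sub("_.*$", "", nm),
             stringsAsFactors = FALSE)
}

# Internal: non-shape feature block for an arbitrary mask.
extract_intensity_block <- function(vol, mask, n_bins) {
  disc_full <- discretize_fixed_bins(vol, mask, n_bins = n_bins)
  # crop once; all texture families share the cropped array
  ok <- which(!is.na(disc_full), arr.ind = TRUE)
  rr <- range(ok[, 1]); rc <- range(ok[, 2]); rs <- range(ok[, 3])
  disc <- disc_full[rr[1]:rr[2], rc[1]:rc[2], rs[1]:rs[2], drop = FALSE]
  nlev <- n_bins
  nst <- neighborhood_stats(disc)
  vals <- vol$data[mask]
  bins <- disc_full[mask]
  c(
    firstorder_features(vals, bins, voxel_volume = prod(vol$spacing)),
    glcm_features(disc, n_levels = nlev),
    glrlm_features(disc, n_levels = nlev),
    glszm_features(disc, n_levels = nlev),
    gldm_features(disc, n_levels = nlev, nstats = nst),
    ngtdm_features(disc, n_levels = nlev, nstats = nst)
  )
}

#' Extract the whole-lesion radiomic feature vector
#'
#' Computes the full 106-feature catalog on a preprocessed volume: shape on
#' the binary mask, first-order on the masked intensities, and the five
#' texture families on the 25-bin fixed-count discretization of the masked
#' intensity range.
#'
#' @param vol a [ct_volume] (resampled and window-clipped HU values).
#' @param mask logical/binary lesion mask on the same grid.
#' @param n_bins gray-level bin count for discretization (default 25).
#' @return Named numeric vector of 106 features, ordered as
#'   [feature_catalog()].
#' @export
extract_whole <- function(vol, mask, n_bins = 25L) {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- mask_as_logical(mask, dim(vol$data))
  if (sum(mask) < 2L) stop("lesion mask must contain at least 2 voxels")
  out <- c(shape_features(mask, vol$spacing),
           extract_intensity_block(vol, mask, n_bins))
  cat_names <- feature_catalog(per_habitat = FALSE)$name
  out <- out[cat_names]
  stopifnot(!anyNA(names(out)))
  out
}

#' Extract per-habitat radiomic features
#'
#' Computes the 93-feature per-habitat catalog (all non-shape families plus
#' `shape_VoxelVolume`) for each habitat label 1..K, with names prefixed
#' `Habitat{k}_`. Intensities are re-discretized within each habitat mask.
#' A habitat absent from the lesion yields an all-`NA` block, which
#' downstream imputation fills in.
#'
#' @param vol a [ct_volume].
#' @param habitat_map integer array: 0 outside the lesion, 1..K habitat labels.
#' @param K number of habitats (default 3).
#' @param n_bins gray-level bin count (default 25).
#' @return Named numeric vector of `93 * K` features.
#' @export
extract_per_habitat <- function(vol, habitat_map, K = 3L, n_bins = 25L) {
  stopifnot(inherits(vol, "ct_volume"))
  hm <- as.array(habitat_map)
  if (!identical(dim(hm), dim(vol$data))) stop("habitat map grid mismatch")
  if (!any(hm > 0, na.rm = TRUE)) stop("empty lesion")
  cat93 <- feature_catalog(per_habitat = TRUE)$name
  out <- numeric(0)
  for (k in seq_len(K)) {
    mk <- !is.na(hm) & hm == k
    block <- stats::setNames(rep(NA_real_, length(cat93)), cat93)
    if (sum(mk) >= 2L) {
      vals <- c(shape_VoxelVolume = sum(mk) * prod(vol$spacing),
                extract_intensity_block(vol, mk, n_bins))
      block[] <- vals[cat93]
    }
    names(block) <- paste0("Habitat", k, "_", cat93)
    out <- c(out, block)
  }
  out
}
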