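#' CT volume container
#'
#' A minimal 3D CT volume: a numeric array of Hounsfield units plus voxel
#' spacing in millimetres and a world origin. All pipeline stages consume and
#' return this container.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing numeric length-3 vector, voxel edge lengths in mm (> 0).
#' @param origin numeric length-3 vector, world coordinate of voxel (1,1,1) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers")
  if (any(!is.finite(data))) stop("`data` must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume: %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Preprocessing specification
#'
#' Geometry and intensity harmonization parameters applied before habitat
#' clustering and texture extraction: isotropic target spacing, the lung
#' window used to clip HU values, and the fixed bin count for gray-level
#' discretization.
#'
#' @param target_spacing numeric length-3, target voxel size in mm.
#' @param window numeric length-2, HU clipping window (low, high).
#' @param n_bins integer >= 2, number of gray-level bins.
#' @return An object of class `preproc_spec`.
#' @export
preproc_spec <- function(target_spacing = c(1, 1, 1),
                         window = c(-1250, 250),
                         n_bins = 25L) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be (low, high) with low < high")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  structure(list(target_spacing = as.numeric(target_spacing),
                 window = as.numeric(window), n_bins = n_bins),
            class = "preproc_spec")
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based). Coordinates are clamped to the array extent, so edge queries
# reuse border values.
trilinear_interp <- function(a, xi, yi, zi) {
  d <- dim(a)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  xi <- clamp(xi, 1, d[1]); yi <- clamp(yi, 1, d[2]); zi <- clamp(zi, 1, d[3])
  x0 <- clamp(floor(xi), 1, max(d[1] - 1, 1)); x1 <- pmin(x0 + 1, d[1])
  y0 <- clamp(floor(yi), 1, max(d[2] - 1, 1)); y1 <- pmin(y0 + 1, d[2])
  z0 <- clamp(floor(zi), 1, max(d[3] - 1, 1)); z1 <- pmin(z0 + 1, d[3])
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  idx <- function(i, j, k) a[cbind(i, j, k)]
  c000 <- idx(x0, y0, z0); c100 <- idx(x1, y0, z0)
  c010 <- idx(x0, y1, z0); c110 <- idx(x1, y1, z0)
  c001 <- idx(x0, y0, z1); c101 <- idx(x1, y0, z1)
  c011 <- idx(x0, y1, z1); c111 <- idx(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto the target grid. Binary masks must be
#' resampled with `method = "nearest"` so label values stay in \{0, 1\}.
#' The output grid samples the same physical extent: output size is
#' `ceiling(dim * spacing / target)`, with grid points at the input origin
#' plus integer multiples of the target spacing.
#'
#' @param vol a [ct_volume].
#' @param spec a [preproc_spec] (only `target_spacing` is used).
#' @param method `"linear"` for intensities, `"nearest"` for label volumes.
#' @return A resampled [ct_volume].
#' @export
resample_isotropic <- function(vol, spec = preproc_spec(), method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "ct_volume"))
  target <- spec$target_spacing
  if (any(target <= 0)) stop("non-positive target spacing")
  d <- dim(vol$data)
  if (isTRUE(all.equal(vol$spacing, target))) return(vol)
  nd <- pmax(as.integer(ceiling(d * vol$spacing / target)), 1L)
  # world coordinates of new grid points, expressed in input voxel indices
  gx <- ((seq_len(nd[1]) - 1) * target[1]) / vol$spacing[1] + 1
  gy <- ((seq_len(nd[2]) - 1) * target[2]) / vol$spacing[2] + 1
  gz <- ((seq_len(nd[3]) - 1) * target[3]) / vol$spacing[3] + 1
  xi <- rep(gx, times = nd[2] * nd[3])
  yi <- rep(rep(gy, each = nd[1]), times = nd[3])
  zi <- rep(gz, each = nd[1] * nd[2])
  if (method == "nearest") {
    clamp <- function(v, hi) pmin(pmax(round(v), 1), hi)
    vals <- vol$data[cbind(clamp(xi, d[1]), clamp(yi, d[2]), clamp(zi, d[3]))]
  } else {
    vals <- trilinear_interp(vol$data, xi, yi, zi)
  }
  ct_volume(array(vals, dim = nd), spacing = target, origin = vol$origin)
}

#' Clip HU values to the lung window
#'
#' Constrains intensities to the lung window (default -1250 to 250 HU,
#' width 1500 / level -500).
#'
#' @inheritParams resample_isotropic
#' @return A [ct_volume] with all values inside the window.
#' @export
clip_window <- function(vol, spec = preproc_spec()) {
  stopifnot(inherits(vol, "ct_volume"))
  vol$data <- pmin(pmax(vol$data, spec$window[1]), spec$window[2])
  vol
}

#' Z-normalize intensities within a lesion mask
#'
#' Centers and scales the masked voxels to mean 0 and variance 1, using the
#' population (divide-by-n) variance convention. Voxels outside the mask are
#' transformed with the same affine map so the whole volume stays consistent.
#'
#' @param vol a [ct_volume].
#' @param mask logical/0-1 array matching `vol` dimensions.
#' @return A [ct_volume] whose masked voxels have mean 0 and variance 1.
#' @export
znormalize <- function(vol, mask) {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- mask_as_logical(mask, dim(vol$data))
  v <- vol$data[mask]
  if (length(v) < 2L) stop("mask must contain at least 2 voxels")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("degenerate lesion: constant intensity inside the mask")
  vol$data <- (vol$data - mu) / sdv
  vol
}

#' Discretize masked intensities into fixed-count equal-width bins
#'
#' Equal-width bins over the masked intensity range (fixed bin count, not
#' fixed bin width). Intervals are half-open with the top edge closed, so the
#' masked maximum falls in bin `n_bins`. A constant lesion occupies bin 1.
#'
#' @param vol a [ct_volume].
#' @param mask logical/0-1 array matching `vol` dimensions.
#' @param n_bins number of gray-level bins (default 25).
#' @return Integer array of `vol`'s dimensions: bin index 1..n_bins inside the
#'   mask, `NA` outside.
#' @export
discretize_fixed_bins <- function(vol, mask, n_bins = 25L) {
  stopifnot(inherits(vol, "ct_volume"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be >= 1")
  mask <- mask_as_logical(mask, dim(vol$data))
  if (!any(mask)) stop("empty mask")
  v <- vol$data[mask]
  lo <- min(v); hi <- max(v)
  out <- array(NA_integer_, dim = dim(vol$data))
  if (hi == lo) {
    out[mask] <- 1L
    return(out)
  }
  b <- floor((v - lo) / (hi - lo) * n_bins) + 1L
  b[b > n_bins] <- n_bins  # top edge closed
  out[mask] <- as.integer(b)
  out
}

# Coerce a numeric/logical mask to a logical array and validate its grid.
mask_as_logical <- function(mask, dims) {
  m <- as.array(mask)
  if (!identical(dim(m), as.integer(dims)))
    stop("mask grid does not match volume grid")
  if (is.numeric(m) && !all(m %in% c(0, 1)))
    stop("mask must be binary")
  array(as.logical(m), dim = dims)
}
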