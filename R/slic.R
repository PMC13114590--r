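#' 3D SLIC superpixel segmentation of a lesion
#'
#' Partitions the masked voxels of a z-normalized volume into compact,
#' spatially connected superpixels by local k-means in joint
#' intensity--space coordinates. Distances are spacing-aware: spatial
#' distance is measured in mm and scaled by the expected superpixel radius,
#' intensity distance by the compactness weight.
#'
#' @param vol_norm a [ct_volume] with z-normalized intensities.
#' @param mask logical/binary lesion mask.
#' @param n_superpixels requested superpixel count (default 50).
#' @param compactness weight of the spatial term relative to intensity
#'   (default 0.1 on z-normalized intensities; larger values give more
#'   compact, intensity-blind superpixels).
#' @param max_iter k-means iterations (default 10).
#' @return An object of class `superpixel_map`: list with `labels` (integer
#'   array, 0 outside the mask, 1..S inside), `n` (S) and `sizes`.
#' @export
slic3d <- function(vol_norm, mask, n_superpixels = 50L, compactness = 0.1,
                   max_iter = 10L) {
  stopifnot(inherits(vol_norm, "ct_volume"))
  mask <- mask_as_logical(mask, dim(vol_norm$data))
  nvox <- sum(mask)
  if (nvox == 0L) stop("empty mask")
  labels <- array(0L, dim(vol_norm$data))
  if (nvox <= n_superpixels) {
    warning("mask smaller than requested superpixel count; one superpixel per voxel")
    labels[mask] <- seq_len(nvox)
    return(structure(list(labels = labels, n = nvox, sizes = rep(1L, nvox)),
                     class = "superpixel_map"))
  }
  coords <- which(mask, arr.ind = TRUE)
  phys <- sweep(coords, 2, vol_norm$spacing, `*`)
  intens <- vol_norm$data[mask]
  voxvol <- prod(vol_norm$spacing)
  S <- (nvox * voxvol / n_superpixels)^(1 / 3)  # expected superpixel radius scale, mm
  # seed on a regular mm grid, snapped to the nearest mask voxel
  rng <- apply(phys, 2, range)
  gs <- lapply(1:3, function(k) {
    n <- max(1L, round((rng[2, k] - rng[1, k]) / S))
    seq(rng[1, k], rng[2, k], length.out = n + 2)[-c(1, n + 2)]
  })
  seeds <- as.matrix(expand.grid(gs[[1]], gs[[2]], gs[[3]]))
  snap <- unique(vapply(seq_len(nrow(seeds)), function(r) {
    which.min(colSums((t(phys) - seeds[r, ])^2))
  }, integer(1)))
  if (length(snap) > n_superpixels)
    snap <- snap[seq(1, length(snap), length.out = n_superpixels)]
  if (length(snap) < 2L)
    snap <- unique(c(snap, round(seq(1, nvox, length.out = min(n_superpixels, nvox)))))
  centers_sp <- phys[snap, , drop = FALSE]
  centers_in <- intens[snap]
  for (it in seq_len(max_iter)) {
    # squared joint distance of every voxel to every center
    d2 <- outer(rep(1, length(intens)), rep(0, nrow(centers_sp)))
    for (k in 1:3)
      d2 <- d2 + outer(phys[, k], centers_sp[, k], `-`)^2 / S^2 * compactness^2
    d2 <- d2 + outer(intens, centers_in, `-`)^2
    assign <- max.col(-d2, ties.method = "first")
    new_sp <- centers_sp
    for (k in 1:3)
      new_sp[, k] <- tapply(phys[, k], factor(assign, levels = seq_len(nrow(centers_sp))),
                            mean)
    new_in <- tapply(intens, factor(assign, levels = seq_len(nrow(centers_sp))), mean)
    keep <- !is.na(new_in)
    centers_sp <- new_sp[keep, , drop = FALSE]
    centers_in <- as.numeric(new_in[keep])
    if (it == max_iter) {
      assign <- as.integer(factor(assign, levels = which(keep)))
    }
  }
  labels[mask] <- assign
  labels <- enforce_connectivity(labels, mask)
  sizes <- tabulate(labels[mask])
  structure(list(labels = labels, n = max(labels), sizes = sizes),
            class = "superpixel_map")
}

# Split disconnected superpixels into their 26-connected components and
# merge every non-dominant fragment into an adjacent superpixel by growing a
# frontier from the dominant (kept) regions. Deterministic; every final
# superpixel is spatially connected.
enforce_connectivity <- function(labels, mask) {
  bb <- which(mask, arr.ind = TRUE)
  rr <- range(bb[, 1]); rc <- range(bb[, 2]); rs <- range(bb[, 3])
  sub <- list(rr[1]:rr[2], rc[1]:rc[2], rs[1]:rs[2])
  m <- mask[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  lab <- labels[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  lab[!m] <- NA_integer_
  dims <- dim(lab)
  comp <- label_zones(lab)
  cm <- comp[m]; lm <- lab[m]
  csize <- tabulate(cm)
  clab <- lm[match(seq_along(csize), cm)]
  dominant <- logical(length(csize))
  for (l in unique(clab)) {
    cc <- which(clab == l)
    dominant[cc[which.max(csize[cc])]] <- TRUE
  }
  orphan <- array(FALSE, dims)
  orphan[m] <- !dominant[cm]
  if (any(orphan)) {
    offs <- neighbor_offsets()
    fixed <- lab
    fixed[orphan] <- NA_integer_
    while (any(orphan)) {
      cand <- array(NA_integer_, dims)
      for (r in seq_len(nrow(offs))) {
        sr <- shift_ranges(dims, offs[r, ])
        if (is.null(sr)) next
        nb <- array(NA_integer_, dims)
        nb[sr$a[[1]], sr$a[[2]], sr$a[[3]]] <-
          fixed[sr$b[[1]], sr$b[[2]], sr$b[[3]]]
        take <- orphan & is.na(cand) & !is.na(nb)
        cand[take] <- nb[take]
      }
      got <- orphan & !is.na(cand)
      if (!any(got)) break  # isolated fragments keep their own label
      fixed[got] <- cand[got]
      orphan[got] <- FALSE
    }
    fixed[orphan] <- lab[orphan]
    lab <- fixed
  }
  out <- array(0L, dim(labels))
  full <- array(NA_integer_, dim(labels))
  full[sub[[1]], sub[[2]], sub[[3]]] <- lab
  out[mask] <- as.integer(factor(full[mask]))
  out
}

#' First-order statistics of each superpixel
#'
#' Ten gray-level histogram statistics per superpixel: mean, median,
#' population variance, skewness, excess kurtosis, minimum, maximum, 10th and
#' 90th percentiles, and histogram entropy (25 equal-width bins over the
#' superpixel's intensity range). Single-voxel superpixels get variance,
#' skewness and kurtosis 0 by convention.
#'
#' @param vol_norm a [ct_volume] (z-normalized intensities).
#' @param spmap a `superpixel_map` from [slic3d()].
#' @return Numeric matrix S x 10 with named columns.
#' @export
superpixel_features <- function(vol_norm, spmap) {
  stopifnot(inherits(vol_norm, "ct_volume"), inherits(spmap, "superpixel_map"))
  inm <- spmap$labels > 0
  vals <- vol_norm$data[inm]
  ids <- spmap$labels[inm]
  S <- spmap$n
  out <- matrix(NA_real_, S, 10,
                dimnames = list(NULL, c("mean", "median", "variance", "skewness",
                                        "kurtosis", "min", "max", "p10", "p90",
                                        "entropy")))
  for (s in seq_len(S)) {
    v <- vals[ids == s]
    mu <- mean(v)
    m2 <- mean((v - mu)^2)
    sk <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
    ku <- if (m2 > 0) mean((v - mu)^4) / m2^2 - 3 else 0
    q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
    if (max(v) > min(v)) {
      h <- tabulate(pmin(floor((v - min(v)) / (max(v) - min(v)) * 25) + 1L, 25L),
                    nbins = 25L)
      pk <- h[h > 0] / length(v)
      ent <- -sum(pk * log2(pk))
    } else ent <- 0
    out[s, ] <- c(mu, stats::median(v), m2, sk, ku, min(v), max(v), q[1], q[2], ent)
  }
  out
}
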