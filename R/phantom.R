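#' Configuration for a synthetic nodule cohort
#'
#' Defines the generative conditions for a cohort of subpleural lung nodule
#' phantoms: cohort size, pleural-invasion prevalence, per-scanner batch
#' effects, and the logit coefficients that link the invasion label to
#' standardized geometric and texture covariates (solid-component diameter,
#' solid--pleural contact length, peripheral-rim texture).
#'
#' @param n_cases number of cases (>= 2 per batch).
#' @param vpi_prevalence marginal invasion prevalence in (0, 1).
#' @param batch_shift additive HU shift per batch.
#' @param batch_scale multiplicative HU scale per batch.
#' @param batch_noise_sd additive Gaussian noise sd per batch (HU).
#' @param effect_sizes named logit coefficients for standardized
#'   `solid_diameter`, `spl` and `rim_texture`.
#' @param diameter_range sampling range of maximal nodule diameter (mm),
#'   upper bound below the 30 mm inclusion limit.
#' @param part_solid_fraction probability that a nodule is part-solid.
#' @param ctr_range sampling range of the consolidation-to-tumor ratio for
#'   part-solid nodules (fractions; default 0.3 to 0.95). High-CTR nodules
#'   have sub-resolution ground-glass shells.
#' @param attach_fraction probability of pleural attachment (DLP = 0).
#' @param subregion_hu mean HU of the rim / transition / core (solid)
#'   subregions.
#' @param rim_texture_range per-case range of the rim speckle fraction: the
#'   proportion of rim voxels carrying a high-attenuation (+250 HU) speckle
#'   component, emulating irregular infiltration of the peripheral subregion.
#'   The realized fraction is the latent rim-texture covariate of the label
#'   model.
#' @param spacing voxel spacing of generated volumes (mm).
#' @param seed RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 192L,
                          vpi_prevalence = 0.38,
                          batch_shift = c(0, 15, -15, 25, -25),
                          batch_scale = c(1, 1.03, 0.97, 1.05, 0.95),
                          batch_noise_sd = c(35, 40, 45, 38, 42),
                          effect_sizes = c(solid_diameter = 1.2, spl = 0.9,
                                           rim_texture = 0.7),
                          diameter_range = c(10, 28),
                          part_solid_fraction = 0.6,
                          ctr_range = c(0.3, 0.95),
                          attach_fraction = 0.55,
                          subregion_hu = c(rim = -600, transition = -300, core = 20),
                          rim_texture_range = c(0.1, 0.5),
                          spacing = c(1, 1, 1),
                          seed = 1L) {
  if (vpi_prevalence <= 0 || vpi_prevalence >= 1)
    stop("`vpi_prevalence` must lie strictly inside (0, 1)")
  nb <- length(batch_shift)
  if (length(batch_scale) != nb || length(batch_noise_sd) != nb)
    stop("batch effect vectors must share one length")
  if (n_cases < 2L * nb) stop("need at least 2 cases per batch")
  if (diameter_range[2] >= 30) stop("maximal diameter must stay below 30 mm")
  structure(list(n_cases = as.integer(n_cases), vpi_prevalence = vpi_prevalence,
                 batch_shift = batch_shift, batch_scale = batch_scale,
                 batch_noise_sd = batch_noise_sd, effect_sizes = effect_sizes,
                 diameter_range = diameter_range,
                 part_solid_fraction = part_solid_fraction,
                 ctr_range = ctr_range,
                 attach_fraction = attach_fraction,
                 subregion_hu = subregion_hu,
                 rim_texture_range = rim_texture_range,
                 spacing = spacing, seed = as.integer(seed)),
            class = "cohort_config")
}

# Build one phantom case from sampled geometric/latent parameters.
build_phantom_case <- function(par, cfg) {
  sp <- cfg$spacing
  r <- par$max_diameter / 2
  rs <- par$solid_diameter / 2
  below <- 4; margin <- 5
  nx <- ceiling((par$max_diameter + 2 * margin) / sp[1])
  ny <- ceiling((par$max_diameter + 2 * margin) / sp[2])
  nz <- ceiling((below + par$dlp + par$max_diameter + margin) / sp[3])
  z_p <- below                                   # pleura plane (mm)
  cx <- nx * sp[1] / 2; cy <- ny * sp[2] / 2
  cz <- z_p + if (par$attached) r - par$push else par$dlp + r
  zs <- cz - (r - rs)                            # solid center: tangent at the bottom
  xc <- (seq_len(nx) - 0.5) * sp[1]
  yc <- (seq_len(ny) - 0.5) * sp[2]
  zc <- (seq_len(nz) - 0.5) * sp[3]
  X <- array(rep(xc, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(yc, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zc, each = nx * ny), c(nx, ny, nz))
  # lobulated lesion boundary: low-frequency sinusoidal perturbation of the radius
  amp <- par$lobul_amp
  pert <- 1 + amp * sin(par$ph1 + 2 * pi * (X - cx) / (2 * r)) *
    cos(par$ph2 + 2 * pi * (Y - cy) / (2 * r))
  rho <- sqrt((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) / (r * pert)
  lesion <- rho <= 1 & Z > z_p
  if (sum(lesion) < 30L) {  # guard tiny degenerate masks
    lesion <- sqrt((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) <= r & Z > z_p
  }
  dsol <- sqrt((X - cx)^2 + (Y - cy)^2 + (Z - zs)^2) / rs
  solid <- lesion & dsol <= 1
  subr <- array(0L, dim(lesion))
  if (par$part_solid) {
    # core = solid component; the ground-glass shell splits into a
    # transition zone (inner half) and a peripheral rim (outer half) via the
    # relative position between the two surfaces
    lam <- (1 - rho) / pmax((1 - rho) + (dsol - 1), .Machine$double.eps)
    subr[lesion] <- 1L                           # rim
    subr[lesion & lam > 0.5] <- 2L               # transition
    subr[solid] <- 3L                            # core
  } else {
    # solid nodules still show a thin partial-volume rim and transition band
    # against aerated lung at the lesion boundary
    subr[lesion] <- 3L
    subr[lesion & rho > 0.76] <- 2L
    subr[lesion & rho > 0.88] <- 1L
  }
  # intensities
  hu <- array(stats::rnorm(length(lesion), -850, 30), dim(lesion))
  wall <- Z <= z_p
  hu[wall] <- stats::rnorm(sum(wall), 20, 20)
  hu[subr == 1L] <- stats::rnorm(sum(subr == 1L), cfg$subregion_hu[["rim"]], 50)
  hu[subr == 2L] <- stats::rnorm(sum(subr == 2L), cfg$subregion_hu[["transition"]], 50)
  hu[subr == 3L] <- stats::rnorm(sum(subr == 3L), cfg$subregion_hu[["core"]], 40)
  # partial-volume blending keeps the rim of solid nodules slightly denser
  if (!par$part_solid) {
    rimv <- subr == 1L
    hu[rimv] <- hu[rimv] + 100
  }
  # subregion-level texture: a per-case fraction of rim voxels receives a
  # high-attenuation speckle component (the label-linked covariate), and the
  # transition zone receives an independent nuisance speckle of the same
  # form. Whole-lesion histogram statistics mix the two sources; only a
  # spatially resolved (habitat) analysis separates them.
  speckle <- function(region_idx, frac) {
    if (length(region_idx)) {
      spk <- region_idx[stats::runif(length(region_idx)) < frac]
      hu[spk] <<- hu[spk] + 150
    }
  }
  speckle(which(subr == 1L), par$rim_sd)
  speckle(which(subr == 2L), par$trans_speckle)
  # per-scanner batch effect: multiplicative, then additive, then noise
  b <- par$batch
  hu <- hu * cfg$batch_scale[b] + cfg$batch_shift[b]
  hu <- hu + stats::rnorm(length(hu), 0, cfg$batch_noise_sd[b])
  hu <- pmin(pmax(hu, -1024), 400)
  geometry <- list(center = c(cx, cy, cz),
                   max_diameter = par$max_diameter,
                   solid_diameter = par$solid_diameter,
                   pleura_plane_z = z_p,
                   dlp = if (par$attached) 0 else par$dlp,
                   pl = par$pl, spl = par$spl,
                   nodule_type = if (par$part_solid) "part_solid" else "solid")
  list(volume = ct_volume(hu, spacing = sp),
       lesion_mask = lesion, solid_mask = solid, subregion_truth = subr,
       geometry = geometry, batch_id = b, vpi_label = NA_integer_,
       rim_sd = par$rim_sd, case_id = par$case_id)
}

#' Generate a synthetic subpleural-nodule cohort
#'
#' Draws nodule geometry, builds the HU volumes with three latent intensity
#' subregions (peripheral rim, transition zone, solid core) abutting a planar
#' pleura, applies per-batch scanner effects, and samples the pleural
#' invasion label from a logistic model on the standardized solid-component
#' diameter, solid--pleural contact length and rim texture. Reproducible:
#' identical output for identical config (including seed).
#'
#' @param config a [cohort_config()].
#' @return An object of class `phantom_cohort`: list with `cases` (each as
#'   documented in [build_phantom_case]) and `meta` (one row per case:
#'   case_id, batch_id, vpi, geometry columns and the latent rim texture).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  sampled <- sample_cohort_parameters(config, reseed = FALSE)
  pars <- sampled$pars
  vpi <- sampled$meta$vpi
  n <- config$n_cases
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- build_phantom_case(pars[[i]], config)
    cases[[i]]$vpi_label <- vpi[i]
  }
  structure(list(cases = cases, meta = sampled$meta, config = config),
            class = "phantom_cohort")
}

#' Sample cohort geometry, batch assignment and invasion labels
#'
#' The parameter-level half of [generate_cohort()]: draws the nodule
#' geometry, latent rim texture, batch ids, and the invasion label from the
#' logistic link on standardized covariates, without building the image
#' volumes. Useful for calibration studies of the label model.
#'
#' @param config a [cohort_config()].
#' @param reseed set the RNG from `config$seed` (default TRUE; internal
#'   callers that already seeded pass FALSE).
#' @return List with `pars` (per-case parameter lists) and `meta`
#'   (the cohort metadata data.frame).
#' @export
sample_cohort_parameters <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (reseed) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed)
  }
  n <- config$n_cases
  nb <- length(config$batch_shift)
  pars <- vector("list", n)
  for (i in seq_len(n)) {
    md <- min(max(stats::rlnorm(1, log(19.5), 0.22), config$diameter_range[1]),
              config$diameter_range[2])
    part_solid <- stats::runif(1) < config$part_solid_fraction
    sd_ <- if (part_solid)
      stats::runif(1, config$ctr_range[1], config$ctr_range[2]) * md else md
    attached <- stats::runif(1) < config$attach_fraction
    r <- md / 2; rs <- sd_ / 2
    push <- stats::runif(1, 0.15, 0.6) * rs
    dlp <- if (attached) 0 else stats::runif(1, 0.5, 6)
    pl <- if (attached) 2 * sqrt(max(push * (2 * r - push), 0)) else 0
    spl <- if (attached) 2 * sqrt(max(push * (2 * rs - push), 0)) else 0
    pars[[i]] <- list(case_id = sprintf("case_%03d", i),
                      max_diameter = md, solid_diameter = sd_,
                      part_solid = part_solid, attached = attached,
                      push = push, dlp = dlp, pl = pl, spl = spl,
                      rim_sd = stats::runif(1, config$rim_texture_range[1],
                                            config$rim_texture_range[2]),
                      trans_speckle = stats::runif(1, config$rim_texture_range[1],
                                                   config$rim_texture_range[2]),
                      lobul_amp = stats::runif(1, 0.02, 0.06),
                      ph1 = stats::runif(1, 0, 2 * pi),
                      ph2 = stats::runif(1, 0, 2 * pi),
                      boundary_jitter = 0,
                      batch = ((i - 1L) %% nb) + 1L)
  }
  # invasion labels from standardized covariates
  sdv <- vapply(pars, function(p) p$solid_diameter, numeric(1))
  spl <- vapply(pars, function(p) p$spl, numeric(1))
  rsd <- vapply(pars, function(p) p$rim_sd, numeric(1))
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  es <- config$effect_sizes
  lp0 <- es[["solid_diameter"]] * zs(sdv) + es[["spl"]] * zs(spl) +
    es[["rim_texture"]] * zs(rsd)
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp0)) - config$vpi_prevalence,
                       c(-20, 20))$root
  vpi <- as.integer(stats::runif(n) < stats::plogis(b0 + lp0))
  meta <- data.frame(
    case_id = vapply(pars, `[[`, character(1), "case_id"),
    batch_id = vapply(pars, `[[`, integer(1), "batch"),
    vpi = vpi,
    max_diameter = vapply(pars, `[[`, numeric(1), "max_diameter"),
    solid_diameter = sdv,
    dlp = vapply(pars, function(p) if (p$attached) 0 else p$dlp, numeric(1)),
    pl = vapply(pars, `[[`, numeric(1), "pl"),
    spl = spl,
    ctr = 100 * sdv / vapply(pars, `[[`, numeric(1), "max_diameter"),
    nodule_type = ifelse(vapply(pars, `[[`, logical(1), "part_solid"),
                         "part_solid", "solid"),
    rim_texture = rsd,
    stringsAsFactors = FALSE)
  list(pars = pars, meta = meta)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d cases, %d batches, VPI prevalence %.2f\n",
              nrow(x$meta), length(unique(x$meta$batch_id)), mean(x$meta$vpi)))
  invisible(x)
}

#' Measure radiological features of a phantom case from its masks
#'
#' Recomputes the quantitative radiological metrics on the voxel grid:
#' maximal diameter and solid-component diameter (largest pairwise surface
#' distance), consolidation-to-tumor ratio
#' CTR = 100 x solid_diameter / max_diameter, the shortest lesion--pleura
#' distance (DLP), and the lesion-- and solid--pleural contact lengths (PL,
#' SPL) measured as the maximal in-plane chord of the mask layer adjacent to
#' the pleura plane.
#'
#' @param case one element of `generate_cohort()$cases`.
#' @return List with `max_diameter`, `solid_diameter`, `ctr`, `dlp`, `pl`,
#'   `spl` (all mm except `ctr` in percent).
#' @export
measure_radiological <- function(case) {
  if (!any(case$lesion_mask)) stop("empty lesion mask")
  sp <- case$volume$spacing
  z_p <- case$geometry$pleura_plane_z
  md <- unname(shape_features(case$lesion_mask, sp)["shape_Maximum3DDiameter"])
  sdm <- if (any(case$solid_mask))
    unname(shape_features(case$solid_mask, sp)["shape_Maximum3DDiameter"]) else 0
  coords <- which(case$lesion_mask, arr.ind = TRUE)
  zmm <- (coords[, 3] - 0.5) * sp[3]
  dlp <- max(0, min(zmm) - z_p - sp[3] / 2)
  chord <- function(mask) {
    cc <- which(mask, arr.ind = TRUE)
    zc <- (cc[, 3] - 0.5) * sp[3]
    layer <- cc[zc <= z_p + sp[3], , drop = FALSE]
    if (nrow(layer) < 2L) return(0)
    pts <- sweep(layer[, 1:2, drop = FALSE], 2, sp[1:2], `*`)
    g <- tcrossprod(pts); sq <- diag(g)
    sqrt(max(outer(sq, sq, `+`) - 2 * g, 0))
  }
  pl <- if (dlp == 0) chord(case$lesion_mask) else 0
  spl <- if (dlp == 0) chord(case$solid_mask) else 0
  list(max_diameter = md, solid_diameter = sdm,
       ctr = 100 * sdm / md, dlp = dlp, pl = pl, spl = spl)
}

#' Simulate two raters re-measuring the same quantities
#'
#' Adds independent Gaussian measurement jitter to a vector or table of
#' measurements twice, producing the paired replicates needed for
#' inter-observer agreement (ICC) analysis.
#'
#' @param measurements numeric vector or matrix/data.frame of true values.
#' @param sd measurement noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return List with components `rater1` and `rater2`.
#' @export
rater_noise <- function(measurements, sd, seed = 1L) {
  if (sd < 0) stop("`sd` must be non-negative")
  m <- as.matrix(measurements)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  r1 <- m + stats::rnorm(length(m), 0, sd)
  r2 <- m + stats::rnorm(length(m), 0, sd)
  list(rater1 = r1, rater2 = r2)
}
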