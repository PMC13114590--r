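# End-to-end orchestration: synthetic cohort -> preprocessing -> habitats ->
# feature extraction -> harmonization -> signatures -> evaluation, with a
# reproducibility manifest; plus NIfTI cohort I/O and model serialization.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param split named split fractions summing to 1; `train` and `validation`
#'   (default 0.7 / 0.3), optionally `test`. Cases are split in deterministic
#'   case-id order (emulating a scan-date-ordered split).
#' @param K number of habitats (default 3).
#' @param n_superpixels SLIC superpixels per lesion (default 50).
#' @param compactness SLIC compactness (default 0.1).
#' @param n_bins gray-level bins (default 25).
#' @param harmonize apply batch harmonization (default TRUE).
#' @param seed stage seed for clustering / CV folds / imputation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       split = c(train = 0.7, validation = 0.3),
                       K = 3L, n_superpixels = 50L, compactness = 0.1,
                       n_bins = 25L, harmonize = TRUE, seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(names(split)) || !all(c("train", "validation") %in% names(split)))
    stop("split must name at least `train` and `validation`")
  structure(list(cohort = cohort, split = split, K = as.integer(K),
                 n_superpixels = as.integer(n_superpixels),
                 compactness = compactness, n_bins = as.integer(n_bins),
                 harmonize = isTRUE(harmonize), seed = as.integer(seed)),
            class = "run_config")
}

# Content hash of an R object (for the manifest).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

split_indices <- function(case_ids, split) {
  ord <- order(case_ids)
  n <- length(ord)
  n_train <- round(split[["train"]] * n)
  n_val <- if ("test" %in% names(split))
    round(split[["validation"]] * n) else n - n_train
  out <- list(train = ord[seq_len(n_train)],
              validation = ord[n_train + seq_len(n_val)])
  if ("test" %in% names(split) && n_train + n_val < n)
    out$test <- ord[(n_train + n_val + 1):n]
  out
}

#' Run the full habitat-radiomics pipeline on a synthetic cohort
#'
#' Executes: cohort simulation, per-case preprocessing (isotropic resampling,
#' lung-window clipping, z-normalization), SLIC superpixels, habitat K-means
#' fitted on the training split and frozen elsewhere, whole-lesion and
#' per-habitat feature extraction, random-forest imputation of missing
#' habitat blocks, batch harmonization fitted on training, the
#' selection chain and three logistic signatures (radiological, whole-lesion
#' radiomic, habitat), and per-split evaluation. All stochastic stages are
#' seeded; two runs with the same config produce identical results.
#'
#' @param config a [run_config()].
#' @return An object of class `pipeline_result`: `models` (cluster model +
#'   signatures), `features`, `evaluation` (per split), `audit` (batch R^2),
#'   `habitat_missing` (per-split imputed-block counts), `splits`, `meta` and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  spec <- preproc_spec(n_bins = config$n_bins)
  cohort <- generate_cohort(config$cohort)
  n <- nrow(cohort$meta)
  splits <- split_indices(cohort$meta$case_id, config$split)
  # ---- preprocessing + superpixels ---------------------------------------
  prep <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- cohort$cases[[i]]
    vol <- resample_isotropic(cs$volume, spec)
    mask_v <- ct_volume(cs$lesion_mask + 0, spacing = cs$volume$spacing)
    mask <- resample_isotropic(mask_v, spec, method = "nearest")$data > 0
    vol <- clip_window(vol, spec)
    voln <- znormalize(vol, mask)
    sp <- slic3d(voln, mask, n_superpixels = config$n_superpixels,
                 compactness = config$compactness)
    prep[[i]] <- list(vol = vol, voln = voln, mask = mask, spmap = sp,
                      spfeat = superpixel_features(voln, sp))
  }
  # ---- habitat model on pooled training superpixels ----------------------
  pooled <- do.call(rbind, lapply(prep[splits$train], `[[`, "spfeat"))
  cmodel <- fit_habitat_model(pooled, K = config$K, seed = config$seed)
  # ---- feature extraction ------------------------------------------------
  whole <- matrix(NA_real_, n, 106,
                  dimnames = list(cohort$meta$case_id, feature_catalog()$name))
  hab <- matrix(NA_real_, n, 93 * config$K)
  radiol <- matrix(NA_real_, n, 6,
                   dimnames = list(cohort$meta$case_id,
                                   c("max_diameter", "solid_diameter", "ctr",
                                     "dlp", "pl", "spl")))
  for (i in seq_len(n)) {
    hm <- assign_habitats(prep[[i]]$voln, prep[[i]]$spmap, cmodel)
    fv <- extract_whole(prep[[i]]$vol, prep[[i]]$mask, n_bins = config$n_bins)
    whole[i, ] <- fv
    hv <- extract_per_habitat(prep[[i]]$vol, hm, K = config$K,
                              n_bins = config$n_bins)
    if (i == 1L) colnames(hab) <- names(hv)
    hab[i, ] <- hv
    m <- measure_radiological(cohort$cases[[i]])
    radiol[i, ] <- unlist(m)[colnames(radiol)]
  }
  # ---- impute missing habitat blocks (per split, training as reference) --
  missing_blocks <- c(train = 0L, validation = 0L, test = 0L)
  imp_tr <- impute_missing_habitats(hab[splits$train, , drop = FALSE],
                                    seed = config$seed)
  hab[splits$train, ] <- imp_tr$table
  missing_blocks["train"] <- imp_tr$n_imputed_blocks
  for (s in setdiff(names(splits), "train")) {
    rows <- splits[[s]]
    block <- rbind(hab[splits$train, , drop = FALSE], hab[rows, , drop = FALSE])
    imp <- impute_missing_habitats(block, seed = config$seed)
    hab[rows, ] <- imp$table[nrow(imp_tr$table) + seq_along(rows), , drop = FALSE]
    missing_blocks[s] <- imp$n_imputed_blocks
  }
  # ---- harmonization -----------------------------------------------------
  feats <- cbind(whole, hab)
  audit <- NULL
  if (config$harmonize) {
    tr_batch <- cohort$meta$batch_id[splits$train]
    cb <- fit_combat(feats[splits$train, , drop = FALSE], tr_batch)
    harmonized <- feats
    harmonized[splits$train, ] <-
      apply_combat(cb, feats[splits$train, , drop = FALSE], tr_batch)
    for (s in setdiff(names(splits), "train")) {
      rows <- splits[[s]]
      harmonized[rows, ] <- apply_combat(cb, feats[rows, , drop = FALSE],
                                         cohort$meta$batch_id[rows])
    }
    audit <- combat_audit(feats[splits$train, , drop = FALSE],
                          harmonized[splits$train, , drop = FALSE], tr_batch)
    feats <- harmonized
  } else cb <- NULL
  # ---- signatures --------------------------------------------------------
  y <- cohort$meta$vpi
  ytr <- y[splits$train]
  # radiological: univariate logistic screen then backward elimination on
  # the raw-scale quantitative measurements
  uni_p <- vapply(colnames(radiol), function(f) {
    fit <- stats::glm(ytr ~ radiol[splits$train, f], family = stats::binomial())
    summary(fit)$coefficients[2, 4]
  }, numeric(1))
  rad_cand <- names(uni_p)[uni_p < 0.05]
  if (length(rad_cand) == 0L) rad_cand <- names(sort(uni_p))[1:2]
  rad_cand <- rad_cand[order(uni_p[rad_cand])]
  # small cohorts can separate perfectly on correlated geometry features:
  # retry with progressively fewer (weakest-first-dropped) candidates
  sig_radiol <- NULL
  while (is.null(sig_radiol) && length(rad_cand) >= 1L) {
    sig_radiol <- tryCatch(
      backward_logistic(radiol[splits$train, rad_cand, drop = FALSE],
                        ytr, name = "radiological"),
      error = function(e) NULL)
    if (is.null(sig_radiol)) rad_cand <- rad_cand[-length(rad_cand)]
  }
  if (is.null(sig_radiol)) {
    # separated even on single measurements: fall back to a penalized fit
    las <- lasso_select(scale(radiol[splits$train, , drop = FALSE]), ytr,
                        seed = config$seed)
    if (!length(las$features)) {
      rg <- glmnet::glmnet(scale(radiol[splits$train, , drop = FALSE]), ytr,
                           family = "binomial", alpha = 0, lambda = 0.1,
                           standardize = FALSE)
      cc <- as.matrix(stats::coef(rg))[, 1]
      las <- list(features = names(cc)[-1], coefficients = cc[-1],
                  intercept = unname(cc[1]))
    }
    zs <- list(mean = colMeans(radiol[splits$train, las$features, drop = FALSE]),
               sd = apply(radiol[splits$train, las$features, drop = FALSE], 2,
                          stats::sd))
    zfeat <- sweep(sweep(radiol[splits$train, las$features, drop = FALSE], 2,
                         zs$mean), 2, zs$sd, `/`)
    probs <- stats::plogis(las$intercept +
                             as.numeric(zfeat %*% las$coefficients))
    sig_radiol <- signature_model("radiological", las$intercept,
                                  las$coefficients,
                                  cutoff = youden_cutoff(probs, ytr),
                                  zstats = zs)
  }
  sig_radiom <- build_signature(feats[splits$train, colnames(whole), drop = FALSE],
                                ytr, name = "radiomic", seed = config$seed)
  sig_hab <- build_signature(feats[splits$train, colnames(hab), drop = FALSE],
                             ytr, name = "habitat", seed = config$seed)
  models <- list(cluster = cmodel, combat = cb,
                 radiological = sig_radiol,
                 radiomic = sig_radiom$model, habitat = sig_hab$model)
  traces <- list(radiomic = sig_radiom$trace, habitat = sig_hab$trace)
  # ---- evaluation --------------------------------------------------------
  evaluation <- list()
  for (s in names(splits)) {
    rows <- splits[[s]]
    probs <- list(
      radiological = predict_signature(sig_radiol,
                                       radiol[rows, , drop = FALSE])$probability,
      radiomic = predict_signature(sig_radiom$model,
                                   feats[rows, , drop = FALSE])$probability,
      habitat = predict_signature(sig_hab$model,
                                  feats[rows, , drop = FALSE])$probability)
    cutoffs <- c(radiological = sig_radiol$cutoff,
                 radiomic = sig_radiom$model$cutoff,
                 habitat = sig_hab$model$cutoff)
    evaluation[[s]] <- evaluate_models(probs, cutoffs, y[rows])
    evaluation[[s]]$probs <- probs
  }
  manifest <- list(
    params = list(split = config$split, K = config$K,
                  n_superpixels = config$n_superpixels,
                  compactness = config$compactness, n_bins = config$n_bins,
                  harmonize = config$harmonize),
    seeds = c(cohort = config$cohort$seed, stages = config$seed),
    hashes = c(cohort = object_hash(cohort$meta),
               features = object_hash(feats),
               cluster_model = object_hash(cmodel),
               signatures = object_hash(models[c("radiological", "radiomic",
                                                 "habitat")]),
               evaluation = object_hash(evaluation)),
    wall_clock = Sys.time())
  structure(list(models = models, traces = traces, features = feats,
                 radiological_features = radiol, evaluation = evaluation,
                 audit = audit, habitat_missing = missing_blocks,
                 splits = splits, meta = cohort$meta, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("habitat radiomics pipeline result\n")
  for (s in names(x$evaluation)) {
    cat("--", s, "--\n")
    print(x$evaluation[[s]]$per_model[, c("model", "auc", "sensitivity_pct",
                                          "specificity_pct", "brier")],
          row.names = FALSE)
  }
  invisible(x)
}

# ---- cohort I/O ----------------------------------------------------------

#' Write / read a phantom cohort as NIfTI volumes plus metadata CSV
#'
#' Each case is stored as `<case_id>_ct.nii.gz` with `_lesion`, `_solid` and
#' `_subregions` label maps; cohort metadata goes to `cohort.csv`.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort`: the directory, invisibly. `read_cohort`: a list
#'   with `cases` (volume + masks as arrays) and `meta`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cohort$cases) {
    base <- file.path(dir, cs$case_id)
    wr <- function(arr, suffix) {
      img <- RNifti::asNifti(arr + 0)
      RNifti::pixdim(img) <- cs$volume$spacing
      RNifti::writeNifti(img, paste0(base, suffix))
    }
    wr(cs$volume$data, "_ct.nii.gz")
    wr(cs$lesion_mask, "_lesion.nii.gz")
    wr(cs$solid_mask, "_solid.nii.gz")
    wr(cs$subregion_truth, "_subregions.nii.gz")
  }
  meta <- cohort$meta
  meta$pleura_plane_z <- vapply(cohort$cases,
                                function(cs) cs$geometry$pleura_plane_z,
                                numeric(1))
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort.csv")
  if (!file.exists(meta_path)) stop("no cohort.csv in ", dir)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$case_id[i]
    base <- file.path(dir, id)
    ct_path <- paste0(base, "_ct.nii.gz")
    if (!file.exists(ct_path)) stop("missing volume for case ", id)
    img <- RNifti::readNifti(ct_path)
    spacing <- RNifti::pixdim(img)[1:3]
    rd <- function(suffix) {
      p <- paste0(base, suffix)
      if (!file.exists(p)) stop("missing mask for case ", id)
      arr <- as.array(RNifti::readNifti(p))
      if (!identical(dim(arr), dim(as.array(img))))
        stop("mask grid does not match volume grid for case ", id)
      arr
    }
    list(case_id = id,
         volume = ct_volume(as.array(img), spacing = spacing),
         lesion_mask = rd("_lesion.nii.gz") > 0,
         solid_mask = rd("_solid.nii.gz") > 0,
         subregion_truth = rd("_subregions.nii.gz"),
         geometry = list(pleura_plane_z = meta$pleura_plane_z[i]),
         batch_id = meta$batch_id[i],
         vpi_label = if ("vpi" %in% names(meta)) meta$vpi[i] else NA_integer_)
  })
  list(cases = cases, meta = meta)
}

# ---- model serialization -------------------------------------------------

#' Serialize and restore the fitted models
#'
#' Writes the frozen cluster model and the three logistic signatures to one
#' JSON file at full numeric precision; reloading reproduces identical
#' predictions. Files with a different format version are refused.
#'
#' @param models list with `cluster` (a `cluster_model`) and
#'   `signature_model` entries.
#' @param path JSON file path.
#' @return `serialize_models`: the path, invisibly. `load_models`: the
#'   restored list.
#' @export
serialize_models <- function(models, path) {
  sigs <- models[vapply(models, inherits, logical(1), "signature_model")]
  obj <- list(type = "habitomics_models", version = 1L,
              cluster = if (!is.null(models$cluster)) list(
                K = models$cluster$K, centroids = models$cluster$centroids,
                feat_mean = models$cluster$feat_mean,
                feat_sd = models$cluster$feat_sd, seed = models$cluster$seed),
              signatures = lapply(sigs, function(m) list(
                name = m$name, intercept = m$intercept,
                coefficients = as.list(m$coefficients), cutoff = m$cutoff,
                z_mean = if (!is.null(m$zstats)) as.list(m$zstats$mean[names(m$coefficients)]),
                z_sd = if (!is.null(m$zstats)) as.list(m$zstats$sd[names(m$coefficients)]))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialize_models
#' @export
load_models <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("unreadable model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$type) || obj$type != "habitomics_models")
    stop("not a habitomics model file")
  if (obj$version != 1L) stop("unsupported model file version ", obj$version)
  out <- list()
  if (!is.null(obj$cluster))
    out$cluster <- structure(list(K = as.integer(obj$cluster$K),
                                  centroids = as.matrix(obj$cluster$centroids),
                                  feat_mean = unlist(obj$cluster$feat_mean),
                                  feat_sd = unlist(obj$cluster$feat_sd),
                                  seed = as.integer(obj$cluster$seed)),
                             class = "cluster_model")
  for (nm in names(obj$signatures)) {
    s <- obj$signatures[[nm]]
    zst <- if (!is.null(s$z_mean))
      list(mean = unlist(s$z_mean), sd = unlist(s$z_sd))
    out[[nm]] <- signature_model(name = s$name, intercept = s$intercept,
                                 coefficients = unlist(s$coefficients),
                                 cutoff = s$cutoff, zstats = zst)
  }
  out
}

#' The three published-equation reference signatures
#'
#' Loads the reference logistic signatures shipped with the package
#' (radiological, whole-lesion radiomic, habitat), whose intercepts,
#' coefficients and classification cutoffs encode the published multicenter
#' model equations. They operate on z-scored radiomic features (the radiomic
#' and habitat signatures) or raw millimetre measurements (the radiological
#' signature).
#'
#' @return Named list of three `signature_model` objects.
#' @export
reference_signatures <- function() {
  path <- system.file("extdata", "reference_signatures.json",
                      package = "habitomics", mustWork = TRUE)
  load_models(path)
}
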