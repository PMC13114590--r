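# Feature-level batch harmonization: parametric empirical-Bayes
# location-scale adjustment fitted on training data, with the fitted
# parameters reusable (frozen) on new cohorts, plus a batch-variance audit.

# Iterative EB solution for one batch's location/scale (standard parametric
# ComBat estimator).
eb_solve <- function(sdat_b, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                     conv = 1e-4, max_iter = 200L) {
  n <- colSums(!is.na(sdat_b))
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums(sweep(sdat_b, 2, g_new)^2)
    d_new <- (b_prior + 0.5 * sum2) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Fit an empirical-Bayes batch harmonization model
#'
#' Parametric location-scale harmonization of a feature table across scanner
#' batches: features are standardized against a batch-weighted grand mean and
#' pooled variance, per-batch location (gamma) and scale (delta) parameters
#' are estimated and shrunk toward common normal / inverse-gamma priors, and
#' the fitted parameters are stored so they can be applied unchanged to
#' validation or test cohorts. Optional covariates (e.g., a biological label)
#' are protected: their fitted effects are left in the data.
#'
#' @param table numeric matrix/data.frame, cases x features.
#' @param batch batch labels, one per case; every batch needs >= 2 cases.
#' @param covariates optional numeric design matrix (cases x q) of biological
#'   covariates to preserve.
#' @return An object of class `combat_model`.
#' @export
fit_combat <- function(table, batch, covariates = NULL) {
  x <- as.matrix(table)
  batch <- factor(batch)
  if (nrow(x) != length(batch)) stop("batch length must match rows of table")
  tb <- table(batch)
  if (any(tb < 2L))
    stop("singleton batch: ", paste(names(tb)[tb < 2L], collapse = ", "))
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning(sum(const), " zero-variance feature(s) passed through unchanged")
  xw <- x[, !const, drop = FALSE]
  B <- nlevels(batch); n <- nrow(xw); p <- ncol(xw)
  bd <- vapply(levels(batch), function(l) as.numeric(batch == l),
               numeric(n))                           # batch one-hot
  D <- if (is.null(covariates)) bd else cbind(bd, as.matrix(covariates))
  beta <- solve(crossprod(D), crossprod(D, xw))      # (B + q) x p
  grand_mean <- as.numeric(crossprod(tb / n, beta[seq_len(B), , drop = FALSE]))
  cov_beta <- if (is.null(covariates)) NULL else
    beta[-seq_len(B), , drop = FALSE]
  fitted_full <- D %*% beta
  var_pooled <- colSums((xw - fitted_full)^2) / n
  var_pooled[var_pooled <= 0] <- .Machine$double.eps
  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  if (!is.null(cov_beta))
    stand_mean <- stand_mean + as.matrix(covariates) %*% cov_beta
  sdat <- (xw - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)
  gamma_star <- delta_star <- matrix(NA_real_, B, p)
  g_hat <- matrix(NA_real_, B, p); d_hat <- matrix(NA_real_, B, p)
  for (b in seq_len(B)) {
    rows <- batch == levels(batch)[b]
    g_hat[b, ] <- colMeans(sdat[rows, , drop = FALSE])
    d_hat[b, ] <- apply(sdat[rows, , drop = FALSE], 2, stats::var)
  }
  d_hat[d_hat <= 0] <- .Machine$double.eps
  if (B == 1L) {
    gamma_star[1, ] <- 0; delta_star[1, ] <- 1
  } else {
    for (b in seq_len(B)) {
      g_bar <- mean(g_hat[b, ]); t2 <- stats::var(g_hat[b, ])
      m <- mean(d_hat[b, ]); s2 <- stats::var(d_hat[b, ])
      if (!is.finite(s2) || s2 <= 0) s2 <- .Machine$double.eps
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      rows <- batch == levels(batch)[b]
      sol <- eb_solve(sdat[rows, , drop = FALSE], g_hat[b, ], d_hat[b, ],
                      g_bar, max(t2, .Machine$double.eps), a_prior, b_prior)
      gamma_star[b, ] <- sol$gamma_star
      delta_star[b, ] <- pmax(sol$delta_star, .Machine$double.eps)
    }
  }
  structure(list(features = colnames(xw), const_features = colnames(x)[const],
                 batch_levels = levels(batch), grand_mean = grand_mean,
                 cov_beta = cov_beta, var_pooled = var_pooled,
                 gamma_star = gamma_star, delta_star = delta_star),
            class = "combat_model")
}

#' Apply a fitted harmonization model to a feature table
#'
#' Adjusts features with the frozen per-batch location/scale parameters from
#' [fit_combat()]. Batches unseen at fit time are an error. Zero-variance
#' features recorded at fit time pass through unchanged.
#'
#' @param model a `combat_model`.
#' @param table cases x features table (must contain the model's features).
#' @param batch batch labels, all known to the model.
#' @param covariates covariate matrix matching the fit design (if used).
#' @return The harmonized table (same dimensions and names as the input).
#' @export
apply_combat <- function(model, table, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- as.matrix(table)
  batch <- factor(batch, levels = model$batch_levels)
  if (anyNA(batch)) stop("unseen batch label(s) not present in the fitted model")
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  if (xor(is.null(model$cov_beta), is.null(covariates)))
    stop("covariate design must match the fit")
  out <- x
  xw <- x[, model$features, drop = FALSE]
  n <- nrow(xw); p <- ncol(xw)
  stand_mean <- matrix(model$grand_mean, n, p, byrow = TRUE)
  if (!is.null(model$cov_beta))
    stand_mean <- stand_mean + as.matrix(covariates) %*% model$cov_beta
  sdat <- (xw - stand_mean) / matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  bi <- as.integer(batch)
  adj <- (sdat - model$gamma_star[bi, , drop = FALSE]) /
    matrix(sqrt(model$delta_star[bi, , drop = FALSE]), n, p)
  out[, model$features] <- adj * matrix(sqrt(model$var_pooled), n, p, byrow = TRUE) +
    stand_mean
  out
}

#' Proportion of feature variance explained by batch
#'
#' Per-feature one-way ANOVA R^2 (between-batch sum of squares over total sum
#' of squares), averaged over features. Constant features have R^2 = 0 by
#' convention.
#'
#' @param table cases x features.
#' @param batch batch labels (>= 2 batches).
#' @return List with `per_feature` (named R^2 vector) and `mean_r2`.
#' @export
batch_r2 <- function(table, batch) {
  x <- as.matrix(table)
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need at least 2 batches")
  r2 <- apply(x, 2, function(v) {
    tot <- sum((v - mean(v))^2)
    if (tot == 0) return(0)
    gm <- tapply(v, batch, mean)
    nb <- tabulate(batch)
    sum(nb * (gm - mean(v))^2) / tot
  })
  list(per_feature = r2, mean_r2 = mean(r2))
}

#' Audit harmonization effectiveness
#'
#' Compares the batch-variance R^2 of a feature table before and after
#' harmonization: mean R^2 on both sides (reported in percent), the relative
#' reduction, and a paired t-test over the per-feature R^2 values.
#'
#' @param before,after cases x features tables.
#' @param batch batch labels.
#' @return An object of class `batch_audit` with `mean_r2_before_pct`,
#'   `mean_r2_after_pct`, `relative_reduction_pct`, `paired_p`, and the
#'   per-feature R^2 vectors.
#' @export
combat_audit <- function(before, after, batch) {
  rb <- batch_r2(before, batch)
  ra <- batch_r2(after, batch)
  tt <- stats::t.test(rb$per_feature, ra$per_feature, paired = TRUE)
  structure(list(mean_r2_before_pct = 100 * rb$mean_r2,
                 mean_r2_after_pct = 100 * ra$mean_r2,
                 relative_reduction_pct =
                   100 * (rb$mean_r2 - ra$mean_r2) / rb$mean_r2,
                 paired_p = tt$p.value,
                 per_feature_before = rb$per_feature,
                 per_feature_after = ra$per_feature),
            class = "batch_audit")
}

#' @export
print.batch_audit <- function(x, ...) {
  cat(sprintf(paste0("batch R2 audit: mean %.2f%% -> %.2f%% ",
                     "(relative reduction %.1f%%), paired p = %.3g\n"),
              x$mean_r2_before_pct, x$mean_r2_after_pct,
              x$relative_reduction_pct, x$paired_p))
  invisible(x)
}
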