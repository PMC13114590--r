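# Signature construction: z-scoring with frozen training statistics, the
# four-step feature-selection chain (Spearman prune -> Mann-Whitney screen ->
# mRMR -> LASSO), backward-elimination logistic fitting, Youden cutoffs and
# collinearity checks.

#' Z-score a feature table with training statistics
#'
#' Fits per-feature mean/sd on the training table (dropping zero-sd columns
#' with a warning) and returns the transform plus frozen statistics that can
#' be applied to validation/test tables.
#'
#' @param table cases x features (training data).
#' @param stats optional list with `mean` and `sd` (frozen statistics); when
#'   supplied, the table is transformed with them instead of refitting.
#' @return List with `table` (z-scored), `mean`, `sd`.
#' @export
zscore_features <- function(table, stats = NULL) {
  x <- as.matrix(table)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    drop <- sdv == 0 | !is.finite(sdv)
    if (any(drop)) {
      warning("dropping ", sum(drop), " zero-variance feature(s)")
      x <- x[, !drop, drop = FALSE]
      mu <- mu[!drop]; sdv <- sdv[!drop]
    }
  } else {
    mu <- stats$mean; sdv <- stats$sd
    x <- x[, names(mu), drop = FALSE]
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  list(table = z, mean = mu, sd = sdv)
}

#' Prune highly correlated features
#'
#' Greedy removal within pairs whose absolute Spearman correlation exceeds
#' the threshold: of each correlated pair, the feature with the weaker
#' univariate class association (larger Mann-Whitney p value; ties break to
#' the later column) is removed.
#'
#' @param table cases x features.
#' @param labels binary class labels (used for the keep/drop tie-break).
#' @param threshold correlation threshold (default 0.9).
#' @return Character vector of surviving feature names.
#' @export
spearman_prune <- function(table, labels, threshold = 0.9) {
  x <- as.matrix(table)
  p <- ncol(x)
  if (p < 2L) return(colnames(x))
  rho <- stats::cor(x, method = "spearman")
  pvals <- mw_pvalues(x, labels)
  keep <- rep(TRUE, p)
  ord <- order(pvals)  # strongest features claim survival first
  for (i in ord) {
    if (!keep[i]) next
    partners <- which(abs(rho[i, ]) > threshold & seq_len(p) != i & keep)
    keep[partners] <- FALSE
  }
  colnames(x)[keep]
}

mw_pvalues <- function(x, labels) {
  labels <- as.integer(labels)
  apply(x, 2, function(v) {
    g1 <- v[labels == 1]; g0 <- v[labels == 0]
    if (length(unique(v)) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(g1, g0)$p.value)
  })
}

#' Mann-Whitney screening of class-associated features
#'
#' Keeps features whose two-sided Mann-Whitney U test against the binary
#' label reaches `p < alpha`. Small samples without ties use the exact null
#' distribution; otherwise the normal approximation with tie correction is
#' used (the behavior of [stats::wilcox.test()]).
#'
#' @param table cases x features.
#' @param labels binary labels (both classes present).
#' @param alpha significance level (default 0.05).
#' @return List with `features` (survivors) and `p` (named p values).
#' @export
mannwhitney_screen <- function(table, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  x <- as.matrix(table)
  p <- mw_pvalues(x, labels)
  list(features = colnames(x)[p < alpha], p = p)
}

# Plug-in mutual information between two discretized vectors.
.mi_disc <- function(a, b) {
  tab <- table(a, b)
  pj <- tab / sum(tab)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

# Equal-frequency discretization into `q` bins.
.quantile_bins <- function(v, q = 4L) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = q + 1),
                               type = 7))
  if (length(br) < 2L) return(rep(1L, length(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection under the mutual-information difference (MID)
#' objective: at each step the feature maximizing
#' `MI(feature; label) - mean MI(feature; selected)` is added. Mutual
#' information is estimated on equal-frequency 4-bin discretized features.
#'
#' @param table cases x features.
#' @param labels binary labels.
#' @param k number of features to retain (default 10).
#' @param n_bins discretization bins for MI estimation.
#' @return Character vector of the selected feature names (in selection order).
#' @export
mrmr_select <- function(table, labels, k = 10L, n_bins = 4L) {
  x <- as.matrix(table)
  p <- ncol(x)
  if (k >= p) {
    if (k > p) warning("k exceeds the number of features; keeping all")
    return(colnames(x))
  }
  d <- apply(x, 2, .quantile_bins, q = n_bins)
  y <- as.integer(labels)
  rel <- apply(d, 2, .mi_disc, b = y)
  selected <- integer(0)
  red <- matrix(0, p, 0)
  for (step in seq_len(k)) {
    if (length(selected) == 0L) {
      cand_score <- rel
    } else {
      cand_score <- rel - rowMeans(red[, seq_along(selected), drop = FALSE])
    }
    cand_score[selected] <- -Inf
    pick <- which.max(cand_score)
    selected <- c(selected, pick)
    newcol <- vapply(seq_len(p), function(j)
      if (j %in% selected) 0 else .mi_disc(d[, j], d[, pick]), numeric(1))
    red <- cbind(red, newcol)
  }
  colnames(x)[selected]
}

#' LASSO-penalized logistic selection
#'
#' L1-penalized logistic regression path with the penalty chosen by
#' stratified 10-fold cross-validation at minimum deviance; features with
#' nonzero coefficients at the selected penalty survive.
#'
#' @param table cases x standardized features.
#' @param labels binary labels.
#' @param nfolds CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return List with `features`, `lambda`, and the nonzero `coefficients`.
#' @export
lasso_select <- function(table, labels, nfolds = 10L, seed = 1L) {
  x <- as.matrix(table)
  y <- as.integer(labels)
  if (ncol(x) < 2L) {
    # the penalized path needs >= 2 columns; a single candidate passes as-is
    fit <- stats::glm(y ~ x[, 1], family = stats::binomial())
    return(list(features = colnames(x), lambda = 0,
                coefficients = stats::setNames(stats::coef(fit)[2], colnames(x)),
                intercept = unname(stats::coef(fit)[1])))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # stratified folds; fold count cannot exceed the minority class size
  nfolds <- max(3L, min(nfolds, min(table(y))))
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  cv <- tryCatch(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                      foldid = foldid, standardize = FALSE),
    error = function(e) NULL)
  if (is.null(cv)) {
    # degenerate folds (minute cohorts): no CV; light ridge keeps the chain
    # going with finite coefficients
    rg <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 0.1,
                         standardize = FALSE)
    cc <- as.matrix(stats::coef(rg))[, 1]
    return(list(features = names(cc[-1])[cc[-1] != 0], lambda = 0.1,
                coefficients = cc[-1][cc[-1] != 0], intercept = unname(cc[1])))
  }
  co_all <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  co <- co_all[-1]
  nz <- co[co != 0]
  list(features = names(nz), lambda = cv$lambda.min, coefficients = nz,
       intercept = unname(co_all[1]))
}

#' Backward-elimination multivariate logistic model
#'
#' Fits a logistic regression and iteratively drops the coefficient with the
#' largest Wald p value until every remaining coefficient satisfies
#' `p < alpha_stay`. Reports odds ratios with Wald 95% confidence intervals.
#'
#' @param table cases x features (the candidate set).
#' @param labels binary labels.
#' @param alpha_stay stay threshold (default 0.05).
#' @param name signature name.
#' @param cutoff optional fixed probability cutoff; by default the Youden
#'   cutoff on the training probabilities is used.
#' @param zstats optional frozen z-score statistics carried into the model.
#' @return A `signature_model`: intercept, named coefficients, cutoff,
#'   `summary` data.frame (coefficient, OR, CI, p), and `zstats`.
#' @export
backward_logistic <- function(table, labels, alpha_stay = 0.05,
                              name = "signature", cutoff = NULL, zstats = NULL) {
  x <- as.data.frame(table)
  y <- as.integer(labels)
  feats <- colnames(x)
  repeat {
    if (length(feats) == 0L) stop("backward elimination removed all features")
    fit <- stats::glm(y ~ ., data = cbind(y = y, x[, feats, drop = FALSE]),
                      family = stats::binomial())
    if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15))
      stop("(quasi-)perfect separation while fitting: ",
           paste(feats, collapse = ", "))
    sm <- summary(fit)$coefficients
    pv <- sm[-1, 4]
    names(pv) <- rownames(sm)[-1]
    if (anyNA(pv)) stop("aliased coefficient in the multivariate fit")
    if (all(pv < alpha_stay)) break
    worst <- names(pv)[which.max(pv)]
    dropped <- make_names_inverse(worst, feats)
    if (!length(dropped) || !any(dropped %in% feats))
      stop("backward elimination could not map coefficient ", worst)
    feats <- setdiff(feats, dropped)
  }
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  keep_names <- feats
  coefs <- stats::setNames(co[-1], keep_names)
  summ <- data.frame(feature = keep_names,
                     coefficient = unname(co[-1]),
                     odds_ratio = exp(unname(co[-1])),
                     ci_low = exp(unname(co[-1] - 1.96 * se[-1])),
                     ci_high = exp(unname(co[-1] + 1.96 * se[-1])),
                     p = unname(summary(fit)$coefficients[-1, 4]),
                     stringsAsFactors = FALSE)
  probs <- stats::fitted(fit)
  if (is.null(cutoff)) cutoff <- youden_cutoff(probs, y)
  signature_model(name = name, intercept = unname(co[1]), coefficients = coefs,
                  cutoff = cutoff, summary = summ, zstats = zstats)
}

# glm may mangle non-syntactic names; map back to the original.
make_names_inverse <- function(mangled, originals) {
  m <- make.names(originals)
  hit <- originals[m == mangled | originals == mangled]
  if (length(hit) == 0L) mangled else hit[1]
}

#' Construct a logistic signature model
#'
#' @param name one of the signature names (free text).
#' @param intercept logistic intercept.
#' @param coefficients named numeric coefficients.
#' @param cutoff probability cutoff in (0, 1); predicted class is positive
#'   when the probability strictly exceeds it.
#' @param summary optional coefficient table.
#' @param zstats optional list(mean, sd) of frozen feature standardization.
#' @return An object of class `signature_model`.
#' @export
signature_model <- function(name, intercept, coefficients, cutoff,
                            summary = NULL, zstats = NULL) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, cutoff = cutoff,
                 summary = summary, zstats = zstats),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3f x %s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("%s signature: ln[p/(1-p)] = %.3f %s; cutoff %.3f\n",
              x$name, x$intercept, terms, x$cutoff))
  invisible(x)
}

#' Predict with a logistic signature
#'
#' Computes `p = plogis(intercept + sum(coef * x))` and the positive class
#' when `p` strictly exceeds the cutoff. If the model carries frozen z-score
#' statistics, raw features are standardized with them first.
#'
#' @param model a `signature_model`.
#' @param features cases x features table containing the model's features.
#' @param standardize apply the model's frozen z statistics (default TRUE
#'   when present).
#' @return data.frame with `probability` and `class`.
#' @export
predict_signature <- function(model, features, standardize = !is.null(model$zstats)) {
  stopifnot(inherits(model, "signature_model"))
  x <- as.matrix(as.data.frame(features))
  miss <- setdiff(names(model$coefficients), colnames(x))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- x[, names(model$coefficients), drop = FALSE]
  if (standardize && !is.null(model$zstats)) {
    mu <- model$zstats$mean[names(model$coefficients)]
    sdv <- model$zstats$sd[names(model$coefficients)]
    x <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  }
  lp <- model$intercept + as.numeric(x %*% model$coefficients)
  p <- stats::plogis(lp)
  data.frame(probability = p, class = as.integer(p > model$cutoff))
}

#' Youden-optimal probability cutoff
#'
#' Maximizes sensitivity + specificity - 1 over the observed probabilities;
#' ties break to the lower cutoff.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels (both classes present).
#' @return The cutoff (a probability).
#' @export
youden_cutoff <- function(probabilities, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cand <- sort(unique(probabilities))
  j <- vapply(cand, function(t) {
    sens <- mean(probabilities[y == 1] > t)
    spec <- mean(probabilities[y == 0] <= t)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]  # which.max returns the first (lowest) maximizer
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R^2_i)` from regressing each feature on all others.
#' Exact collinearity is reported as `Inf` with a warning.
#'
#' @param table cases x features (n > number of features, >= 2 features).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(table) {
  x <- as.matrix(table)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 features")
  if (nrow(x) <= p) stop("need more cases than features")
  out <- stats::setNames(numeric(p), colnames(x))
  for (i in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -i, drop = FALSE]), x[, i])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, i] - mean(x[, i]))^2)
    if (r2 >= 1 - 1e-12) {
      warning("exact collinearity for feature ", colnames(x)[i])
      out[i] <- Inf
    } else out[i] <- 1 / (1 - r2)
  }
  out
}

#' Run the full selection chain and fit a signature
#'
#' The four-step chain on z-scored training features: Spearman prune
#' (|rho| > 0.9), Mann-Whitney screen (p < 0.05), mRMR top-10, LASSO at the
#' CV-minimum penalty, followed by backward-elimination logistic fitting and
#' a Youden training cutoff. Returns the fitted signature plus the selection
#' trace (survivors of each step).
#'
#' @param table cases x raw features (training data).
#' @param labels binary labels.
#' @param name signature name.
#' @param seed RNG seed (CV folds).
#' @param mw_alpha Mann-Whitney screen level.
#' @param mrmr_k mRMR retention count.
#' @return List with `model` (a `signature_model`) and `trace` (named list of
#'   per-step survivor vectors).
#' @export
build_signature <- function(table, labels, name = "radiomic", seed = 1L,
                            mw_alpha = 0.05, mrmr_k = 10L) {
  zs <- zscore_features(table)
  z <- zs$table
  trace <- list(input = colnames(z))
  s1 <- spearman_prune(z, labels)
  trace$spearman <- s1
  scr <- mannwhitney_screen(z[, s1, drop = FALSE], labels, alpha = mw_alpha)
  s2 <- scr$features
  if (length(s2) == 0L) {
    # very small cohorts may pass nothing at alpha; continue with the
    # strongest candidates rather than aborting the chain
    warning("no feature passed the Mann-Whitney screen; keeping the ",
            min(mrmr_k, length(scr$p)), " smallest-p features")
    s2 <- names(sort(scr$p))[seq_len(min(mrmr_k, length(scr$p)))]
  }
  trace$mannwhitney <- s2
  s3 <- mrmr_select(z[, s2, drop = FALSE], labels, k = min(mrmr_k, length(s2)))
  trace$mrmr <- s3
  las <- lasso_select(z[, s3, drop = FALSE], labels, seed = seed)
  s4 <- las$features
  if (length(s4) == 0L) s4 <- s3  # fully shrunk path: fall back to mRMR set
  trace$lasso <- s4
  # small cohorts can reach (quasi-)separation in the multivariate fit;
  # retry with the weakest univariate feature dropped until the fit is stable
  pv <- mw_pvalues(z[, s4, drop = FALSE], labels)
  cand <- s4[order(pv)]
  model <- NULL
  while (is.null(model) && length(cand) >= 1L) {
    model <- tryCatch(
      backward_logistic(z[, cand, drop = FALSE], labels, name = name,
                        zstats = list(mean = zs$mean, sd = zs$sd)),
      error = function(e) NULL)
    if (is.null(model)) cand <- cand[-length(cand)]
  }
  if (is.null(model)) {
    # fully separated data: keep a penalized fit as the signature, whose
    # coefficients are finite by construction (L1 if it selected anything,
    # otherwise a light ridge on the mRMR set)
    if (length(las$features)) {
      co <- las$coefficients; b0 <- las$intercept; sel <- las$features
    } else {
      rg <- glmnet::glmnet(z[, s3, drop = FALSE], as.integer(labels),
                           family = "binomial", alpha = 0, lambda = 0.1,
                           standardize = FALSE)
      cc <- as.matrix(stats::coef(rg))[, 1]
      b0 <- unname(cc[1]); co <- cc[-1]; sel <- names(co)
    }
    probs <- stats::plogis(b0 + as.numeric(z[, sel, drop = FALSE] %*% co))
    model <- signature_model(name = name, intercept = b0, coefficients = co,
                             cutoff = youden_cutoff(probs, labels),
                             zstats = list(mean = zs$mean, sd = zs$sd))
  }
  trace$final <- names(model$coefficients)
  list(model = model, trace = trace)
}
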