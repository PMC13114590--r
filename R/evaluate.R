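# Discrimination, comparison, calibration, clinical-utility and agreement
# statistics for the fitted signatures.

# Midrank placement values of the DeLong structural decomposition.
delong_components <- function(probs, labels) {
  y <- as.integer(labels)
  xs <- probs[y == 1]; ys <- probs[y == 0]
  m <- length(xs); n <- length(ys)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r_all <- rank(c(xs, ys), ties.method = "average")
  rx <- rank(xs, ties.method = "average")
  ry <- rank(ys, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n             # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m     # per-negative placements
  auc <- sum(r_all[seq_len(m)]) / (m * n) - (m + 1) / (2 * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC analysis with a DeLong confidence interval
#'
#' AUC via the Mann-Whitney formulation with midrank tie handling; the 95%
#' confidence interval uses the DeLong variance estimate, computed on the
#' logit scale so the bounds respect `[0, 1]` (degenerate AUCs of exactly 0
#' or 1 fall back to the untransformed interval).
#'
#' @param probabilities predicted probabilities or scores.
#' @param labels binary labels (both classes present).
#' @return An object of class `roc_result`: `auc`, `ci` (length 2), `se`,
#'   `n_pos`, `n_neg`, and the ROC points (`fpr`, `tpr`).
#' @export
roc_auc <- function(probabilities, labels) {
  dc <- delong_components(probabilities, labels)
  var_auc <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  se <- sqrt(var_auc)
  if (dc$auc > 0 && dc$auc < 1 && se > 0) {
    lo <- stats::qlogis(dc$auc); se_lo <- se / (dc$auc * (1 - dc$auc))
    ci <- stats::plogis(lo + c(-1.96, 1.96) * se_lo)
  } else {
    ci <- pmin(pmax(dc$auc + c(-1.96, 1.96) * se, 0), 1)
  }
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  y <- as.integer(labels)
  tpr <- vapply(th, function(t) mean(probabilities[y == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(probabilities[y == 0] >= t), numeric(1))
  structure(list(auc = dc$auc, ci = ci, se = se, n_pos = dc$m, n_neg = dc$n,
                 fpr = fpr, tpr = tpr),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of two models' AUCs computed on the same cases,
#' using the structural-components covariance estimate;
#' `Z = (AUC_A - AUC_B) / SE` with a two-sided normal p value.
#'
#' @param probs_a,probs_b probabilities of the two models for the same cases.
#' @param labels binary labels.
#' @return List with `z`, `p`, `auc_a`, `auc_b`, `diff`, `se`.
#' @export
delong_test <- function(probs_a, probs_b, labels) {
  if (length(probs_a) != length(probs_b))
    stop("both models must score the same cases")
  da <- delong_components(probs_a, labels)
  db <- delong_components(probs_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff <= 0)
    stop("zero variance of the AUC difference (identical predictors?)")
  z <- (da$auc - db$auc) / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), auc_a = da$auc, auc_b = db$auc,
       diff = da$auc - db$auc, se = sqrt(var_diff))
}

#' Confusion-matrix metrics with printed-fraction formatting
#'
#' Sensitivity, specificity, PPV and NPV as exact count fractions plus
#' percentages rounded to one decimal. Metrics with an empty denominator are
#' reported as `NA` (undefined).
#'
#' @param predicted predicted binary classes.
#' @param labels true binary labels.
#' @return An object of class `confusion_report` with counts, fractions,
#'   percent strings and a `format` helper output like `"64/73 [87.7%]"`.
#' @export
confusion_metrics <- function(predicted, labels) {
  pr <- as.integer(predicted); y <- as.integer(labels)
  tp <- sum(pr == 1 & y == 1); fp <- sum(pr == 1 & y == 0)
  tn <- sum(pr == 0 & y == 0); fn <- sum(pr == 0 & y == 1)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  fmt <- function(num, den) {
    if (den == 0) return(NA_character_)
    sprintf("%d/%d [%.1f%%]", num, den, round(100 * num / den, 1))
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = frac(tp, tp + fn), specificity = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp), npv = frac(tn, tn + fn),
    sensitivity_pct = round(100 * frac(tp, tp + fn), 1),
    specificity_pct = round(100 * frac(tn, tn + fp), 1),
    ppv_pct = round(100 * frac(tp, tp + fp), 1),
    npv_pct = round(100 * frac(tn, tn + fn), 1),
    formatted = c(sensitivity = fmt(tp, tp + fn), specificity = fmt(tn, tn + fp),
                  ppv = fmt(tp, tp + fp), npv = fmt(tn, tn + fn))),
    class = "confusion_report")
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome.
#'
#' @param probabilities probabilities in `[0, 1]`.
#' @param labels binary labels.
#' @return The Brier score.
#' @export
brier <- function(probabilities, labels) {
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  mean((probabilities - as.integer(labels))^2)
}

#' Calibration curve
#'
#' Equal-width probability bins; per occupied bin the mean predicted
#' probability, the observed event rate and the count. Empty bins are
#' omitted.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels.
#' @param n_bins number of equal-width bins (default 10).
#' @return data.frame with `mean_predicted`, `observed_rate`, `n`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  y <- as.integer(labels)
  b <- pmin(floor(probabilities * n_bins) + 1L, n_bins)
  occupied <- sort(unique(b))
  data.frame(
    mean_predicted = vapply(occupied, function(k) mean(probabilities[b == k]),
                            numeric(1)),
    observed_rate = vapply(occupied, function(k) mean(y[b == k]), numeric(1)),
    n = vapply(occupied, function(k) sum(b == k), numeric(1)))
}

#' Decision-curve analysis
#'
#' Net benefit `NB(t) = TP/n - FP/n * t/(1-t)` of the model across a
#' threshold grid, together with the treat-all and treat-none reference
#' strategies.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels.
#' @param thresholds threshold grid in (0, 1) (default 0.01 to 0.80 by 0.01).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.80, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  y <- as.integer(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(t) {
    pos <- probabilities > t
    sum(pos & y == 1) / n - sum(pos & y == 0) / n * t / (1 - t)
  }, numeric(1))
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

#' Intraclass correlation for two raters
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measurement,
#' from the mean squares of the cases x raters two-way layout. Values above
#' 0.80 are flagged as satisfactory agreement.
#'
#' @param ratings numeric matrix, cases x 2 raters (no missing values).
#' @return List with `icc`, `satisfactory` (icc > 0.80) and the mean squares.
#' @export
icc_agreement <- function(ratings) {
  x <- as.matrix(ratings)
  if (ncol(x) != 2L || nrow(x) < 2L) stop("need a cases x 2 raters matrix")
  if (anyNA(x)) stop("missing ratings")
  n <- nrow(x); k <- ncol(x)
  row_m <- rowMeans(x); col_m <- colMeans(x); gm <- mean(x)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0 || stats::var(row_m) == 0) {
    warning("no between-case variance; ICC set to 0")
    icc <- 0
  } else icc <- (msr - mse) / denom
  list(icc = icc, satisfactory = icc > 0.80,
       ms = c(rows = msr, cols = msc, error = mse))
}

#' Evaluate a set of signatures on one data split
#'
#' Per model: AUC with DeLong CI, confusion metrics at the model's cutoff,
#' and Brier score; plus the pairwise DeLong comparison table.
#'
#' @param probs named list of probability vectors (one per model).
#' @param cutoffs named numeric cutoffs matching `probs`.
#' @param labels binary labels.
#' @return List with `per_model` (data.frame) and `delong` (data.frame of
#'   pairwise comparisons).
#' @export
evaluate_models <- function(probs, cutoffs, labels) {
  nm <- names(probs)
  per <- do.call(rbind, lapply(nm, function(m) {
    r <- roc_auc(probs[[m]], labels)
    cm <- confusion_metrics(as.integer(probs[[m]] > cutoffs[[m]]), labels)
    data.frame(model = m, auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
               sensitivity_pct = cm$sensitivity_pct,
               specificity_pct = cm$specificity_pct,
               ppv_pct = cm$ppv_pct, npv_pct = cm$npv_pct,
               brier = brier(probs[[m]], labels),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  dl <- do.call(rbind, lapply(pairs, function(pp) {
    d <- tryCatch(delong_test(probs[[pp[1]]], probs[[pp[2]]], labels),
                  error = function(e) NULL)  # degenerate pair (tiny split)
    if (is.null(d)) {
      ra <- roc_auc(probs[[pp[1]]], labels); rb <- roc_auc(probs[[pp[2]]], labels)
      d <- list(z = NA_real_, p = NA_real_, auc_a = ra$auc, auc_b = rb$auc)
    }
    data.frame(model_a = pp[1], model_b = pp[2], z = d$z, p = d$p,
               auc_a = d$auc_a, auc_b = d$auc_b, stringsAsFactors = FALSE)
  }))
  list(per_model = per, delong = dl)
}
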