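test_that("Spearman pruning drops the weaker member of correlated pairs", {
  set.seed(1)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  strong <- y * 2 + rnorm(n, 0, 0.5)
  weak <- strong + rnorm(n, 0, 0.15)       # |rho| > 0.9 with strong
  indep <- rnorm(n)
  x <- cbind(strong = strong, weak = weak, indep = indep)
  kept <- spearman_prune(x, y)
  expect_true("strong" %in% kept)
  expect_false("weak" %in% kept)
  expect_true("indep" %in% kept)
  # duplicated column: exactly one survives
  xd <- cbind(a = strong, b = strong)
  expect_length(spearman_prune(xd, y), 1)
})

test_that("independent Gaussian columns survive pruning", {
  set.seed(2)
  removed <- 0
  for (s in 1:20) {
    x <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(200, 1, 0.5)
    removed <- removed + (length(spearman_prune(x, y)) < 6)
  }
  expect_lte(removed, 1)
})

test_that("Mann-Whitney screen matches exact small-sample enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2 * 1/20 = 0.1
  p <- stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value
  expect_equal(p, 0.1)
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  res <- mannwhitney_screen(x, c(1, 1, 1, 0, 0, 0), alpha = 0.15)
  expect_equal(unname(res$p["f"]), 0.1)
  expect_identical(res$features, "f")
  res2 <- mannwhitney_screen(x, c(1, 1, 1, 0, 0, 0), alpha = 0.05)
  expect_length(res2$features, 0)
  expect_error(mannwhitney_screen(x, rep(1, 6)), "both classes")
})

test_that("null features are retained at roughly the nominal rate", {
  set.seed(3)
  kept <- 0; total <- 0
  for (s in 1:300) {
    x <- cbind(f = rnorm(60))
    y <- rep(c(0, 1), each = 30)
    kept <- kept + length(mannwhitney_screen(x, y)$features)
    total <- total + 1
  }
  expect_gt(kept / total, 0.02)
  expect_lt(kept / total, 0.09)
})

test_that("mRMR penalizes redundant copies and matches exhaustive search", {
  set.seed(4)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  info <- y + rnorm(n, 0, 0.4)
  copies <- sapply(1:9, function(i) info + rnorm(n, 0, 0.02))
  weaker <- y + rnorm(n, 0, 1.5)
  x <- cbind(info = info, copies, weaker = weaker)
  colnames(x) <- c("info", paste0("copy", 1:9), "weaker")
  sel <- mrmr_select(x, y, k = 2)
  expect_true(sel[1] %in% c("info", paste0("copy", 1:9)))
  expect_equal(sel[2], "weaker")
  # k = #features keeps everything
  expect_length(mrmr_select(x, y, k = ncol(x)), ncol(x))
  # greedy path agrees with brute-force maximization of the same objective
  set.seed(5)
  x6 <- matrix(rnorm(120 * 6), 120, 6, dimnames = list(NULL, paste0("g", 1:6)))
  x6[, 1] <- x6[, 1] + y[1:120] * 1.5
  x6[, 2] <- x6[, 2] + y[1:120] * 0.8
  y6 <- y[1:120]
  sel3 <- mrmr_select(x6, y6, k = 3)
  d6 <- apply(x6, 2, habitomics:::.quantile_bins, q = 4L)
  mi <- habitomics:::.mi_disc
  rel <- apply(d6, 2, mi, b = y6)
  chosen <- character(0)
  for (step in 1:3) {
    cand <- setdiff(colnames(x6), chosen)
    scores <- sapply(cand, function(f) {
      if (!length(chosen)) rel[f]
      else rel[f] - mean(sapply(chosen, function(s) mi(d6[, f], d6[, s])))
    })
    chosen <- c(chosen, cand[which.max(scores)])
  }
  expect_identical(sel3, chosen)
})

test_that("LASSO selection recovers a planted support and shrinks to empty", {
  set.seed(6)
  hits <- 0
  for (s in 1:10) {
    n <- 400; p <- 30
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    lp <- 1.5 * x[, 1] - 1.5 * x[, 2] + 1.2 * x[, 3]
    y <- rbinom(n, 1, plogis(lp))
    sel <- lasso_select(x, y, seed = s)
    if (all(c("v1", "v2", "v3") %in% sel$features)) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # unpenalized fit equals glm on a well-conditioned fixture
  set.seed(7)
  x2 <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, c("a", "b")))
  y2 <- rbinom(500, 1, plogis(x2[, 1] - 0.5 * x2[, 2]))
  g0 <- glmnet::glmnet(x2, y2, family = "binomial", lambda = 0,
                       standardize = FALSE, thresh = 1e-12)
  ref <- stats::glm(y2 ~ x2, family = stats::binomial())
  expect_equal(as.numeric(stats::coef(g0)), unname(stats::coef(ref)),
               tolerance = 1e-4)
})

test_that("backward elimination keeps only significant terms and reports ORs", {
  set.seed(8)
  n <- 1000
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "noise")))
  y <- rbinom(n, 1, plogis(1 * x[, 1] - 1 * x[, 2]))
  m <- backward_logistic(x, y)
  expect_setequal(names(m$coefficients), c("a", "b"))
  expect_lt(abs(m$coefficients["a"] - 1), 2 * 0.12)
  expect_lt(abs(m$coefficients["b"] + 1), 2 * 0.12)
  expect_equal(m$summary$odds_ratio, exp(m$summary$coefficient))
  # printed-value arithmetic: coefficient -1.234 -> OR 0.291 at 3 decimals
  expect_equal(round(exp(-1.234), 3), 0.291)
  expect_equal(exp(0), 1)
})

test_that("signature prediction follows the printed equation conventions", {
  ref <- reference_signatures()
  rad <- ref$radiological
  # all covariates zero: p = plogis(-3.164), negative at cutoff 0.348
  pr <- predict_signature(rad, data.frame(solid_diameter = 0, spl = 0))
  expect_equal(pr$probability, plogis(-3.164))
  expect_equal(pr$probability, 0.0405, tolerance = 2e-3)
  expect_equal(pr$class, 0L)
  # probability exactly at the cutoff is negative (strict inequality)
  m <- signature_model("toy", intercept = 0, coefficients = c(x = 1),
                       cutoff = 0.5)
  expect_equal(predict_signature(m, data.frame(x = 0))$class, 0L)
  # monotonicity in a positive coefficient
  p1 <- predict_signature(rad, data.frame(solid_diameter = 10, spl = 2))
  p2 <- predict_signature(rad, data.frame(solid_diameter = 10, spl = 8))
  expect_gt(p2$probability, p1$probability)
  expect_error(predict_signature(rad, data.frame(solid_diameter = 1)),
               "missing feature")
})

test_that("Youden cutoff equals the exhaustive scan", {
  set.seed(9)
  probs <- runif(20)
  y <- rbinom(20, 1, probs)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  got <- youden_cutoff(probs, y)
  cand <- sort(unique(probs))
  js <- sapply(cand, function(t) mean(probs[y == 1] > t) + mean(probs[y == 0] <= t) - 1)
  expect_equal(got, cand[which.max(js)])
  expect_true(got >= min(probs) && got <= max(probs))
  expect_error(youden_cutoff(probs, rep(1, 20)), "both classes")
})

test_that("variance inflation factors match constructed regressions", {
  set.seed(10)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  expect_equal(unname(vif(cbind(a = a, b = b))), c(1, 1), tolerance = 0.05)
  # third column built for R^2 = 0.75 -> VIF = 4
  c3 <- sqrt(0.75) * scale(a)[, 1] + sqrt(0.25) * rnorm(n)
  v <- vif(cbind(a = a, b = b, c = c3))
  expect_equal(unname(v["c"]), 4, tolerance = 0.6)
  w <- capture_warnings(vd <- vif(cbind(a = a, dup = a, b = b)))
  expect_match(w, "collinearity", all = TRUE)
  expect_true(is.infinite(vd[["a"]]) && is.infinite(vd[["dup"]]))
})

test_that("the full selection chain is deterministic and nested", {
  set.seed(11)
  n <- 150
  y <- rbinom(n, 1, 0.45)
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
  x[, 1] <- x[, 1] + 1.2 * y; x[, 2] <- x[, 2] - 1.0 * y
  r1 <- build_signature(x, y, seed = 5)
  r2 <- build_signature(x, y, seed = 5)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$model$coefficients, r2$model$coefficients)
  tr <- r1$trace
  expect_true(all(tr$mannwhitney %in% tr$spearman))
  expect_true(all(tr$mrmr %in% tr$mannwhitney))
  expect_true(all(tr$lasso %in% tr$mrmr))
  expect_true(all(tr$final %in% tr$lasso))
})
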