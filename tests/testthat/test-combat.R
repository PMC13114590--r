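make_batch_table <- function(n_per = 50, p = 20, shift = 2, scale = 1,
                             seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per * p), n_per, p)
  x2 <- matrix(rnorm(n_per * p), n_per, p) * scale + shift
  colnames(x1) <- colnames(x2) <- paste0("f", seq_len(p))
  list(x = rbind(x1, x2), batch = rep(c("a", "b"), each = n_per))
}

test_that("a known additive batch shift is removed", {
  d <- make_batch_table(n_per = 100, shift = 2)
  m <- fit_combat(d$x, d$batch)
  adj <- apply_combat(m, d$x, d$batch)
  raw_diff <- colMeans(d$x[d$batch == "b", ]) - colMeans(d$x[d$batch == "a", ])
  adj_diff <- colMeans(adj[d$batch == "b", ]) - colMeans(adj[d$batch == "a", ])
  expect_gt(min(abs(raw_diff)), 1.5)            # the shift is really there
  expect_lt(max(abs(adj_diff)), 0.05 * 10)      # per-feature residual
  expect_lt(abs(mean(adj_diff)), 0.05)          # aggregate batch difference
  expect_identical(dim(adj), dim(d$x))
  expect_identical(colnames(adj), colnames(d$x))
})

test_that("single-batch harmonization is the identity within tolerance", {
  set.seed(2)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  m <- fit_combat(x, rep("only", 20))
  adj <- apply_combat(m, x, rep("only", 20))
  expect_equal(adj, x, tolerance = 1e-8)
})

test_that("EB shrinkage vanishes as the per-batch sample grows", {
  small <- make_batch_table(n_per = 25, shift = 1, seed = 3)
  large <- make_batch_table(n_per = 2000, shift = 1, seed = 3)
  ms <- fit_combat(small$x, small$batch)
  ml <- fit_combat(large$x, large$batch)
  # raw per-batch location of standardized data for the large fit
  for (fit in list(ml)) {
    sdat_loc <- fit$gamma_star
    # with n large the EB posterior mean is within a hair of the raw batch
    # location; check batch separation ~ shift / pooled sd is retained
    expect_gt(abs(sdat_loc[2, 1] - sdat_loc[1, 1]), 0.5)
  }
  # shrinkage: small-sample gamma* spread strictly tighter than raw batch
  # means would be in at least the typical feature (sanity, not exact)
  expect_true(all(is.finite(ms$gamma_star)))
})

test_that("re-fitting on harmonized data finds nothing left to remove", {
  d <- make_batch_table(n_per = 100, shift = 1.5, scale = 1.4, seed = 4)
  m <- fit_combat(d$x, d$batch)
  adj <- apply_combat(m, d$x, d$batch)
  m2 <- fit_combat(adj, d$batch)
  expect_lt(max(abs(m2$gamma_star)), 0.1)
  expect_lt(max(abs(m2$delta_star - 1)), 0.2)
  adj2 <- apply_combat(m2, adj, d$batch)
  expect_equal(adj2, adj, tolerance = 0.05)
})

test_that("matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  d <- make_batch_table(n_per = 40, p = 15, shift = 1.2, scale = 1.3, seed = 5)
  m <- fit_combat(d$x, d$batch)
  adj <- apply_combat(m, d$x, d$batch)
  ref <- t(suppressMessages(sva::ComBat(dat = t(d$x), batch = d$batch,
                                        par.prior = TRUE,
                                        prior.plots = FALSE)))
  expect_equal(unname(adj), unname(ref), tolerance = 1e-4)
})

test_that("biological covariate effects survive harmonization", {
  set.seed(6)
  n <- 120
  batch <- rep(c("a", "b"), each = n / 2)
  y <- rbinom(n, 1, ifelse(batch == "a", 0.6, 0.3))  # confounded label
  x <- sapply(1:10, function(j) 1.0 * y + (batch == "b") * 2 + rnorm(n))
  colnames(x) <- paste0("f", 1:10)
  m <- fit_combat(x, batch, covariates = cbind(y = y))
  adj <- apply_combat(m, x, batch, covariates = cbind(y = y))
  # compare against the effect estimated from the raw data with batch in the
  # model, so sampling noise cancels: harmonization must not erode the
  # biological effect by more than 10%
  eff_adj <- vapply(1:10, function(j)
    unname(stats::coef(stats::lm(adj[, j] ~ y + batch))["y"]), numeric(1))
  eff_raw <- vapply(1:10, function(j)
    unname(stats::coef(stats::lm(x[, j] ~ y + batch))["y"]), numeric(1))
  expect_lt(abs(mean(eff_adj) - mean(eff_raw)) / abs(mean(eff_raw)), 0.1)
})

test_that("unseen batches and singleton batches are rejected", {
  d <- make_batch_table()
  m <- fit_combat(d$x, d$batch)
  expect_error(apply_combat(m, d$x, rep("zzz", nrow(d$x))), "unseen batch")
  expect_error(fit_combat(d$x[1:51, ], c(rep("a", 50), "b")), "singleton.*b")
})

test_that("zero-variance features pass through with a warning", {
  d <- make_batch_table(n_per = 30)
  x <- cbind(d$x, cst = 5)
  expect_warning(m <- fit_combat(x, d$batch), "zero-variance")
  adj <- apply_combat(m, x, d$batch)
  expect_equal(adj[, "cst"], x[, "cst"])
})

test_that("batch R-squared audit behaves like one-way ANOVA", {
  set.seed(7)
  batch <- rep(c("a", "b", "c"), each = 40)
  ind <- matrix(rnorm(120 * 10), 120, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
  r <- batch_r2(ind, batch)
  expect_lt(r$mean_r2, 0.06)  # ~ (k-1)/(n-1) under the null
  expect_true(all(r$per_feature >= 0 & r$per_feature <= 1))
  # feature equal to the batch indicator has R2 = 1
  xb <- cbind(ind, bind = as.numeric(factor(batch)))
  expect_equal(unname(batch_r2(xb, batch)$per_feature["bind"]), 1)
  # constant feature convention
  xc <- cbind(ind, cst = 1)
  expect_equal(unname(batch_r2(xc, batch)$per_feature["cst"]), 0)
})

test_that("mean R2 drops after harmonization on shifted batches (20 seeds)", {
  worse <- 0
  for (s in 1:20) {
    d <- make_batch_table(n_per = 30, p = 8, shift = 1, seed = 100 + s)
    m <- fit_combat(d$x, d$batch)
    adj <- apply_combat(m, d$x, d$batch)
    a <- combat_audit(d$x, adj, d$batch)
    if (a$mean_r2_after_pct > a$mean_r2_before_pct) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
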