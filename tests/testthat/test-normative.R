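test_that("deviation z formula, antisymmetry and scale equivariance", {
  expect_equal(deviation_z(2, 0, 1.2, 0.9), 2 / sqrt(2.25))
  expect_equal(deviation_z(5, 5, 0.3, 1), 0)
  expect_equal(deviation_z(1, 3, 0.5, 0.5), -deviation_z(3, 1, 0.5, 0.5))
  c_ <- 7.3
  expect_equal(deviation_z(c_ * 3, c_ * 1, c_ * 0.5, c_ * 0.8),
               deviation_z(3, 1, 0.5, 0.8))
  expect_error(deviation_z(1, 0, 0, 0), "zero")
})

test_that("held-out control z-maps are standard normal under the generator", {
  fx <- tiny_fit()
  dev <- deviations(fx$fit, fx$cohort, groups = "HC_test")
  mu <- colMeans(dev$z)
  sdv <- apply(dev$z, 2, sd)
  expect_lt(max(abs(mean(mu))), 0.1)
  expect_gt(mean(sdv), 0.9)
  expect_lt(mean(sdv), 1.1)
  # extremes round-trip against z and the threshold
  expect_identical(dev$pos, dev$z > dev$z_thr)
  expect_identical(dev$neg, dev$z < -dev$z_thr)
  expect_false(any(dev$pos & dev$neg))
})

test_that("partial pooling shrinks identical batches toward the pooled fit", {
  sch <- tiny_scheme()
  spec <- data.frame(site = paste0("s", 1:4), n_hc = 40, n_case = 0)
  coh <- make_cohort(sch, spec, effects = list(
    site_offsets = setNames(rep(0, 4), paste0("s", 1:4)),
    site_noise_scales = setNames(rep(0.1, 4), paste0("s", 1:4)),
    sex_offset = 0), seed = 11)
  coh$subjects$group <- "HC_train"
  fit <- normative(coh)
  # batch intercepts hug the shared prior mean when batches are identical
  dev_from_pool <- abs(sweep(fit$alpha, 2, fit$hyper$mu_alpha))
  pooled_se <- sqrt(fit$s20 / nrow(coh$phenotype))
  expect_gt(mean(dev_from_pool < 0.5 * rep(pooled_se,
                                           each = nrow(fit$alpha))), 0.9)
})

test_that("noise-free linear data is reproduced exactly", {
  sch <- make_parcellation(10, 2, 2, seed = 9)
  n <- 40
  subjects <- data.frame(
    id = sprintf("n%02d", 1:n), age = seq(20, 60, length.out = n),
    sex = rep(c("M", "F"), n / 2), site = rep(c("p", "q"), each = n / 2),
    group = "HC_train")
  eta <- outer(0.01 * subjects$age, rep(1, 12)) + 1
  phen <- exp(eta)
  colnames(phen) <- sch$regions$region_id
  rownames(phen) <- subjects$id
  coh <- structure(list(subjects = subjects, phenotype = phen),
                   class = "cohort")
  fit <- normative(coh, min_batch = 5, lambda = 0)
  expect_lt(max(fit$sigma), 1e-6)
  pred <- predict(fit, coh)
  expect_equal(pred$yhat, log(phen), tolerance = 1e-8)
})

test_that("generator site offsets are recovered within posterior intervals", {
  fx <- tiny_fit()
  fit <- fx$fit
  coh <- fx$cohort
  truth <- attr(coh, "truth")
  # true batch means of the transformed noise-free phenotype vs fitted
  # batch means, scored by the posterior SE
  tr <- coh$subjects$group == "HC_train"
  batch <- paste(coh$subjects$site, coh$subjects$sex, sep = ":")[tr]
  age <- coh$subjects$age[tr]
  nf <- truth$noise_free[coh$subjects$id[tr], ]
  hits <- 0; cells <- 0
  for (b in fit$batches) {
    rows <- batch == b
    for (j in seq_along(fit$regions)) {
      r <- fit$regions[j]
      yt_true <- mean(boxcox_transform(nf[rows, r], fit$lambda[j]))
      est <- fit$alpha[b, r] +
        fit$beta[b, r] * (mean(age[rows]) - fit$ref_age)
      se <- sqrt(fit$pv_alpha[b, r])
      cells <- cells + 1
      hits <- hits + (abs(est - yt_true) < 1.96 * se +
                        1e-3 * abs(yt_true))
    }
  }
  expect_gt(hits / cells, 0.9)
})

test_that("fit metrics match hand-coded formulas and their fixed points", {
  set.seed(3)
  y <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("r1", "r2")))
  yhat <- y + matrix(rnorm(40, sd = 0.3), 20, 2)
  s2 <- matrix(0.09, 20, 2)
  mu0 <- c(0, 0); s20 <- c(1, 1)
  m <- fit_metrics(y, yhat, s2, mu0, s20)
  # independent brute-force recomputation
  for (j in 1:2) {
    ev <- 1 - var(y[, j] - yhat[, j]) / var(y[, j])
    smse <- mean((y[, j] - yhat[, j])^2) / mean((y[, j] - mu0[j])^2)
    ll <- mean(0.5 * log(2 * pi * s2[, j]) +
                 (y[, j] - yhat[, j])^2 / (2 * s2[, j]))
    ll0 <- mean(0.5 * log(2 * pi * s20[j]) +
                  (y[, j] - mu0[j])^2 / (2 * s20[j]))
    expect_equal(m$ev[j], ev, tolerance = 1e-10)
    expect_equal(m$smse[j], smse, tolerance = 1e-10)
    expect_equal(m$msll[j], ll - ll0, tolerance = 1e-10)
  }
  # perfect prediction and the trivial predictor as fixed points
  mp <- fit_metrics(y, y, s2, mu0, s20)
  expect_equal(mp$ev, c(1, 1))
  expect_equal(mp$smse, c(0, 0))
  mt <- fit_metrics(y, matrix(mu0, 20, 2, byrow = TRUE),
                    matrix(s20, 20, 2, byrow = TRUE), mu0, s20)
  expect_equal(mt$smse, c(1, 1), tolerance = 1e-10)
  expect_equal(mt$msll, c(0, 0), tolerance = 1e-10)
})

test_that("cross-validation predicts every subject exactly once", {
  sch <- tiny_scheme()
  spec <- data.frame(site = c("u", "v"), n_hc = 40, n_case = 0)
  coh <- make_cohort(sch, spec, seed = 21)
  coh$subjects$group <- "HC_train"
  cv <- crossval_evaluate(coh, k = 5, min_batch = 5, seed = 2)
  expect_false(anyNA(cv$z))
  expect_equal(sort(unique(cv$folds)), 1:5)
  # batch-stratified assignment keeps fold sizes near balance
  expect_lte(diff(range(table(cv$folds))), 4)
  # well-specified generator: median EV should be modest but positive
  # (age explains a small share of variance by design)
  expect_true(all(is.finite(cv$metrics$ev)))
})

test_that("site-leakage score separates leaky from clean z-maps", {
  set.seed(8)
  z <- matrix(rnorm(200 * 30), 200, 30)
  sites <- rep(paste0("s", 1:4), each = 50)
  clean <- site_leakage_score(z, sites, repeats = 5, seed = 1)
  expect_gt(clean$mean, 0.4)
  expect_lt(clean$mean, 0.6)
  zl <- z + (sites == "s1") * 2      # constant offset: separable
  leaky <- site_leakage_score(zl, sites, repeats = 2, seed = 1)
  expect_gt(leaky$per_site[["s1"]], 0.9)
  # both the tiny site and its complement class are too small: every
  # site is skipped with a warning
  w <- capture_warnings(
    site_leakage_score(z[1:52, ], c(rep("a", 50), "b", "b"), folds = 2))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 2)
})
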