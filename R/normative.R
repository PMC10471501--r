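#' Fit a hierarchical normative model of a regional phenotype
#'
#' Fits, independently for each region, a partial-pooling model of the
#' Box-Cox-transformed phenotype on age with batch-specific (site x sex)
#' intercepts, age slopes and noise scales shrunk toward shared
#' hyperpriors. The backend is a two-stage empirical-Bayes fit: per-batch
#' maximum likelihood (ordinary least squares on age, centred at the
#' training mean age), followed by method-of-moments hyperpriors across
#' batches and conjugate shrinkage of each batch's intercept, slope and
#' log noise variance. Batches whose parameters are indistinguishable
#' collapse toward the pooled estimate; well-separated batches keep their
#' own parameters.
#'
#' Training rows are those with `group == "HC_train"` (falling back to
#' `"HC"` when the cohort has not been split). Batches with fewer than
#' `min_batch` training subjects are excluded from the fit, matching the
#' cell-exclusion rule applied by [split_train_test()].
#'
#' @param cohort a `"cohort"`.
#' @param min_batch minimum training subjects per (site, sex) batch.
#' @param lambda optional fixed Box-Cox lambda (scalar or per-region
#'   vector); estimated by region-wise maximum likelihood when `NULL`.
#' @return An object of class `"normative"` with components `lambda`,
#'   `ref_age`, `batches`, per-batch-per-region parameter matrices
#'   (`alpha`, `beta`, `sigma`, posterior variances), hyperparameters,
#'   training summaries (`mu0`, `s20` per region on the transformed
#'   scale) and the training design (for `residuals()`).
#' @seealso [predict.normative()], [deviations()], [deviation_z()],
#'   [crossval_evaluate()], [site_leakage_score()]
#' @export
normative <- function(cohort, min_batch = 10, lambda = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$subjects
  train <- which(s$group == "HC_train")
  if (length(train) == 0L) train <- which(s$group == "HC")
  if (length(train) == 0L) stop_arg("no training controls in cohort")

  age <- s$age[train]
  batch <- paste(s$site[train], s$sex[train], sep = ":")
  keep_batches <- names(which(table(batch) >= min_batch))
  if (length(keep_batches) < 2L)
    stop_arg("need at least 2 batches with >= min_batch training subjects")
  in_batch <- batch %in% keep_batches
  train <- train[in_batch]
  age <- age[in_batch]
  batch <- batch[in_batch]

  Y <- cohort$phenotype[train, , drop = FALSE]
  R <- ncol(Y)
  rids <- colnames(Y)

  if (is.null(lambda)) {
    lambda <- vapply(seq_len(R), function(j)
      boxcox_lambda(Y[, j], region = rids[j]), numeric(1))
  } else lambda <- rep_len(lambda, R)
  Yt <- vapply(seq_len(R), function(j)
    boxcox_transform(Y[, j], lambda[j], region = rids[j]),
    numeric(nrow(Y)))
  colnames(Yt) <- rids

  ref_age <- mean(age)
  B <- length(keep_batches)
  alpha <- beta <- sigma2 <- va <- vb <- matrix(
    NA_real_, B, R, dimnames = list(keep_batches, rids))
  nb <- integer(B)
  for (b in seq_len(B)) {
    idx <- batch == keep_batches[b]
    nb[b] <- sum(idx)
    ab <- age[idx] - ref_age
    if (stats::sd(ab) == 0)
      stop_arg(sprintf("degenerate batch %s: constant age", keep_batches[b]))
    yv <- apply(Yt[idx, , drop = FALSE], 2, stats::var)
    if (any(yv == 0))
      stop_arg(sprintf("degenerate batch %s: zero phenotype variance (region %s)",
                       keep_batches[b], rids[which(yv == 0)[1]]))
    X <- cbind(1, ab)
    fit <- stats::lm.fit(X, Yt[idx, , drop = FALSE])
    alpha[b, ] <- fit$coefficients[1, ]
    beta[b, ] <- fit$coefficients[2, ]
    df <- nb[b] - 2L
    sigma2[b, ] <- colSums(fit$residuals^2) / df
    xtxi <- diag(solve(crossprod(X)))
    va[b, ] <- xtxi[1] * sigma2[b, ]
    vb[b, ] <- xtxi[2] * sigma2[b, ]
  }

  shrink <- function(est, sv) {
    mu <- colMeans(est)
    # between-batch variance: unbiased moment estimates pooled across
    # regions (site and sex effects are largely global for a volumetric
    # phenotype, and pooling removes the upward bias a per-region
    # truncated estimator would have when batches are exchangeable)
    raw <- apply(est, 2, stats::var) - colMeans(sv)
    tau2 <- rep(max(0, mean(raw)), ncol(est))
    tau2e <- pmax(tau2, 1e-12)
    var_mu <- 1 / colSums(1 / (sv + rep(tau2e, each = nrow(sv))))
    post <- est
    pv <- sv
    for (b in seq_len(nrow(est))) {
      exact <- sv[b, ] < 1e-300
      prec <- 1 / sv[b, ] + 1 / tau2e
      post[b, ] <- ifelse(exact, est[b, ],
                          (est[b, ] / sv[b, ] + mu / tau2e) / prec)
      pv[b, ] <- ifelse(exact, 0, 1 / prec + var_mu)
    }
    list(post = post, pv = pv, mu = mu, tau2 = tau2)
  }
  sa <- shrink(alpha, va)
  sb <- shrink(beta, vb)

  # noise scales: per-batch ML (Bessel-corrected). These are deliberately
  # NOT shrunk toward the shared prior: deviation z-scores divide by
  # sigma, so any pull of a genuinely low- or high-noise site toward the
  # prior mean translates one-for-one into mis-scaled z maps, and with
  # min_batch training subjects the per-batch estimates are already
  # stable. The shared-prior hyperparameters for the noise are still
  # reported for inspection.
  sigma2_post <- sigma2
  if (all(sigma2 > 1e-300)) {
    L <- log(sigma2)
    sl <- list(mu = colMeans(L),
               tau2 = pmax(0, apply(L, 2, stats::var) -
                             mean(2 / (nb - 2L))))
  } else {
    sl <- list(mu = colMeans(sigma2), tau2 = rep(0, R))
  }

  out <- list(
    lambda = stats::setNames(lambda, rids),
    ref_age = ref_age,
    batches = keep_batches,
    n_batch = stats::setNames(nb, keep_batches),
    alpha = sa$post, beta = sb$post, sigma = sqrt(sigma2_post),
    pv_alpha = sa$pv, pv_beta = sb$pv,
    hyper = list(mu_alpha = sa$mu, tau2_alpha = sa$tau2,
                 mu_beta = sb$mu, tau2_beta = sb$tau2,
                 mu_logs2 = sl$mu, tau2_logs2 = sl$tau2),
    mu0 = colMeans(Yt),
    s20 = apply(Yt, 2, stats::var),
    regions = rids,
    train = list(id = s$id[train], age = age, batch = batch, Yt = Yt)
  )
  class(out) <- "normative"
  out
}

#' @export
print.normative <- function(x, ...) {
  cat(sprintf(
    "Hierarchical normative model: %d regions, %d batches (%d subjects)\n",
    length(x$regions), length(x$batches), sum(x$n_batch)))
  cat(sprintf("  Box-Cox lambda: median %.3f [%.3f, %.3f]\n",
              stats::median(x$lambda), min(x$lambda), max(x$lambda)))
  cat(sprintf("  reference age: %.1f years\n", x$ref_age))
  invisible(x)
}

#' @export
summary.normative <- function(object, ...) {
  h <- object$hyper
  out <- data.frame(
    parameter = c("intercept", "age slope", "log noise var"),
    prior_mean = c(mean(h$mu_alpha), mean(h$mu_beta), mean(h$mu_logs2)),
    prior_var = c(mean(h$tau2_alpha), mean(h$tau2_beta),
                  mean(h$tau2_logs2)))
  cat("Shared-prior hyperparameters (averaged over regions):\n")
  print(out, row.names = FALSE)
  cat(sprintf("\nBatches: %s\n", paste(object$batches, collapse = ", ")))
  invisible(out)
}

#' @export
coef.normative <- function(object, region = NULL, ...) {
  rs <- region %||% object$regions
  rs <- as.character(rs)
  do.call(rbind, lapply(rs, function(r) data.frame(
    region = r, batch = object$batches,
    intercept = object$alpha[, r], slope = object$beta[, r],
    sigma = object$sigma[, r], row.names = NULL)))
}

#' Predict held-out subjects under the normative model
#'
#' Returns, per subject and region, the predicted transformed phenotype
#' `yhat`, the epistemic predictive uncertainty `sigma_i` (posterior
#' standard error of the prediction at the subject's age and batch), the
#' normative (aleatoric) scale `sigma_n` (the batch noise scale), and the
#' deviation z-scores when the cohort carries phenotype values.
#'
#' @param object a `"normative"` fit.
#' @param cohort a `"cohort"` holding the subjects to score.
#' @param subset optional row indices or logical over subjects.
#' @param ... unused.
#' @return list of class `"normative_pred"` with matrices `yhat`,
#'   `sigma_i`, `sigma_n`, `z` and the scored `subjects` data frame.
#' @export
predict.normative <- function(object, cohort, subset = NULL, ...) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$subjects
  idx <- if (is.null(subset)) seq_len(nrow(s)) else which(
    if (is.logical(subset)) subset else seq_len(nrow(s)) %in% subset)
  batch <- paste(s$site[idx], s$sex[idx], sep = ":")
  unknown <- setdiff(unique(batch), object$batches)
  if (length(unknown) > 0L)
    stop_arg(sprintf("batch(es) not in fit: %s",
                     paste(unknown, collapse = ", ")))
  b <- match(batch, object$batches)
  a <- s$age[idx] - object$ref_age

  yhat <- object$alpha[b, , drop = FALSE] +
    object$beta[b, , drop = FALSE] * a
  sigma_i <- sqrt(object$pv_alpha[b, , drop = FALSE] +
                    object$pv_beta[b, , drop = FALSE] * a^2)
  sigma_n <- object$sigma[b, , drop = FALSE]
  rownames(yhat) <- rownames(sigma_i) <- rownames(sigma_n) <- s$id[idx]

  z <- NULL
  if (!is.null(cohort$phenotype)) {
    Y <- cohort$phenotype[idx, object$regions, drop = FALSE]
    Yt <- vapply(seq_along(object$regions), function(j)
      boxcox_transform(Y[, j], object$lambda[j],
                       region = object$regions[j]),
      numeric(length(idx)))
    dimnames(Yt) <- dimnames(yhat)
    z <- deviation_z(Yt, yhat, sigma_i, sigma_n)
  }
  structure(list(yhat = yhat, sigma_i = sigma_i, sigma_n = sigma_n,
                 z = z, subjects = s[idx, , drop = FALSE]),
            class = "normative_pred")
}

#' Deviation z-score
#'
#' Standardises an observed value against the normative prediction,
#' combining predictive uncertainty and normative variance:
#' \deqn{z_{ij} = (y_{ij} - \hat y_{ij}) / \sqrt{\sigma_{ij}^2 +
#'   \sigma_{nj}^2}.}
#' Antisymmetric in the residual and invariant under common rescaling of
#' all four arguments.
#'
#' @param y observed (transformed) value(s).
#' @param yhat predicted value(s).
#' @param sigma_i predictive uncertainty (>= 0).
#' @param sigma_n normative scale (> 0; jointly zero denominators are an
#'   error).
#' @export
deviation_z <- function(y, yhat, sigma_i, sigma_n) {
  den2 <- sigma_i^2 + sigma_n^2
  if (any(den2 == 0))
    stop_arg("sigma_i and sigma_n are both zero: z undefined")
  (y - yhat) / sqrt(den2)
}

#' @export
residuals.normative <- function(object, ...) {
  tr <- object$train
  b <- match(tr$batch, object$batches)
  a <- tr$age - object$ref_age
  yhat <- object$alpha[b, , drop = FALSE] + object$beta[b, , drop = FALSE] * a
  sigma_i <- sqrt(object$pv_alpha[b, , drop = FALSE] +
                    object$pv_beta[b, , drop = FALSE] * a^2)
  z <- deviation_z(tr$Yt, yhat, sigma_i, object$sigma[b, , drop = FALSE])
  rownames(z) <- tr$id
  z
}

#' @export
simulate.normative <- function(object, nsim = 1, seed = NULL, cohort, ...) {
  with_seed(seed, {
    pred <- stats::predict(object, cohort)
    lapply(seq_len(nsim), function(k) {
      e <- matrix(stats::rnorm(length(pred$yhat)), nrow(pred$yhat))
      Yt <- pred$yhat + e * pred$sigma_n
      out <- vapply(seq_along(object$regions), function(j)
        boxcox_inverse(Yt[, j], object$lambda[j]), numeric(nrow(Yt)))
      dimnames(out) <- dimnames(pred$yhat)
      out
    })
  })
}

#' @export
plot.normative <- function(x, region = 1, cohort = NULL, batch = NULL, ...) {
  r <- as.character(if (is.numeric(region)) x$regions[region] else region)
  tr <- x$train
  b <- batch %||% x$batches[1]
  graphics::plot(tr$age, tr$Yt[, r], pch = 16, cex = 0.5,
                 col = ifelse(tr$batch == b, "steelblue", "grey70"),
                 xlab = "age (years)", ylab = "transformed phenotype",
                 main = sprintf("region %s, batch %s", r, b), ...)
  ag <- seq(min(tr$age), max(tr$age), length.out = 50)
  bi <- match(b, x$batches)
  mu <- x$alpha[bi, r] + x$beta[bi, r] * (ag - x$ref_age)
  sn <- x$sigma[bi, r]
  graphics::lines(ag, mu, lwd = 2)
  for (q in c(0.95, 0.99)) {
    k <- stats::qnorm(1 - (1 - q) / 2)
    graphics::lines(ag, mu + k * sn, lty = ifelse(q == 0.99, 1, 2))
    graphics::lines(ag, mu - k * sn, lty = ifelse(q == 0.99, 1, 2))
  }
  invisible(x)
}

#' Model-fit metrics for normative predictions
#'
#' Explained variance `EV = 1 - Var(y - yhat) / Var(y)`, standardised
#' mean-squared error `SMSE = MSE / MSE of the training-mean predictor`,
#' and mean standardised log-loss `MSLL` (mean Gaussian log-loss of the
#' prediction minus that of the trivial predictor using the training mean
#' and variance; negative is better). Computed per region.
#'
#' @param y observed transformed values (subjects x regions).
#' @param yhat predictions (same shape).
#' @param s2 predictive variances (`sigma_i^2 + sigma_n^2`, same shape).
#' @param mu0,s20 training mean and variance per region.
#' @return data frame: `region`, `ev`, `smse`, `msll`, `degenerate`
#'   (TRUE when `Var(y) = 0` and EV/SMSE are undefined).
#' @export
fit_metrics <- function(y, yhat, s2, mu0, s20) {
  if (nrow(y) < 2L) stop_arg("need at least 2 test subjects")
  res <- y - yhat
  vy <- apply(y, 2, stats::var)
  mse <- colMeans(res^2)
  mse0 <- colMeans((y - rep(mu0, each = nrow(y)))^2)
  ll <- colMeans(0.5 * log(2 * pi * s2) + res^2 / (2 * s2))
  ll0 <- colMeans(0.5 * log(2 * pi * rep(s20, each = nrow(y))) +
                    (y - rep(mu0, each = nrow(y)))^2 /
                    (2 * rep(s20, each = nrow(y))))
  degenerate <- vy == 0
  data.frame(
    region = colnames(y) %||% seq_len(ncol(y)),
    ev = ifelse(degenerate, NA_real_, 1 - apply(res, 2, stats::var) / vy),
    smse = ifelse(mse0 == 0, NA_real_, mse / mse0),
    msll = ll - ll0,
    degenerate = degenerate,
    row.names = NULL)
}

#' Cross-validated model evaluation
#'
#' Stratified k-fold cross-validation over the training controls: fold
#' assignment is balanced within each (site, sex) batch (falling back to
#' pooled random assignment, with a warning, when a batch is smaller than
#' `k`); each subject is predicted exactly once by a model fit on the
#' remaining folds.
#'
#' @param cohort a `"cohort"` with training controls.
#' @param k number of folds.
#' @param min_batch passed to [normative()].
#' @param lambda passed to [normative()].
#' @param seed RNG seed for fold assignment.
#' @return list with `metrics` (data frame: fold x region metrics), `z`
#'   (cross-validated deviation z for every training subject) and `folds`
#'   (assignment).
#' @export
crossval_evaluate <- function(cohort, k = 5, min_batch = 10, lambda = NULL,
                              seed = 1L) {
  s <- cohort$subjects
  train <- which(s$group %in% c("HC_train", "HC"))
  n <- length(train)
  if (k < 2 || k > n) stop_arg("`k` must be between 2 and the number of subjects")
  batch <- paste(s$site[train], s$sex[train], sep = ":")

  folds <- integer(n)
  with_seed(seed, {
    small <- table(batch)[unique(batch)] < k
    if (any(small)) {
      warning("batch smaller than k: pooled random fold assignment")
      folds <- sample(rep(seq_len(k), length.out = n))
    } else {
      for (bt in unique(batch)) {
        idx <- which(batch == bt)
        folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    }

    z <- matrix(NA_real_, n, ncol(cohort$phenotype),
                dimnames = list(s$id[train], colnames(cohort$phenotype)))
    metrics <- vector("list", k)
    for (f in seq_len(k)) {
      tr_rows <- train[folds != f]
      te_rows <- train[folds == f]
      sub <- cohort
      sub$subjects <- s
      sub$subjects$group <- s$group
      sub$subjects$group[] <- ""
      sub$subjects$group[tr_rows] <- "HC_train"
      fit <- normative(sub, min_batch = min_batch, lambda = lambda)
      pred <- stats::predict(fit, cohort, subset = te_rows)
      z[match(s$id[te_rows], rownames(z)), ] <- pred$z
      Yt <- pred$z * sqrt(pred$sigma_i^2 + pred$sigma_n^2) + pred$yhat
      m <- fit_metrics(Yt, pred$yhat, pred$sigma_i^2 + pred$sigma_n^2,
                       fit$mu0, fit$s20)
      m$fold <- f
      metrics[[f]] <- m
    }
    list(metrics = do.call(rbind, metrics), z = z, folds = folds)
  })
}

#' Site-leakage diagnostic via linear support vector machines
#'
#' Quantifies residual site information in deviation z-maps: for each
#' site, a one-versus-all linear SVM (slack/cost parameter 1) is trained
#' and tested under stratified `folds`-fold cross-validation on the z-map
#' matrix, and the balanced accuracy (mean of sensitivity and
#' specificity over the pooled held-out predictions) is reported.
#' Balanced accuracy at chance (50%) indicates the model has absorbed the
#' site effects. With `repeats > 1` the fold split is redrawn and the
#' per-site scores averaged, reducing the Monte-Carlo error of the
#' estimate without changing the estimand.
#'
#' @param z subjects x regions matrix of deviation z-scores.
#' @param sites site label per subject.
#' @param folds number of CV folds (default 2).
#' @param cost SVM slack parameter.
#' @param repeats number of repeated fold splits averaged.
#' @param seed RNG seed.
#' @return list with `per_site` (named vector of balanced accuracies) and
#'   `mean`.
#' @export
site_leakage_score <- function(z, sites, folds = 2, cost = 1, repeats = 1,
                               seed = 1L) {
  sites <- as.character(sites)
  us <- unique(sites)
  if (length(us) < 2L) stop_arg("need at least 2 sites")
  with_seed(seed, {
    per_site <- stats::setNames(rep(NA_real_, length(us)), us)
    for (st in us) {
      lab <- factor(ifelse(sites == st, "this", "rest"),
                    levels = c("this", "rest"))
      if (min(table(lab)) < 2 * folds) {
        warning(sprintf("site %s smaller than the number of folds: skipped",
                        st))
        next
      }
      accs <- numeric(repeats)
      for (r in seq_len(repeats)) {
        fold <- integer(length(lab))
        for (cl in levels(lab)) {
          idx <- which(lab == cl)
          fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
        }
        pred <- factor(rep(NA_character_, length(lab)),
                       levels = levels(lab))
        for (f in seq_len(folds)) {
          fit <- e1071::svm(x = z[fold != f, , drop = FALSE],
                            y = lab[fold != f], kernel = "linear",
                            cost = cost, scale = FALSE)
          pred[fold == f] <- stats::predict(
            fit, z[fold == f, , drop = FALSE])
        }
        sens <- mean(pred[lab == "this"] == "this")
        spec <- mean(pred[lab == "rest"] == "rest")
        accs[r] <- (sens + spec) / 2
      }
      per_site[st] <- mean(accs)
    }
    list(per_site = per_site, mean = mean(per_site, na.rm = TRUE))
  })
}
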