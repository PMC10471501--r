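# Permutation inference: group-label and spatial spin null models,
# generalized-Pareto tail approximation, BH correction.

#' Generalized-Pareto tail approximation of a permutation p-value
#'
#' For an observed statistic inside the bulk of the null sample the plain
#' add-one empirical proportion is returned; counting remains exact there
#' and, on the discrete statistics produced by overlap proportions, it
#' respects ties that a smooth tail model would undercount. Only when the
#' observed value is (nearly) beyond the permutation resolution -- fewer
#' than `min_exceed_obs` null values at or above it -- is a generalized
#' Pareto distribution fitted by maximum likelihood to the exceedances
#' over the empirical `1 - tail_frac` quantile, screened with an
#' Anderson-Darling goodness-of-fit test (parametric bootstrap) and a
#' threshold lowered in steps of 10 order statistics until the fit is
#' accepted; the p-value is then the tail mass times the GPD survival at
#' the observed value, allowing inference beyond the `1/n_perm`
#' resolution. If no threshold yields an acceptable fit the empirical
#' proportion (floored at `1/(n+1)`) is returned with a warning.
#'
#' @param null numeric null sample (>= 100 values for the tail branch).
#' @param observed observed statistic.
#' @param tail_frac tail mass used for the initial threshold (default
#'   0.10).
#' @param gof_alpha acceptance level of the goodness-of-fit screen.
#' @param n_boot bootstrap replicates for the GOF p-value.
#' @param min_exceed smallest exceedance count to attempt.
#' @param min_exceed_obs counting is kept unless fewer than this many
#'   null values reach the observed statistic (default 10).
#' @return a single p-value in (0, 1].
#' @export
gpd_tail_pvalue <- function(null, observed, tail_frac = 0.10,
                            gof_alpha = 0.05, n_boot = 49,
                            min_exceed = 10, min_exceed_obs = 10) {
  n <- length(null)
  p_emp <- perm_pvalue(null, observed)
  if (sum(null >= observed) >= min_exceed_obs || n < 100) return(p_emp)
  tail <- gpd_tail_fit(null, tail_frac, gof_alpha, n_boot, min_exceed)
  if (is.null(tail)) {
    warning("GPD tail fit never accepted; returning empirical proportion")
    return(max(p_emp, 1 / (n + 1)))
  }
  max(tail$frac * gpd_survival(observed - tail$u, tail$sigma, tail$xi),
      .Machine$double.xmin)
}

# Knijnenburg-style tail selection: fit the GPD to the exceedances over
# the empirical (1 - tail_frac) quantile and lower the threshold in steps
# of 10 order statistics until the Anderson-Darling screen accepts.
# Returns NULL when no threshold yields an acceptable fit. The fit is
# shared by all evaluations against the same null sample (e.g. the
# max-statistic null in FWE correction).
gpd_tail_fit <- function(null, tail_frac = 0.10, gof_alpha = 0.05,
                         n_boot = 49, min_exceed = 10) {
  n <- length(null)
  s <- sort(null)
  n_exc <- floor(tail_frac * n)
  while (n_exc >= min_exceed) {
    u <- (s[n - n_exc] + s[n - n_exc + 1]) / 2
    w <- null[null > u] - u
    if (length(w) < min_exceed || stats::var(w) == 0) return(NULL)
    fit <- gpd_fit(w)
    if (gpd_gof_ok(w, fit, gof_alpha, n_boot))
      return(list(u = u, sigma = fit$sigma, xi = fit$xi,
                  frac = length(w) / n))
    n_exc <- n_exc - 10L
  }
  NULL
}

# ML fit of the generalized Pareto distribution to exceedances w > 0.
# Falls back to the exponential sub-model (xi = 0) when the sample is
# degenerate or the optimiser cannot start.
gpd_fit <- function(w) {
  m <- mean(w)
  v <- stats::var(w)
  if (!is.finite(v) || v <= 0 || m <= 0)
    return(list(sigma = max(m, .Machine$double.eps), xi = 0))
  xi0 <- 0.5 * (1 - m^2 / v)
  sigma0 <- 0.5 * m * (m^2 / v + 1)
  if (!is.finite(xi0) || !is.finite(sigma0) || sigma0 <= 0) {
    xi0 <- 0; sigma0 <- m
  }
  xi0 <- min(max(xi0, -50), 50)
  nll <- function(par) {
    if (any(!is.finite(par)) || abs(par[1]) > 500) return(1e10)
    sigma <- exp(par[1]); xi <- par[2]
    val <- if (abs(xi) < 1e-8) {
      length(w) * log(sigma) + sum(w) / sigma
    } else {
      t <- 1 + xi * w / sigma
      if (any(t <= 0)) return(1e10)
      length(w) * log(sigma) + (1 + 1 / xi) * sum(log(t))
    }
    if (!is.finite(val)) 1e10 else val
  }
  opt <- tryCatch(
    stats::optim(c(log(max(sigma0, 1e-8)), xi0), nll,
                 method = "Nelder-Mead"),
    error = function(e) list(par = c(log(max(sigma0, 1e-8)), xi0)))
  list(sigma = exp(opt$par[1]), xi = opt$par[2])
}

gpd_survival <- function(q, sigma, xi) {
  q <- pmax(q, 0)
  if (abs(xi) < 1e-8) return(exp(-q / sigma))
  t <- 1 + xi * q / sigma
  ifelse(t <= 0, 0, t^(-1 / xi))
}

gpd_quantile_sim <- function(n, sigma, xi) {
  u <- stats::runif(n)
  if (abs(xi) < 1e-8) -sigma * log(u) else sigma * (u^(-xi) - 1) / xi
}

# Anderson-Darling GOF screen with parametric bootstrap p-value.
gpd_gof_ok <- function(w, fit, alpha, n_boot) {
  a2 <- gpd_ad_stat(w, fit)
  boot <- vapply(seq_len(n_boot), function(b) {
    wb <- gpd_quantile_sim(length(w), fit$sigma, fit$xi)
    gpd_ad_stat(wb, gpd_fit(wb))
  }, numeric(1))
  p <- (1 + sum(boot >= a2)) / (n_boot + 1)
  p >= alpha
}

gpd_ad_stat <- function(w, fit) {
  n <- length(w)
  z <- sort(1 - gpd_survival(w, fit$sigma, fit$xi))
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  -n - mean((2 * seq_len(n) - 1) * (log(z) + log(1 - rev(z))))
}

#' Group-label permutation test for overlap differences
#'
#' Tests per-unit (region or network) differences in group means of a
#' subject-level feature matrix -- extreme-deviation indicators,
#' circuit-union indicators, network-deviance bits or threshold-weighted
#' scores -- by permuting the case/control labels. One-sided tail
#' proportions use the add-one estimator and are refined with the
#' generalized-Pareto tail; the two-tailed p is
#' `min(1, 2 min(p_upper, p_lower))`.
#'
#' @param case_mat,control_mat subjects x units matrices (logical or
#'   numeric).
#' @param n_perm number of label permutations.
#' @param seed RNG seed (permutation streams are reproducible
#'   bit-for-bit).
#' @param use_gpd refine tail p-values with the GPD approximation.
#' @param q_fdr BH false-discovery-rate level for the significance flags.
#' @param keep_null keep the per-unit null samples in the result.
#' @return object of class `"perm_test"`: data frame `table` with
#'   `unit`, `delta`, `p_unc`, `p_fdr`, `sig_unc`, `sig_fdr`, plus
#'   `null_model = "group"` and optionally `null` (n_perm x units).
#' @export
group_permutation_test <- function(case_mat, control_mat, n_perm = 10000,
                                   seed = 1L, use_gpd = TRUE,
                                   q_fdr = 0.05, keep_null = FALSE) {
  case_mat <- as.matrix(case_mat) * 1
  control_mat <- as.matrix(control_mat) * 1
  if (nrow(case_mat) == 0L || nrow(control_mat) == 0L)
    stop_arg("both groups must be nonempty")
  if (n_perm < 100) warning("n_perm < 100: unstable p-values")
  X <- rbind(case_mat, control_mat)
  n1 <- nrow(case_mat); n0 <- nrow(control_mat); n <- n1 + n0
  obs <- colMeans(case_mat) - colMeans(control_mat)

  with_seed(seed, {
    W <- matrix(-1 / n0, n_perm, n)
    for (t in seq_len(n_perm))
      W[t, sample.int(n, n1)] <- 1 / n1
    null <- W %*% X
    finish_perm_test(obs, null, colnames(X), use_gpd, q_fdr,
                     "group", keep_null)
  })
}

# Shared tail/two-tailed/FDR machinery for permutation tests.
finish_perm_test <- function(obs, null, units, use_gpd, q_fdr,
                             null_model, keep_null) {
  n_units <- length(obs)
  p_up <- p_lo <- numeric(n_units)
  for (u in seq_len(n_units)) {
    if (use_gpd) {
      # discrete nulls routinely fail the GOF screen and fall back to
      # counting; that is expected here, not worth a warning per unit
      p_up[u] <- suppressWarnings(gpd_tail_pvalue(null[, u], obs[u]))
      p_lo[u] <- suppressWarnings(gpd_tail_pvalue(-null[, u], -obs[u]))
    } else {
      p_up[u] <- perm_pvalue(null[, u], obs[u])
      p_lo[u] <- perm_pvalue(-null[, u], -obs[u])
    }
  }
  p_unc <- pmin(1, 2 * pmin(p_up, p_lo))
  p_fdr <- stats::p.adjust(p_unc, method = "BH")
  out <- list(
    table = data.frame(
      unit = units %||% seq_len(n_units),
      delta = obs, p_unc = p_unc, p_fdr = p_fdr,
      sig_unc = p_unc < 0.05, sig_fdr = p_fdr < q_fdr,
      row.names = NULL),
    null_model = null_model)
  if (keep_null) out$null <- null
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s null): %d units, %d significant at FDR\n",
              x$null_model, nrow(x$table), sum(x$table$sig_fdr)))
  top <- x$table[order(x$table$p_unc), ][seq_len(min(5, nrow(x$table))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH over the tested units; returns the rejection flags and the
#' adjusted p-values.
#'
#' @param p p-values in (0, 1].
#' @param q FDR level.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0L) return(list(reject = logical(0), p_fdr = numeric(0)))
  p_fdr <- stats::p.adjust(p, method = "BH")
  list(reject = p_fdr < q, p_fdr = p_fdr)
}

#' Spin-rotation assignment of cortical regions
#'
#' Draws a uniform random 3D rotation, applies it to the right-hemisphere
#' coordinates and its mirror image (across the x = 0 midline) to the
#' left, and solves the cost-minimising bipartite assignment between
#' rotated and original positions within each hemisphere (Hungarian /
#' shortest-augmenting-path method). The result is a bijection, so a
#' spun surrogate map preserves the original value multiset exactly --
#' and hence each subject's deviation burden after re-thresholding.
#'
#' @param coords n x 3 matrix of unit-sphere coordinates.
#' @param hemisphere `"L"`/`"R"` per region; hemispheres must have equal
#'   size.
#' @param seed RNG seed (ignored when `rotation` is given).
#' @param rotation optional fixed 3 x 3 rotation matrix (applied to the
#'   right hemisphere).
#' @return integer permutation `perm`: the surrogate value at region `i`
#'   is the original value at region `perm[i]`.
#' @export
spin_rotation_assignment <- function(coords, hemisphere, seed = NULL,
                                     rotation = NULL) {
  coords <- as.matrix(coords)
  hemisphere <- as.character(hemisphere)
  nl <- sum(hemisphere == "L"); nr <- sum(hemisphere == "R")
  if (nl != nr) stop_arg("hemispheres of unequal size")
  rot <- rotation %||% with_seed(seed, random_rotation())
  mir <- diag(c(-1, 1, 1))
  perm <- integer(nrow(coords))
  for (h in c("L", "R")) {
    idx <- which(hemisphere == h)
    Rh <- if (h == "R") rot else mir %*% rot %*% mir
    P <- coords[idx, , drop = FALSE] %*% t(Rh)
    cost <- -P %*% t(coords[idx, , drop = FALSE])
    a <- .solve_assignment(cost)         # rotated i -> original slot a[i]
    perm[idx[a]] <- idx
  }
  perm
}

# Uniform random rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Shared spin pool for spatial null tests
#'
#' Precomputes a pool of `n_perm` spin permutations of the cortical
#' regions (each from one random rotation, mirrored across hemispheres).
#' Inside [spatial_null_test()] every subject draws its own rotation
#' from the pool in each permutation, so surrogate seed locations are
#' independent across individuals while each individual's value multiset
#' (and hence burden) is preserved; subcortical entries map to
#' themselves here and are shuffled per subject in the test. The same
#' pool is intended to be shared between the circuit- and network-level
#' spatial tests.
#'
#' @param scheme a `"parcellation"`.
#' @param n_perm pool size.
#' @param seed RNG seed.
#' @return integer matrix (n_perm x regions) of source indices, with
#'   attribute `subcortex` (column indices of subcortical regions).
#' @export
make_spin_ensemble <- function(scheme, n_perm, seed = 1L) {
  r <- scheme$regions
  cort <- which(r$compartment == "cortex")
  with_seed(seed, {
    ens <- matrix(rep(seq_len(nrow(r)), each = n_perm), n_perm, nrow(r))
    for (t in seq_len(n_perm)) {
      p <- spin_rotation_assignment(
        as.matrix(r[cort, c("x", "y", "z")]), r$hemisphere[cort],
        rotation = random_rotation())
      ens[t, cort] <- cort[p]
    }
    attr(ens, "subcortex") <- which(r$compartment == "subcortex")
    ens
  })
}

#' Spatial (spin) permutation test preserving deviation burden
#'
#' The second null model: each subject's unthresholded deviation map is
#' spatially rotated on the sphere (cortex; value-preserving bijection
#' via [spin_rotation_assignment()], drawn independently per subject
#' from a precomputed pool) and its subcortical values are shuffled,
#' the surrogate maps are re-thresholded, the downstream aggregation
#' (regional indicators, circuit union maps, or network deviance) is
#' rebuilt, and the group overlap difference is recomputed. Because
#' every surrogate preserves each subject's set of deviation values
#' exactly, group differences in deviation burden survive under the
#' null -- the surrogates realise "the same number of seeds per person,
#' randomly placed" -- so a significant result indicates preferential
#' spatial targeting, not just higher burden.
#'
#' Since thresholding commutes with a value-preserving relabelling, the
#' test operates directly on the extreme-indicator matrix.
#'
#' @param dev a `"deviation_maps"` object.
#' @param values optional subjects x regions numeric matrix replacing
#'   the extreme indicators as the per-subject regional feature
#'   (regional downstream only) -- e.g. [threshold_weighted_scores()].
#'   The scores must be an entrywise function of the deviation map, so
#'   that rotating values and recomputing scores coincide.
#' @param case,control row indices (into `dev$subjects`) of the two
#'   groups.
#' @param scheme the `"parcellation"`.
#' @param downstream `"regional"`, `"circuit"` or `"network"`.
#' @param sign which extremes to analyse.
#' @param circuits a `"circuit_cache"` (required for
#'   `downstream = "circuit"`).
#' @param netmap region -> network mapping from [assign_networks()]
#'   (required for `downstream = "network"`).
#' @param n_perm number of surrogates.
#' @param seed RNG seed (drives both the ensemble, if not supplied, and
#'   the subcortical shuffles).
#' @param ensemble optional precomputed [make_spin_ensemble()] matrix,
#'   shared across downstream analyses.
#' @param use_gpd refine tail p-values with the GPD approximation.
#' @param q_fdr BH level for significance flags.
#' @param keep_null keep null samples.
#' @return a `"perm_test"` (with `null_model = "spatial"`).
#' @export
spatial_null_test <- function(dev, case, control, scheme,
                              downstream = c("regional", "circuit",
                                             "network"),
                              sign = c("negative", "positive"),
                              circuits = NULL, netmap = NULL,
                              values = NULL,
                              n_perm = 1000, seed = 1L, ensemble = NULL,
                              use_gpd = TRUE, q_fdr = 0.05,
                              keep_null = FALSE) {
  downstream <- match.arg(downstream)
  sign <- match.arg(sign)
  if (!is.null(values) && downstream != "regional")
    stop_arg("`values` is only meaningful for downstream = 'regional'")
  E <- if (is.null(values)) (if (sign == "negative") dev$neg else
    dev$pos) * 1 else as.matrix(values)
  if (is.logical(case)) case <- which(case)
  if (is.logical(control)) control <- which(control)

  aggregate <- switch(downstream,
    regional = function(M) M,
    circuit = {
      if (is.null(circuits)) stop_arg("downstream='circuit' needs `circuits`")
      C <- circuit_matrix(circuits, colnames(E))
      function(M) (M %*% C > 0) * 1
    },
    network = {
      if (is.null(netmap)) stop_arg("downstream='network' needs `netmap`")
      Mn <- outer(names(netmap), sort(unique(netmap)),
                  function(r, nt) netmap[r] == nt) * 1
      rownames(Mn) <- names(netmap)
      colnames(Mn) <- sort(unique(netmap))
      Mn <- Mn[colnames(E), , drop = FALSE]
      function(M) (M %*% Mn > 0) * 1
    })

  obs_units <- aggregate(E)
  obs <- colMeans(obs_units[case, , drop = FALSE]) -
    colMeans(obs_units[control, , drop = FALSE])

  with_seed(seed, {
    if (is.null(ensemble))
      ensemble <- make_spin_ensemble(scheme, n_perm,
                                     seed = sample.int(2^30, 1))
    if (nrow(ensemble) < n_perm)
      stop_arg("ensemble smaller than n_perm")
    sub_cols <- attr(ensemble, "subcortex")
    ns <- nrow(E)
    nR <- ncol(E)
    nsub <- length(sub_cols)
    n_pool <- nrow(ensemble)
    rowidx <- rep(seq_len(ns), times = nR)
    null <- matrix(NA_real_, n_perm, ncol(obs_units))
    for (t in seq_len(n_perm)) {
      # one spin per subject, drawn from the pool
      rid <- sample.int(n_pool, ns, replace = TRUE)
      idx <- ensemble[rid, , drop = FALSE]
      if (nsub > 1L) {
        # per-subject subcortical shuffle, vectorised via rank keys
        keys <- matrix(stats::runif(ns * nsub), ns, nsub)
        pos <- matrix(0L, ns, nsub)
        for (j in seq_len(nsub))
          pos[, j] <- rowSums(keys <= keys[, j])
        # subject i's value at sub slot pos[i, j] comes from sub col j
        idx[cbind(rep(seq_len(ns), nsub),
                  sub_cols[as.vector(pos)])] <-
          rep(sub_cols, each = ns)
      }
      Et <- matrix(E[cbind(rowidx, as.vector(idx))], ns, nR)
      Ut <- aggregate(Et)
      null[t, ] <- colMeans(Ut[case, , drop = FALSE]) -
        colMeans(Ut[control, , drop = FALSE])
    }
    finish_perm_test(obs, null, colnames(obs_units), use_gpd, q_fdr,
                     "spatial", keep_null)
  })
}

#' Cross-scale contrast of circuit- versus regional-level overlap
#'
#' Per region, the statistic is the circuit-level overlap difference
#' minus the regional-level overlap difference (both case minus control);
#' inference is by group-label permutation recomputing both levels under
#' each shuffle. Since both levels are group means of subject-level
#' indicator matrices, this reduces to a group permutation test on their
#' elementwise difference, and the contrast is antisymmetric under
#' swapping the groups.
#'
#' @param union_maps subjects x regions circuit-union indicator matrix
#'   (see [union_maps()]).
#' @param extremes subjects x regions extreme-indicator matrix (same
#'   subjects, same regions).
#' @param case,control group row indices.
#' @inheritParams group_permutation_test
#' @return a `"perm_test"` on the per-region contrast.
#' @export
crossscale_contrast <- function(union_maps, extremes, case, control,
                                n_perm = 10000, seed = 1L, use_gpd = TRUE,
                                q_fdr = 0.05) {
  if (!identical(dim(union_maps), dim(extremes)))
    stop_arg("union maps and extremes have mismatched dimensions")
  D <- union_maps * 1 - extremes * 1
  if (is.logical(case)) case <- which(case)
  if (is.logical(control)) control <- which(control)
  out <- group_permutation_test(D[case, , drop = FALSE],
                                D[control, , drop = FALSE],
                                n_perm = n_perm, seed = seed,
                                use_gpd = use_gpd, q_fdr = q_fdr)
  out$null_model <- "group (cross-scale contrast)"
  out
}
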