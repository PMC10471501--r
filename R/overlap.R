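#' Deviation maps for scored subjects
#'
#' Scores a set of subjects against a normative fit and thresholds the
#' resulting z-maps into positive and negative extreme-deviation
#' indicators.
#'
#' @param fit a `"normative"` model.
#' @param cohort a `"cohort"`.
#' @param z_thr extreme-deviation threshold (strict: `z > z_thr` /
#'   `z < -z_thr`); default 2.6, the conventional |z| cut corresponding to
#'   an uncorrected two-sided tail of 1%% (0.5%% per sign).
#' @param groups which `subjects$group` values to score; default all rows
#'   not used for training (`!= "HC_train"`).
#' @return object of class `"deviation_maps"`: list with `z` (subjects x
#'   regions), `pos`, `neg` (logical indicator matrices), `subjects`,
#'   `z_thr`.
#' @export
deviations <- function(fit, cohort, z_thr = 2.6, groups = NULL) {
  s <- cohort$subjects
  idx <- if (is.null(groups)) which(s$group != "HC_train") else
    which(s$group %in% groups)
  if (length(idx) == 0L) stop_arg("no subjects to score")
  pred <- stats::predict(fit, cohort, subset = idx)
  ext <- threshold_extremes(pred$z, z_thr)
  structure(list(z = pred$z, pos = ext$pos, neg = ext$neg,
                 subjects = pred$subjects, z_thr = z_thr),
            class = "deviation_maps")
}

#' @export
print.deviation_maps <- function(x, ...) {
  cat(sprintf("Deviation maps: %d subjects x %d regions (|z| > %.2f)\n",
              nrow(x$z), ncol(x$z), x$z_thr))
  cat(sprintf("  extremes: %d positive, %d negative\n",
              sum(x$pos), sum(x$neg)))
  invisible(x)
}

#' Threshold a deviation z-map into extreme indicators
#'
#' Strict inequalities on both sides: positive extreme iff `z > z_thr`,
#' negative iff `z < -z_thr`; a value exactly at the threshold is not
#' extreme.
#'
#' @param z numeric matrix (or vector) of deviation z-scores; must be
#'   finite.
#' @param z_thr positive threshold.
#' @return list with logical `pos` and `neg` of the same shape as `z`.
#' @export
threshold_extremes <- function(z, z_thr = 2.6) {
  if (z_thr <= 0) stop_arg("`z_thr` must be positive")
  bad <- !is.finite(z)
  if (any(bad)) {
    w <- which(bad, arr.ind = is.matrix(z))
    stop_arg(sprintf("non-finite z at %s",
                     paste(utils::head(apply(as.matrix(w), 1, paste,
                                             collapse = ","), 3),
                           collapse = "; ")))
  }
  list(pos = z > z_thr, neg = z < -z_thr)
}

#' Per-subject deviation burden
#'
#' Counts each subject's extreme deviations per sign.
#'
#' @param dev a `"deviation_maps"` object (or a list with logical `pos`
#'   and `neg` matrices).
#' @return data frame: `id`, `n_pos`, `n_neg`, `n_total`.
#' @export
deviation_burden <- function(dev) {
  np <- rowSums(dev$pos)
  nn <- rowSums(dev$neg)
  data.frame(id = rownames(dev$pos) %||% seq_along(np),
             n_pos = np, n_neg = nn, n_total = np + nn,
             row.names = NULL)
}

#' Permutation test for a group difference in deviation burden
#'
#' One-sided group-label permutation p-value for mean burden being higher
#' in cases than controls, with the add-one estimator
#' `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param case_burden,control_burden numeric vectors of per-subject
#'   burdens.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `p`, `observed` (difference in means) and `null`.
#' @export
compare_burden <- function(case_burden, control_burden, n_perm = 10000,
                           seed = 1L) {
  if (length(case_burden) == 0L || length(control_burden) == 0L)
    stop_arg("both groups must be nonempty")
  x <- c(case_burden, control_burden)
  n1 <- length(case_burden)
  obs <- mean(case_burden) - mean(control_burden)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(x), n1)
      mean(x[idx]) - mean(x[-idx])
    }, numeric(1))
    list(p = perm_pvalue(null, obs), observed = obs, null = null)
  })
}

#' Group overlap map of extreme deviations
#'
#' The proportion of a group's members showing an extreme deviation in
#' each region (proportions, not raw counts, so groups of different sizes
#' are comparable).
#'
#' @param ind logical subjects x regions indicator matrix (one sign).
#' @param members row indices (or logical) selecting the group.
#' @return object of class `"overlap_map"`: named numeric vector of
#'   per-region proportions with attribute `n_group`.
#' @export
overlap_map <- function(ind, members = seq_len(nrow(ind))) {
  if (is.logical(members)) members <- which(members)
  if (length(members) == 0L) stop_arg("empty group")
  p <- colMeans(ind[members, , drop = FALSE])
  structure(p, n_group = length(members), class = "overlap_map")
}

#' Case-minus-control overlap difference map
#'
#' @param case_map,control_map `"overlap_map"`s on the same parcellation.
#' @return named numeric vector of per-region differences in `[-1, 1]`.
#' @export
delta_overlap <- function(case_map, control_map) {
  if (length(case_map) != length(control_map) ||
      !identical(names(case_map), names(control_map)))
    stop_arg("overlap maps are on different region sets")
  stats::setNames(as.vector(unclass(case_map)) -
                    as.vector(unclass(control_map)), names(case_map))
}

#' Threshold-weighted overlap map
#'
#' A threshold-free alternative to the fixed |z| cut: z-maps are
#' thresholded over `n_thr` log-spaced thresholds in `(z_min, z_max)`;
#' the per-threshold survival proportion is weighted by the linear ramp
#' \deqn{W_{th} = 2 (th - z_{min}) / (z_{max} - z_{min}),} which
#' penalises lenient thresholds; the weighted curve is integrated over
#' thresholds and normalised by its maximum attainable value, so a region
#' where every group member exceeds `z_max` at every threshold scores 1
#' and a region where no one ever crosses `z_min` scores 0.
#'
#' @param z subjects x regions z matrix.
#' @param members group rows (indices or logical).
#' @param sign `"positive"` (`z > th`) or `"negative"` (`z < -th`).
#' @param z_min,z_max threshold range (defaults 1.64 and 3.10).
#' @param n_thr number of thresholds (>= 2), log-spaced inclusive of the
#'   endpoints.
#' @return named numeric vector of per-region weighted overlaps in
#'   `[0, 1]`.
#' @export
threshold_weighted_overlap <- function(z, members = seq_len(nrow(z)),
                                       sign = c("negative", "positive"),
                                       z_min = 1.64, z_max = 3.10,
                                       n_thr = 100) {
  if (is.logical(members)) members <- which(members)
  if (length(members) == 0L) stop_arg("empty group")
  s <- threshold_weighted_scores(z, sign = sign, z_min = z_min,
                                 z_max = z_max, n_thr = n_thr)
  colMeans(s[members, , drop = FALSE])
}

#' @rdname threshold_weighted_overlap
#' @details `threshold_weighted_scores()` returns the per-subject score
#'   matrix whose group mean is the threshold-weighted overlap: each
#'   entry is the weight-normalised sum over thresholds the subject's
#'   |z| exceeds. Because the score is a function of each entry alone,
#'   it commutes with any relabelling of regions, which is what lets
#'   the spatial null operate on it directly.
#' @export
threshold_weighted_scores <- function(z, sign = c("negative", "positive"),
                                      z_min = 1.64, z_max = 3.10,
                                      n_thr = 100) {
  sign <- match.arg(sign)
  if (!(z_max > z_min && z_min > 0)) stop_arg("need z_max > z_min > 0")
  if (n_thr < 2) stop_arg("`n_thr` must be >= 2")
  zz <- if (sign == "negative") -z else z
  th <- exp(seq(log(z_min), log(z_max), length.out = n_thr))
  w <- 2 * (th - z_min) / (z_max - z_min)
  # score(v) = sum of weights of thresholds below v, normalised; a step
  # function of the single value, evaluated via the cumulative weights
  cw <- c(0, cumsum(w))
  k <- findInterval(zz, th, left.open = TRUE)  # thresholds strictly below
  s <- matrix(cw[k + 1] / sum(w), nrow(z), ncol(z))
  dimnames(s) <- dimnames(z)
  s
}
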