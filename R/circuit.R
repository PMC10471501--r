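# Circuit-level mapping: normative seed functional connectivity of
# deviant regions, cluster-enhanced FWE thresholding, parcel-level
# binarization, per-subject union maps.

#' Seed functional-connectivity map for one atlas subject
#'
#' Extracts the mean time course over the seed region's grayordinates,
#' correlates it with every grayordinate (the seed's own included) and
#' applies Fisher's r-to-z transform. Correlations of exactly +/-1 (the
#' seed's own grayordinates when the seed has a single one) are clamped
#' just inside the open interval before `atanh`, with a warning.
#'
#' @param ts grayordinates x timepoints matrix for one atlas subject.
#' @param seed_gray row indices of the seed's grayordinates.
#' @return numeric vector of Fisher-z values, one per grayordinate.
#' @export
seed_fc_map <- function(ts, seed_gray) {
  if (length(seed_gray) == 0L) stop_arg("seed has no grayordinates")
  if (ncol(ts) < 3L) stop_arg("need at least 3 timepoints")
  tc <- colMeans(ts[seed_gray, , drop = FALSE])
  if (stats::sd(tc) == 0) stop_arg("zero-variance seed time course")
  v <- apply(ts, 1, stats::sd)
  if (any(v == 0)) stop_arg("zero-variance grayordinate time course")
  r <- as.vector(stats::cor(tc, t(ts)))
  if (any(abs(r) >= 1 - 1e-12)) {
    warning("|r| = 1 clamped before Fisher transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

#' One-sample t-map across atlas subjects
#'
#' One-sample t statistic of the Fisher-z values against zero at each
#' grayordinate. Grayordinates with zero across-subject variance get an
#' infinite sentinel (with a warning).
#'
#' @param zmaps subjects x grayordinates matrix of Fisher-z values.
#' @return numeric t vector, one value per grayordinate.
#' @export
group_t_map <- function(zmaps) {
  n <- nrow(zmaps)
  if (n < 2L) stop_arg("need at least 2 atlas subjects")
  m <- colMeans(zmaps)
  v <- (colSums(zmaps^2) - n * m^2) / (n - 1)
  t_ <- m / sqrt(pmax(v, 0) / n)
  if (any(v <= 1e-300)) {
    warning("zero across-subject variance: t set to a +/-Inf sentinel")
    deg <- v <= 1e-300
    t_[deg] <- ifelse(m[deg] == 0, 0, sign(m[deg]) * Inf)
  }
  t_
}

#' Threshold-free cluster enhancement on a grayordinate graph
#'
#' For each node g, integrates `extent(h, g)^E * h^H` over supra-threshold
#' heights h (step `dh`, right endpoints), where `extent(h, g)` is the
#' size of g's connected component in the subgraph of nodes with
#' statistic >= h. Only the positive part of the statistic is enhanced.
#' The caller is expected to run cortex and subcortex separately (their
#' grayordinates live in disconnected components anyway).
#'
#' @param stat node statistic.
#' @param edges two-column matrix of node indices (each undirected edge
#'   once).
#' @param E,H extent and height exponents (defaults 0.5 and 2, the
#'   standard surface/graph setting).
#' @param dh height step; `NULL` uses `max(stat)/100` floored at 1e-3
#'   (resolution-independent).
#' @return enhanced statistic per node.
#' @export
tfce_enhance <- function(stat, edges, E = 0.5, H = 2, dh = NULL) {
  if (!is.null(dh) && dh <= 0) stop_arg("`dh` must be positive")
  if (is.null(dh)) dh <- max(max(stat, 0) / 100, 1e-3)
  edges <- as.matrix(edges)
  .tfce_graph(pmax(stat, 0), as.integer(edges[, 1] - 1L),
              as.integer(edges[, 2] - 1L), dh, E, H)
}

#' FWE-thresholded binary map from subject-level Fisher-z maps
#'
#' Aggregates the subject maps with a one-sample t-test, enhances the
#' t-map with TFCE, and compares each grayordinate's enhanced value
#' against the max-TFCE null distribution obtained by sign-flipping
#' whole subjects (exchangeable under a symmetric null). Family-wise
#' error p-values use add-one counting against the null maxima with
#' generalized-Pareto tail refinement; cortex and subcortex are tested
#' independently, each at level `alpha` (0.025 = 0.05/2 by default, the
#' two-compartment split).
#'
#' @param zmaps subjects x grayordinates Fisher-z matrix.
#' @param edges grayordinate adjacency (two-column index matrix).
#' @param compartment `"cortex"`/`"subcortex"` per grayordinate.
#' @param n_perm sign-flip permutations (default 500; below 50 the GPD
#'   tail is unstable and a warning is issued).
#' @param alpha per-compartment FWE level.
#' @param E,H,dh TFCE parameters (see [tfce_enhance()]).
#' @param seed RNG seed for the sign flips.
#' @return logical vector: grayordinates significant at `p_FWE < alpha`.
#' @export
fwe_binarize <- function(zmaps, edges, compartment, n_perm = 500,
                         alpha = 0.025, E = 0.5, H = 2, dh = NULL,
                         seed = 1L) {
  n <- nrow(zmaps)
  if (n < 2L) stop_arg("need at least 2 atlas subjects")
  if (n_perm < 50) warning("n_perm < 50: unstable GPD tail fit")
  edges <- as.matrix(edges)
  sig <- logical(ncol(zmaps))

  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    css <- colSums(zmaps^2)
    for (cp in unique(compartment)) {
      idx <- which(compartment == cp)
      sub_edges <- edges[edges[, 1] %in% idx & edges[, 2] %in% idx, ,
                         drop = FALSE]
      remap <- match(sub_edges, idx)
      dim(remap) <- dim(sub_edges)
      Z <- zmaps[, idx, drop = FALSE]
      tobs <- suppressWarnings(group_t_map(Z))
      # +/-Inf sentinels become just-above-maximum finite heights
      inf <- is.infinite(tobs)
      if (any(inf))
        tobs[inf] <- sign(tobs[inf]) * (max(abs(tobs[!inf]), 0) + 1)
      dh_cp <- dh %||% max(max(tobs, 0) / 100, 1e-3)
      enh <- tfce_enhance(tobs, remap, E, H, dh_cp)

      # sign-flip null: means change, second moments do not
      M <- (S %*% Z) / n
      V <- (rep(css[idx], each = n_perm) - n * M^2) / (n - 1)
      Tn <- M / sqrt(pmax(V, .Machine$double.eps) / n)
      null_max <- vapply(seq_len(n_perm), function(t)
        max(tfce_enhance(Tn[t, ], remap, E, H, dh_cp)), numeric(1))

      # shared max-statistic null: one tail fit serves every grayordinate;
      # the GPD only extrapolates beyond the counting resolution
      p <- vapply(enh, function(e) perm_pvalue(null_max, e), numeric(1))
      cnt <- vapply(enh, function(e) sum(null_max >= e), numeric(1))
      in_tail <- cnt < 10
      if (any(in_tail) && n_perm >= 100) {
        tail <- gpd_tail_fit(null_max)
        if (!is.null(tail))
          p[in_tail] <- pmax(
            tail$frac * gpd_survival(enh[in_tail] - tail$u,
                                     tail$sigma, tail$xi),
            .Machine$double.xmin)
      }
      sig[idx] <- p < alpha
    }
  })
  sig
}

#' Parcellate a binary grayordinate map to regions
#'
#' A region is included iff strictly more than `frac` of its
#' grayordinates survive (`0.5` by default; `0.75` for the conservative
#' mapping threshold).
#'
#' @param gray_sig logical per-grayordinate significance.
#' @param lookup grayordinate -> region id (as in an `"fc_atlas"`).
#' @param frac inclusion fraction (strict inequality).
#' @return named logical vector per region.
#' @export
parcellate_binary <- function(gray_sig, lookup, frac = 0.5) {
  counts <- table(lookup)
  if (any(counts == 0)) stop_arg("region with zero grayordinates")
  surv <- tapply(gray_sig, lookup, sum)
  out <- as.vector(surv / as.vector(counts[names(surv)])) > frac
  names(out) <- names(surv)
  # order regions numerically
  out[order(as.numeric(names(out)))]
}

#' Map the normative functional circuits of a set of seed regions
#'
#' For each seed region: seed FC maps across all atlas subjects, group
#' t-map, TFCE + sign-flip FWE thresholding per compartment, and
#' parcel-level binarization. Circuits are computed once per unique seed
#' and cached; the RNG stream is split per seed so the cache is
#' deterministic given (atlas, seed region, seed).
#'
#' @param atlas an `"fc_atlas"`.
#' @param scheme the matching `"parcellation"`.
#' @param seed_regions region ids to map (default: all regions).
#' @param n_perm,alpha,E,H,dh see [fwe_binarize()].
#' @param frac parcel inclusion fraction (see [parcellate_binary()]).
#' @param seed RNG seed.
#' @return object of class `"circuit_cache"`: logical seeds x regions
#'   matrix (row = seed region, columns = coupled regions) with
#'   provenance in attributes.
#' @export
build_circuits <- function(atlas, scheme, seed_regions = NULL,
                           n_perm = 500, alpha = 0.025, frac = 0.5,
                           E = 0.5, H = 2, dh = NULL, seed = 1L) {
  rids <- scheme$regions$region_id
  seed_regions <- seed_regions %||% rids
  if (!all(seed_regions %in% rids)) stop_arg("unknown seed region id")
  gray_region <- atlas$lookup
  n_sub <- length(atlas$timeseries)

  # standardized series per subject, computed once: the Fisher-z map of
  # any seed is then a single matrix product (same result as
  # seed_fc_map, asserted in the tests)
  Tn <- ncol(atlas$timeseries[[1]])
  Xs <- lapply(atlas$timeseries, function(ts) {
    m <- rowMeans(ts)
    s <- sqrt(rowSums((ts - m)^2) / (Tn - 1))
    if (any(s == 0)) stop_arg("zero-variance grayordinate time course")
    (ts - m) / s
  })

  out <- matrix(FALSE, length(seed_regions), length(rids),
                dimnames = list(seed_regions, rids))
  for (k in seq_along(seed_regions)) {
    sr <- seed_regions[k]
    gidx <- which(gray_region == sr)
    if (length(gidx) == 0L) stop_arg(sprintf("region %s has no grayordinates", sr))
    zmaps <- t(vapply(seq_len(n_sub), function(s) {
      tc <- colMeans(atlas$timeseries[[s]][gidx, , drop = FALSE])
      tc <- (tc - mean(tc))
      sdt <- sqrt(sum(tc^2) / (Tn - 1))
      if (sdt == 0) stop_arg("zero-variance seed time course")
      r <- as.vector(Xs[[s]] %*% (tc / sdt)) / (Tn - 1)
      r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
      atanh(r)
    }, numeric(length(gray_region))))
    gray_sig <- fwe_binarize(zmaps, atlas$adjacency, atlas$compartment,
                             n_perm = n_perm, alpha = alpha,
                             E = E, H = H, dh = dh,
                             seed = seed + k)
    out[k, ] <- parcellate_binary(gray_sig, gray_region, frac)[
      as.character(rids)]
  }
  structure(out, class = "circuit_cache",
            provenance = list(n_perm = n_perm, alpha = alpha, frac = frac,
                              E = E, H = H, n_atlas_subjects = n_sub,
                              seed = seed))
}

#' @export
print.circuit_cache <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf(
    "Circuit cache: %d seeds x %d regions (FWE alpha %.3f, %d perms, frac %.2f)\n",
    nrow(x), ncol(x), pr$alpha, pr$n_perm, pr$frac))
  cat(sprintf("  mean circuit size: %.1f regions\n", mean(rowSums(x))))
  invisible(x)
}

# Full regions x regions matrix from a cache, erroring on regions the
# cache does not cover.
circuit_matrix <- function(circuits, region_names) {
  miss <- setdiff(region_names, rownames(circuits))
  if (length(miss) > 0L)
    stop_arg(sprintf(
      "no cached circuit for region(s) %s; build the cache for all regions",
      paste(utils::head(miss, 5), collapse = ", ")))
  (circuits[region_names, region_names, drop = FALSE]) * 1
}

#' Per-subject circuit union map
#'
#' The elementwise OR over the circuits of a subject's extreme regions:
#' one binary region vector marking every area significantly coupled to
#' at least one of the person's deviations. An empty extreme set yields
#' an all-zero map; adding a seed can only turn regions on.
#'
#' @param extreme_regions region ids where the subject has an extreme
#'   deviation (one sign).
#' @param circuits a `"circuit_cache"` covering those regions.
#' @return named logical region vector.
#' @export
union_map <- function(extreme_regions, circuits) {
  if (length(extreme_regions) == 0L)
    return(stats::setNames(rep(FALSE, ncol(circuits)), colnames(circuits)))
  miss <- setdiff(as.character(extreme_regions), rownames(circuits))
  if (length(miss) > 0L)
    stop_arg(sprintf("no cached circuit for region %s", miss[1]))
  colSums(circuits[as.character(extreme_regions), , drop = FALSE]) > 0
}

#' Circuit union maps for every subject
#'
#' @param ind subjects x regions extreme-indicator matrix (one sign).
#' @param circuits a `"circuit_cache"` covering all regions.
#' @return subjects x regions logical matrix of union maps.
#' @export
union_maps <- function(ind, circuits) {
  C <- circuit_matrix(circuits, colnames(ind))
  U <- (ind * 1) %*% C > 0
  dimnames(U) <- dimnames(ind)
  U
}

#' Circuit-level overlap map
#'
#' Per region, the proportion of the group's members whose circuit union
#' map covers it.
#'
#' @param U subjects x regions union-map matrix (see [union_maps()]).
#' @param members group rows.
#' @return an `"overlap_map"`.
#' @export
circuit_overlap <- function(U, members = seq_len(nrow(U))) {
  overlap_map(U, members)
}
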