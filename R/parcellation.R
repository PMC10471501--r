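#' Generate a synthetic spherical parcellation
#'
#' Builds a miniature brain parcellation: `n_cortex` cortical regions placed
#' quasi-uniformly on the unit sphere (a Fibonacci lattice per hemisphere,
#' mirrored across the x = 0 midline) and `n_subcortex` subcortical regions
#' placed inside a central ball. Cortical regions are assigned to the seven
#' canonical functional networks (visual, somatomotor, dorsal attention,
#' salience/ventral attention, limbic, frontoparietal, default mode) as
#' contiguous spherical Voronoi patches, so that spatial spin tests remain
#' meaningful; subcortical regions are assigned to medial temporal lobe,
#' thalamus or basal ganglia. A finer 20-network labelling (17 cortical
#' subnetworks nested inside the 7, plus the 3 subcortical groups) is
#' generated as a refinement of the coarse patches. Each region owns
#' `gray_per_region` grayordinates jittered around the region centroid.
#'
#' @param n_cortex number of cortical regions (even; split across hemispheres).
#' @param n_subcortex number of subcortical regions.
#' @param gray_per_region grayordinates per region.
#' @param seed RNG seed; the scheme is a pure function of its arguments.
#' @return An object of class `"parcellation"`: a list with elements
#'   `regions` (data frame: `region_id`, `hemisphere`, `compartment`,
#'   `x`, `y`, `z`, `network10`, `network20`) and `gray` (data frame:
#'   `gray_id`, `region_id`, `x`, `y`, `z`).
#' @examples
#' sch <- make_parcellation(100, 8, 4, seed = 1)
#' nrow(sch$regions)  # 108
#' @export
make_parcellation <- function(n_cortex, n_subcortex, gray_per_region,
                              seed = 1L) {
  n_cortex <- check_count(n_cortex, "n_cortex")
  n_subcortex <- check_count(n_subcortex, "n_subcortex")
  gray_per_region <- check_count(gray_per_region, "gray_per_region")
  if (n_cortex %% 2L != 0L)
    stop_arg("`n_cortex` must be even (regions are split across hemispheres)")

  with_seed(seed, {
    nh <- n_cortex %/% 2L
    # Fibonacci lattice on the x > 0 hemisphere, then mirrored for the left.
    i <- seq_len(nh)
    xh <- (i - 0.5) / nh                 # in (0, 1): distance from midline
    phi <- (1 + sqrt(5)) / 2
    theta <- 2 * pi * i / phi
    rho <- sqrt(pmax(0, 1 - xh^2))
    right <- cbind(x = xh, y = rho * cos(theta), z = rho * sin(theta))
    left <- right
    left[, "x"] <- -left[, "x"]
    coords <- rbind(left, right)
    hemi <- rep(c("L", "R"), each = nh)

    # 7 cortical networks as Voronoi patches of random seed directions,
    # classified on mirrored coordinates (|x|, y, z) so patches are
    # homotopic across hemispheres.
    net7 <- c("VIS", "SM", "DA", "SAL/VA", "L", "F", "DM")
    seeds7 <- matrix(stats::rnorm(21), 7, 3)
    seeds7 <- seeds7 / sqrt(rowSums(seeds7^2))
    seeds7[, 1] <- abs(seeds7[, 1])
    mirr <- coords
    mirr[, 1] <- abs(mirr[, 1])
    sim <- mirr %*% t(seeds7)
    network10 <- net7[max.col(sim, ties.method = "first")]

    # 17-network refinement: split each coarse patch into 2-3 spatial
    # subpatches (3+3+3+2+2+2+2 = 17), nested by construction.
    n_split <- c(3L, 3L, 3L, 2L, 2L, 2L, 2L)
    network20 <- character(n_cortex)
    for (k in seq_along(net7)) {
      idx <- which(network10 == net7[k])
      if (length(idx) == 0L) next
      # mirrored coordinates coincide across hemispheres; cluster the
      # distinct points and assign regions to the nearest centre so the
      # refinement stays homotopic
      pts <- unique(mirr[idx, , drop = FALSE])
      ns <- min(n_split[k], nrow(pts))
      if (ns <= 1L) {
        network20[idx] <- paste0(net7[k], ".1")
      } else {
        centers <- if (nrow(pts) > ns)
          stats::kmeans(pts, centers = ns, nstart = 5)$centers
        else pts  # tiny patch: every distinct point is its own centre
        nn <- apply(mirr[idx, , drop = FALSE], 1, function(p)
          which.min(colSums((t(centers) - p)^2)))
        network20[idx] <- paste0(net7[k], ".", nn)
      }
    }

    # Subcortex: points in a ball of radius 0.4, L/R alternating,
    # anatomical groups cycling through MeTe/Tha/Bas.
    subnet <- c("MeTe", "Tha", "Bas")
    sub_coords <- matrix(stats::rnorm(3 * n_subcortex), ncol = 3)
    sub_coords <- 0.4 * sub_coords /
      sqrt(rowSums(sub_coords^2)) * stats::runif(n_subcortex)^(1 / 3)
    sub_net <- subnet[(seq_len(n_subcortex) - 1L) %% 3L + 1L]
    sub_hemi <- rep(c("L", "R"), length.out = n_subcortex)

    regions <- data.frame(
      region_id = seq_len(n_cortex + n_subcortex),
      hemisphere = c(hemi, sub_hemi),
      compartment = rep(c("cortex", "subcortex"), c(n_cortex, n_subcortex)),
      x = c(coords[, 1], sub_coords[, 1]),
      y = c(coords[, 2], sub_coords[, 2]),
      z = c(coords[, 3], sub_coords[, 3]),
      network10 = c(network10, sub_net),
      network20 = c(network20, sub_net),
      stringsAsFactors = FALSE
    )

    # Grayordinates: jitter around the region centroid; cortical ones are
    # re-projected to the sphere.
    nreg <- nrow(regions)
    gid <- seq_len(nreg * gray_per_region)
    rid <- rep(regions$region_id, each = gray_per_region)
    g <- matrix(stats::rnorm(length(gid) * 3, sd = 0.02), ncol = 3)
    g <- g + as.matrix(regions[match(rid, regions$region_id),
                               c("x", "y", "z")])
    cort <- regions$compartment[match(rid, regions$region_id)] == "cortex"
    g[cort, ] <- g[cort, ] / sqrt(rowSums(g[cort, , drop = FALSE]^2))
    gray <- data.frame(gray_id = gid, region_id = rid,
                       x = g[, 1], y = g[, 2], z = g[, 3])

    out <- list(regions = regions, gray = gray)
    class(out) <- "parcellation"
    validate_parcellation(out)
    out
  })
}

validate_parcellation <- function(scheme) {
  r <- scheme$regions
  cort <- r$compartment == "cortex"
  nrm <- sqrt(r$x[cort]^2 + r$y[cort]^2 + r$z[cort]^2)
  if (any(abs(nrm - 1) > 1e-9))
    stop_arg("cortical coordinates must lie on the unit sphere")
  if (anyDuplicated(scheme$gray$gray_id))
    stop_arg("grayordinate ids must be disjoint across regions")
  if (!all(r$region_id %in% scheme$gray$region_id))
    stop_arg("every region needs at least one grayordinate")
  if (!all(r$network10[!cort] %in% c("MeTe", "Tha", "Bas")))
    stop_arg("subcortical regions must be labelled MeTe, Tha or Bas")
  invisible(scheme)
}

#' @export
print.parcellation <- function(x, ...) {
  r <- x$regions
  cat(sprintf(
    "Parcellation: %d regions (%d cortical, %d subcortical), %d grayordinates\n",
    nrow(r), sum(r$compartment == "cortex"),
    sum(r$compartment == "subcortex"), nrow(x$gray)))
  cat("Networks (10):", paste(sort(unique(r$network10)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Map regions to functional networks
#'
#' Returns the region-to-network assignment at the coarse (10-network:
#' 7 cortical + 3 subcortical) or fine (20-network: 17 cortical +
#' 3 subcortical) level.
#'
#' @param scheme a `"parcellation"`.
#' @param level 10 or 20.
#' @return named character vector, one network label per region, names are
#'   region ids.
#' @export
assign_networks <- function(scheme, level = 10) {
  if (!level %in% c(10, 20)) stop_arg("`level` must be 10 or 20")
  lab <- if (level == 10) scheme$regions$network10 else scheme$regions$network20
  if (any(is.na(lab) | lab == ""))
    stop_arg("unlabelled region in parcellation")
  cort <- scheme$regions$compartment == "cortex"
  if (any(lab[!cort] %in% setdiff(unique(lab[cort]), c("MeTe", "Tha", "Bas"))))
    stop_arg("subcortical region carries a cortical network label")
  stats::setNames(lab, scheme$regions$region_id)
}
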