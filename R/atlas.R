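#' Generate a synthetic normative functional-connectivity atlas
#'
#' Simulates a reference cohort of resting-state-like grayordinate time
#' series with community structure aligned to the parcellation's network
#' labels. Each grayordinate's series is a weighted sum of a latent
#' signal shared within its fine (20-level) network patch (weight
#' `community_strength`), a weaker latent shared within its coarse
#' (10-level) network (weight `community_strength * mix10`, so circuits
#' stay spatially specific while coarse networks remain positively
#' coupled), an optional hub latent broadcast to the grayordinates of
#' `hub_regions` (creating a strongly inter-coupled hub set), and unit
#' white noise. The grayordinate adjacency is a symmetric
#' k-nearest-neighbour graph built within each compartment, augmented to
#' be connected within compartment, so cortex and subcortex form exactly
#' two components (the cluster-enhancement step runs separately per
#' compartment).
#'
#' @param scheme a `"parcellation"`.
#' @param n_subjects reference cohort size (>= 10).
#' @param T timepoints per scan (>= 50; a warning below 50 would be an
#'   error here since correlations are unstable).
#' @param community_strength weight of the network latent signal (0 = pure
#'   noise).
#' @param hub_regions optional region ids receiving an additional shared
#'   latent (weight `hub_strength`), creating a strongly inter-coupled hub
#'   set.
#' @param hub_strength weight of the hub latent; default 0.8.
#' @param mix10 relative weight of the coarse-network latent; default
#'   0.3.
#' @param knn neighbours per grayordinate in the adjacency graph.
#' @param seed RNG seed.
#' @return An object of class `"fc_atlas"`: list with `timeseries` (list of
#'   grayordinate x T matrices, one per subject), `adjacency` (two-column
#'   edge matrix of grayordinate indices, each undirected edge once),
#'   `lookup` (grayordinate -> region id), and `compartment` (per
#'   grayordinate).
#' @export
make_fc_atlas <- function(scheme, n_subjects = 30, T = 200,
                          community_strength = 0.6,
                          hub_regions = NULL, hub_strength = 0.8,
                          mix10 = 0.3, knn = 6, seed = 1L) {
  stopifnot(inherits(scheme, "parcellation"))
  n_subjects <- check_count(n_subjects, "n_subjects", min = 10L)
  T <- check_count(T, "T", min = 3L)
  if (T < 50) warning("T < 50: correlation estimates will be unstable")

  gray <- scheme$gray
  ng <- nrow(gray)
  reg <- scheme$regions
  ridx <- match(gray$region_id, reg$region_id)
  net10 <- reg$network10[ridx]
  net20 <- reg$network20[ridx]
  comp <- reg$compartment[ridx]
  nets10 <- unique(net10)
  nets20 <- unique(net20)
  hub_gray <- gray$region_id %in% hub_regions

  with_seed(seed, {
    ts <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      lat10 <- matrix(stats::rnorm(length(nets10) * T), length(nets10), T,
                      dimnames = list(nets10, NULL))
      lat20 <- matrix(stats::rnorm(length(nets20) * T), length(nets20), T,
                      dimnames = list(nets20, NULL))
      hub_lat <- stats::rnorm(T)
      x <- community_strength * lat20[net20, , drop = FALSE] +
        community_strength * mix10 * lat10[net10, , drop = FALSE] +
        matrix(stats::rnorm(ng * T), ng, T)
      if (any(hub_gray))
        x[hub_gray, ] <- x[hub_gray, ] +
          hub_strength * matrix(hub_lat, sum(hub_gray), T, byrow = TRUE)
      rownames(x) <- gray$gray_id
      ts[[s]] <- x
    }

    adjacency <- knn_graph(as.matrix(gray[, c("x", "y", "z")]), comp, knn)

    out <- list(timeseries = ts, adjacency = adjacency,
                lookup = stats::setNames(gray$region_id, gray$gray_id),
                compartment = comp)
    class(out) <- "fc_atlas"
    out
  })
}

# Symmetric kNN graph within compartments, augmented with minimal bridging
# edges so each compartment is one connected component.
knn_graph <- function(coords, compartment, k) {
  n <- nrow(coords)
  edges <- matrix(integer(0), 0, 2)
  for (cp in unique(compartment)) {
    idx <- which(compartment == cp)
    d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
    diag(d) <- Inf
    kk <- min(k, length(idx) - 1L)
    e <- do.call(rbind, lapply(seq_along(idx), function(i) {
      nb <- order(d[i, ])[seq_len(kk)]
      cbind(idx[i], idx[nb])
    }))
    e <- t(apply(e, 1, sort))
    e <- unique(e)
    # bridge components until the compartment is connected
    repeat {
      cmp <- edge_components(n, e)[idx]
      if (length(unique(cmp)) <= 1L) break
      main <- idx[cmp == cmp[1]]
      other <- idx[cmp != cmp[1]]
      dd <- as.matrix(stats::dist(coords))[main, other, drop = FALSE]
      w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      e <- rbind(e, sort(c(main[w[1]], other[w[2]])))
    }
    edges <- rbind(edges, e)
  }
  colnames(edges) <- c("from", "to")
  edges[edges[, 1] != edges[, 2], , drop = FALSE]
}

# Connected-component labels from an edge list (simple union-find in R).
edge_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat(sprintf(
    "FC atlas: %d subjects, %d grayordinates x %d timepoints, %d edges\n",
    length(x$timeseries), nrow(x$timeseries[[1]]),
    ncol(x$timeseries[[1]]), nrow(x$adjacency)))
  invisible(x)
}

#' Region-level normative coupling matrix
#'
#' Mean (across atlas subjects) Pearson correlation between region-mean
#' time courses; a convenient symmetric region x region reference for
#' scenario construction and sanity checks.
#'
#' @param atlas an `"fc_atlas"`.
#' @param scheme the matching `"parcellation"`.
#' @return symmetric regions x regions matrix with unit diagonal.
#' @export
region_coupling <- function(atlas, scheme) {
  rids <- scheme$regions$region_id
  acc <- 0
  for (ts in atlas$timeseries) {
    rts <- rowsum(ts, group = atlas$lookup) /
      as.vector(table(atlas$lookup)[as.character(sort(unique(atlas$lookup)))])
    acc <- acc + stats::cor(t(rts))
  }
  m <- acc / length(atlas$timeseries)
  m <- m[as.character(rids), as.character(rids)]
  (m + t(m)) / 2
}
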