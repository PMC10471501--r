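# Network-level aggregation of extreme deviations.

#' Per-subject network deviance
#'
#' A network is deviant for a subject iff at least one of its member
#' regions carries an extreme deviation (per sign).
#'
#' @param ind subjects x regions extreme-indicator matrix (one sign).
#' @param netmap region -> network mapping from [assign_networks()];
#'   must cover every column of `ind`.
#' @return subjects x networks logical matrix.
#' @export
network_deviance <- function(ind, netmap) {
  miss <- setdiff(colnames(ind), names(netmap))
  if (length(miss) > 0L)
    stop_arg(sprintf("region %s missing from the network mapping",
                     miss[1]))
  nets <- sort(unique(netmap))
  M <- vapply(nets, function(nt)
    netmap[colnames(ind)] == nt, logical(ncol(ind))) * 1
  out <- (ind * 1) %*% M > 0
  dimnames(out) <- list(rownames(ind), nets)
  out
}

#' Network-level overlap map
#'
#' Per network, the proportion of the group's members with at least one
#' extreme deviation in that network. Because the network bit is an OR
#' over member regions, network overlap is always at least the maximum
#' regional overlap among members. Differences between networks are
#' confounded by network size; the intended comparison is case versus
#' control within each network.
#'
#' @param nd subjects x networks deviance matrix (see
#'   [network_deviance()]).
#' @param members group rows.
#' @return an `"overlap_map"` over networks.
#' @export
network_overlap <- function(nd, members = seq_len(nrow(nd))) {
  overlap_map(nd, members)
}
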