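# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small parcellation/cohort/atlas used by many unit tests.
tiny_scheme <- function() fixture("tiny_scheme",
  make_parcellation(40, 6, 4, seed = 1))

tiny_cohort <- function() fixture("tiny_cohort", {
  spec <- data.frame(site = c("a", "b", "c", "d"), n_hc = 50, n_case = 10)
  make_cohort(tiny_scheme(), spec, seed = 2)
})

tiny_atlas <- function() fixture("tiny_atlas",
  make_fc_atlas(tiny_scheme(), n_subjects = 12, T = 120,
                community_strength = 0.7, hub_regions = c(3, 9),
                seed = 3))

tiny_fit <- function() fixture("tiny_fit", {
  coh <- split_train_test(tiny_cohort(), seed = 5)
  list(cohort = coh, fit = normative(coh))
})

# Independent brute-force TFCE oracle with explicit component labelling.
tfce_oracle <- function(stat, edges, E = 0.5, H = 2, dh = 0.1) {
  n <- length(stat)
  out <- numeric(n)
  hmax <- max(stat)
  hs <- seq(dh, hmax + 1e-12, by = dh)
  for (h in hs) {
    on <- which(stat >= h - 1e-12)
    if (length(on) == 0) next
    # label components by repeated BFS over the induced subgraph
    lab <- rep(NA_integer_, n)
    cur <- 0L
    for (v in on) {
      if (!is.na(lab[v])) next
      cur <- cur + 1L
      queue <- v
      lab[v] <- cur
      while (length(queue) > 0) {
        u <- queue[1]; queue <- queue[-1]
        nb <- c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1])
        nb <- nb[nb %in% on & is.na(lab[nb])]
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    sizes <- table(lab)
    for (v in on)
      out[v] <- out[v] + dh * as.numeric(sizes[lab[v]])^E * h^H
  }
  out
}
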