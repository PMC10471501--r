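test_that("TFCE of an isolated node integrates height only", {
  # node of height 1.0, dh = 0.1: 0.1 * sum_{h=0.1..1.0} 1^E * h^2 = 0.385
  v <- tfce_enhance(c(1, 0), rbind(c(1, 2)), E = 0.5, H = 2, dh = 0.1)
  expect_equal(v[1], 0.385, tolerance = 1e-9)
  expect_equal(v[2], 0)
  expect_equal(tfce_enhance(c(0, 0, 0), rbind(c(1, 2), c(2, 3))),
               c(0, 0, 0))
  expect_error(tfce_enhance(c(1, 0), rbind(c(1, 2)), dh = -0.1),
               "positive")
})

test_that("TFCE on small graphs equals the brute-force oracle", {
  edges_path <- cbind(1:5, 2:6)
  set.seed(5)
  for (rep in 1:5) {
    stat <- round(runif(6, 0, 2), 2)
    got <- tfce_enhance(stat, edges_path, E = 0.5, H = 2, dh = 0.1)
    want <- tfce_oracle(stat, edges_path, E = 0.5, H = 2, dh = 0.1)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # a branched graph too
  edges_tree <- rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(4, 6))
  stat <- c(1.2, 0.4, 0.9, 1.6, 0.2, 1.1)
  expect_equal(tfce_enhance(stat, edges_tree, dh = 0.1),
               tfce_oracle(stat, edges_tree, dh = 0.1), tolerance = 1e-9)
})

test_that("FWE thresholding is calibrated on null maps and detects signal", {
  sch <- tiny_scheme()
  # null atlas: nothing should survive much beyond the nominal level
  a0 <- make_fc_atlas(sch, n_subjects = 12, T = 150,
                      community_strength = 0, seed = 13)
  gidx <- which(a0$lookup == 5)
  zmaps <- t(sapply(a0$timeseries, seed_fc_map, seed_gray = gidx))
  # drop the seed's own grayordinates from the calibration count
  own <- which(a0$lookup == 5)
  sig <- fwe_binarize(zmaps, a0$adjacency, a0$compartment,
                      n_perm = 200, alpha = 0.025, seed = 2)
  expect_lt(mean(sig[-own]), 0.05)

  # strong community coupling: the seed's network lights up beyond the seed
  a9 <- make_fc_atlas(sch, n_subjects = 12, T = 200,
                      community_strength = 0.9, seed = 13)
  zs <- t(sapply(a9$timeseries, seed_fc_map, seed_gray = which(a9$lookup == 5)))
  sig9 <- fwe_binarize(zs, a9$adjacency, a9$compartment,
                       n_perm = 200, alpha = 0.025, seed = 2)
  expect_gt(sum(sig9[-own]), 0)

  # degenerate input: all-zero maps yield nothing significant
  z0 <- matrix(0, 12, length(a0$lookup))
  expect_silent({
    s0 <- suppressWarnings(fwe_binarize(z0, a0$adjacency, a0$compartment,
                                        n_perm = 60, seed = 1))
  })
  expect_false(any(s0))
})

test_that("fast per-seed Fisher maps agree with seed_fc_map", {
  atl <- tiny_atlas()
  sch <- tiny_scheme()
  gidx <- which(atl$lookup == 3)
  direct <- seed_fc_map(atl$timeseries[[1]], gidx)
  # the cached-standardisation path inside build_circuits
  ts <- atl$timeseries[[1]]
  Tn <- ncol(ts)
  m <- rowMeans(ts); s <- sqrt(rowSums((ts - m)^2) / (Tn - 1))
  X <- (ts - m) / s
  tc <- colMeans(ts[gidx, , drop = FALSE]); tc <- tc - mean(tc)
  r <- as.vector(X %*% (tc / sqrt(sum(tc^2) / (Tn - 1)))) / (Tn - 1)
  expect_equal(atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)), direct,
               tolerance = 1e-10)
})

test_that("group t-map matches hand computation", {
  z <- matrix(c(1, 2, 3, -1, 0, 1), 3, 2)
  t_ <- group_t_map(z)
  expect_equal(t_[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(t_[2], 0)
  expect_error(group_t_map(z[1, , drop = FALSE]), "at least 2")
  expect_warning(group_t_map(matrix(1, 3, 2)), "variance")
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
})
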