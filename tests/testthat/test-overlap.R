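test_that("thresholding is strict and burden counts are additive", {
  ext <- threshold_extremes(c(2.61, 2.60, -3.0, -2.6, 0), 2.6)
  expect_equal(ext$pos, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(ext$neg, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(threshold_extremes(c(1, NaN)), "non-finite")

  z <- rbind(a = c(3.1, -2.7, 0.2), b = c(0, 0, 0))
  ext <- threshold_extremes(z)
  b <- deviation_burden(ext)
  expect_equal(b$n_pos, c(1, 0))
  expect_equal(b$n_neg, c(1, 0))
  expect_equal(b$n_total, c(2, 0))
  expect_equal(sum(b$n_total), sum(ext$pos) + sum(ext$neg))
})

test_that("overlap maps are exact group proportions", {
  ind <- matrix(c(1, 0, 1, 0,
                  1, 1, 0, 0,
                  0, 0, 0, 0,
                  1, 1, 1, 1,
                  0, 1, 0, 1,
                  1, 0, 0, 1,
                  0, 0, 1, 1), 7, 4, byrow = TRUE,
                dimnames = list(NULL, paste0("r", 1:4)))
  om <- overlap_map(ind == 1)
  # brute-force hand count
  expect_equal(as.vector(unclass(om)), c(4, 3, 3, 4) / 7)
  expect_true(all(abs(unclass(om) * attr(om, "n_group") -
                        round(unclass(om) * attr(om, "n_group"))) < 1e-12))
  expect_error(overlap_map(ind, integer(0)), "empty")

  o2 <- overlap_map(ind == 1, 1:2)
  d <- delta_overlap(o2, om)
  expect_equal(d, -delta_overlap(om, o2))
  expect_true(all(d >= -1 & d <= 1))
})

test_that("burden comparison matches exhaustive enumeration on a 2v2 toy", {
  # cases {1,1}, controls {0,0}: of the 6 equally likely label splits only
  # the observed one attains the maximal difference -> one-sided p = 1/6
  res <- compare_burden(c(1, 1), c(0, 0), n_perm = 12000, seed = 3)
  expect_equal(res$p, 1 / 6, tolerance = 0.02)
  # identical groups: p near 1
  res2 <- compare_burden(c(2, 2, 2), c(2, 2, 2), n_perm = 500, seed = 1)
  expect_gte(res2$p, 0.5)
  # complete separation: p at the estimator floor
  res3 <- compare_burden(11:20, 1:10, n_perm = 2000, seed = 1)
  expect_equal(res3$p, 1 / 2001)
})

test_that("threshold-weighted overlap: ramp weights and normalisation", {
  # ramp value at the midpoint of the log-range endpoints
  z_min <- 1.64; z_max <- 3.10
  w_mid <- 2 * ((z_min + z_max) / 2 - z_min) / (z_max - z_min)
  expect_equal(w_mid, 1.0)

  z <- matrix(c(10, 10, 0, 0), 2, 2,
              dimnames = list(NULL, c("all", "none")))
  tw <- threshold_weighted_overlap(z, sign = "positive")
  expect_equal(unname(tw["all"]), 1)
  expect_equal(unname(tw["none"]), 0)

  # monotone: raising any |z| never decreases the map
  set.seed(4)
  z1 <- matrix(rnorm(60, sd = 2), 10, 6)
  z2 <- z1 + runif(60)          # larger everywhere (positive sign)
  t1 <- threshold_weighted_overlap(z1, sign = "positive")
  t2 <- threshold_weighted_overlap(z2, sign = "positive")
  expect_true(all(t2 >= t1 - 1e-12))
  expect_error(threshold_weighted_overlap(z1, z_min = 2, z_max = 1),
               "z_max")
  expect_error(threshold_weighted_overlap(z1, n_thr = 1), "n_thr")

  # per-subject scores reproduce the direct threshold-loop computation
  th <- exp(seq(log(1.64), log(3.10), length.out = 100))
  w <- 2 * (th - 1.64) / (3.10 - 1.64)
  direct <- 0
  for (k in seq_along(th)) direct <- direct + w[k] * colMeans(z1 > th[k])
  direct <- direct / sum(w)
  s <- threshold_weighted_scores(z1, sign = "positive")
  expect_equal(colMeans(s), direct, tolerance = 1e-12)
})
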