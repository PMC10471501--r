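test_that("parcel binarization uses a strict fraction rule", {
  lookup <- rep(c(1, 2), each = 4)
  sig <- c(TRUE, TRUE, TRUE, FALSE,  FALSE, FALSE, FALSE, FALSE)
  expect_equal(unname(parcellate_binary(sig, lookup, 0.5)), c(TRUE, FALSE))
  expect_equal(unname(parcellate_binary(sig, lookup, 0.75)),
               c(FALSE, FALSE))   # 0.75 is not > 0.75
  expect_equal(unname(parcellate_binary(rep(FALSE, 8), lookup, 0.5)),
               c(FALSE, FALSE))
})

test_that("union maps are ORs of cached circuits", {
  circ <- matrix(FALSE, 3, 6, dimnames = list(c("1", "2", "3"),
                                              as.character(1:6)))
  circ[1, c(1, 2)] <- TRUE
  circ[2, c(3, 4, 5)] <- TRUE
  circ[3, c(1, 6)] <- TRUE
  class(circ) <- "circuit_cache"

  expect_equal(sum(union_map(integer(0), circ)), 0)
  expect_equal(union_map(1, circ), circ[1, ] > 0)
  # disjoint circuits of sizes 2 and 3: union has 5 ones
  expect_equal(sum(union_map(c(1, 2), circ)), 5)
  expect_error(union_map(5, circ), "region 5")

  # union monotonicity: adding a seed never turns a region off
  u12 <- union_map(c(1, 2), circ)
  u123 <- union_map(c(1, 2, 3), circ)
  expect_true(all(u123 >= u12))

  ind <- rbind(a = c(TRUE, TRUE, rep(FALSE, 4)),
               b = rep(FALSE, 6))
  colnames(ind) <- as.character(1:6)
  expect_error(union_maps(ind, circ), "cached circuit")
})

test_that("circuit cache is deterministic and circuits contain their seed", {
  sch <- tiny_scheme()
  atl <- tiny_atlas()
  c1 <- build_circuits(atl, sch, seed_regions = c(3, 9, 20),
                       n_perm = 120, seed = 5)
  c2 <- build_circuits(atl, sch, seed_regions = c(3, 9, 20),
                       n_perm = 120, seed = 5)
  expect_identical(c1, c2)
  # self-correlation: every circuit contains its own seed region
  expect_true(all(diag(unclass(c1[, as.character(c(3, 9, 20))]) * 1) == 1))
  # hub coupling: hub 3's circuit contains hub 9 and vice versa
  expect_true(c1["3", "9"])
  expect_true(c1["9", "3"])
})

test_that("circuit overlap dominates regional overlap when seeds self-couple", {
  # when every seed circuit contains its own seed, the union map covers
  # the extreme-indicator map, so circuit overlap >= regional overlap
  circ <- fixture("tiny_circuits",
                  build_circuits(tiny_atlas(), tiny_scheme(),
                                 n_perm = 120, seed = 6))
  if (all(diag(unclass(circ)) )) {
    fx <- tiny_fit()
    dev <- deviations(fx$fit, fx$cohort)
    U <- union_maps(dev$neg, circ)
    expect_true(all(U >= dev$neg))
    grp <- startsWith(dev$subjects$group, "case")
    expect_true(all(unclass(circuit_overlap(U, grp)) >=
                      unclass(overlap_map(dev$neg, grp)) - 1e-12))
  } else skip("cache without full self-coupling on this fixture")
})
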