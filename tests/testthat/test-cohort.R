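test_that("cohort generation: counts, positivity, determinism, limits", {
  sch <- tiny_scheme()
  spec <- data.frame(site = paste0("s", 1:4), n_hc = 60, n_case = 20)
  coh <- make_cohort(sch, spec, seed = 1)
  expect_equal(sum(coh$subjects$group == "HC"), 240)
  expect_equal(sum(startsWith(coh$subjects$group, "case")), 80)
  expect_true(all(coh$phenotype > 0))
  expect_identical(coh, make_cohort(sch, spec, seed = 1))

  # degenerate limit: all effects zero, noise -> 0 gives a constant
  # phenotype per region
  cd <- make_cohort(sch, spec, effects = list(
    age_slope = 0, sex_offset = 0, baseline_sd = 0.3,
    site_offsets = setNames(rep(0, 4), paste0("s", 1:4)),
    site_noise_scales = setNames(rep(1e-12, 4), paste0("s", 1:4))),
    seed = 1)
  expect_lt(max(apply(cd$phenotype, 2, sd) / colMeans(cd$phenotype)), 1e-9)

  expect_error(make_cohort(sch, spec, effects = list(
    site_noise_scales = setNames(c(-1, 1, 1, 1), paste0("s", 1:4)))),
    "positive")
  expect_warning(make_cohort(sch, data.frame(site = "solo", n_hc = 30),
                             seed = 1), "single site")
})

test_that("train/test split follows the site and cell exclusion rules", {
  sch <- tiny_scheme()
  # sites: 29 HC (all -> train), 40 HC (4 -> test), cell of 9 HCs dropped,
  # case-site dropped when cases fall under 10
  spec <- data.frame(site = c("big", "small"), n_hc = c(40, 29),
                     n_case = c(12, 0))
  coh <- make_cohort(sch, spec, seed = 3)
  sp <- split_train_test(coh, seed = 4)
  tab <- table(sp$subjects$site, sp$subjects$group)
  expect_equal(unname(tab["small", "HC_test"]), 0)       # < 30 HCs
  expect_equal(unname(tab["big", "HC_test"]), 4)         # 10% of 40
  expect_equal(unname(tab["big", "HC_train"]), 36)

  # a (site, sex) cell with < 10 HCs is excluded from both splits
  coh2 <- make_cohort(sch, data.frame(site = c("x", "y"), n_hc = 40,
                                      n_case = 0), seed = 5)
  nine <- which(coh2$subjects$site == "x" &
                  coh2$subjects$sex == "M")[seq_len(9)]
  keep <- sort(c(nine, which(!(coh2$subjects$site == "x" &
                                 coh2$subjects$sex == "M"))))
  coh2$subjects <- coh2$subjects[keep, ]
  coh2$phenotype <- coh2$phenotype[keep, ]
  sp2 <- split_train_test(coh2, seed = 6)
  expect_equal(sum(sp2$subjects$site == "x" & sp2$subjects$sex == "M"), 0)
})

test_that("deviation injection respects scenario contracts", {
  sch <- tiny_scheme()
  coh <- tiny_cohort()
  atl <- tiny_atlas()
  fc <- fixture("tiny_fc", region_coupling(atl, sch))

  expect_identical(
    inject_case_deviations(coh, sch, fc, deviation_scenario("null")), coh)

  sc <- deviation_scenario("region_focal", focal_set = 7,
                           effect_size = 4, seed = 2)
  ci <- inject_case_deviations(coh, sch, fc, sc)
  hc_rows <- coh$subjects$group == "HC"
  expect_identical(ci$phenotype[hc_rows, ], coh$phenotype[hc_rows, ])
  inj <- attr(ci, "injected")
  expect_true(all(unlist(inj) == 7))

  expect_error(deviation_scenario("circuit_convergent"), "hub_set")
  expect_error(deviation_scenario("burden_only", hub_set = 1), "hub_set")
  expect_error(deviation_scenario("region_focal"), "focal_set")
  expect_error(deviation_scenario("banana"), "arg")
})

test_that("region_focal deviations are detected at the focal region", {
  sch <- tiny_scheme()
  coh <- tiny_cohort()
  sc <- deviation_scenario("region_focal", focal_set = 7,
                           burden = list(p0 = 0, lambda = 50),
                           effect_size = 4, seed = 2)
  ci <- inject_case_deviations(coh, sch, NULL, sc)
  sp <- split_train_test(ci, seed = 3)
  fit <- normative(sp)
  dev <- deviations(fit, sp)
  cases <- startsWith(dev$subjects$group, "case")
  ov <- overlap_map(dev$neg, cases)
  expect_gte(ov[["7"]], 0.9)  # z ~ -4 nearly always beats the -2.6 cut
  expect_lt(max(ov[names(ov) != "7"]), 0.3)
})
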