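#' Generate a synthetic multi-site phenotype cohort
#'
#' Simulates a grey-matter-volume-like regional phenotype for healthy
#' controls and (optionally) clinical cases across several scan sites. The
#' phenotype is generated on the log scale and exponentiated, so values are
#' strictly positive and the Box-Cox step of the normative model has a real
#' transformation to recover (the log, i.e. lambda near 0):
#' \deqn{y_{ij} = \exp(b_j + \beta_{age} age_i + \beta_{sex} 1[M]
#'   + u_{site(i)} + \epsilon_{ij}), \epsilon_{ij} \sim N(0, s_{site(i)}^2).}
#'
#' @param scheme a `"parcellation"`.
#' @param site_spec data frame with columns `site`, `n_hc`, `n_case`
#'   (cases per site; 0 for a control-only cohort).
#' @param age_range length-2 numeric, years; ages are uniform within it.
#' @param effects list with `age_slope` (log-units per year), `sex_offset`
#'   (log-units added for males), `site_offsets` and `site_noise_scales`
#'   (named per site; defaults drawn/set per site when `NULL`), and
#'   `baseline_sd` (between-region SD of the log-scale baseline).
#' @param dx diagnosis label used for case rows (`group = "case:<dx>"`).
#' @param seed RNG seed; the cohort is a pure function of its arguments.
#' @return An object of class `"cohort"`: list with `subjects` (data frame:
#'   `id`, `age`, `sex`, `site`, `group`) and `phenotype`
#'   (subjects x regions matrix, column names are region ids). The
#'   generating parameters are kept in `attr(, "truth")` for parameter
#'   recovery studies.
#' @export
make_cohort <- function(scheme, site_spec,
                        age_range = c(18, 64),
                        effects = list(),
                        dx = "case",
                        seed = 1L) {
  stopifnot(inherits(scheme, "parcellation"))
  site_spec <- as.data.frame(site_spec)
  if (!all(c("site", "n_hc") %in% names(site_spec)))
    stop_arg("`site_spec` needs columns site, n_hc (and optionally n_case)")
  if (is.null(site_spec$n_case)) site_spec$n_case <- 0L
  if (nrow(site_spec) < 2L)
    warning("single site: site random effects are unidentifiable")

  with_seed(seed, {
    nreg <- nrow(scheme$regions)
    sites <- as.character(site_spec$site)

    age_slope <- effects$age_slope %||% -0.004
    sex_offset <- effects$sex_offset %||% 0.05
    baseline_sd <- effects$baseline_sd %||% 0.3
    site_offsets <- effects$site_offsets %||%
      stats::setNames(stats::rnorm(length(sites), sd = 0.05), sites)
    site_noise <- effects$site_noise_scales %||%
      stats::setNames(seq(0.08, 0.14, length.out = length(sites)), sites)
    if (any(site_noise <= 0)) stop_arg("site noise scales must be positive")

    baseline <- stats::rnorm(nreg, mean = 0.5, sd = baseline_sd)

    n_tot <- sum(site_spec$n_hc) + sum(site_spec$n_case)
    site <- rep(sites, site_spec$n_hc + site_spec$n_case)
    group <- unlist(lapply(seq_along(sites), function(k)
      rep(c("HC", paste0("case:", dx)),
          c(site_spec$n_hc[k], site_spec$n_case[k]))))
    age <- stats::runif(n_tot, age_range[1], age_range[2])
    sex <- sample(c("M", "F"), n_tot, replace = TRUE)

    eta <- matrix(baseline, n_tot, nreg, byrow = TRUE) +
      age_slope * age + sex_offset * (sex == "M") +
      site_offsets[site]
    eps <- matrix(stats::rnorm(n_tot * nreg), n_tot, nreg) * site_noise[site]
    phen <- exp(eta + eps)
    colnames(phen) <- scheme$regions$region_id

    subjects <- data.frame(
      id = sprintf("sub-%04d", seq_len(n_tot)),
      age = age, sex = sex, site = site, group = group,
      stringsAsFactors = FALSE)
    rownames(phen) <- subjects$id

    out <- list(subjects = subjects, phenotype = phen)
    class(out) <- "cohort"
    noise_free <- exp(eta)
    dimnames(noise_free) <- dimnames(phen)
    attr(out, "truth") <- list(
      baseline = baseline, age_slope = age_slope, sex_offset = sex_offset,
      site_offsets = site_offsets, site_noise_scales = site_noise,
      noise_free = noise_free)
    out
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("Cohort: %d subjects x %d regions\n", nrow(x$phenotype),
              ncol(x$phenotype)))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  sites: ", paste(unique(x$subjects$site), collapse = ", "), "\n")
  invisible(x)
}

#' Describe a case-deviation scenario
#'
#' A scenario controls how extreme deviations are injected into case
#' subjects: `"null"` (no injection), `"burden_only"` (seed regions drawn
#' uniformly at random — cases differ from controls only in how many
#' deviations they carry), `"circuit_convergent"` (seeds drawn
#' preferentially among regions strongly coupled to a hub set, emulating
#' preferential circuit targeting) or `"region_focal"` (seeds restricted to
#' a small fixed region list). The number of seeds per case is drawn from a
#' zero-inflated Poisson with zero-mass `p0` and rate `lambda`
#' (mean burden `(1 - p0) * lambda`).
#'
#' @param kind one of `"null"`, `"burden_only"`, `"circuit_convergent"`,
#'   `"region_focal"`.
#' @param burden list(p0, lambda); default `p0 = 0.25`, `lambda = 8`
#'   (mean burden 6).
#' @param effect_size deviation depth in normative z units (>= 0).
#' @param hub_set region ids (required iff `kind = "circuit_convergent"`).
#' @param focal_set region ids (required iff `kind = "region_focal"`).
#' @param sign `"negative"` (phenotype below expectation) or `"positive"`.
#' @param seed RNG seed for the injection.
#' @export
deviation_scenario <- function(kind = c("null", "burden_only",
                                        "circuit_convergent", "region_focal"),
                               burden = list(p0 = 0.25, lambda = 8),
                               effect_size = 4,
                               hub_set = NULL, focal_set = NULL,
                               sign = c("negative", "positive"),
                               seed = 1L) {
  kind <- match.arg(kind)
  sign <- match.arg(sign)
  if (effect_size < 0) stop_arg("`effect_size` must be >= 0")
  if (kind == "circuit_convergent" && length(hub_set) == 0L)
    stop_arg("circuit_convergent requires a nonempty `hub_set`")
  if (kind != "circuit_convergent" && length(hub_set) > 0L)
    stop_arg("`hub_set` is only meaningful for circuit_convergent")
  if (kind == "region_focal" && length(focal_set) == 0L)
    stop_arg("region_focal requires a nonempty `focal_set`")
  structure(list(kind = kind, burden = burden, effect_size = effect_size,
                 hub_set = hub_set, focal_set = focal_set, sign = sign,
                 seed = seed),
            class = "deviation_scenario")
}

#' Inject case-specific extreme deviations into a cohort
#'
#' For each case subject, draws a number of seed regions from the
#' scenario's burden distribution, selects the regions according to the
#' scenario kind, and shifts the (log-scale) phenotype there by
#' `effect_size` times the subject's site noise scale, so the expected
#' normative z at seeded regions equals `-effect_size` (or `+effect_size`
#' for positive scenarios). Control rows are untouched; a `"null"` scenario
#' returns the cohort unchanged.
#'
#' @param cohort a `"cohort"` from [make_cohort()].
#' @param scheme the matching `"parcellation"`.
#' @param fc_reference symmetric regions x regions coupling matrix (e.g.
#'   from [region_coupling()]); used by `circuit_convergent` to rank
#'   regions by coupling to the hub set (eligible = above the 80th
#'   percentile).
#' @param scenario a [deviation_scenario()].
#' @return the modified cohort; injected seeds are recorded in
#'   `attr(, "injected")` (list per case id).
#' @export
inject_case_deviations <- function(cohort, scheme, fc_reference = NULL,
                                   scenario) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(scenario, "deviation_scenario"))
  if (scenario$kind == "null") return(cohort)

  truth <- attr(cohort, "truth")
  noise <- truth$site_noise_scales
  cases <- which(startsWith(cohort$subjects$group, "case"))
  rids <- as.integer(colnames(cohort$phenotype))

  eligible <- switch(scenario$kind,
    burden_only = rids,
    region_focal = {
      if (!all(scenario$focal_set %in% rids))
        stop_arg("focal_set contains unknown region ids")
      scenario$focal_set
    },
    circuit_convergent = {
      if (is.null(fc_reference))
        stop_arg("circuit_convergent requires `fc_reference`")
      if (max(abs(fc_reference - t(fc_reference))) > 1e-8)
        stop_arg("`fc_reference` must be symmetric")
      hubs <- match(scenario$hub_set, rids)
      if (anyNA(hubs)) stop_arg("hub_set contains unknown region ids")
      score <- apply(fc_reference[, hubs, drop = FALSE], 1, max)
      score[hubs] <- Inf   # hubs themselves are always eligible
      rids[score > stats::quantile(score[is.finite(score)], 0.8)]
    })

  shift <- scenario$effect_size * ifelse(scenario$sign == "negative", -1, 1)

  with_seed(scenario$seed, {
    injected <- list()
    for (i in cases) {
      k <- if (stats::runif(1) < scenario$burden$p0) 0L else
        stats::rpois(1, scenario$burden$lambda)
      k <- min(k, length(eligible))
      if (k == 0L) next
      seeds <- eligible[sample.int(length(eligible), k)]
      cols <- match(seeds, rids)
      s <- noise[cohort$subjects$site[i]]
      cohort$phenotype[i, cols] <-
        cohort$phenotype[i, cols] * exp(shift * s)
      injected[[cohort$subjects$id[i]]] <- seeds
    }
    attr(cohort, "injected") <- injected
    cohort
  })
}

#' Split a cohort into normative training and test sets
#'
#' Applies the multi-site stratification rules: (site, sex) cells with
#' fewer than `min_batch` healthy controls are dropped entirely (their case
#' rows as well); a site whose cases fall below `min_batch` after cell
#' exclusion is dropped wholesale (only applied to sites that contribute
#' cases); sites with at least `site_min_for_split` controls contribute a
#' random `1 - train_frac` share of them to the held-out test set, smaller
#' sites contribute all controls to training. Cases always go to the test
#' side.
#'
#' @param cohort a `"cohort"`.
#' @param train_frac fraction of controls (per eligible site) used for
#'   training; default 0.9.
#' @param site_min_for_split minimum controls at a site for it to
#'   contribute to the test set; default 30.
#' @param min_batch minimum controls per (site, sex) cell; default 10.
#' @param seed RNG seed for the per-site sampling.
#' @return the cohort with `subjects$group` relabelled to `"HC_train"` /
#'   `"HC_test"` (cases keep their labels) and excluded rows removed.
#' @export
split_train_test <- function(cohort, train_frac = 0.9,
                             site_min_for_split = 30, min_batch = 10,
                             seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$subjects
  is_hc <- s$group %in% c("HC", "HC_train", "HC_test")
  is_case <- startsWith(s$group, "case")

  keep <- rep(TRUE, nrow(s))
  # drop (site, sex) cells with < min_batch HCs
  cell <- interaction(s$site, s$sex, drop = TRUE)
  for (cl in levels(cell)) {
    in_cell <- cell == cl
    if (sum(in_cell & is_hc) < min_batch) keep[in_cell] <- FALSE
  }
  # a case-contributing site left with < min_batch cases is dropped
  for (st in unique(s$site)) {
    in_site <- s$site == st
    if (any(in_site & is_case) &&
        sum(in_site & is_case & keep) < min_batch)
      keep[in_site] <- FALSE
  }
  if (!any(keep & is_hc)) stop_arg("no site survives the exclusion rules")

  group <- s$group
  with_seed(seed, {
    for (st in unique(s$site)) {
      hc_idx <- which(keep & is_hc & s$site == st)
      if (length(hc_idx) == 0L) next
      if (length(hc_idx) >= site_min_for_split) {
        n_test <- floor(length(hc_idx) * (1 - train_frac) + 1e-9)
        test_idx <- if (n_test > 0) sample(hc_idx, n_test) else integer(0)
        group[hc_idx] <- "HC_train"
        group[test_idx] <- "HC_test"
      } else {
        group[hc_idx] <- "HC_train"
      }
    }
    cohort$subjects$group <- group
    cohort$subjects <- cohort$subjects[keep, , drop = FALSE]
    cohort$phenotype <- cohort$phenotype[keep, , drop = FALSE]
    cohort
  })
}
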