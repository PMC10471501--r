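# Tabular I/O for the typed objects and the end-to-end pipeline.

#' Read and write the pipeline's typed objects
#'
#' Plain-text round-trip formats: a parcellation is a TSV of regions plus
#' a JSON sidecar with the grayordinate table; a cohort is a covariate
#' TSV plus a phenotype TSV; an FC atlas is one matrix TSV per subject
#' plus an edge-list TSV. Invariants are checked on load with
#' descriptive errors (missing columns, duplicate region ids,
#' non-positive phenotypes, regions absent from the scheme).
#'
#' @param scheme,cohort,atlas objects to write.
#' @param path directory (created if needed) holding the files.
#' @return readers return the typed object; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_parcellation <- function(scheme, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(scheme$regions, file.path(path, "regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(scheme$gray, file.path(path, "grayordinates.json"),
                       digits = NA)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_parcellation <- function(path) {
  f <- file.path(path, "regions.tsv")
  regions <- utils::read.table(f, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  need <- c("region_id", "hemisphere", "compartment", "x", "y", "z",
            "network10", "network20")
  miss <- setdiff(need, names(regions))
  if (length(miss) > 0L)
    stop_arg(sprintf("%s: missing column(s) %s", f,
                     paste(miss, collapse = ", ")))
  if (anyDuplicated(regions$region_id))
    stop_arg(sprintf("%s: duplicate region_id", f))
  gray <- as.data.frame(jsonlite::read_json(
    file.path(path, "grayordinates.json"), simplifyVector = TRUE))
  out <- list(regions = regions, gray = gray)
  class(out) <- "parcellation"
  validate_parcellation(out)
  out
}

#' @rdname pipeline_io
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$subjects, file.path(path, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  phen <- data.frame(id = rownames(cohort$phenotype),
                     cohort$phenotype, check.names = FALSE)
  utils::write.table(phen, file.path(path, "phenotype.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param scheme_check optional `"parcellation"`; when given, the cohort's
#'   region columns are checked against it.
#' @export
read_cohort <- function(path, scheme_check = NULL) {
  subjects <- utils::read.table(file.path(path, "subjects.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "site", "group")
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0L)
    stop_arg(sprintf("subjects.tsv: missing column(s) %s",
                     paste(miss, collapse = ", ")))
  if (anyNA(subjects[need]))
    stop_arg("subjects.tsv: missing covariate values")
  phen <- utils::read.table(file.path(path, "phenotype.tsv"),
                            header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  m <- as.matrix(phen[, -1, drop = FALSE])
  rownames(m) <- phen$id
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_arg(sprintf("phenotype.tsv: non-positive value at row %s, region %s",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  if (!is.null(scheme_check)) {
    unknown <- setdiff(colnames(m),
                       as.character(scheme_check$regions$region_id))
    if (length(unknown) > 0L)
      stop_arg(sprintf("phenotype region %s absent from the parcellation",
                       unknown[1]))
  }
  out <- list(subjects = subjects, phenotype = m[subjects$id, , drop = FALSE])
  class(out) <- "cohort"
  out
}

#' @rdname pipeline_io
#' @export
write_fc_atlas <- function(atlas, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(atlas$timeseries))
    utils::write.table(atlas$timeseries[[s]],
                       file.path(path, sprintf("timeseries_%03d.tsv", s)),
                       sep = "\t", row.names = TRUE, col.names = FALSE,
                       quote = FALSE)
  utils::write.table(atlas$adjacency, file.path(path, "adjacency.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(gray_id = names(atlas$lookup), region_id = atlas$lookup,
               compartment = atlas$compartment),
    file.path(path, "lookup.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_fc_atlas <- function(path) {
  files <- sort(list.files(path, "^timeseries_", full.names = TRUE))
  if (length(files) == 0L) stop_arg("no timeseries files found")
  ts <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = "\t", row.names = 1))
    colnames(m) <- NULL
    m
  })
  adjacency <- as.matrix(utils::read.table(
    file.path(path, "adjacency.tsv"), header = TRUE, sep = "\t"))
  lk <- utils::read.table(file.path(path, "lookup.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  out <- list(timeseries = ts, adjacency = adjacency,
              lookup = stats::setNames(lk$region_id, lk$gray_id),
              compartment = lk$compartment)
  class(out) <- "fc_atlas"
  out
}

#' Configuration for the end-to-end pipeline
#'
#' Bundles the analysis parameters with their conventional defaults: the
#' extreme-deviation threshold `z_thr = 2.6`, the threshold-weighted
#' range 1.64-3.10 over 100 log-spaced steps, the parcel inclusion
#' fraction 0.5, the per-compartment FWE level 0.025 (= 0.05/2), the
#' permutation counts, the BH level 0.05, and one explicit seed per
#' stochastic stage.
#'
#' @param z_thr extreme-deviation threshold (> 0).
#' @param z_min,z_max,n_thr threshold-weighted mapping parameters.
#' @param parcel_frac parcel inclusion fraction (alternative 0.75).
#' @param network_level 10 or 20.
#' @param alpha_fwe per-compartment FWE level.
#' @param n_perm_group,n_perm_spatial,n_perm_tfce permutation counts.
#' @param q_fdr BH level.
#' @param min_batch minimum controls per (site, sex) batch.
#' @param seeds named list of per-stage seeds (`fit`, `circuit`,
#'   `group`, `spatial`).
#' @export
run_config <- function(z_thr = 2.6, z_min = 1.64, z_max = 3.10,
                       n_thr = 100, parcel_frac = 0.5, network_level = 10,
                       alpha_fwe = 0.025, n_perm_group = 10000,
                       n_perm_spatial = 10000, n_perm_tfce = 500,
                       q_fdr = 0.05, min_batch = 10,
                       seeds = list(fit = 1L, circuit = 2L, group = 3L,
                                    spatial = 4L)) {
  if (z_thr <= 0 || z_min <= 0 || z_max <= z_min || alpha_fwe <= 0 ||
      q_fdr <= 0 || parcel_frac < 0)
    stop_arg("invalid configuration: thresholds must be positive and ordered")
  stopifnot(all(c("fit", "circuit", "group", "spatial") %in% names(seeds)))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full multiscale heterogeneity analysis
#'
#' Orchestrates: train/test handling, normative fit, deviation maps,
#' per-sign regional overlap and group/spatial tests, circuit mapping
#' and circuit-level tests, network-level tests, the cross-scale
#' contrast, and a burden comparison, writing every result table as TSV
#' under `out_dir` together with a JSON manifest (configuration and
#' seeds) from which each number can be reproduced.
#'
#' @param cohort a split `"cohort"` (see [split_train_test()]) containing
#'   `HC_train`, `HC_test` and case rows.
#' @param scheme the `"parcellation"`.
#' @param atlas the `"fc_atlas"`.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param signs which deviation signs to analyse.
#' @return (invisibly) a list with the fitted model, deviation maps,
#'   circuit cache and all test tables.
#' @export
run_pipeline <- function(cohort, scheme, atlas, config = run_config(),
                         out_dir, signs = c("negative", "positive")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_arg(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e))))
  }

  fit <- stage("fit", normative(cohort, min_batch = config$min_batch))
  dev <- stage("deviate", deviations(fit, cohort, z_thr = config$z_thr))
  grp <- dev$subjects$group
  case <- which(startsWith(grp, "case"))
  ctrl <- which(grp == "HC_test")
  if (length(case) == 0L || length(ctrl) == 0L)
    stop_arg("pipeline needs both case and HC_test subjects")

  circuits <- stage("circuit", build_circuits(
    atlas, scheme, n_perm = config$n_perm_tfce, alpha = config$alpha_fwe,
    frac = config$parcel_frac, seed = config$seeds$circuit))
  netmap <- assign_networks(scheme, config$network_level)
  ens <- make_spin_ensemble(scheme, config$n_perm_spatial,
                            seed = config$seeds$spatial)

  results <- list(fit = fit, deviations = dev, circuits = circuits)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)

  burden <- deviation_burden(dev)
  burden$group <- grp
  tsv(burden, "burden.tsv")
  results$burden_test <- compare_burden(
    burden$n_total[case], burden$n_total[ctrl],
    n_perm = config$n_perm_group, seed = config$seeds$group)

  for (sg in signs) {
    E <- if (sg == "negative") dev$neg else dev$pos
    U <- union_maps(E, circuits)
    nd <- network_deviance(E, netmap)

    o_case <- overlap_map(E, case); o_ctrl <- overlap_map(E, ctrl)
    tsv(data.frame(region_id = names(o_case), overlap_case = unclass(o_case),
                   overlap_hc = unclass(o_ctrl),
                   delta = delta_overlap(o_case, o_ctrl)),
        sprintf("regional_overlap_%s.tsv", sg))

    reg_g <- stage("regional", group_permutation_test(
      E[case, , drop = FALSE], E[ctrl, , drop = FALSE],
      n_perm = config$n_perm_group, seed = config$seeds$group,
      q_fdr = config$q_fdr))
    reg_s <- stage("regional", spatial_null_test(
      dev, case, ctrl, scheme, downstream = "regional", sign = sg,
      n_perm = config$n_perm_spatial, seed = config$seeds$spatial,
      ensemble = ens, q_fdr = config$q_fdr))

    cir_g <- stage("circuit", group_permutation_test(
      U[case, , drop = FALSE], U[ctrl, , drop = FALSE],
      n_perm = config$n_perm_group, seed = config$seeds$group,
      q_fdr = config$q_fdr))
    cir_s <- stage("circuit", spatial_null_test(
      dev, case, ctrl, scheme, downstream = "circuit", sign = sg,
      circuits = circuits, n_perm = config$n_perm_spatial,
      seed = config$seeds$spatial, ensemble = ens, q_fdr = config$q_fdr))

    net_g <- stage("network", group_permutation_test(
      nd[case, , drop = FALSE], nd[ctrl, , drop = FALSE],
      n_perm = config$n_perm_group, seed = config$seeds$group,
      q_fdr = config$q_fdr))
    net_s <- stage("network", spatial_null_test(
      dev, case, ctrl, scheme, downstream = "network", sign = sg,
      netmap = netmap, n_perm = config$n_perm_spatial,
      seed = config$seeds$spatial, ensemble = ens, q_fdr = config$q_fdr))

    contrast <- stage("contrast", crossscale_contrast(
      U, E, case, ctrl, n_perm = config$n_perm_group,
      seed = config$seeds$group, q_fdr = config$q_fdr))

    for (nm in c("reg_g", "reg_s", "cir_g", "cir_s", "net_g", "net_s",
                 "contrast")) {
      tt <- get(nm)$table
      tt$null_model <- get(nm)$null_model
      tt$sign <- sg
      tsv(tt, sprintf("%s_%s.tsv", sub("_g$", "_group",
                                       sub("_s$", "_spatial", nm)), sg))
      results[[paste0(nm, "_", sg)]] <- get(nm)
    }
  }

  manifest <- config
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  manifest$n_case <- length(case)
  manifest$n_hc_test <- length(ctrl)
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
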