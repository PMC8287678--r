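#' Pipeline configuration
#'
#' Central configuration with the analysis defaults: 5-mm geodesic apex
#' patch, 98th-percentile high-WSS region, area-weighted region averages,
#' 20%-of-maximum envelope threshold with 5-column median smoothing.
#' Round-trips through YAML unchanged.
#'
#' @param patch_radius mm.
#' @param patch_metric `"geodesic"` or `"euclidean"`.
#' @param percentile high-WSS percentile.
#' @param area_weighted logical.
#' @param envelope_threshold digitizer intensity threshold (fraction).
#' @param envelope_smooth digitizer median window (columns).
#' @param seed integer seed for generators.
#' @param cohort optional list of [cohort_params()] arguments.
#' @export
pipeline_config <- function(patch_radius = 5, patch_metric = "geodesic",
                            percentile = 98, area_weighted = TRUE,
                            envelope_threshold = 0.2, envelope_smooth = 5,
                            seed = 1L, cohort = list()) {
  stopifnot(patch_radius >= 0, percentile >= 0, percentile <= 100,
            envelope_threshold > 0, envelope_threshold < 1)
  structure(list(patch_radius = patch_radius, patch_metric = patch_metric,
                 percentile = percentile, area_weighted = area_weighted,
                 envelope_threshold = envelope_threshold,
                 envelope_smooth = envelope_smooth,
                 seed = as.integer(seed), cohort = cohort),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @param config a [pipeline_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the per-subject wall-metric stage
#'
#' Loads (or takes) a mesh and a time-resolved wall-shear field — or a
#' zonal preset name to generate one — and produces one cohort-table row
#' of region metrics, optionally writing an annotated VTK surface with
#' the named point-data arrays TAWSS, OSI, WSSG_P, WSSG_Q, WSSG_MAG,
#' WSSG_SIGN.
#'
#' @param mesh a [surface_mesh()] or mesh file path.
#' @param field a [wall_field()] or a zonal preset name
#'   (`"case_like"` / `"control_like"`).
#' @param config a [pipeline_config()].
#' @param subject_id row identifier.
#' @param group `"case"` or `"control"`.
#' @param vtk_out optional path for the annotated VTK surface.
#' @return one-row `data.frame` in the cohort-table schema (dirWSSG
#'   encoded 1 = positive, 0 = negative); the `region_metrics` object is
#'   attached as attribute `"metrics"`.
#' @export
run_subject <- function(mesh, field, config = pipeline_config(),
                        subject_id = "subject", group = "case",
                        vtk_out = NULL) {
  if (is.character(mesh)) mesh <- read_surface_mesh(mesh)
  if (!inherits(mesh, "surface_mesh")) stop("geometry stage: invalid mesh")
  if (is.null(mesh$apex_vertex)) stop("geometry stage: mesh has no apex vertex")
  if (is.character(field))
    field <- make_zonal_wss_field(mesh, zonal_preset(field),
                                  seed = config$seed)
  if (!inherits(field, "wall_field")) stop("wall_metrics stage: invalid field")
  rm <- subject_metrics(field, radius = config$patch_radius,
                        percentile = config$percentile,
                        metric = config$patch_metric,
                        area_weighted = config$area_weighted)
  f <- attr(rm, "fields")
  if (!is.null(vtk_out)) {
    pd <- list(TAWSS = f$tawss, OSI = ifelse(is.finite(f$osi), f$osi, -1),
               WSSG_P = ifelse(is.finite(f$wssg$d_tau_dp), f$wssg$d_tau_dp, 0),
               WSSG_Q = ifelse(is.finite(f$wssg$d_tau_dq), f$wssg$d_tau_dq, 0),
               WSSG_MAG = ifelse(is.finite(f$wssg$magnitude),
                                 f$wssg$magnitude, 0),
               WSSG_SIGN = ifelse(f$wssg$defined, f$wssg$sign, 0))
    write_surface_mesh(mesh, vtk_out, "vtk", point_data = pd)
  }
  row <- data.frame(subject_id = subject_id, group = group,
                    WSS = rm$wss, WSSG = rm$wssg_signed,
                    absWSSG = rm$abs_wssg, OSI = rm$osi,
                    dirWSSG = as.integer(rm$dir_wssg == "positive"),
                    stringsAsFactors = FALSE)
  attr(row, "metrics") <- rm
  row
}

#' Read / write a cohort CSV
#'
#' @param path CSV file in the cohort-table schema.
#' @return a validated `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param table a `cohort_table`.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Run the cohort-level statistical stage
#'
#' Takes a cohort table (or CSV path, or `NULL` to generate one from the
#' configured cohort parameters) and writes the full report: group
#' comparison, contingency, regression and ROC tables as CSV, a JSON
#' summary, and a machine-readable provenance record (configuration,
#' seed, package version).
#'
#' @param table `cohort_table`, CSV path, or `NULL` to generate.
#' @param out_dir report directory (created if missing).
#' @param config a [pipeline_config()].
#' @return the [casecontrol_analysis()] object, invisibly.
#' @export
run_study <- function(table = NULL, out_dir, config = pipeline_config()) {
  if (is.null(table)) {
    cp <- do.call(cohort_params, c(config$cohort, list(seed = config$seed)))
    table <- make_cohort(cp)
  } else if (is.character(table)) {
    table <- read_cohort_csv(table)
  } else {
    table <- cohort_table(as.data.frame(table))
  }
  cc <- casecontrol_analysis(table)
  s <- summary(cc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(s$comparison, file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(as.table(s$contingency)),
                   file.path(out_dir, "contingency.csv"), row.names = FALSE)
  utils::write.csv(s$regression, file.path(out_dir, "regression.csv"),
                   row.names = FALSE)
  roc_pts <- data.frame(threshold = cc$roc_wssg$thresholds,
                        sensitivity = cc$roc_wssg$sensitivities,
                        specificity = cc$roc_wssg$specificities)
  utils::write.csv(roc_pts, file.path(out_dir, "roc_wssg.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fisher_p = s$fisher_p,
         odds_ratio = s$odds_ratio[c("or", "ci_low", "ci_high")],
         selected = as.list(s$selected),
         auc_wssg = s$auc_wssg, auc_score = s$auc_score,
         cutoff_wssg = cc$roc_wssg$cutoff,
         cutoff_sensitivity = cc$roc_wssg$cutoff_sensitivity,
         cutoff_specificity = cc$roc_wssg$cutoff_specificity),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "wallshear",
         version = as.character(utils::packageVersion("wallshear")),
         r_version = as.character(getRversion()),
         seed = config$seed, config = unclass(config),
         n_case = sum(table$group == "case"),
         n_control = sum(table$group == "control")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(cc)
}
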