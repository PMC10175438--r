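#' Pipeline configuration
#'
#' Collects every tunable of the measurement pipeline with its default:
#' bone threshold 226 HU, 26-connectivity, minimum fragment size 50 voxels,
#' smoothing factor 0.4 (10 iterations), articular heuristic (45 degrees,
#' top 15% band), fracture-line proximity 7.5 mm, prognostic boundaries
#' 150/550/1000 mm^2 and critical cut-off 550 mm^2. The configuration is
#' echoed (with a digest) into every report for provenance.
#'
#' @param threshold bone threshold, HU.
#' @param connectivity 6, 18 or 26.
#' @param min_voxels minimum fragment size, voxels.
#' @param smoothing,smoothing_iterations mesh smoothing factor and passes.
#' @param max_angle,band_frac articular heuristic parameters.
#' @param d_max,facing_tol,w_min fracture-line trim parameters.
#' @param boundaries prognostic group boundaries, mm^2.
#' @param cutoff high-risk cut-off, mm^2.
#' @param ties Cox tie handling.
#' @param seed RNG seed echoed into reports.
#' @return A list of class `run_config`.
#' @export
run_config <- function(threshold = 226, connectivity = 26, min_voxels = 50,
                       smoothing = 0.4, smoothing_iterations = 10,
                       max_angle = 45, band_frac = 0.15, d_max = 7.5,
                       facing_tol = 0.02, w_min = 1,
                       boundaries = c(150, 550, 1000), cutoff = 550,
                       ties = "breslow", seed = 1) {
  structure(list(threshold = threshold, connectivity = connectivity,
                 min_voxels = min_voxels, smoothing = smoothing,
                 smoothing_iterations = smoothing_iterations,
                 max_angle = max_angle, band_frac = band_frac, d_max = d_max,
                 facing_tol = facing_tol, w_min = w_min,
                 boundaries = boundaries, cutoff = cutoff, ties = ties,
                 seed = seed),
            class = "run_config")
}

#' Run the full gap-area pipeline
#'
#' End-to-end: segmentation (threshold + connected components), fragment
#' meshing, gap-area measurement, prognostic classification and high-risk
#' flag. Input may be a `ct_volume`, a NIfTI path, or a `phantom` (whose
#' exact articular annotations are then used unless others are supplied).
#'
#' @param input a `ct_volume`, NIfTI path, or `phantom`.
#' @param config a [run_config()].
#' @param annotations optional articular annotations (list of per-vertex
#'   logical vectors, or an annotation data frame).
#' @param out optional path for a JSON report.
#' @return A list of class `gap_report`: configuration echo and digest,
#'   per-stage log, fragment counts, total and per-loop gap area,
#'   prognostic group and high-risk flag.
#' @export
run_pipeline <- function(input, config = run_config(), annotations = NULL,
                         out = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name, t_start) {
    stages[[length(stages) + 1L]] <<-
      list(stage = name,
           seconds = round(proc.time()[["elapsed"]] - t_start, 3))
  }

  run_stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    tick(name, ts)
    res
  }

  if (is.character(input)) input <- run_stage("read", read_volume(input))

  if (inherits(input, "phantom")) {
    meshes <- input$meshes
    if (is.null(annotations)) annotations <- input$annotations
    labels <- input$labels
  } else {
    stopifnot(inherits(input, "ct_volume"))
    mask <- run_stage("segment", segment_bone(input, config$threshold))
    labels <- run_stage("label",
                        label_fragments(mask,
                                        connectivity = config$connectivity,
                                        min_voxels = config$min_voxels))
    if (labels$n_fragments == 0) stop("stage 'label' failed: no fragments")
    meshes <- run_stage("mesh", lapply(seq_len(labels$n_fragments),
      function(i) extract_mesh(labels, i, smoothing = config$smoothing,
                               iterations = config$smoothing_iterations)))
  }
  if (is.data.frame(annotations))
    annotations <- .annotation_list(annotations, meshes)

  params <- gap_params(d_max = config$d_max, facing_tol = config$facing_tol,
                       w_min = config$w_min, max_angle = config$max_angle,
                       band_frac = config$band_frac)
  res <- run_stage("measure",
                   measure_gap_area(meshes, annotations = annotations,
                                    params = params))
  grp <- as.character(classify_prognosis(res$total_area, config$boundaries))
  risk <- high_risk_flag(res$total_area, config$cutoff)

  report <- structure(list(
    config = unclass(config),
    config_hash = .fnv1a(unclass(config)),
    n_fragments = length(meshes),
    fragment_voxels = if (!is.null(labels))
      as.integer(tabulate(labels$labels[labels$labels > 0],
                          nbins = labels$n_fragments)) else NULL,
    n_fracture_lines = res$n_fracture_lines,
    n_loops = length(res$loop_areas),
    loop_areas_mm2 = round(res$loop_areas, 6),
    total_gap_area_mm2 = round(res$total_area, 6),
    prognosis = grp,
    high_risk = risk,
    stages = stages,
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3)),
    class = "gap_report")

  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    payload <- unclass(report)
    payload$stages <- NULL # wall times vary between runs
    payload$total_seconds <- NULL
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

#' @exportS3Method base::print
print.gap_report <- function(x, ...) {
  cat("Gap-area report (config ", x$config_hash, ")\n", sep = "")
  cat("  fragments: ", x$n_fragments, ", fracture lines: ",
      x$n_fracture_lines, ", loops: ", x$n_loops, "\n", sep = "")
  cat("  total 3D gap area: ", format(x$total_gap_area_mm2, digits = 6),
      " mm^2 -> ", x$prognosis,
      if (isTRUE(x$high_risk)) " (high risk)" else "", "\n", sep = "")
  invisible(x)
}

#' Cohort-level prognosis report
#'
#' Runs the statistical layer on a cohort table: ROC and critical cut-off,
#' Kaplan-Meier survivorship per prognostic group, log-rank test, and
#' unadjusted plus adjusted Cox models for the high-risk flag.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @param config a [run_config()].
#' @return A list of class `prognosis_report` with elements `roc`, `cutoff`,
#'   `km`, `logrank`, `cox_unadjusted`, `cox_adjusted`.
#' @export
prognosis_report <- function(cohort, config = run_config()) {
  cohort$prognosis <- classify_prognosis(cohort$gap_area_mm2,
                                         config$boundaries)
  cohort$high_risk <- as.integer(high_risk_flag(cohort$gap_area_mm2,
                                                config$cutoff))
  cohort$male <- as.integer(cohort$sex == "M")
  roc <- roc_curve(cohort$gap_area_mm2, cohort$tka)
  cutoff <- select_cutoff(cohort$gap_area_mm2, cohort$tka)
  km <- km_estimate(cohort$followup_years, cohort$tka, cohort$prognosis)
  lr <- logrank_test(cohort$followup_years, cohort$tka, cohort$prognosis)
  cox_u <- cox_fit(cohort, "high_risk", ties = config$ties)
  cox_a <- cox_fit(cohort, c("high_risk", "age", "male", "smoking", "bmi",
                             "inadequate_reduction"), ties = config$ties)
  structure(list(roc = roc, cutoff = cutoff, km = km, logrank = lr,
                 cox_unadjusted = cox_u, cox_adjusted = cox_a,
                 config_hash = .fnv1a(unclass(config))),
            class = "prognosis_report")
}

#' @exportS3Method base::print
print.prognosis_report <- function(x, ...) {
  cat("Prognosis report (config ", x$config_hash, ")\n", sep = "")
  cat("  AUC: ", format(x$roc$auc, digits = 3), ", selected cut-off: ",
      format(as.numeric(x$cutoff), digits = 5), " mm^2\n", sep = "")
  cat("  log-rank: chi-sq ", format(x$logrank$statistic, digits = 4),
      " on ", x$logrank$df, " df, p = ",
      format.pval(x$logrank$p_value, digits = 3), "\n", sep = "")
  hr <- x$cox_adjusted$coefficients
  hr <- hr[hr$term == "high_risk", ]
  cat("  adjusted HR (high risk): ", sprintf("%.2f (%.2f-%.2f)", hr$hr,
                                             hr$hr_lower, hr$hr_upper),
      "\n", sep = "")
  invisible(x)
}
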