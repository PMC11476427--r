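# End-to-end orchestration: geometry -> boundary conditions -> pulsatile flow
# -> wall metrics -> cross-section structural analysis -> feature row, and the
# full cohort study (split, both imbalance arms, cross-validation, held-out
# test, Shapley importance).

#' Synthetic ultrasound measurement record
#'
#' PSV/EDV/pulse rate and per-branch measurement-site areas (the planar model
#' maps a site area to channel width times unit depth).
#'
#' @param geom a `bifurcation_geometry` providing the site widths.
#' @param seed integer seed.
#' @return an object of class `us_measurement`.
#' @export
generate_us_measurement <- function(geom, seed = 1) {
  u <- with_local_seed(seed, stats::runif(4))
  psv <- 0.6 + 1.0 * u[1]
  edv <- psv * (0.25 + 0.15 * u[2])
  obj <- structure(list(
    psv = psv, edv = edv,
    pulse_rate = 55 + 40 * u[3],
    site_area = c(cca = geom$d_cca * 1, eca = geom$d_eca * 1),
    eca_velocity_scale = 0.5 + 0.2 * u[4]
  ), class = "us_measurement")
  validate_us_measurement(obj)
}

validate_us_measurement <- function(x) {
  if (!(x$edv > 0 && x$edv < x$psv)) stop_module("synth_data", "require 0 < edv < psv")
  if (x$pulse_rate < 30 || x$pulse_rate > 200) stop_module("synth_data", "pulse rate outside [30, 200]")
  if (any(x$site_area <= 0)) stop_module("synth_data", "site areas must be positive")
  invisible(x)
}

#' @export
print.us_measurement <- function(x, ...) {
  cat(sprintf("<us_measurement> PSV %.2f m/s, EDV %.2f m/s, pulse %.0f bpm\n",
              x$psv, x$edv, x$pulse_rate))
  invisible(x)
}

#' Pipeline configuration with paper-anchored solver controls
#'
#' Solver controls keep their anchored defaults (convergence tolerance 1e-4,
#' iteration limit 150, low-TAWSS threshold 0.4 Pa, OSI threshold 0.2,
#' estimators 100, learning rate 0.1, depth 3, test fraction 0.3, 5 folds).
#' Mesh and timestep sizes default to desk-scale values chosen so one case
#' completes in minutes on one CPU; the finer anchored sizes (0.16 mm flow
#' elements, 0.05 mm structural faces) remain the op-level defaults of
#' [mesh_domain()] and [mesh_cross_section()].
#'
#' @param ... overrides of any nested default, e.g. `solver = list(h_max = 5e-4)`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    geometry = list(reference_diameters = c(cca = 6e-3, ica = 4.5e-3, eca = 3.5e-3),
                    stenosis_severity = 0.4),
    solver = list(h_max = 9e-4, dt_fraction = 0.02, n_cycles = 3,
                  tol = 1e-4, max_iter = 150),
    thresholds = list(low_tawss = 0.4, high_osi = 0.2, high_tawss = 40),
    pressure_offset_mmhg = 80,
    structural = list(face_size = 3.5e-4, wall_thickness = 1.3e-3,
                      plaque_arc_extent = 120, cap_thickness = 2.5e-4,
                      n_increments = 5),
    ml = list(n_estimators = 100, learning_rate = 0.1, max_depth = 3,
              test_fraction = 0.3, n_folds = 5, k_neighbors = 5, threshold = 0.5),
    cohort = list(n0 = 115, n1 = 19)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  seed %d | stenosis %.0f%% | h_max %.3g m | dt %.3g T | cycles %d\n",
              x$seed, 100 * x$geometry$stenosis_severity, x$solver$h_max,
              x$solver$dt_fraction, x$solver$n_cycles))
  cat(sprintf("  GBT: %d estimators, lr %.2g, depth %d | folds %d | test %.0f%%\n",
              x$ml$n_estimators, x$ml$learning_rate, x$ml$max_depth,
              x$ml$n_folds, 100 * x$ml$test_fraction))
  invisible(x)
}

#' Serialize / restore a pipeline configuration as JSON
#' @param cfg a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(cfg, path) {
  obj <- unclass(cfg)
  # named atomic vectors serialize as JSON objects so names survive the trip
  obj$geometry$reference_diameters <- as.list(obj$geometry$reference_diameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$geometry$reference_diameters <- unlist(obj$geometry$reference_diameters)
  structure(obj, class = "pipeline_config")
}

#' Run one synthetic case end to end
#'
#' Executes geometry generation, ultrasound-derived boundary conditions,
#' transient flow, wall shear metrics, cross-section structural analysis, and
#' emits one feature row. Intermediate artifacts are returned (and optionally
#' persisted) so each stage can be re-run independently.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional directory; when given, waveforms, meshes, wall
#'   shear records and the feature row are written there.
#' @return list with `features` (one-row data.frame), `stages` (intermediate
#'   objects) and `timing` (seconds).
#' @export
run_case <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_module("pipeline", "stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  props <- fluid_props()
  geom <- stage("geometry", generate_geometry(
    config$geometry$reference_diameters, config$geometry$stenosis_severity,
    seed = substream_seed(config$seed, "geometry")))
  us <- stage("ultrasound", generate_us_measurement(geom, seed = substream_seed(config$seed, "us")))
  period <- cycle_duration(us$pulse_rate)
  vw <- stage("waveform", velocity_waveform(us$psv, us$edv, period))
  mw_cca <- mass_flow_waveform(vw, us$site_area["cca"], props)
  vw_eca <- velocity_waveform(us$psv * us$eca_velocity_scale,
                              us$edv * us$eca_velocity_scale, period)
  mw_eca <- mass_flow_waveform(vw_eca, us$site_area["eca"], props)
  mesh <- stage("meshing", mesh_domain(geom, h_max = config$solver$h_max))
  sol <- stage("flow", suppressMessages(solve_transient(
    mesh, flow_bc(mw_cca, "inlet"), flow_bc(mw_eca, "outlet_eca"), props,
    dt = config$solver$dt_fraction * period, n_cycles = config$solver$n_cycles,
    tol = config$solver$tol, max_iter = config$solver$max_iter)))
  rec <- wall_shear_series(sol)
  bp <- boundary_pressure_series(sol)
  offset <- config$pressure_offset_mmhg * 133.322
  feats <- stage("metrics", feature_summary(
    tawss(rec), osi(rec), rec$arclength,
    list(cca = bp$cca, ica = bp$ica, eca = bp$eca),
    thresholds = config$thresholds, pressure_offset = offset))
  cs <- stage("cross_section", generate_cross_section(
    config$structural$wall_thickness, config$structural$plaque_arc_extent,
    config$structural$cap_thickness, seed = substream_seed(config$seed, "cross_section")))
  smesh <- stage("structural_mesh", mesh_cross_section(cs, config$structural$face_size))
  p_load <- max(bp$cca) + offset   # cycle-maximum absolute pressure at the site
  ssol <- stage("structural", solve_structural(
    smesh, list(wall = arterial_wall_material(), plaque = fibrosis_material()),
    luminal_pressure = p_load, n_increments = config$structural$n_increments))
  ps <- plaque_structural_stress(ssol)
  row <- cbind(as.data.frame(feats),
               data.frame(pss = ps$pss, max_deformation = ps$max_deformation,
                          max_von_mises = ps$max_von_mises,
                          luminal_pressure = p_load,
                          picard_iterations_max = max(sol$picard_iters),
                          periodicity = cycle_periodicity(sol)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_waveform_csv(vw, file.path(out_dir, "velocity_waveform.csv"))
    write_waveform_csv(mw_cca, file.path(out_dir, "massflow_cca.csv"))
    write_geometry_csv(geom, file.path(out_dir, "geometry.csv"))
    write_mesh_vtk(mesh, file.path(out_dir, "flow_mesh.vtk"))
    write_wall_shear_csv(rec, file.path(out_dir, "wall_shear.csv"))
    write_cross_section_csv(cs, file.path(out_dir, "cross_section.csv"))
    utils::write.csv(row, file.path(out_dir, "feature_row.csv"), row.names = FALSE)
  }
  list(features = row,
       stages = list(geometry = geom, us = us, waveform = vw, mesh = mesh,
                     flow = sol, wall_record = rec, pressures = bp,
                     cross_section = cs, structural = ssol, plaque_stress = ps),
       timing = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full cohort study
#'
#' Generates (or accepts) a cohort, applies the stratified 70-30 split, and
#' runs both imbalance-handling arms: SMOTE oversampling and random
#' undersampling. Each arm gets a stratified 5-fold cross-validation on the
#' training partition (correction applied inside training folds only), a
#' model trained on the balanced full training set, a held-out test report,
#' and - for the SMOTE arm - a Shapley global importance ranking.
#'
#' @param config a `pipeline_config`.
#' @param cohort optional `cohort_table`; generated from the config when NULL.
#' @param attribution compute the Shapley importance ranking (default TRUE).
#' @param out_dir optional output directory for CSV reports.
#' @return an object of class `cohort_study`.
#' @export
run_cohort_study <- function(config = pipeline_config(), cohort = NULL,
                             attribution = TRUE, out_dir = NULL) {
  ml <- config$ml
  if (is.null(cohort)) {
    spec <- generative_risk_spec(n0 = config$cohort$n0, n1 = config$cohort$n1,
                                 seed = substream_seed(config$seed, "cohort"))
    cohort <- generate_cohort(spec)
  }
  fm <- encode_features(cohort)
  sp <- stratified_split(fm, test_fraction = ml$test_fraction,
                         seed = substream_seed(config$seed, "split"))
  arms <- list()
  for (method in c("smote", "undersample")) {
    seed_m <- substream_seed(config$seed, paste0("arm_", method))
    balanced <- switch(method,
                       smote = smote_oversample(sp$train, k_neighbors = ml$k_neighbors, seed = seed_m),
                       undersample = random_undersample(sp$train, seed = seed_m))
    cv <- cross_validate(sp$train, n_folds = ml$n_folds, imbalance_method = method,
                         seed = seed_m, n_estimators = ml$n_estimators,
                         learning_rate = ml$learning_rate, max_depth = ml$max_depth,
                         threshold = ml$threshold, k_neighbors = ml$k_neighbors)
    model <- gbt_fit(balanced, n_estimators = ml$n_estimators,
                     learning_rate = ml$learning_rate, max_depth = ml$max_depth)
    arms[[method]] <- list(model = model, balanced_train = balanced, cv = cv,
                           test_report = evaluate(model, sp$test, ml$threshold))
  }
  att <- NULL
  if (attribution) {
    seed_a <- substream_seed(config$seed, "attribution")
    nx <- min(25, nrow(fm$X))
    idx <- with_local_seed(seed_a, sample.int(nrow(fm$X), nx))
    att <- sampled_shapley(arms$smote$model, fm$X[idx, , drop = FALSE],
                           sp$train$X, n_permutations = 30, seed = seed_a)
  }
  # aggregated test-set table (both arms)
  test_table <- do.call(rbind, lapply(names(arms), function(m) {
    r <- arms[[m]]$test_report
    data.frame(method = m, accuracy = r$accuracy, roc_auc = r$auc,
               recall = r$weighted_recall, specificity = r$specificity,
               f1 = r$weighted_f1, balanced_accuracy = r$balanced_accuracy)
  }))
  study <- structure(list(cohort = cohort, feature_matrix = fm, split = sp,
                          arms = arms, attribution = att, test_table = test_table,
                          importance = if (!is.null(att)) global_importance(att) else NULL,
                          config = config), class = "cohort_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    for (m in names(arms)) {
      utils::write.csv(arms[[m]]$cv$folds, file.path(out_dir, sprintf("cv_%s.csv", m)),
                       row.names = FALSE)
    }
    utils::write.csv(test_table, file.path(out_dir, "test_metrics.csv"), row.names = FALSE)
    if (!is.null(study$importance)) {
      utils::write.csv(study$importance, file.path(out_dir, "importance.csv"), row.names = FALSE)
    }
  }
  study
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study> %d subjects (%d events), train %d / test %d\n",
              nrow(x$cohort), sum(x$cohort$event), length(x$split$train$y),
              length(x$split$test$y)))
  print(x$test_table, row.names = FALSE, digits = 3)
  if (!is.null(x$importance)) {
    cat("top features:", paste(utils::head(x$importance$feature, 3), collapse = ", "), "\n")
  }
  invisible(x)
}
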