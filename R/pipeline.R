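#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run (segment -> mask ->
#' detect -> register -> match -> report) in one validated object. The
#' config is serialised verbatim into the output report for provenance.
#'
#' @param input either a [phantom_spec()] (volumes are generated) or a list
#'   `list(lowres = path, highres = path)` of volume files readable by
#'   [read_volume()].
#' @param steps_lowres dilation steps evaluated on the low-resolution side
#'   (default `1:3`, the > 0.164 / 0.328 / 0.492 mm cut-offs at 0.082 mm).
#' @param reference_diameter_mm fixed reference cut-off detected on the
#'   high-resolution side (default 0.10 mm, i.e. 3 steps at 0.018 mm).
#' @param thickness_lowres_mm,thickness_highres_mm cortical mask thickness
#'   per modality (defaults 0.328 / 0.324 mm).
#' @param lowres_filter,lowres_threshold_permille low-resolution
#'   segmentation settings (see [segment_lowres()]).
#' @param highres_max_value maximum possible voxel value of the
#'   high-resolution acquisition (default 1000, the phantom convention).
#' @param calibrate_highres_to_bvtv if `TRUE`, replace the constant
#'   high-resolution threshold by one calibrated to the low-resolution
#'   BV/TV (see [calibrate_threshold_to_bvtv()]).
#' @param overlap_min voxel-overlap match criterion (default 20).
#' @param register `"auto"` (run [register_rigid()]), `"identity"`, or a
#'   [rigid_transform()] known a priori (e.g. a phantom ground truth).
#' @param seed integer seed for every stochastic element (phantom noise).
#' @param output_dir artifact directory, or `NULL` to skip writing.
#' @return A `cg_run_config`.
#' @export
pipeline_config <- function(input,
                            steps_lowres = 1:3,
                            reference_diameter_mm = 0.10,
                            thickness_lowres_mm = 0.328,
                            thickness_highres_mm = 0.324,
                            lowres_filter = "laplace_hamming",
                            lowres_threshold_permille = 450,
                            highres_max_value = 1000,
                            calibrate_highres_to_bvtv = FALSE,
                            overlap_min = 20L,
                            register = "auto",
                            seed = 1L,
                            output_dir = NULL) {
  if (!(inherits(input, "cg_phantom_spec") ||
        (is.list(input) && !is.null(input$lowres) && !is.null(input$highres))))
    stop("config error: input must be a phantom_spec or lowres/highres paths")
  stopifnot(length(steps_lowres) >= 1, all(steps_lowres >= 1))
  structure(list(input = input, steps_lowres = as.integer(steps_lowres),
                 reference_diameter_mm = reference_diameter_mm,
                 thickness_lowres_mm = thickness_lowres_mm,
                 thickness_highres_mm = thickness_highres_mm,
                 lowres_filter = lowres_filter,
                 lowres_threshold_permille = lowres_threshold_permille,
                 highres_max_value = highres_max_value,
                 calibrate_highres_to_bvtv = calibrate_highres_to_bvtv,
                 overlap_min = as.integer(overlap_min),
                 register = register, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "cg_run_config")
}

#' Run the full detection-and-matching pipeline on one joint pair
#'
#' Executes, deterministically for a given seed: volume acquisition
#' (phantom generation or file reading), periosteal auto-contouring, bone
#' segmentation per modality, constant-thickness cortical masks,
#' interruption detection on the low-resolution side at every configured
#' cut-off and on the high-resolution side at the fixed reference cut-off,
#' rigid registration (unless a transform is supplied), majority-vote label
#' resampling onto the low-resolution grid, overlap matching, and the
#' lesion-level reliability metrics. Artifacts (label volumes, per-component
#' CSVs, match CSVs, a JSON report embedding the config) are written to
#' `output_dir` when set; the JSON report contains no timestamps, so reruns
#' with the same seed are byte-identical.
#'
#' @param config a [pipeline_config()] or the path of a YAML file whose
#'   keys mirror its arguments.
#' @return A `cg_run_result`: per-cut-off detections (`detections_lowres`),
#'   the reference set (`detection_reference`), match reports, a data frame
#'   `lesion_metrics` with `ppv_0.10mm` / `sensitivity_0.10mm` per cut-off,
#'   the transform used, and the config.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "cg_run_config"))
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  vols <- stage("input", {
    if (inherits(config$input, "cg_phantom_spec")) {
      ph <- generate_phantom(config$input)
      list(lowres = ph$lowres, highres = ph$highres, truth = ph$truth)
    } else {
      list(lowres = read_volume(config$input$lowres),
           highres = read_volume(config$input$highres), truth = NULL)
    }
  })

  contour_lo <- stage("contour", auto_contour(vols$lowres))
  contour_hi <- stage("contour", auto_contour(vols$highres))

  seg_lo <- stage("segment", segment_lowres(
    vols$lowres, contour_lo, filter = config$lowres_filter,
    threshold_permille = config$lowres_threshold_permille))
  seg_hi <- stage("segment", {
    if (isTRUE(config$calibrate_highres_to_bvtv)) {
      thr <- calibrate_threshold_to_bvtv(vols$highres, contour_hi,
                                         target_bvtv = seg_lo$bvtv)
      segment_highres(vols$highres, contour_hi,
                      threshold_permille = 1000 * thr / config$highres_max_value,
                      max_value = config$highres_max_value)
    } else {
      segment_highres(vols$highres, contour_hi,
                      max_value = config$highres_max_value)
    }
  })

  cmask_lo <- stage("mask", build_cortical_mask(contour_lo,
                                                config$thickness_lowres_mm))
  cmask_hi <- stage("mask", build_cortical_mask(contour_hi,
                                                config$thickness_highres_mm))

  k_ref <- choose_steps_for_diameter(config$reference_diameter_mm,
                                     vols$highres$voxel_size_mm)
  det_ref <- stage("detect", detect_interruptions(seg_hi, cmask_hi, k_ref))
  dets <- lapply(config$steps_lowres, function(k)
    stage("detect", detect_interruptions(seg_lo, cmask_lo, k)))
  names(dets) <- paste0("k", config$steps_lowres)

  transform <- stage("register", {
    if (inherits(config$register, "cg_rigid_transform")) config$register
    else if (identical(config$register, "identity"))
      rigid_transform(center_mm = vols$lowres$origin_mm +
                        (dim(vols$lowres$data) - 1) / 2 *
                        vols$lowres$voxel_size_mm)
    else register_rigid(vols$highres, vols$lowres)
  })

  ref_on_lo <- stage("resample", resample_labels(det_ref$labels, transform,
                                                 vols$lowres))
  matches <- lapply(dets, function(d)
    stage("match", match_interruptions(d, ref_on_lo,
                                       overlap_min = config$overlap_min,
                                       mode = "fixed_ref_diameter",
                                       n_B = det_ref$joint_totals$count)))

  lesion <- do.call(rbind, lapply(seq_along(matches), function(i) {
    m <- matches[[i]]
    k <- config$steps_lowres[i]
    data.frame(
      k = k,
      min_diameter_mm = map_steps_to_diameter(k, vols$lowres$voxel_size_mm),
      n_lowres = m$n_A, n_reference = m$n_B,
      ppv_0.10mm = if (m$n_A >= 1) ppv(m$matched_A, m$n_A) else NA_real_,
      sensitivity_0.10mm = if (m$n_B >= 1) sensitivity(m$matched_B, m$n_B)
                           else NA_real_)
  }))

  result <- structure(list(
    detections_lowres = dets, detection_reference = det_ref,
    matches = matches, lesion_metrics = lesion, transform = transform,
    segmentations = list(lowres = seg_lo, highres = seg_hi),
    truth = vols$truth, config = config),
    class = "cg_run_result")
  if (!is.null(config$output_dir))
    stage("write", write_run_artifacts(result, config$output_dir))
  result
}

#' @export
print.cg_run_result <- function(x, ...) {
  cat("<cg_run_result>\n")
  print(x$lesion_metrics, row.names = FALSE)
  invisible(x)
}

write_run_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$detections_lowres)) {
    d <- result$detections_lowres[[nm]]
    write_labels(d$labels, file.path(dir, paste0("interruptions_", nm, ".nii")))
    utils::write.csv(d$components,
                     file.path(dir, paste0("components_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$matches[[nm]]$pairs,
                     file.path(dir, paste0("matches_", nm, ".csv")),
                     row.names = FALSE)
  }
  write_labels(result$detection_reference$labels,
               file.path(dir, "interruptions_reference.nii"))
  cfg <- result$config
  cfg$output_dir <- NULL      # environment-specific, not provenance
  cfg$input <- if (inherits(cfg$input, "cg_phantom_spec"))
    unclass_for_json(cfg$input) else cfg$input
  report <- list(
    lesion_metrics = result$lesion_metrics,
    joint_totals_lowres = lapply(result$detections_lowres,
                                 function(d) d$joint_totals),
    joint_totals_reference = result$detection_reference$joint_totals,
    transform = list(rotation = result$transform$rotation,
                     translation_mm = result$transform$translation_mm,
                     center_mm = result$transform$center_mm),
    config = unclass_for_json(cfg))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

unclass_for_json <- function(x) {
  x <- unclass(x)
  lapply(x, function(e) if (is.list(e) && !is.data.frame(e))
    unclass_for_json(e) else unclass(e))
}

config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    if (!is.null(ph$holes)) ph$holes <- as.data.frame(ph$holes)
    y$input <- do.call(phantom_spec, ph)
    y$phantom <- NULL
  }
  do.call(pipeline_config, y)
}
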