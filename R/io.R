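kinetics_to_list <- function(kin) unclass(kin)

kinetics_from_list <- function(x) {
  switch(x$mode,
    blood = tissue_kinetics("blood"),
    macro = tissue_kinetics("macro", Ki = x$Ki, Vd = x$Vd),
    micro = tissue_kinetics("micro", K1 = x$K1, k2 = x$k2, k3 = x$k3,
                            vb = x$vb))
}

#' Write a dynamic phantom to NIfTI-1 + sidecar JSON
#'
#' Stores the 4D activity volume and the 3D label map as NIfTI-1 (voxel size
#' in the header pixdim) and everything else --- frame schedule, per-label
#' truth kinetics, input-function and partition parameters, noise level and
#' seed --- in a sidecar JSON, so a phantom is fully reconstructable from
#' disk.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- phantom$voxel_size
  ref4 <- list(pixdim = c(0, v, v, v, 1, 0, 0, 0))
  act_path <- file.path(dir, paste0(prefix, "_activity.nii"))
  lab_path <- file.path(dir, paste0(prefix, "_labels.nii"))
  json_path <- file.path(dir, paste0(prefix, ".json"))
  RNifti::writeNifti(RNifti::asNifti(phantom$activity, reference = ref4,
                                     datatype = "double"), act_path)
  RNifti::writeNifti(RNifti::asNifti(phantom$labels + 0L, reference = ref4,
                                     datatype = "int32"), lab_path)
  side <- list(
    schedule = list(start = phantom$schedule$start,
                    duration = phantom$schedule$duration,
                    bed = phantom$schedule$bed),
    truth = lapply(phantom$truth, kinetics_to_list),
    params = unclass(phantom$params),
    partition = unclass(phantom$partition),
    voxel_size = phantom$voxel_size,
    noise_scale = phantom$noise_scale,
    seed = phantom$seed)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(activity = act_path, labels = lab_path, sidecar = json_path))
}

#' Read a dynamic phantom written by [write_phantom()]
#'
#' @param dir directory holding the files.
#' @param prefix file name prefix used at write time.
#' @return A \code{"dynamic_phantom"} object. Errors if the number of frames
#'   in the 4D volume disagrees with the sidecar schedule.
#' @export
read_phantom <- function(dir, prefix = "phantom") {
  act <- RNifti::readNifti(file.path(dir, paste0(prefix, "_activity.nii")))
  lab <- RNifti::readNifti(file.path(dir, paste0(prefix, "_labels.nii")))
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  activity <- array(as.vector(as.array(act)), dim(act))  # strip NIfTI attrs
  if (dim(activity)[4] != length(side$schedule$start))
    stop("frame count mismatch between volume and sidecar schedule")
  sched <- frame_schedule(side$schedule$start, side$schedule$duration,
                          side$schedule$bed)
  truth <- lapply(side$truth, kinetics_from_list)
  params <- do.call(input_function_params, side$params)
  part <- do.call(partition_model, side$partition)
  vs <- RNifti::pixdim(act)[1]
  if (abs(vs - side$voxel_size) > 1e-6)
    stop("voxel size mismatch between NIfTI header and sidecar")
  structure(list(activity = activity,
                 labels = array(as.integer(as.array(lab)), dim(lab)),
                 truth = truth, schedule = sched,
                 voxel_size = side$voxel_size, params = params,
                 partition = part, noise_scale = side$noise_scale,
                 seed = side$seed),
            class = "dynamic_phantom")
}

#' Write parametric maps and the SUV image as NIfTI-1
#'
#' Units are recorded in the header description field.
#'
#' @param maps a [fit_patlak_map()] result.
#' @param suv optional [static_suv_image()] result.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_maps <- function(maps, suv = NULL, dir) {
  stopifnot(inherits(maps, "parametric_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- maps$voxel_size
  wr <- function(arr, name, unit) {
    p <- file.path(dir, paste0(name, ".nii"))
    im <- RNifti::asNifti(arr, reference = list(
      pixdim = c(0, v, v, v, 1, 0, 0, 0), descrip = unit),
      datatype = "double")
    RNifti::writeNifti(im, p)
    p
  }
  out <- c(Ki = wr(maps$Ki_map, "ki_map", "Ki mL/min/mL"),
           Vd = wr(maps$Vd_map, "vd_map", "Vd mL/mL"),
           qc = wr(maps$qc_map, "qc_map", "weighted R^2"))
  if (!is.null(suv))
    out <- c(out, suv = wr(suv$volume, "suv_image", "SUV g/mL"))
  invisible(out)
}

#' Write an input function as CSV + JSON tail parameters
#'
#' @param idif an [estimate_input_function()] result or a [plasma_input()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
write_input_function <- function(idif, dir, prefix = "idif") {
  cp <- if (inherits(idif, "idif")) idif$Cp else idif
  stopifnot(inherits(cp, "plasma_input"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(data.frame(t_min = cp$grid, Cp_kBq_per_mL = cp$Cp),
                   csv, row.names = FALSE)
  paths <- csv
  if (!is.null(cp$tail_params)) {
    js <- file.path(dir, paste0(prefix, "_tail.json"))
    jsonlite::write_json(as.list(cp$tail_params), js, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}

#' Write lesion records with units in the column headers
#'
#' @param records lesion-record data frame.
#' @param path output CSV path.
#' @export
write_lesion_records <- function(records, path) {
  out <- records
  ren <- c(Ki_max = "Ki_max_mL_per_min_per_mL", Vd_max = "Vd_max_mL_per_mL",
           SUV_max = "SUV_max_g_per_mL", true_Ki = "true_Ki_mL_per_min_per_mL",
           true_Vd = "true_Vd_mL_per_mL")
  names(out) <- ifelse(names(out) %in% names(ren), ren[names(out)],
                       names(out))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A fully serializable description of one end-to-end run; a run is
#' reproducible from its configuration alone.
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param shape phantom dimensions, voxels.
#' @param voxel_size mm.
#' @param n_early_60s,n_passes,n_beds,sec_per_bed schedule parameters (see
#'   [make_study_schedule()]).
#' @param params [input_function_params()].
#' @param partition [partition_model()].
#' @param t_star Patlak window start, minutes.
#' @param noise_scale frame-noise magnitude.
#' @param cohort a [cohort_spec()] (its seed is overridden by \code{seed}).
#' @param dose,weight injected activity (MBq) and body weight (kg) for SUV.
#' @param static_window static acquisition window for SUV, minutes.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1, shape = c(48, 48, 48), voxel_size = 4,
                       n_early_60s = 5, n_passes = 11, n_beds = 5,
                       sec_per_bed = 35,
                       params = input_function_params(),
                       partition = partition_model(),
                       t_star = 20, noise_scale = 0.05,
                       cohort = cohort_spec(noise_scale = noise_scale),
                       dose = 210, weight = 75,
                       static_window = c(60, 70)) {
  cohort$seed <- seed + 1000L
  cohort$noise_scale <- noise_scale
  structure(list(seed = seed, shape = shape, voxel_size = voxel_size,
                 n_early_60s = n_early_60s, n_passes = n_passes,
                 n_beds = n_beds, sec_per_bed = sec_per_bed,
                 params = params, partition = partition, t_star = t_star,
                 noise_scale = noise_scale, cohort = cohort,
                 dose = dose, weight = weight,
                 static_window = static_window),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  listify <- function(el) if (!is.null(names(el))) as.list(el) else el
  x <- lapply(unclass(config), function(el)
    if (inherits(el, "cohort_spec")) {
      el <- unclass(el)
      el$liver <- unclass(el$liver)
      lapply(el, listify)  # keep group names on the per-group vectors
    } else if (is.object(el)) unclass(el) else el)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- x$cohort
  cohort <- cohort_spec(
    n_cancer = co$n_cancer, n_inflammatory = co$n_inflammatory,
    ki_median = unlist(co$ki_median), ki_iqr = unlist(co$ki_iqr),
    vd_median = unlist(co$vd_median), vd_iqr = unlist(co$vd_iqr),
    vb_median = unlist(co$vb_median), vb_iqr = unlist(co$vb_iqr),
    liver = kinetics_from_list(co$liver),
    noise_scale = co$noise_scale, seed = co$seed)
  cfg <- run_config(seed = x$seed, shape = unlist(x$shape),
                    voxel_size = x$voxel_size,
                    n_early_60s = x$n_early_60s, n_passes = x$n_passes,
                    n_beds = x$n_beds, sec_per_bed = x$sec_per_bed,
                    params = do.call(input_function_params, x$params),
                    partition = do.call(partition_model, x$partition),
                    t_star = x$t_star, noise_scale = x$noise_scale,
                    cohort = cohort, dose = x$dose, weight = x$weight,
                    static_window = unlist(x$static_window))
  cfg$cohort$seed <- co$seed
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> idif -> fit -> measure -> compare on synthetic
#' data: builds the dynamic phantom and the lesion cohort, estimates the
#' image-derived input function from the phantom, fits voxelwise Ki/Vd maps
#' and a late-window SUV image, measures the cohort's lesions against the
#' IDIF (and the phantom's lesions on the maps), and summarises the
#' two-group statistics with ROC analysis of Ki_max. All outputs and a
#' manifest (seed, configuration, per-stage status and timing, file MD5
#' hashes) are written under \code{out_dir}. Any stage error halts the run;
#' the failed stage is recorded in the manifest before the error propagates.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "dynpatlak",
                   version = as.character(utils::packageVersion("dynpatlak")),
                   r_version = R.version.string,
                   seed = config$seed, stages = list())
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  res <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    r
  }
  res$phantom <- stage("simulate", {
    sched <- make_study_schedule(config$n_early_60s, config$n_passes,
                                 config$n_beds, config$sec_per_bed)
    phantom <- build_phantom(shape = config$shape,
                             voxel_size = config$voxel_size,
                             params = config$params, schedule = sched,
                             noise_scale = config$noise_scale,
                             seed = config$seed,
                             partition = config$partition)
    res$cohort <- generate_cohort(config$cohort, params = config$params,
                                   schedule = sched,
                                   static_window = config$static_window)
    write_phantom(phantom, out_dir)
    phantom
  })
  res$idif <- stage("idif", {
    idif <- estimate_input_function(
      res$phantom, t_max = config$static_window[2] + 1)
    write_input_function(idif, out_dir)
    idif
  })
  res$maps <- stage("fit", {
    maps <- fit_patlak_map(res$phantom, res$idif$Cp, config$t_star)
    span <- range(res$phantom$schedule$start +
                    res$phantom$schedule$duration)
    suv <- static_suv_image(res$phantom, c(max(0, span[2] - 10), span[2]),
                            config$dose, config$weight)
    write_maps(maps, suv, out_dir)
    res$suv <- suv
    maps
  })
  res$records <- stage("measure", {
    records <- measure_cohort(res$cohort, Cp = res$idif$Cp,
                              t_star = config$t_star, dose = config$dose,
                              weight = config$weight)
    write_lesion_records(records, file.path(out_dir, "lesion_records.csv"))
    vois <- phantom_vois(res$phantom)
    phantom_records <- measure_lesions(res$maps, res$suv, vois)
    write_lesion_records(phantom_records,
                         file.path(out_dir, "phantom_records.csv"))
    res$phantom_records <- phantom_records
    records
  })
  res$summary <- stage("compare", {
    summ <- summarize_cohort(res$records)
    utils::write.csv(summ$table, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    roc <- roc_youden(res$records$Ki_max,
                      res$records$group == "cancer")
    utils::write.csv(data.frame(threshold = roc$thresholds,
                                sensitivity = roc$sensitivities,
                                specificity = roc$specificities),
                     file.path(out_dir, "roc_ki_max.csv"),
                     row.names = FALSE)
    res$roc <- roc
    jsonlite::write_json(
      list(table = summ$table,
           paired_lbr = summ$paired_lbr,
           spearman = as.list(summ$spearman),
           roc = list(auc = roc$auc, youden_cutoff = roc$youden_cutoff,
                      sensitivity = roc$sensitivity_at_cutoff,
                      specificity = roc$specificity_at_cutoff)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    summ
  })
  files <- list.files(out_dir, full.names = TRUE)
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
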