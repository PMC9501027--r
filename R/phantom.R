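#' Default phantom label geometry
#'
#' Builds a 3D integer label map containing the structures the analysis needs:
#' 0 = background, 1 = aortic tube (a cylinder along z near one edge),
#' 2 = liver (a sphere in the opposite half), and labels >= 3 = spherical
#' lesions embedded in the liver, stacked along z.
#'
#' @param shape integer length-3 volume dimensions (voxels).
#' @param n_lesions number of lesion spheres.
#' @param lesion_radius lesion radius in voxels (default scales with the
#'   volume).
#' @return Integer 3D array of labels.
#' @export
phantom_labels <- function(shape, n_lesions = 2,
                           lesion_radius = max(2, round(min(shape) / 12))) {
  stopifnot(length(shape) == 3, all(shape >= 12))
  labels <- array(0L, dim = shape)
  ax <- round(shape[1] / 4); ay <- round(shape[2] / 2)
  ar <- max(2, round(min(shape[1:2]) / 12))
  xs <- seq_len(shape[1]); ys <- seq_len(shape[2])
  tube2d <- outer((xs - ax)^2, (ys - ay)^2, "+") <= ar^2
  for (z in seq_len(shape[3])) labels[, , z][tube2d] <- 1L
  lx <- round(3 * shape[1] / 4); ly <- round(shape[2] / 2)
  lz <- round(shape[3] / 2); lr <- round(min(shape) / 4)
  idx <- as.matrix(expand.grid(x = xs, y = ys, z = seq_len(shape[3])))
  d2liver <- (idx[, 1] - lx)^2 + (idx[, 2] - ly)^2 + (idx[, 3] - lz)^2
  labels[idx[d2liver <= lr^2, , drop = FALSE]] <- 2L
  if (n_lesions > 0) {
    zc <- round(seq(lz - lr / 2, lz + lr / 2, length.out = n_lesions))
    for (j in seq_len(n_lesions)) {
      d2 <- (idx[, 1] - lx)^2 + (idx[, 2] - ly)^2 + (idx[, 3] - zc[j])^2
      sel <- d2 <= lesion_radius^2
      labels[idx[sel, , drop = FALSE]] <- 2L + j
    }
  }
  labels
}

label_curve_function <- function(kin, cp_fine, partition) {
  switch(kin$mode,
    blood = {
      p <- eval_partition(partition, cp_fine$grid)
      wb <- cp_fine$Cp / p
      stats::approxfun(cp_fine$grid, wb, rule = 2)
    },
    macro = {
      ct <- macro_patlak_curve(kin, cp_fine, cp_fine$grid)
      stats::approxfun(cp_fine$grid, ct, rule = 2)
    },
    micro = {
      ct <- solve_2tc_irreversible(kin, cp_fine, cp_fine$grid)
      stats::approxfun(cp_fine$grid, ct, rule = 2)
    })
}

#' Build a 4D dynamic phantom
#'
#' Simulates a dynamic whole-body acquisition of a digital phantom: every
#' voxel's frame series is the frame-averaged curve of its label's kinetics
#' plus duration-scaled Gaussian noise. The aortic tube follows the
#' whole-blood curve (the plasma model divided by the time-varying
#' plasma-to-whole-blood ratio), so that an exact image-derived input
#' function pipeline can recover the plasma curve. Ground truth (labels,
#' kinetics, input model, seed) is stored alongside the data.
#'
#' @param shape length-3 volume dimensions in voxels.
#' @param voxel_size isotropic voxel size, mm.
#' @param truth named list mapping label id (as character: "1", "2", ...) to
#'   [tissue_kinetics()]. Label 1 must be \code{blood} mode; unknown labels
#'   (absent from the label map) are an error.
#' @param params [input_function_params()] of the simulated plasma curve.
#' @param schedule [frame_schedule()] of the acquisition.
#' @param noise_scale noise magnitude passed to [add_noise()].
#' @param seed integer RNG seed.
#' @param partition [partition_model()] used to derive whole blood from
#'   plasma.
#' @param labels optional precomputed label map; defaults to
#'   [phantom_labels()] with one lesion sphere per truth label >= 3.
#' @return An object of class \code{"dynamic_phantom"}: list with
#'   \code{activity} (4D array x,y,z,frame, kBq/mL), \code{labels},
#'   \code{truth}, \code{schedule}, \code{voxel_size}, \code{params},
#'   \code{partition}, \code{noise_scale}, \code{seed}.
#' @export
build_phantom <- function(shape = c(48, 48, 48), voxel_size = 4,
                          truth = default_phantom_truth(),
                          params = input_function_params(),
                          schedule = make_study_schedule(),
                          noise_scale = 0, seed = 1,
                          partition = partition_model(),
                          labels = NULL) {
  stopifnot(length(shape) == 3, voxel_size > 0)
  lesion_labels <- as.integer(names(truth))
  lesion_labels <- lesion_labels[lesion_labels >= 3L]
  if (is.null(labels))
    labels <- phantom_labels(shape, n_lesions = length(lesion_labels))
  stopifnot(all(dim(labels) == shape))
  present <- sort(unique(as.integer(labels)))
  truth_ids <- as.integer(names(truth))
  if (any(!truth_ids %in% present))
    stop("truth contains labels absent from the label map: ",
         paste(setdiff(truth_ids, present), collapse = ", "))
  n_frames <- nrow(schedule)
  n_vox <- prod(shape)
  act <- matrix(0, n_vox, n_frames)
  lab_vec <- as.integer(labels)
  cp_fine <- true_input_grid(params, schedule)
  for (id in truth_ids) {
    f <- label_curve_function(truth[[as.character(id)]], cp_fine, partition)
    frames <- sample_frames(f, schedule)
    act[lab_vec == id, ] <- matrix(frames, sum(lab_vec == id), n_frames,
                                   byrow = TRUE)
  }
  act <- add_noise(act, schedule, noise_scale, seed)
  structure(list(activity = array(act, c(shape, n_frames)),
                 labels = labels, truth = truth, schedule = schedule,
                 voxel_size = voxel_size, params = params,
                 partition = partition, noise_scale = noise_scale,
                 seed = seed),
            class = "dynamic_phantom")
}

true_input_grid <- function(params, schedule) {
  t_end <- max(schedule$start + schedule$duration)
  plasma_input_from_params(params, t_max = t_end + 1, grid_step = 0.005)
}

#' Ground-truth plasma input of a phantom
#'
#' The exact tabulated plasma curve a phantom's voxel data were synthesised
#' from, on the simulator's internal fine grid. Fitting against it isolates
#' kinetic-model error from input-function estimation error.
#'
#' @param phantom a [build_phantom()] result.
#' @return A [plasma_input()].
#' @export
phantom_true_input <- function(phantom) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  true_input_grid(phantom$params, phantom$schedule)
}

#' Default phantom ground-truth kinetics
#'
#' Aorta (label 1) as blood pool; liver (label 2) with two-tissue-compartment
#' micro-kinetics whose implied macro-parameters sit at normal-liver values
#' (Ki ~1.0e-2 mL/min/mL, Patlak intercept ~1.1 mL/mL) --- micro mode matters
#' here because a Patlak-linear liver would equilibrate instantaneously and
#' rival the blood pool on the earliest frames; a cancer-like (Ki 3.0e-2) and
#' an inflammation-like (Ki 2.0e-2) lesion with exact macro kinetics.
#'
#' @return Named list of [tissue_kinetics()] keyed by label id.
#' @export
default_phantom_truth <- function() {
  list("1" = tissue_kinetics("blood"),
       "2" = tissue_kinetics("micro", K1 = 0.8, k2 = 0.76, k3 = 0.0097,
                             vb = 0.05),
       "3" = tissue_kinetics("macro", Ki = 0.030, Vd = 0.9),
       "4" = tissue_kinetics("macro", Ki = 0.020, Vd = 0.7))
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Dynamic phantom: %d x %d x %d voxels (%.1f mm), %d frames, noise %.3g, seed %d\n",
              d[1], d[2], d[3], x$voxel_size, d[4], x$noise_scale, x$seed))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s (%d vox)", names(tab), tab),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Extract the mean time-activity curve of a label
#'
#' @param phantom a [build_phantom()] result.
#' @param label integer label id.
#' @return Numeric vector: per-frame mean activity over the label's voxels.
#' @export
label_tac <- function(phantom, label) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  sel <- as.integer(phantom$labels) == label
  if (!any(sel)) stop("label not present in phantom")
  n_frames <- dim(phantom$activity)[4]
  m <- matrix(phantom$activity, ncol = n_frames)
  colMeans(m[sel, , drop = FALSE])
}
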