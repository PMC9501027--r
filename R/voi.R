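#' Realize a spherical VOI on a voxel grid
#'
#' Returns the voxels whose centers lie within a sphere of nominal volume
#' \code{volume_cm3} around \code{center}. The radius is
#' \eqn{r = (3V/4\pi)^{1/3}}. The center voxel (nearest grid point) is always
#' included, so the realized set is never empty even when the radius is
#' smaller than half a voxel. Coordinates are 0-based in x/y/z order.
#'
#' @param center numeric length-3, 0-based voxel coordinates.
#' @param volume_cm3 nominal sphere volume, cm^3 (> 0).
#' @param voxel_size isotropic voxel size, mm.
#' @param dim integer length-3 volume dimensions.
#' @return List with \code{index} (1-based linear indices into a volume of
#'   dimension \code{dim}) and \code{coords} (n x 3 matrix of 0-based voxel
#'   coordinates).
#' @export
realize_voi <- function(center, volume_cm3, voxel_size, dim) {
  stopifnot(length(center) == 3, volume_cm3 > 0, voxel_size > 0,
            length(dim) == 3)
  if (any(center < 0) || any(center > dim - 1))
    stop("VOI center outside volume bounds")
  r_mm <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  r_vox <- r_mm / voxel_size
  lo <- pmax(floor(center - r_vox), 0)
  hi <- pmin(ceiling(center + r_vox), dim - 1)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                             z = lo[3]:hi[3]))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2
  sel <- g[d2 <= r_vox^2, , drop = FALSE]
  cvox <- matrix(pmin(pmax(round(center), 0), dim - 1), 1)
  if (nrow(sel) == 0) sel <- cvox
  else if (!any(sel[, 1] == cvox[1] & sel[, 2] == cvox[2] &
                sel[, 3] == cvox[3]))
    sel <- rbind(sel, cvox)
  idx <- sel[, 1] + dim[1] * (sel[, 2] + dim[2] * sel[, 3]) + 1L
  list(index = as.integer(idx), coords = unname(sel))
}

#' Max and mean over a voxel set
#'
#' @param volume 3D array.
#' @param voxels list from [realize_voi()] or a vector of linear indices.
#' @return Named vector \code{c(max, mean)}.
#' @export
voi_stats <- function(volume, voxels) {
  idx <- if (is.list(voxels)) voxels$index else voxels
  if (length(idx) == 0) stop("empty voxel set")
  vals <- volume[idx]
  c(max = max(vals), mean = mean(vals))
}

#' Liver-normalized lesion-to-background ratio
#'
#' @param lesion_max lesion maximum value.
#' @param liver_mean mean value in normal liver tissue (> 0).
#' @return \code{lesion_max / liver_mean}.
#' @export
lesion_to_background <- function(lesion_max, liver_mean) {
  if (any(liver_mean <= 0)) stop("invalid reference: liver mean must be > 0")
  lesion_max / liver_mean
}

#' Standard VOI table for a phantom
#'
#' Places a spherical VOI at the centroid of every lesion label (tag
#' \code{"lesion"}, 2 cm^3 by default) and one liver reference VOI (3 cm^3,
#' the nominal liver volume of the measurement protocol) at the liver
#' centroid, offset away from embedded lesions when possible.
#'
#' @param phantom a [build_phantom()] result.
#' @param lesion_volume_cm3 nominal lesion VOI volume.
#' @param liver_volume_cm3 nominal liver VOI volume.
#' @return Data frame with columns \code{id}, \code{tag}, \code{cx},
#'   \code{cy}, \code{cz} (0-based voxel coordinates), \code{volume_cm3}.
#' @export
phantom_vois <- function(phantom, lesion_volume_cm3 = 2,
                         liver_volume_cm3 = 3) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  labs <- sort(unique(as.integer(phantom$labels)))
  centroid <- function(id) {
    w <- which(phantom$labels == id, arr.ind = TRUE) - 1  # 0-based
    colMeans(w)
  }
  rows <- list()
  if (2L %in% labs) {
    # normal-liver reference: centre the VOI inside the lesion-free liver
    # core, as far from any lesion as the parenchyma allows
    liver_mask <- phantom$labels == 2L
    r_vox <- (3 * liver_volume_cm3 * 1000 / (4 * pi))^(1 / 3) /
      phantom$voxel_size
    core <- liver_mask
    for (i in seq_len(max(1L, ceiling(r_vox)))) {
      nxt <- erode_3d(core)
      if (!any(nxt)) break
      core <- nxt
    }
    cand_vox <- which(core, arr.ind = TRUE) - 1
    lesion_cent <- lapply(labs[labs >= 3L], centroid)
    if (length(lesion_cent) > 0) {
      dmin <- Reduce(pmin, lapply(lesion_cent, function(cc)
        rowSums((cand_vox - matrix(cc, nrow(cand_vox), 3,
                                   byrow = TRUE))^2)))
      cand <- cand_vox[which.max(dmin), ]
    } else cand <- centroid(2L)
    rows[[length(rows) + 1L]] <-
      data.frame(id = "liver", tag = "liver", cx = cand[1], cy = cand[2],
                 cz = cand[3], volume_cm3 = liver_volume_cm3)
  }
  for (id in labs[labs >= 3L]) {
    cc <- centroid(id)
    rows[[length(rows) + 1L]] <-
      data.frame(id = sprintf("lesion%d", id - 2L), tag = "lesion",
                 cx = cc[1], cy = cc[2], cz = cc[3],
                 volume_cm3 = lesion_volume_cm3)
  }
  do.call(rbind, rows)
}

#' Measure lesions and reference tissue on parametric and SUV images
#'
#' Extracts SUV_max, Ki_max and Vd_max in every lesion VOI and the
#' corresponding means in the liver reference VOI, and forms the three
#' liver-normalized lesion-to-background ratios
#' LBR = lesion_max / liver_mean. Deterministic.
#'
#' @param maps a [fit_patlak_map()] result.
#' @param suv a [static_suv_image()] result.
#' @param vois VOI table as from [phantom_vois()]; must contain exactly one
#'   row tagged \code{"liver"} and any number tagged \code{"lesion"}. An
#'   optional \code{group} column (cancer/inflammatory) is carried through.
#' @param voxel_size isotropic voxel size, mm.
#' @return Data frame of lesion records: \code{lesion_id}, optional
#'   \code{group}, \code{SUV_max}, \code{Ki_max}, \code{Vd_max},
#'   \code{LBR_suv}, \code{LBR_ki}, \code{LBR_vd}.
#' @export
measure_lesions <- function(maps, suv, vois, voxel_size = maps$voxel_size) {
  stopifnot(inherits(maps, "parametric_maps"), inherits(suv, "suv_image"))
  dims <- dim(maps$Ki_map)
  liver_row <- vois[vois$tag == "liver", , drop = FALSE]
  if (nrow(liver_row) != 1) stop("missing liver reference VOI")
  lv <- realize_voi(unlist(liver_row[1, c("cx", "cy", "cz")]),
                    liver_row$volume_cm3[1], voxel_size, dims)
  liver_suv <- voi_stats(suv$volume, lv)[["mean"]]
  liver_ki <- voi_stats(maps$Ki_map, lv)[["mean"]]
  liver_vd <- voi_stats(maps$Vd_map, lv)[["mean"]]
  lesions <- vois[vois$tag == "lesion", , drop = FALSE]
  out <- lapply(seq_len(nrow(lesions)), function(i) {
    v <- realize_voi(unlist(lesions[i, c("cx", "cy", "cz")]),
                     lesions$volume_cm3[i], voxel_size, dims)
    suv_max <- voi_stats(suv$volume, v)[["max"]]
    ki_max <- voi_stats(maps$Ki_map, v)[["max"]]
    vd_max <- voi_stats(maps$Vd_map, v)[["max"]]
    data.frame(lesion_id = lesions$id[i],
               group = if ("group" %in% names(lesions)) lesions$group[i]
                       else NA_character_,
               SUV_max = suv_max, Ki_max = ki_max, Vd_max = vd_max,
               LBR_suv = lesion_to_background(suv_max, liver_suv),
               LBR_ki = lesion_to_background(ki_max, liver_ki),
               LBR_vd = lesion_to_background(vd_max, liver_vd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Measure a synthetic lesion cohort
#'
#' Runs the Patlak fit on every lesion's (and the liver reference's)
#' time-activity curve, converts the simulated static-window activities to
#' SUV, and attaches the three liver-normalized lesion-to-background ratios.
#' For single-curve lesions the VOI maximum and mean coincide, so the curve
#' measurement stands in for both.
#'
#' @param cohort a [generate_cohort()] result.
#' @param Cp plasma input used for the fits; defaults to the cohort's true
#'   analytic input (pass an IDIF estimate to study input-function error).
#' @param t_star Patlak window start, minutes.
#' @param dose injected activity, MBq.
#' @param weight body weight, kg.
#' @return The cohort's record table augmented with \code{SUV_max},
#'   \code{Ki_max}, \code{Vd_max}, \code{LBR_suv}, \code{LBR_ki},
#'   \code{LBR_vd}.
#' @export
measure_cohort <- function(cohort, Cp = NULL, t_star = 20,
                           dose = 210, weight = 75) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (is.null(Cp)) {
    t_end <- max(cohort$schedule$start + cohort$schedule$duration)
    Cp <- plasma_input_from_params(cohort$params,
                                   t_max = max(t_end,
                                               cohort$static_window[2]) + 1,
                                   grid_step = 0.005)
  }
  design <- patlak_design(Cp, cohort$schedule, t_star, average = "frame")
  fit_one <- function(tac) coef(fit_patlak(tac[design$frame], design))
  n <- nrow(cohort$records)
  rec <- cohort$records
  if (n > 0) {
    fits <- t(vapply(seq_len(n), function(i) fit_one(cohort$tacs[i, ]),
                     numeric(2)))
    rec$Ki_max <- fits[, 1]
    rec$Vd_max <- fits[, 2]
    rec$SUV_max <- cohort$static * weight / dose
  } else {
    rec$Ki_max <- rec$Vd_max <- rec$SUV_max <- numeric(0)
  }
  liver_fit <- fit_one(cohort$liver_tac)
  liver_suv <- cohort$liver_static * weight / dose
  rec$LBR_suv <- lesion_to_background(rec$SUV_max, liver_suv)
  rec$LBR_ki <- lesion_to_background(rec$Ki_max, liver_fit[["Ki"]])
  rec$LBR_vd <- lesion_to_background(rec$Vd_max, liver_fit[["Vd"]])
  attr(rec, "liver") <- c(Ki_mean = liver_fit[["Ki"]],
                          Vd_mean = liver_fit[["Vd"]], SUV_mean = liver_suv)
  rec
}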