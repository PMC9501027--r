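#' Frame schedule of a dynamic acquisition
#'
#' A frame schedule holds the start time and duration of every reconstructed
#' frame of a dynamic PET acquisition, in minutes post-injection. Frames must
#' be time-ordered and non-overlapping. An optional per-frame \code{bed_label}
#' distinguishes the early single-bed cardiac segment from later whole-body
#' passes.
#'
#' @param frame_start numeric vector of frame start times (minutes).
#' @param frame_duration numeric vector of frame durations (minutes), all > 0.
#' @param bed_label optional character vector of per-frame tags (recycled).
#'
#' @return An object of class \code{"frame_schedule"}: a data frame with
#'   columns \code{start}, \code{duration}, \code{mid} (frame mid-time) and
#'   \code{bed}.
#' @seealso [make_study_schedule()]
#' @export
frame_schedule <- function(frame_start, frame_duration, bed_label = "frame") {
  stopifnot(length(frame_start) == length(frame_duration),
            length(frame_start) >= 1L)
  if (any(frame_duration <= 0)) stop("all frame durations must be positive")
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  ends <- frame_start + frame_duration
  if (any(ends[-length(ends)] > frame_start[-1] + 1e-9))
    stop("frames must not overlap")
  out <- data.frame(
    start = as.numeric(frame_start),
    duration = as.numeric(frame_duration),
    mid = as.numeric(frame_start + frame_duration / 2),
    bed = rep_len(as.character(bed_label), length(frame_start)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Build the study's dynamic whole-body frame schedule
#'
#' Reproduces the acquisition design of a dynamic whole-body FDG protocol: an
#' early continuous single-bed cardiac segment with a fixed frame ladder
#' (12 x 5 s, 4 x 10 s, 8 x 25 s, then \code{n_early_60s} x 60 s), followed by
#' unidirectional whole-body passes. Only one tracked bed position is
#' represented: each pass contributes a single frame of \code{sec_per_bed}
#' seconds, and consecutive passes are spaced \code{n_beds * sec_per_bed}
#' seconds apart (the even temporal gaps that the unidirectional design
#' guarantees), starting immediately after the cardiac segment.
#'
#' @param n_early_60s number of 60 s frames closing the cardiac segment
#'   (the protocol used 5 +/- 4).
#' @param n_passes number of whole-body passes (the protocol used 11 +/- 3).
#' @param n_beds number of bed positions per pass (the protocol used 5 +/- 1).
#' @param sec_per_bed seconds spent per bed position (default 35 s).
#'
#' @return A [frame_schedule()] with beds labelled \code{"cardiac"} and
#'   \code{"wb"}.
#' @examples
#' sched <- make_study_schedule()
#' range(sched$start + sched$duration)  # early segment ends at 10 min
#' @export
make_study_schedule <- function(n_early_60s = 5, n_passes = 11, n_beds = 5,
                                sec_per_bed = 35) {
  stopifnot(n_early_60s >= 0, n_passes >= 0, n_beds >= 1, sec_per_bed > 0)
  early_sec <- c(rep(5, 12), rep(10, 4), rep(25, 8), rep(60, n_early_60s))
  early_start <- cumsum(c(0, early_sec[-length(early_sec)]))
  t_end <- sum(early_sec)  # seconds
  if (n_passes > 0) {
    wb_start <- t_end + (seq_len(n_passes) - 1) * n_beds * sec_per_bed
    start <- c(early_start, wb_start) / 60
    dur <- c(early_sec, rep(sec_per_bed, n_passes)) / 60
    bed <- c(rep("cardiac", length(early_sec)), rep("wb", n_passes))
  } else {
    start <- early_start / 60
    dur <- early_sec / 60
    bed <- rep("cardiac", length(early_sec))
  }
  frame_schedule(start, dur, bed)
}

#' BMI-adapted FDG dosing
#'
#' Injected activity follows a body-mass-index adapted protocol:
#' 1.5 MBq/kg for BMI < 20, 2 MBq/kg for BMI 20-24.5, 3.1 MBq/kg for
#' BMI > 24.5, never exceeding 320 MBq.
#'
#' @param weight body weight in kg.
#' @param height body height in m.
#' @return Injected activity in MBq.
#' @examples
#' bmi_adapted_dose(55, 1.72)   # 82.5 MBq
#' bmi_adapted_dose(146, 1.86)  # capped at 320 MBq
#' @export
bmi_adapted_dose <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  bmi <- weight / height^2
  per_kg <- ifelse(bmi < 20, 1.5, ifelse(bmi <= 24.5, 2, 3.1))
  pmin(per_kg * weight, 320)
}
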