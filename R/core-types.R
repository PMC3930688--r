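#' Frame schedule of a dynamic PET acquisition
#'
#' Holds per-frame start times and durations in seconds. Frames must be
#' strictly positive in duration, strictly increasing in start time, and
#' non-overlapping. Mid-frame times (the time axis used for all kinetic
#' computations) are derived as `start + dur/2` and reported in minutes.
#'
#' @param start_s numeric vector of frame start times, seconds.
#' @param dur_s numeric vector of frame durations, seconds.
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(start_s, dur_s) {
  start_s <- as.numeric(start_s)
  dur_s <- as.numeric(dur_s)
  if (length(start_s) != length(dur_s))
    stop("frame_schedule: start_s and dur_s must have equal length")
  if (length(start_s) == 0L)
    stop("frame_schedule: at least one frame is required")
  if (any(!is.finite(start_s)) || any(!is.finite(dur_s)))
    stop("frame_schedule: times must be finite")
  if (any(dur_s <= 0))
    stop("frame_schedule: frame durations must be strictly positive")
  if (length(start_s) > 1L && any(diff(start_s) <= 0))
    stop("frame_schedule: frame start times must be strictly increasing")
  if (length(start_s) > 1L &&
      any(start_s[-1L] < (start_s + dur_s)[-length(start_s)] - 1e-9))
    stop("frame_schedule: frames overlap")
  structure(list(start_s = start_s, dur_s = dur_s), class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start_s)

#' Mid-frame times in minutes
#' @param sched a [frame_schedule()].
#' @return numeric vector, minutes.
#' @export
frame_mid_min <- function(sched) {
  stopifnot(inherits(sched, "frame_schedule"))
  (sched$start_s + sched$dur_s / 2) / 60
}

#' End of acquisition in minutes
#' @param sched a [frame_schedule()].
#' @export
scan_end_min <- function(sched) {
  stopifnot(inherits(sched, "frame_schedule"))
  (sched$start_s[length(sched$start_s)] +
     sched$dur_s[length(sched$dur_s)]) / 60
}

#' Default 90-minute frame ladder
#'
#' 8 x 30 s, 6 x 60 s, 5 x 120 s, 14 x 300 s: 33 contiguous frames covering
#' 90 minutes, frames of increasing length from 30 s to 5 min.
#' @return a [frame_schedule()].
#' @export
default_schedule <- function() {
  dur <- c(rep(30, 8), rep(60, 6), rep(120, 5), rep(300, 14))
  frame_schedule(start_s = cumsum(c(0, dur[-length(dur)])), dur_s = dur)
}

#' Time-activity curve
#'
#' @param times numeric, sample times in minutes, strictly increasing.
#' @param values numeric, activity concentration in kBq/mL. Negative values
#'   are allowed (reconstruction noise) and never clipped.
#' @return An object of class `tac`.
#' @export
tac <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("tac: times and values must have equal length")
  if (length(times) == 0L)
    stop("tac: empty curve")
  if (any(!is.finite(times)))
    stop("tac: times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("tac: times must be strictly increasing")
  structure(list(times = times, values = values), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d samples, t = [%.3g, %.3g] min, peak %.4g kBq/mL\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              max(x$values)))
  invisible(x)
}

#' Evaluate a TAC at arbitrary times by linear interpolation
#'
#' Outside the sampled support the nearest sampled value is held constant
#' (this matters for late blood samples drawn just after the last mid-frame
#' time).
#' @param x a [tac()].
#' @param t times in minutes.
#' @return numeric values, kBq/mL.
#' @export
tac_at <- function(x, t) {
  stopifnot(inherits(x, "tac"))
  if (length(x$times) == 1L) return(rep(x$values, length(t)))
  stats::approx(x$times, x$values, xout = t, rule = 2)$y
}

#' Area under a TAC by the trapezoid rule
#'
#' Integration starts from (0, 0) when the first sample is at t > 0: the
#' curve is assumed to rise linearly from zero activity at injection.
#' @param x a [tac()].
#' @param from,to integration limits in minutes; defaults cover the curve.
#' @return numeric, kBq/mL * min.
#' @export
tac_auc <- function(x, from = 0, to = max(x$times)) {
  stopifnot(inherits(x, "tac"))
  tt <- x$times
  vv <- x$values
  if (tt[1] > 0) {
    tt <- c(0, tt)
    vv <- c(0, vv)
  }
  grid <- sort(unique(c(tt, from, to)))
  grid <- grid[grid >= from & grid <= to]
  y <- stats::approx(tt, vv, xout = grid, rule = 2)$y
  if (length(grid) < 2L) return(0)
  sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
}

#' Arterial blood sample set
#'
#' Sparse arterial samples anchoring partial-volume and metabolite
#' correction: whole-blood activity and parent (unmetabolized) fraction at a
#' few times, plus the subject's plasma free fraction f_P.
#'
#' @param times sample times, minutes.
#' @param whole_blood whole-blood activity, kBq/mL.
#' @param parent_fraction unmetabolized parent fraction, in `[0, 1]`.
#' @param f_P plasma free fraction, in `(0, 1]`.
#' @return An object of class `blood_samples`.
#' @export
blood_samples <- function(times, whole_blood, parent_fraction, f_P) {
  times <- as.numeric(times)
  whole_blood <- as.numeric(whole_blood)
  parent_fraction <- as.numeric(parent_fraction)
  n <- length(times)
  if (n < 2L)
    stop("blood_samples: at least 2 samples are required")
  if (length(whole_blood) != n || length(parent_fraction) != n)
    stop("blood_samples: column lengths differ")
  if (any(diff(times) <= 0))
    stop("blood_samples: sample times must be strictly increasing")
  if (any(parent_fraction < 0 | parent_fraction > 1))
    stop("blood_samples: parent_fraction outside [0, 1]")
  if (!is.numeric(f_P) || length(f_P) != 1L || f_P <= 0 || f_P > 1)
    stop("blood_samples: f_P must be a single value in (0, 1]")
  structure(list(times = times, whole_blood = whole_blood,
                 parent_fraction = parent_fraction, f_P = f_P),
            class = "blood_samples")
}

#' Dynamic PET image
#'
#' @param voxels 4D numeric array (x, y, z, frame) of activity concentration
#'   in kBq/mL. Values may be negative (filtered-back-projection noise) and
#'   are never clipped. Decay correction is assumed already applied.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param schedule a [frame_schedule()] whose length matches the frame axis.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, voxel_size_mm, schedule) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop("dynamic_image: voxels must be a 4D array (x, y, z, frame)")
  if (!inherits(schedule, "frame_schedule"))
    stop("dynamic_image: schedule must be a frame_schedule")
  if (dim(voxels)[4] != length(schedule))
    stop(sprintf(
      "dynamic_image: frame axis length %d does not match schedule length %d",
      dim(voxels)[4], length(schedule)))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("dynamic_image: voxel_size_mm must be 3 positive numbers")
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm,
                 schedule = schedule), class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels (%gx%gx%g mm), %d frames, %g min\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3], d[4], scan_end_min(x$schedule)))
  invisible(x)
}

#' Binary mask volume
#'
#' @param indicator 3D logical array.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(indicator) {
  if (!is.array(indicator) || length(dim(indicator)) != 3L)
    stop("mask_volume: indicator must be a 3D array")
  storage.mode(indicator) <- "logical"
  if (anyNA(indicator))
    stop("mask_volume: indicator contains NA")
  structure(list(indicator = indicator), class = "mask_volume")
}

#' @export
sum.mask_volume <- function(x, ..., na.rm = FALSE) sum(x$indicator)

check_same_grid <- function(a_dim, b_dim, what) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s: grid mismatch (%s vs %s)", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
}

#' Region label volume
#'
#' @param labels 3D integer array, 0 = background.
#' @param names optional named character vector or data.frame mapping label
#'   integers to region names.
#' @return An object of class `region_labels`.
#' @export
region_labels <- function(labels, names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("region_labels: labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("region_labels: labels must be nonnegative")
  structure(list(labels = labels, names = names), class = "region_labels")
}

#' Affine spatial transform between template and subject voxel grids
#'
#' A 4x4 matrix acting on homogeneous 0-based voxel coordinates of the
#' template grid, returning subject-grid voxel coordinates. The identity is
#' the default everywhere a transform is accepted.
#' @param matrix 4x4 invertible numeric matrix; default identity.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(4L, 4L)))
    stop("affine_transform: matrix must be 4x4")
  d <- det(matrix)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("affine_transform: matrix is not invertible")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @rdname affine_transform
#' @param xf an `affine_transform`.
#' @export
invert_transform <- function(xf) {
  stopifnot(inherits(xf, "affine_transform"))
  affine_transform(solve(xf$matrix))
}
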