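# Mask construction: gray/white matter masks from probability maps, the
# vascular template (averaged blood-weight image), carotid and surround
# template masks, and nearest-neighbour warping of template masks to a
# subject grid. All literature thresholds ("greater than 0.9", "higher than
# 0.2", "between 0.1 and 0.001") are strict inequalities.

.check_prob <- function(p, what) {
  if (!is.array(p) || length(dim(p)) != 3L)
    stop(sprintf("%s: probability map must be a 3D array", what))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop(sprintf("%s: probabilities outside [0, 1]", what))
}

#' Gray-matter mask from a probability map
#'
#' Voxels with gray-matter probability strictly greater than `threshold`
#' (default 0.9).
#' @param gm_prob 3D probability array in `[0, 1]`.
#' @param threshold strict lower bound, default 0.9.
#' @return a [mask_volume()].
#' @export
gray_matter_mask <- function(gm_prob, threshold = 0.9) {
  .check_prob(gm_prob, "gray_matter_mask")
  mask_volume(gm_prob > threshold)
}

#' White-matter mask excluding gray-matter spill-over
#'
#' A spill map is built by Gaussian-blurring the binary gray-matter mask
#' (probability > 0.5) at the scanner FWHM; with a unit-activity convention
#' the blurred indicator is directly the fraction of an imaginary uniform
#' gray-matter activity reaching each voxel. The white-matter mask keeps
#' voxels with white-matter probability > 0.5 whose spill fraction is below
#' `spill_threshold` (default 0.5%).
#'
#' @param gm_prob,wm_prob 3D probability arrays on one grid.
#' @param voxel_size_mm voxel sizes, mm.
#' @param fwhm_mm blur width, default 7 mm.
#' @param spill_threshold maximum tolerated gray spill fraction, default
#'   0.005.
#' @return a [mask_volume()].
#' @export
white_matter_mask <- function(gm_prob, wm_prob, voxel_size_mm,
                              fwhm_mm = 7, spill_threshold = 0.005) {
  .check_prob(gm_prob, "white_matter_mask")
  .check_prob(wm_prob, "white_matter_mask")
  check_same_grid(dim(gm_prob), dim(wm_prob), "white_matter_mask")
  spill <- apply_psf(array(as.numeric(gm_prob > 0.5), dim(gm_prob)),
                     fwhm_mm, voxel_size_mm)
  mask_volume(wm_prob > 0.5 & spill < spill_threshold)
}

#' Average blood-weight maps into a vascular template
#'
#' Voxel-wise arithmetic mean of the cohort's blood-weight volumes (already
#' mapped to the template grid).
#' @param weight_list list of 3D nonnegative arrays (or `weight_maps`
#'   objects, whose `$blood` volume is used).
#' @return An object of class `vascular_template`: fields `values` (3D
#'   array), `n_subjects`.
#' @export
average_blood_weights <- function(weight_list) {
  if (!length(weight_list)) stop("average_blood_weights: empty cohort")
  vols <- lapply(weight_list, function(w) {
    if (inherits(w, "weight_maps")) w$blood else w
  })
  d <- dim(vols[[1]])
  for (v in vols) check_same_grid(dim(v), d, "average_blood_weights")
  avg <- Reduce(`+`, vols) / length(vols)
  if (any(avg < 0)) stop("average_blood_weights: negative weights")
  structure(list(values = avg, n_subjects = length(vols)),
            class = "vascular_template")
}

#' Carotid template mask from the vascular template
#'
#' Voxels whose averaged blood weight is strictly higher than `threshold`
#' (default 0.2), after removing an optional manual exclusion mask (venous
#' sinuses / noise).
#' @param vt a `vascular_template` (from [average_blood_weights()]).
#' @param exclude optional [mask_volume()] of voxels to drop; default none.
#' @param threshold strict lower bound, default 0.2.
#' @return a [mask_volume()]; warns if empty.
#' @export
carotid_template_mask <- function(vt, exclude = NULL, threshold = 0.2) {
  stopifnot(inherits(vt, "vascular_template"))
  keep <- vt$values > threshold
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "mask_volume"))
    check_same_grid(dim(exclude$indicator), dim(vt$values),
                    "carotid_template_mask")
    keep <- keep & !exclude$indicator
  }
  if (!any(keep))
    warning("carotid_template_mask: no voxel above threshold; empty mask")
  mask_volume(keep)
}

#' Surrounding-tissue template mask
#'
#' The binary carotid mask is Gaussian-blurred at the scanner FWHM and
#' voxels with blurred values strictly between `lo` (0.001) and `hi` (0.1)
#' are kept — a shell around the carotids near enough to share spill-in
#' geometry but far enough to carry little blood signal. Carotid voxels are
#' excluded explicitly so the two masks are disjoint for every geometry
#' (thin vessels can place their own edge voxels inside the band).
#'
#' @param carotid_mask a nonempty [mask_volume()].
#' @param voxel_size_mm voxel sizes, mm.
#' @param fwhm_mm blur width, default 7 mm.
#' @param lo,hi strict band limits, defaults 0.001 and 0.1.
#' @return a [mask_volume()] disjoint from `carotid_mask`.
#' @export
surround_template_mask <- function(carotid_mask, voxel_size_mm,
                                   fwhm_mm = 7, lo = 0.001, hi = 0.1) {
  stopifnot(inherits(carotid_mask, "mask_volume"))
  if (!any(carotid_mask$indicator))
    stop("surround_template_mask: empty carotid mask")
  blurred <- apply_psf(array(as.numeric(carotid_mask$indicator),
                             dim(carotid_mask$indicator)),
                       fwhm_mm, voxel_size_mm)
  mask_volume(blurred > lo & blurred < hi & !carotid_mask$indicator)
}

#' Warp a template-space mask onto a subject grid
#'
#' Nearest-neighbour resampling of the indicator through an affine
#' transform mapping template voxel coordinates (0-based) to subject voxel
#' coordinates. Each subject voxel is pulled back through the inverse
#' transform and sampled from the template mask.
#'
#' @param template_mask a [mask_volume()].
#' @param xf an [affine_transform()] (template -> subject); identity
#'   default.
#' @param subject_dim integer length-3 subject grid dimensions; defaults to
#'   the template grid.
#' @return a [mask_volume()] on the subject grid.
#' @export
warp_mask <- function(template_mask, xf = affine_transform(),
                      subject_dim = dim(template_mask$indicator)) {
  stopifnot(inherits(template_mask, "mask_volume"),
            inherits(xf, "affine_transform"))
  subject_dim <- as.integer(subject_dim)
  inv <- invert_transform(xf)$matrix
  if (identical(unname(inv), diag(4)) &&
      identical(subject_dim, dim(template_mask$indicator)))
    return(mask_volume(template_mask$indicator))
  g <- expand.grid(x = seq_len(subject_dim[1]) - 1L,
                   y = seq_len(subject_dim[2]) - 1L,
                   z = seq_len(subject_dim[3]) - 1L)
  pts <- inv %*% rbind(t(as.matrix(g)), 1)
  src <- round(pts[1:3, , drop = FALSE]) + 1L
  td <- dim(template_mask$indicator)
  ok <- src[1, ] >= 1 & src[1, ] <= td[1] &
    src[2, ] >= 1 & src[2, ] <= td[2] &
    src[3, ] >= 1 & src[3, ] <= td[3]
  out <- logical(prod(subject_dim))
  lin <- src[1, ok] + td[1] * (src[2, ok] - 1L) +
    td[1] * td[2] * (src[3, ok] - 1L)
  out[ok] <- template_mask$indicator[lin]
  mask_volume(array(out, subject_dim))
}
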