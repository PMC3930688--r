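# Synthetic dynamic-PET phantom with full ground truth. The stated world:
# a reduced 64x64x24 grid at the scanner's 2 x 2 x 4.25 mm voxel size, a
# 33-frame / 90-min ladder (30 s rising to 5 min frames), an arterial curve
# with a sharp early peak and tri-exponential washout, a head ellipsoid of
# two-tissue-compartment gray matter with an inner white-matter ellipsoid,
# two thin vertical carotid cylinders embedded in the gray matter, 7 mm
# Gaussian PSF, and additive Gaussian noise whose frame variance scales
# inversely with frame duration (filtered back projection allows negative
# voxels). The three kinetic classes are exactly the three supervised-
# clustering templates; spill-in to the carotids comes from gray and white
# matter.

#' Phantom specification
#'
#' Defaults describe a desk-scale analogue of a clinical 90-min brain
#' acquisition; see the methods vignette for the rationale behind each
#' value. Geometry is in voxel units of the stated grid unless suffixed
#' `_mm`.
#'
#' @param grid_dim integer length-3 grid, default `c(64, 64, 24)`.
#' @param voxel_size_mm default `c(2, 2, 4.25)`.
#' @param schedule a [frame_schedule()], default [default_schedule()].
#' @param carotid_centers two-row matrix of in-plane (x, y) voxel centers;
#'   defaults place the vessels laterally and anteriorly inside gray
#'   matter.
#' @param carotid_radius_mm cylinder radius, default 2.5 mm (>= 1 voxel).
#' @param carotid_z_range inclusive z-slab of the cylinders, default 5:20.
#' @param brain_center,brain_radii_mm,white_radii_mm head / inner-white
#'   ellipsoids (voxel center, mm radii).
#' @param kin_gray,kin_white [kinetic_params()] per tissue.
#' @param input an [input_params()] whole-blood curve model.
#' @param parent_a,parent_lambda monoexponential parent-fraction truth.
#' @param parent_model `"mono"` (default) or `"bi"`: the biexponential
#'   mismatch mode adds a fast-decaying component for robustness tests.
#' @param f_P plasma free fraction truth, default 0.04.
#' @param fwhm_mm scanner PSF, default 7 mm.
#' @param noise fractional noise level, default 0.05: frame f gets additive
#'   Gaussian noise with sd `noise * A_f / sqrt(dur_f_min)` where `A_f` is
#'   the mean noiseless activity over the head in that frame.
#' @param fine_dt_s fine simulation step, default 0.25 s.
#' @param seed RNG seed for the noise draw, default 1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(64L, 64L, 24L),
                         voxel_size_mm = c(2, 2, 4.25),
                         schedule = default_schedule(),
                         carotid_centers = rbind(c(21, 20), c(43, 20)),
                         carotid_radius_mm = 2.5,
                         carotid_z_range = 5:20,
                         brain_center = c(32, 32, 12),
                         brain_radii_mm = c(56, 48, 46),
                         white_radii_mm = c(30, 24, 26),
                         kin_gray = kinetic_params(0.35, 0.12, 0.05, 0.08, 0.05),
                         kin_white = kinetic_params(0.15, 0.09, 0.03, 0.07, 0.03),
                         input = input_params(),
                         parent_a = 0.95, parent_lambda = 0.012,
                         parent_model = c("mono", "bi"),
                         f_P = 0.04,
                         fwhm_mm = 7, noise = 0.05,
                         fine_dt_s = 0.25, seed = 1L) {
  parent_model <- match.arg(parent_model)
  grid_dim <- as.integer(grid_dim)
  if (carotid_radius_mm < min(voxel_size_mm[1:2]) / 2)
    stop("phantom_spec: carotid radius must be at least one voxel")
  if (fwhm_mm < 0 || noise < 0)
    stop("phantom_spec: fwhm_mm and noise must be >= 0")
  if (any(carotid_centers[, 1] < 1) || any(carotid_centers[, 1] > grid_dim[1]) ||
      any(carotid_centers[, 2] < 1) || any(carotid_centers[, 2] > grid_dim[2]) ||
      min(carotid_z_range) < 1 || max(carotid_z_range) > grid_dim[3])
    stop("phantom_spec: carotid cylinder outside grid")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Parent-fraction truth of a phantom spec
#' @param spec a [phantom_spec()].
#' @param t times, minutes.
#' @return fractions in `[0, 1]`.
#' @export
phantom_parent_fraction <- function(spec, t) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$parent_model == "mono") {
    pmin(spec$parent_a * exp(-spec$parent_lambda * t), 1)
  } else {
    # model-mismatch mode: 70/30 split with a 10x faster second component
    pmin(spec$parent_a * (0.7 * exp(-spec$parent_lambda * t) +
                            0.3 * exp(-10 * spec$parent_lambda * t)), 1)
  }
}

.ellipsoid_mask <- function(dim3, voxel, center_vox, radii_mm) {
  cx <- (center_vox - 0.5) * voxel
  x <- ((seq_len(dim3[1]) - 0.5) * voxel[1] - cx[1]) / radii_mm[1]
  y <- ((seq_len(dim3[2]) - 0.5) * voxel[2] - cx[2]) / radii_mm[2]
  z <- ((seq_len(dim3[3]) - 0.5) * voxel[3] - cx[3]) / radii_mm[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

.phantom_masks <- function(spec) {
  d <- spec$grid_dim
  vox <- spec$voxel_size_mm
  brain <- .ellipsoid_mask(d, vox, spec$brain_center, spec$brain_radii_mm)
  white <- .ellipsoid_mask(d, vox, spec$brain_center, spec$white_radii_mm) &
    brain
  xm <- (seq_len(d[1]) - 0.5) * vox[1]
  ym <- (seq_len(d[2]) - 0.5) * vox[2]
  inplane_car <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(nrow(spec$carotid_centers))) {
    cc <- (spec$carotid_centers[r, ] - 0.5) * vox[1:2]
    inplane_car <- inplane_car |
      (outer((xm - cc[1])^2, (ym - cc[2])^2, "+") <=
         spec$carotid_radius_mm^2)
  }
  carotid <- array(FALSE, d)
  for (k in spec$carotid_z_range) carotid[, , k] <- inplane_car
  carotid <- carotid & brain          # vessels live inside the head
  if (!any(carotid))
    stop(".phantom_masks: carotid cylinders fall outside the head")
  gray <- brain & !white & !carotid
  white <- white & !carotid
  list(carotid = mask_volume(carotid), gray = mask_volume(gray),
       white = mask_volume(white), brain = mask_volume(brain))
}

#' Build one synthetic phantom subject
#'
#' Deterministic given the spec (the seed drives only the noise draw). With
#' `fwhm_mm = 0` and `noise = 0`, voxels inside the true carotid mask carry
#' exactly the frame-integrated true whole-blood curve.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [dynamic_image()]) and `truth` (class
#'   `phantom_truth`): true fine and frame-integrated whole-blood and
#'   plasma-parent curves, per-tissue frame TACs, ground-truth masks,
#'   gray/white probability maps, analytic V_T and V_T/f_P, the noiseless
#'   unblurred and noiseless blurred intermediates, and the spec itself.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim
  sched <- spec$schedule
  t_fine <- seq(0, scan_end_min(sched), by = spec$fine_dt_s / 60)
  wb_fine <- input_model(spec$input, t_fine)
  plasma_fine <- tac(t_fine, wb_fine$values *
                       phantom_parent_fraction(spec, t_fine))
  fine <- list(
    gray = simulate_tissue(plasma_fine, spec$kin_gray, wb_fine),
    white = simulate_tissue(plasma_fine, spec$kin_white, wb_fine))
  frames <- lapply(fine, integrate_frames, schedule = sched)
  wb_frames <- integrate_frames(wb_fine, sched)
  plasma_frames <- integrate_frames(plasma_fine, sched)
  masks <- .phantom_masks(spec)
  nf <- length(sched)
  nvox <- prod(d)
  mat <- matrix(0, nvox, nf)
  mat[which(masks$gray$indicator), ] <-
    rep(frames$gray$values, each = sum(masks$gray$indicator))
  mat[which(masks$white$indicator), ] <-
    rep(frames$white$values, each = sum(masks$white$indicator))
  mat[which(masks$carotid$indicator), ] <-
    rep(wb_frames$values, each = sum(masks$carotid$indicator))
  clean <- array(mat, c(d, nf))
  blurred <- clean
  if (spec$fwhm_mm > 0)
    for (f in seq_len(nf))
      blurred[, , , f] <- apply_psf(clean[, , , f], spec$fwhm_mm,
                                    spec$voxel_size_mm)
  noisy <- blurred
  if (spec$noise > 0) {
    set.seed(spec$seed)
    body <- masks$brain$indicator
    a_f <- colMeans(matrix(blurred, ncol = nf)[which(body), , drop = FALSE])
    sd_f <- spec$noise * a_f / sqrt(sched$dur_s / 60)
    eps <- matrix(stats::rnorm(nvox * nf), nvox, nf)
    eps <- sweep(eps, 2, sd_f, "*")
    noisy <- array(matrix(blurred, ncol = nf) + eps, c(d, nf))
  }
  gm_prob <- array(0, d)
  gm_prob[masks$gray$indicator] <- 0.99
  gm_prob[masks$white$indicator] <- 0.005
  wm_prob <- array(0, d)
  wm_prob[masks$white$indicator] <- 0.99
  wm_prob[masks$gray$indicator] <- 0.005
  truth <- structure(list(
    wb_fine = wb_fine, wb_frames = wb_frames,
    plasma_fine = plasma_fine, plasma_frames = plasma_frames,
    tissue_frames = frames, tissue_fine = fine,
    masks = masks, gm_prob = gm_prob, wm_prob = wm_prob,
    vt = list(gray = analytic_vt(spec$kin_gray),
              white = analytic_vt(spec$kin_white)),
    vt_fp = list(gray = analytic_vt(spec$kin_gray) / spec$f_P,
                 white = analytic_vt(spec$kin_white) / spec$f_P),
    f_P = spec$f_P,
    clean_image = dynamic_image(clean, spec$voxel_size_mm, sched),
    blurred_image = dynamic_image(blurred, spec$voxel_size_mm, sched),
    spec = spec), class = "phantom_truth")
  list(image = dynamic_image(noisy, spec$voxel_size_mm, sched),
       truth = truth)
}

#' Draw arterial blood samples from the phantom truth
#'
#' Instantaneous true whole-blood values and parent fractions at the
#' requested times (the clinical protocol samples at 6, 20, 60 and 90 min),
#' with the true f_P.
#' @param truth a `phantom_truth`.
#' @param times sample times, minutes.
#' @return a [blood_samples()].
#' @export
sample_blood <- function(truth, times = c(6, 20, 60, 90)) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  blood_samples(times,
                input_model(spec$input, times)$values,
                phantom_parent_fraction(spec, times),
                spec$f_P)
}

#' Build a jittered phantom cohort
#'
#' `n` subjects whose carotid position (integer voxel shifts), carotid
#' radius, kinetic parameters, input-curve amplitude/peak time and
#' parent-fraction parameters are jittered around the base spec, all
#' reproducibly from one seed.
#'
#' @param base_spec a [phantom_spec()].
#' @param n number of subjects.
#' @param seed cohort seed; subject i uses noise seed `seed * 1000 + i`.
#' @return list of `n` results of [build_phantom()].
#' @export
build_phantom_cohort <- function(base_spec, n, seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"), n >= 1L)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    jit <- function(x, sd_) x * exp(stats::rnorm(1, 0, sd_))
    kin_j <- function(kp) kinetic_params(
      jit(kp$K1, 0.08), jit(kp$k2, 0.08),
      if (kp$k3 > 0) jit(kp$k3, 0.08) else 0,
      if (kp$k4 > 0) jit(kp$k4, 0.08) else 0,
      min(jit(kp$vb, 0.08), 0.2))
    centers <- base_spec$carotid_centers +
      matrix(sample(-1:1, 4, replace = TRUE), 2, 2)
    sp <- phantom_spec(
      grid_dim = base_spec$grid_dim,
      voxel_size_mm = base_spec$voxel_size_mm,
      schedule = base_spec$schedule,
      carotid_centers = centers,
      carotid_radius_mm = base_spec$carotid_radius_mm *
        stats::runif(1, 0.9, 1.1),
      carotid_z_range = base_spec$carotid_z_range,
      brain_center = base_spec$brain_center,
      brain_radii_mm = base_spec$brain_radii_mm,
      white_radii_mm = base_spec$white_radii_mm,
      kin_gray = kin_j(base_spec$kin_gray),
      kin_white = kin_j(base_spec$kin_white),
      input = input_params(peak = base_spec$input$peak *
                             stats::runif(1, 0.85, 1.15),
                           t_peak = base_spec$input$t_peak *
                             stats::runif(1, 0.9, 1.1),
                           frac = base_spec$input$frac,
                           lambda = base_spec$input$lambda),
      parent_a = min(base_spec$parent_a * stats::runif(1, 0.95, 1.03), 1),
      parent_lambda = base_spec$parent_lambda * stats::runif(1, 0.8, 1.2),
      parent_model = base_spec$parent_model,
      f_P = base_spec$f_P,
      fwhm_mm = base_spec$fwhm_mm, noise = base_spec$noise,
      fine_dt_s = base_spec$fine_dt_s,
      seed = seed * 1000L + i)
    build_phantom(sp)
  })
}
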