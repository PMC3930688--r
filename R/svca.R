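# Supervised clustering: per-frame activity standardization, construction of
# the three tissue template curves from a template cohort, and voxel-wise
# NNLS weighting of each voxel's standardized curve against the templates.

#' Field-of-view mask from mean activity
#'
#' Voxels whose time-averaged activity exceeds a fraction of the maximum
#' time-averaged activity. Used as the default statistics/analysis mask so
#' empty air does not dominate the per-frame mean and standard deviation.
#'
#' @param img a [dynamic_image()].
#' @param frac fraction of the maximum mean activity, default 0.05.
#' @return a [mask_volume()].
#' @export
fov_mask <- function(img, frac = 0.05) {
  stopifnot(inherits(img, "dynamic_image"))
  mean_vol <- rowMeans(matrix(img$voxels, ncol = dim(img$voxels)[4]))
  dim(mean_vol) <- dim(img$voxels)[1:3]
  mask_volume(mean_vol > frac * max(mean_vol))
}

#' Standardize each frame to zero mean, unit variance
#'
#' Per frame, the mean and sample standard deviation (ddof = 1) are computed
#' over `stats_mask` and the whole frame is transformed with those
#' statistics, so voxels outside the mask are standardized consistently.
#'
#' @param img a [dynamic_image()].
#' @param stats_mask a nonempty [mask_volume()]; default [fov_mask()].
#' @return An object of class `standardized_image` with fields `voxels`
#'   (4D z-score array), `stats_mask`, `schedule`, `frame_mean`, `frame_sd`.
#' @export
standardize_frames <- function(img, stats_mask = fov_mask(img)) {
  stopifnot(inherits(img, "dynamic_image"), inherits(stats_mask, "mask_volume"))
  d <- dim(img$voxels)
  check_same_grid(d[1:3], dim(stats_mask$indicator), "standardize_frames")
  idx <- which(stats_mask$indicator)
  if (length(idx) < 2L)
    stop("standardize_frames: stats_mask must contain at least 2 voxels")
  nf <- d[4]
  mat <- matrix(img$voxels, ncol = nf)
  sub <- mat[idx, , drop = FALSE]
  mu <- colMeans(sub)
  sd_ <- sqrt(colSums((sub - rep(mu, each = length(idx)))^2) /
                (length(idx) - 1))
  bad <- which(sd_ <= 0)
  if (length(bad))
    stop(sprintf(
      "standardize_frames: zero within-mask variance in frame(s) %s",
      paste(bad, collapse = ", ")))
  z <- sweep(sweep(mat, 2, mu, "-"), 2, sd_, "/")
  dim(z) <- d
  structure(list(voxels = z, stats_mask = stats_mask, schedule = img$schedule,
                 frame_mean = mu, frame_sd = sd_),
            class = "standardized_image")
}

#' Mean standardized TAC over a mask
#' @param std a `standardized_image`.
#' @param mask a nonempty [mask_volume()].
#' @return numeric vector, one standardized value per frame.
#' @export
mask_mean_curve <- function(std, mask) {
  stopifnot(inherits(std, "standardized_image"), inherits(mask, "mask_volume"))
  d <- dim(std$voxels)
  check_same_grid(d[1:3], dim(mask$indicator), "mask_mean_curve")
  idx <- which(mask$indicator)
  if (!length(idx)) stop("mask_mean_curve: empty mask")
  colMeans(matrix(std$voxels, ncol = d[4])[idx, , drop = FALSE])
}

#' Build the three tissue template curves from a template cohort
#'
#' Per subject, the mean standardized curve is taken over that subject's
#' gray-matter, white-matter and blood (carotid) masks; the template for
#' each tissue is the across-subject mean of those curves.
#'
#' @param cohort list of subjects; each a list with elements `std`
#'   (`standardized_image`), `gray`, `white`, `blood` ([mask_volume()]s).
#' @return An object of class `tissue_templates`: fields `gray`, `white`,
#'   `blood` (numeric per-frame curves), `schedule`, `n_subjects`.
#' @export
build_template_tacs <- function(cohort) {
  if (!length(cohort)) stop("build_template_tacs: empty cohort")
  sched <- cohort[[1]]$std$schedule
  curves <- lapply(cohort, function(s) {
    if (length(s$std$schedule) != length(sched) ||
        max(abs(s$std$schedule$start_s - sched$start_s)) > 1e-9 ||
        max(abs(s$std$schedule$dur_s - sched$dur_s)) > 1e-9)
      stop("build_template_tacs: subjects must share one frame schedule")
    vapply(list(s$gray, s$white, s$blood),
           function(m) mask_mean_curve(s$std, m),
           numeric(length(sched)))
  })
  avg <- Reduce(`+`, curves) / length(curves)
  tmpl <- structure(list(gray = avg[, 1], white = avg[, 2], blood = avg[, 3],
                         schedule = sched, n_subjects = length(cohort)),
                    class = "tissue_templates")
  .check_templates(tmpl)
  tmpl
}

.template_matrix <- function(templates) {
  cbind(gray = templates$gray, white = templates$white,
        blood = templates$blood)
}

.check_templates <- function(templates) {
  T <- .template_matrix(templates)
  if (any(!is.finite(T)))
    stop("tissue_templates: non-finite template values")
  if (qr(T)$rank < 3L)
    stop("tissue_templates: template curves are linearly dependent")
  invisible(templates)
}

#' Read / write template curves as TSV
#'
#' Four columns: `frame_mid_min`, `gray`, `white`, `blood`; frame durations
#' in a fifth column `frame_dur_s` so the schedule round-trips.
#' @param templates a `tissue_templates`.
#' @param path TSV path.
#' @export
write_templates <- function(templates, path) {
  stopifnot(inherits(templates, "tissue_templates"))
  .write_tsv(data.frame(frame_mid_min = frame_mid_min(templates$schedule),
                        gray = templates$gray, white = templates$white,
                        blood = templates$blood,
                        frame_dur_s = templates$schedule$dur_s), path)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  need <- c("frame_mid_min", "gray", "white", "blood", "frame_dur_s")
  if (!all(need %in% names(df)))
    stop(sprintf("read_templates: %s lacks columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  start_s <- df$frame_mid_min * 60 - df$frame_dur_s / 2
  tmpl <- structure(list(gray = df$gray, white = df$white, blood = df$blood,
                         schedule = frame_schedule(start_s, df$frame_dur_s),
                         n_subjects = NA_integer_),
                    class = "tissue_templates")
  .check_templates(tmpl)
  tmpl
}

#' Voxel-wise NNLS tissue weights
#'
#' For each voxel in the analysis mask, solves
#' `w(v) = argmin_{w >= 0} || y_v - T w ||^2` where `y_v` is the voxel's
#' standardized curve and `T` the frame x 3 template matrix. The weights
#' quantify similarity to each tissue class; they are deliberately not
#' normalized to sum to one (their amplitude is reused when averaging
#' carotid voxels). Voxels outside the mask get zero weights.
#'
#' @param std a `standardized_image`.
#' @param templates a `tissue_templates` on the same schedule.
#' @param analysis_mask a [mask_volume()]; default the standardization mask.
#' @return An object of class `weight_maps`: 3D arrays `gray`, `white`,
#'   `blood`, plus `rss` (per-voxel residual sum of squares).
#' @export
solve_weights <- function(std, templates, analysis_mask = std$stats_mask) {
  stopifnot(inherits(std, "standardized_image"),
            inherits(templates, "tissue_templates"),
            inherits(analysis_mask, "mask_volume"))
  .check_templates(templates)
  d <- dim(std$voxels)
  check_same_grid(d[1:3], dim(analysis_mask$indicator), "solve_weights")
  if (length(templates$schedule) != d[4])
    stop("solve_weights: template frame count does not match image")
  idx <- which(analysis_mask$indicator)
  if (!length(idx)) stop("solve_weights: empty analysis mask")
  Y <- t(matrix(std$voxels, ncol = d[4])[idx, , drop = FALSE])  # frames x m
  fit <- nnls_multi(.template_matrix(templates), Y)
  zero <- array(0, d[1:3])
  maps <- list(gray = zero, white = zero, blood = zero, rss = zero)
  maps$gray[idx] <- fit$coef[1, ]
  maps$white[idx] <- fit$coef[2, ]
  maps$blood[idx] <- fit$coef[3, ]
  maps$rss[idx] <- fit$rss
  structure(maps, class = "weight_maps")
}

#' Relative blood-weight fraction of a weight_maps object
#'
#' `w_blood / (w_gray + w_white + w_blood)`, 0 where the total weight is 0.
#' @param weights a `weight_maps`.
#' @return 3D array in `[0, 1]`.
#' @export
blood_fraction <- function(weights) {
  stopifnot(inherits(weights, "weight_maps"))
  tot <- weights$gray + weights$white + weights$blood
  out <- array(0, dim(tot))
  nz <- tot > 0
  out[nz] <- weights$blood[nz] / tot[nz]
  out
}
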