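# End-to-end pipeline: template construction from a template cohort,
# supervised-clustering weights, carotid/surround template masks, per-subject
# input-function derivation and Logan quantification, driven by a JSON
# config and writing all intermediates plus a JSON run report.

#' Pipeline configuration
#'
#' All tunable thresholds of the method with their literature defaults:
#' carotid template threshold 0.2, surround band (0.001, 0.1), gray-matter
#' probability 0.9, white-matter spill 0.005, carotid blood-fraction 0.5,
#' surround blood cutoff 0.001, PSF FWHM 7 mm, Logan t* 30 min.
#'
#' @param template_subjects list of template subjects; each a list of paths
#'   `pet`, `timing`, `gm_prob`, `wm_prob`, `carotid_mask`.
#' @param subjects list of analysis subjects; each a list with `id` and
#'   paths `pet`, `timing`, `blood`, plus optional `gm_prob` (defines the
#'   gray-matter region for Logan) and optional `labels` volume.
#' @param out_dir output directory.
#' @param carotid_threshold,surround_lo,surround_hi,gray_threshold,
#'   wm_spill_threshold,fraction_threshold,blood_cutoff,fwhm_mm,t_star
#'   method thresholds; defaults as above.
#' @param seed integer seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(template_subjects, subjects, out_dir,
                            carotid_threshold = 0.2, surround_lo = 0.001,
                            surround_hi = 0.1, gray_threshold = 0.9,
                            wm_spill_threshold = 0.005,
                            fraction_threshold = 0.5, blood_cutoff = 0.001,
                            fwhm_mm = 7, t_star = 30, seed = 1L) {
  th <- c(carotid_threshold, surround_lo, surround_hi, gray_threshold,
          wm_spill_threshold, fraction_threshold, blood_cutoff)
  if (any(th <= 0 | th >= 1))
    stop("pipeline_config: thresholds must lie in (0, 1)")
  if (surround_lo >= surround_hi)
    stop("pipeline_config: surround_lo must be < surround_hi")
  if (fwhm_mm < 0 || t_star <= 0)
    stop("pipeline_config: fwhm_mm >= 0 and t_star > 0 required")
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(pipeline_config, x)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.load_subject_image <- function(s, stage) {
  .stage(stage, {
    if (!file.exists(s$pet))
      stop(sprintf("missing PET image: %s", s$pet))
    timing <- if (!is.null(s$timing)) s$timing else default_timing_path(s$pet)
    read_dynamic_image(s$pet, timing)
  })
}

#' Run the full cluster-IDIF pipeline
#'
#' Template stage: standardize each template subject, build the three
#' tissue template curves (gray mask from the probability map at the 0.9
#' threshold, white mask with the spill-over rule, carotid mask supplied —
#' the manually-drawn early-frame step), compute each template subject's
#' blood-weight map, average into the vascular template and derive the
#' carotid and surround template masks. Subject stage: standardize, solve
#' weights, map the template masks to the subject grid (identity transform
#' unless supplied), derive the corrected input function and run Logan on
#' the subject's gray-matter (or labelled) regions. Deterministic: the same
#' config produces bit-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param transform an [affine_transform()] from template to subject voxel
#'   grid; identity default.
#' @return list with `templates`, `carotid_mask`, `surround_mask`,
#'   `results` (data.frame: subject, region, VT, VT_fP, R2, n_points, RC,
#'   SP, n_carotid_voxels) and `report` (per-subject diagnostics); all
#'   artifacts are also written under `config$out_dir`.
#' @export
run_pipeline <- function(config, transform = affine_transform()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tmpl_data <- lapply(seq_along(config$template_subjects), function(i) {
    s <- config$template_subjects[[i]]
    stage <- sprintf("template_subject_%d", i)
    img <- .load_subject_image(s, stage)
    .stage(stage, {
      std <- standardize_frames(img)
      gm_prob <- read_nifti(s$gm_prob)$data
      wm_prob <- read_nifti(s$wm_prob)$data
      list(std = std,
           gray = gray_matter_mask(gm_prob, config$gray_threshold),
           white = white_matter_mask(gm_prob, wm_prob, img$voxel_size_mm,
                                     config$fwhm_mm,
                                     config$wm_spill_threshold),
           blood = read_mask(s$carotid_mask),
           voxel_size_mm = img$voxel_size_mm)
    })
  })
  templates <- .stage("build_templates", build_template_tacs(tmpl_data))
  vox_mm <- tmpl_data[[1]]$voxel_size_mm
  blood_weights <- .stage("template_weights", lapply(tmpl_data, function(td) {
    solve_weights(td$std, templates)
  }))
  vt <- .stage("vascular_template", average_blood_weights(blood_weights))
  carotid_tmpl <- .stage("carotid_mask",
                         carotid_template_mask(vt, threshold = config$carotid_threshold))
  surround_tmpl <- .stage("surround_mask",
                          surround_template_mask(carotid_tmpl, vox_mm,
                                                 config$fwhm_mm,
                                                 config$surround_lo,
                                                 config$surround_hi))
  write_templates(templates, file.path(config$out_dir, "templates.tsv"))
  write_mask(carotid_tmpl, file.path(config$out_dir, "carotid_mask.nii"),
             pixdim = vox_mm)
  write_mask(surround_tmpl, file.path(config$out_dir, "surround_mask.nii"),
             pixdim = vox_mm)
  rows <- list()
  report <- list()
  for (s in config$subjects) {
    stage <- sprintf("subject_%s", s$id)
    img <- .load_subject_image(s, stage)
    res <- .stage(stage, {
      if (!file.exists(s$blood))
        stop(sprintf("missing blood sample TSV: %s", s$blood))
      blood <- read_blood_samples(s$blood)
      std <- standardize_frames(img)
      weights <- solve_weights(std, templates)
      caro <- warp_mask(carotid_tmpl, transform, dim(img$voxels)[1:3])
      surr <- warp_mask(surround_tmpl, transform, dim(img$voxels)[1:3])
      deriv <- derive_input_function(img, caro, surr, weights, blood,
                                     config$fraction_threshold,
                                     config$blood_cutoff)
      write_tac(deriv$plasma_tac,
                file.path(config$out_dir,
                          sprintf("%s_input_function.tsv", s$id)))
      regions <- if (!is.null(s$labels)) {
        nii <- read_nifti(s$labels)
        region_labels(array(as.integer(nii$data), dim = nii$dim))
      } else {
        gm <- gray_matter_mask(read_nifti(s$gm_prob)$data,
                               config$gray_threshold)
        region_labels(array(as.integer(gm$indicator),
                            dim = dim(gm$indicator)),
                      names = c("1" = "gray_matter"))
      }
      tacs <- regional_tacs(img, regions)
      lrs <- lapply(tacs, logan_vt, input_fn = deriv$input_fn,
                    t_star = config$t_star, f_P = blood$f_P)
      list(deriv = deriv, lrs = lrs)
    })
    for (rn in names(res$lrs)) {
      lr <- res$lrs[[rn]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, region = rn, VT = lr$VT, VT_fP = lr$VT_fP,
        R2 = lr$r_squared, n_points = lr$n_points,
        RC = res$deriv$pvc$RC, SP = res$deriv$pvc$SP,
        n_carotid_voxels = attr(res$deriv$carotid, "n_voxels"))
    }
    report[[s$id]] <- list(
      RC = res$deriv$pvc$RC, SP = res$deriv$pvc$SP,
      pvc_residual = res$deriv$pvc$residual_norm,
      parent_a = res$deriv$parent_fit$a,
      parent_lambda = res$deriv$parent_fit$lambda,
      triexp_rmse = res$deriv$input_fn$rmse,
      n_carotid_voxels = attr(res$deriv$carotid, "n_voxels"),
      n_surround_voxels = attr(res$deriv$surround, "n_voxels"))
  }
  results <- do.call(rbind, rows)
  .write_tsv(results, file.path(config$out_dir, "results.tsv"))
  jsonlite::write_json(
    list(seed = config$seed,
         thresholds = unclass(config)[setdiff(names(config),
                                              c("template_subjects",
                                                "subjects", "out_dir"))],
         subjects = report),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(templates = templates, carotid_mask = carotid_tmpl,
       surround_mask = surround_tmpl, results = results, report = report)
}

#' Write a phantom cohort to disk in the pipeline's file formats
#'
#' One directory per subject: `pet.nii` + timing sidecar, `gm_prob.nii`,
#' `wm_prob.nii`, `carotid_mask.nii` (truth), `blood.tsv` (samples at 6,
#' 20, 60, 90 min) and `truth.tsv` (true V_T/f_P per tissue).
#'
#' @param cohort result of [build_phantom_cohort()].
#' @param dir output directory.
#' @return character vector of subject directories, invisibly.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(cohort), function(i) {
    sd_ <- file.path(dir, sprintf("sub%02d", i))
    dir.create(sd_, showWarnings = FALSE)
    ph <- cohort[[i]]
    vox <- ph$image$voxel_size_mm
    write_dynamic_image(ph$image, file.path(sd_, "pet.nii"))
    write_nifti(ph$truth$gm_prob, file.path(sd_, "gm_prob.nii"), vox)
    write_nifti(ph$truth$wm_prob, file.path(sd_, "wm_prob.nii"), vox)
    write_mask(ph$truth$masks$carotid, file.path(sd_, "carotid_mask.nii"),
               vox)
    write_blood_samples(sample_blood(ph$truth), file.path(sd_, "blood.tsv"))
    .write_tsv(data.frame(tissue = c("gray", "white"),
                          VT = c(ph$truth$vt$gray, ph$truth$vt$white),
                          VT_fP = c(ph$truth$vt_fp$gray,
                                    ph$truth$vt_fp$white)),
               file.path(sd_, "truth.tsv"))
    sd_
  }, character(1))
  invisible(paths)
}
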