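# Readers and writers for the pipeline's file formats: NIfTI-1 volumes,
# TSV frame-timing sidecars (frame_start_s, frame_dur_s), two-column TAC
# TSVs, and blood-sample TSVs with an f_P header line.

#' Read a 4D dynamic PET image with its frame-timing sidecar
#'
#' @param image_path NIfTI path (`.nii` / `.nii.gz`), 4D.
#' @param timing_path TSV sidecar with columns `frame_start_s`, `frame_dur_s`
#'   and one row per frame.
#' @return a [dynamic_image()].
#' @export
read_dynamic_image <- function(image_path, timing_path) {
  nii <- read_nifti(image_path)
  if (length(nii$dim) != 4L)
    stop(sprintf("read_dynamic_image: %s is not 4D", image_path))
  tm <- utils::read.delim(timing_path, sep = "\t", check.names = FALSE)
  need <- c("frame_start_s", "frame_dur_s")
  if (!all(need %in% names(tm)))
    stop(sprintf("read_dynamic_image: %s lacks columns %s", timing_path,
                 paste(need, collapse = ", ")))
  if (nrow(tm) != nii$dim[4])
    stop(sprintf(
      "read_dynamic_image: %d timing rows for %d frames", nrow(tm),
      nii$dim[4]))
  dynamic_image(nii$data, voxel_size_mm = nii$pixdim,
                schedule = frame_schedule(tm$frame_start_s, tm$frame_dur_s))
}

#' Write a 4D dynamic PET image and its frame-timing sidecar
#'
#' Voxel data are stored as float64, so [read_dynamic_image()] inverts this
#' bit-exactly; schedule times are printed with 12 significant digits.
#' @param img a [dynamic_image()].
#' @param image_path output NIfTI path.
#' @param timing_path output TSV path; defaults to `image_path` with the
#'   NIfTI extension replaced by `_timing.tsv`.
#' @return `image_path`, invisibly.
#' @export
write_dynamic_image <- function(img, image_path,
                                timing_path = default_timing_path(image_path)) {
  stopifnot(inherits(img, "dynamic_image"))
  write_nifti(img$voxels, image_path, pixdim = img$voxel_size_mm,
              datatype = "float64")
  df <- data.frame(frame_start_s = img$schedule$start_s,
                   frame_dur_s = img$schedule$dur_s)
  .write_tsv(df, timing_path)
  invisible(image_path)
}

#' @rdname write_dynamic_image
#' @export
default_timing_path <- function(image_path) {
  sub("\\.nii(\\.gz)?$", "_timing.tsv", image_path)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read arterial blood samples from TSV
#'
#' The file carries a header comment line `# f_P <value>` followed by a
#' tab-separated table with columns `time_min`, `whole_blood_kBq_mL`,
#' `parent_fraction`.
#' @param path TSV path.
#' @return a [blood_samples()].
#' @export
read_blood_samples <- function(path) {
  lines <- readLines(path)
  fp_line <- grep("^#\\s*f_P\\b", lines, value = TRUE)
  if (length(fp_line) != 1L)
    stop(sprintf("read_blood_samples: %s needs one '# f_P <value>' line", path))
  f_P <- as.numeric(sub("^#\\s*f_P\\s+", "", fp_line))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t")
  need <- c("time_min", "whole_blood_kBq_mL", "parent_fraction")
  if (!all(need %in% names(df)))
    stop(sprintf("read_blood_samples: %s lacks columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  blood_samples(df$time_min, df$whole_blood_kBq_mL, df$parent_fraction, f_P)
}

#' Write arterial blood samples to TSV
#' @param blood a [blood_samples()].
#' @param path output path.
#' @export
write_blood_samples <- function(blood, path) {
  stopifnot(inherits(blood, "blood_samples"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# f_P %.12g", blood$f_P), con)
  df <- data.frame(time_min = sprintf("%.12g", blood$times),
                   whole_blood_kBq_mL = sprintf("%.12g", blood$whole_blood),
                   parent_fraction = sprintf("%.12g", blood$parent_fraction))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a time-activity curve as two-column TSV
#'
#' Columns `time_min`, `kBq_mL`; lossless round trip at 12 significant
#' digits.
#' @param path TSV path.
#' @return a [tac()].
#' @export
read_tac <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  if (nrow(df) == 0L)
    stop(sprintf("read_tac: %s is empty", path))
  if (!all(c("time_min", "kBq_mL") %in% names(df)))
    stop(sprintf("read_tac: %s lacks columns time_min, kBq_mL", path))
  tac(df$time_min, df$kBq_mL)
}

#' @rdname read_tac
#' @param x a [tac()].
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  .write_tsv(data.frame(time_min = x$times, kBq_mL = x$values), path)
  invisible(path)
}

#' Read / write a mask volume as NIfTI (uint8)
#' @param path NIfTI path.
#' @return a [mask_volume()].
#' @export
read_mask <- function(path) {
  nii <- read_nifti(path)
  if (length(nii$dim) != 3L)
    stop(sprintf("read_mask: %s is not 3D", path))
  mask_volume(array(nii$data != 0, dim = nii$dim))
}

#' @rdname read_mask
#' @param mask a [mask_volume()].
#' @param pixdim voxel sizes, mm.
#' @export
write_mask <- function(mask, path, pixdim = c(1, 1, 1)) {
  stopifnot(inherits(mask, "mask_volume"))
  write_nifti(array(as.integer(mask$indicator), dim = dim(mask$indicator)),
              path, pixdim = pixdim, datatype = "uint8")
  invisible(path)
}
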