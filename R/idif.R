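# Image-derived input function: carotid and surround TAC extraction from
# the weight maps, partial-volume / spill-in correction against sparse
# arterial samples (Chen-style linear model
# C_carotid(t) = RC * C_wb(t) + SP * C_surround(t)), monoexponential
# metabolite correction, and the final tri-exponential input-function fit.

#' Weighted carotid time-activity curve
#'
#' Within the carotid mask, voxels whose relative blood-weight fraction
#' `w_blood / (w_gray + w_white + w_blood)` exceeds `fraction_threshold`
#' (default 0.5: blood weight outweighs the other two classes combined) are
#' selected; the curve is their blood-weight-weighted average at mid-frame
#' times.
#'
#' @param img a [dynamic_image()].
#' @param carotid_mask a nonempty [mask_volume()] on the image grid.
#' @param weights a `weight_maps` on the image grid.
#' @param fraction_threshold strict selection threshold, default 0.5.
#' @return a [tac()]; attribute `n_voxels` records the selection size.
#' @export
extract_carotid_tac <- function(img, carotid_mask, weights,
                                fraction_threshold = 0.5) {
  stopifnot(inherits(img, "dynamic_image"),
            inherits(carotid_mask, "mask_volume"),
            inherits(weights, "weight_maps"))
  d <- dim(img$voxels)
  check_same_grid(d[1:3], dim(carotid_mask$indicator), "extract_carotid_tac")
  check_same_grid(d[1:3], dim(weights$blood), "extract_carotid_tac")
  frac <- blood_fraction(weights)
  sel <- which(carotid_mask$indicator & frac > fraction_threshold)
  if (!length(sel))
    stop(paste("extract_carotid_tac: no carotid voxel passes the blood-",
               "fraction threshold; inspect the weight maps / thresholds",
               sep = ""))
  w <- weights$blood[sel]
  if (sum(w) <= 0)
    stop("extract_carotid_tac: selected voxels have zero total blood weight")
  mat <- matrix(img$voxels, ncol = d[4])[sel, , drop = FALSE]
  vals <- as.numeric(crossprod(mat, w)) / sum(w)
  out <- tac(frame_mid_min(img$schedule), vals)
  attr(out, "n_voxels") <- length(sel)
  out
}

#' Unweighted surrounding-tissue time-activity curve
#'
#' Within the surround mask, only voxels with relative blood-weight
#' fraction strictly below `blood_cutoff` (default 0.001, i.e. less than
#' 0.1% blood) enter an unweighted average.
#'
#' @inheritParams extract_carotid_tac
#' @param surround_mask a nonempty [mask_volume()].
#' @param blood_cutoff strict upper bound on the blood fraction, default
#'   0.001.
#' @return a [tac()]; attribute `n_voxels` records the selection size.
#' @export
extract_surround_tac <- function(img, surround_mask, weights,
                                 blood_cutoff = 0.001) {
  stopifnot(inherits(img, "dynamic_image"),
            inherits(surround_mask, "mask_volume"),
            inherits(weights, "weight_maps"))
  d <- dim(img$voxels)
  check_same_grid(d[1:3], dim(surround_mask$indicator), "extract_surround_tac")
  frac <- blood_fraction(weights)
  sel <- which(surround_mask$indicator & frac < blood_cutoff)
  if (!length(sel))
    stop("extract_surround_tac: no surround voxel below the blood cutoff")
  mat <- matrix(img$voxels, ncol = d[4])[sel, , drop = FALSE]
  out <- tac(frame_mid_min(img$schedule), colMeans(mat))
  attr(out, "n_voxels") <- length(sel)
  out
}

#' Fit recovery and spill-in coefficients against blood samples
#'
#' Ordinary least squares of `C_carotid(t_i) = RC * C_wb(t_i) +
#' SP * C_surround(t_i)` over the blood-sample times (2-4 points, two
#' unknowns). TAC values at sample times come from linear interpolation of
#' the mid-frame curves (held constant beyond the last mid-frame time).
#' A negative SP is flagged with a warning, not an error.
#'
#' @param carotid,surround [tac()]s at mid-frame times.
#' @param blood a [blood_samples()].
#' @return An object of class `pvc_coefficients`: `RC`, `SP`,
#'   `residual_norm`, `n_samples`.
#' @export
fit_pvc <- function(carotid, surround, blood) {
  stopifnot(inherits(carotid, "tac"), inherits(surround, "tac"),
            inherits(blood, "blood_samples"))
  t_i <- blood$times
  X <- cbind(wb = blood$whole_blood, surround = tac_at(surround, t_i))
  y <- tac_at(carotid, t_i)
  if (qr(X)$rank < 2L)
    stop(paste("fit_pvc: whole-blood and surround curves are collinear at",
               "the sample times"))
  cf <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% cf
  RC <- cf[1]
  SP <- cf[2]
  if (RC <= 0)
    stop(sprintf("fit_pvc: nonpositive recovery coefficient (RC = %.4g)", RC))
  if (SP < -1e-10)
    warning(sprintf("fit_pvc: negative spill-in coefficient (SP = %.4g)", SP))
  structure(list(RC = RC, SP = SP, residual_norm = sqrt(sum(res^2)),
                 n_samples = length(t_i)),
            class = "pvc_coefficients")
}

#' Partial-volume and spill-in correction of the carotid curve
#'
#' Inverts the Chen model at every mid-frame time:
#' `C_wb_IDIF(t) = (C_carotid(t) - SP * C_surround(t)) / RC`.
#'
#' @param carotid,surround [tac()]s on one time grid.
#' @param coefs a `pvc_coefficients` with `RC > 0`.
#' @return whole-blood IDIF as a [tac()].
#' @export
correct_pvc <- function(carotid, surround, coefs) {
  stopifnot(inherits(carotid, "tac"), inherits(surround, "tac"),
            inherits(coefs, "pvc_coefficients"))
  if (coefs$RC <= 0) stop("correct_pvc: RC must be > 0")
  if (length(carotid$times) != length(surround$times) ||
      max(abs(carotid$times - surround$times)) > 1e-9)
    stop("correct_pvc: carotid and surround curves must share times")
  tac(carotid$times, (carotid$values - coefs$SP * surround$values) / coefs$RC)
}

#' Monoexponential parent-fraction fit
#'
#' Least-squares fit of `f(t) = a exp(-lambda t)` to the sampled parent
#' fractions: a log-linear solve on the positive fractions seeds a bounded
#' quasi-Newton refinement of the untransformed residuals. Evaluation
#' clamps predictions to `[0, 1]`.
#'
#' @param blood a [blood_samples()] with at least 2 samples of positive
#'   parent fraction.
#' @return An object of class `parent_fraction_fit`: `a`, `lambda`, `rss`.
#' @export
fit_parent_fraction <- function(blood) {
  stopifnot(inherits(blood, "blood_samples"))
  pos <- blood$parent_fraction > 0
  if (sum(pos) < 2L)
    stop("fit_parent_fraction: need >= 2 samples with parent_fraction > 0")
  t <- blood$times
  f <- blood$parent_fraction
  lf <- stats::lm.fit(cbind(1, t[pos]), log(f[pos]))$coefficients
  start <- c(a = exp(lf[1]), lambda = max(-lf[2], 0))
  sse <- function(p) sum((f - p[1] * exp(-p[2] * t))^2)
  opt <- stats::optim(start, sse, method = "L-BFGS-B",
                      lower = c(1e-12, 0), upper = c(10, 10))
  structure(list(a = unname(opt$par[1]), lambda = unname(opt$par[2]),
                 rss = opt$value),
            class = "parent_fraction_fit")
}

#' Evaluate a parent-fraction fit (clamped to `[0, 1]`)
#' @param pf a `parent_fraction_fit`.
#' @param t times, minutes.
#' @return numeric fractions in `[0, 1]`.
#' @export
parent_fraction_at <- function(pf, t) {
  stopifnot(inherits(pf, "parent_fraction_fit"))
  pmin(pmax(pf$a * exp(-pf$lambda * t), 0), 1)
}

#' Metabolite correction of the whole-blood IDIF
#'
#' Multiplies the whole-blood curve by the fitted parent fraction at each
#' time, yielding the plasma parent concentration curve.
#' @param wb_idif a [tac()].
#' @param pf a `parent_fraction_fit`.
#' @return a [tac()].
#' @export
metabolite_correct <- function(wb_idif, pf) {
  stopifnot(inherits(wb_idif, "tac"))
  tac(wb_idif$times, wb_idif$values * parent_fraction_at(pf, wb_idif$times))
}

#' Tri-exponential input-function fit
#'
#' Fits `sum_j A_j exp(-lambda_j (t - t_peak))` to the post-peak samples of
#' the plasma curve by variable projection: for each candidate rate triple
#' the amplitudes are the exact NNLS solution, and the rates are refined by
#' bounded quasi-Newton from a grid of multi-start seeds. The measured
#' rising part of the curve (up to the peak) is kept as is; the final input
#' function is the piecewise curve (raw rise, fitted decay).
#'
#' @param plasma a [tac()] whose maximum is not at the last sample.
#' @return An object of class `input_function`: fields `peak_time`,
#'   `peak_value`, `rise_times`, `rise_values` (measured samples up to and
#'   including the peak), `amplitudes`, `lambdas` (sorted decreasing),
#'   `rmse`, `end_time`.
#' @export
fit_triexponential <- function(plasma) {
  stopifnot(inherits(plasma, "tac"))
  ip <- which.max(plasma$values)
  n <- length(plasma$times)
  if (ip == n)
    stop("fit_triexponential: curve maximum at last sample; no decay to fit")
  t_peak <- plasma$times[ip]
  td <- plasma$times[ip:n] - t_peak
  yd <- plasma$values[ip:n]
  fit_for <- function(lam) {
    # collapse numerically identical rates so the design keeps full rank
    keep <- !duplicated(signif(lam, 8))
    D <- exp(-outer(td, lam[keep]))
    if (qr(D)$rank < ncol(D)) {
      keep <- seq_along(lam) == which.min(lam)
      D <- exp(-outer(td, lam[keep]))
    }
    r <- nnls_multi(D, yd)
    coef <- numeric(3)
    coef[keep] <- r$coef[, 1]
    list(rss = r$rss, coef = coef)
  }
  obj <- function(lam) fit_for(lam)$rss
  t_span <- max(td[length(td)], 1)
  starts <- list(c(2, 0.2, 0.01), c(5, 0.5, 0.02), c(1, 0.1, 0.005),
                 c(8, 0.8, 0.05), c(0.5, 0.05, 0.002))
  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(s, obj, method = "L-BFGS-B",
                            lower = rep(1e-6, 3), upper = rep(50, 3),
                            control = list(factr = 1e4)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("fit_triexponential: no start converged; inspect the curve")
  lam <- best$par
  amp <- fit_for(lam)$coef
  ord <- order(lam, decreasing = TRUE)
  rmse <- sqrt(best$value / length(td))
  structure(list(peak_time = t_peak, peak_value = plasma$values[ip],
                 rise_times = plasma$times[1:ip],
                 rise_values = plasma$values[1:ip],
                 amplitudes = amp[ord], lambdas = lam[ord], rmse = rmse,
                 end_time = plasma$times[n]),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "<input_function> peak %.4g kBq/mL at %.3g min; A = (%s), lambda = (%s)/min, fit RMSE %.3g\n",
    x$peak_value, x$peak_time,
    paste(sprintf("%.3g", x$amplitudes), collapse = ", "),
    paste(sprintf("%.3g", x$lambdas), collapse = ", "), x$rmse))
  invisible(x)
}

#' Evaluate an input function
#'
#' Piecewise: linear interpolation through (0, 0) and the measured rise up
#' to the peak; the fitted tri-exponential from the peak onward. The fitted
#' tail is nonnegative by construction (nonnegative amplitudes and rates).
#'
#' @param fn an `input_function`.
#' @param t times, minutes.
#' @return numeric values, kBq/mL.
#' @export
input_function_at <- function(fn, t) {
  stopifnot(inherits(fn, "input_function"))
  out <- numeric(length(t))
  pre <- t <= fn$peak_time
  if (any(pre)) {
    rt <- fn$rise_times
    rv <- fn$rise_values
    if (rt[1] > 0) {
      rt <- c(0, rt)
      rv <- c(0, rv)
    }
    out[pre] <- stats::approx(rt, rv, xout = t[pre], rule = 2)$y
  }
  if (any(!pre)) {
    dt <- t[!pre] - fn$peak_time
    out[!pre] <- colSums(fn$amplitudes * exp(-outer(fn$lambdas, dt)))
  }
  out
}

#' Full input-function derivation from image and blood data
#'
#' Convenience wrapper chaining [extract_carotid_tac()],
#' [extract_surround_tac()], [fit_pvc()], [correct_pvc()],
#' [fit_parent_fraction()], [metabolite_correct()] and
#' [fit_triexponential()].
#'
#' @inheritParams extract_carotid_tac
#' @inheritParams extract_surround_tac
#' @param blood a [blood_samples()].
#' @return list with `input_fn` (`input_function`), `plasma_tac`,
#'   `wb_idif`, `carotid`, `surround`, `pvc` (`pvc_coefficients`),
#'   `parent_fit`.
#' @export
derive_input_function <- function(img, carotid_mask, surround_mask, weights,
                                  blood, fraction_threshold = 0.5,
                                  blood_cutoff = 0.001) {
  carotid <- extract_carotid_tac(img, carotid_mask, weights,
                                 fraction_threshold)
  surround <- extract_surround_tac(img, surround_mask, weights, blood_cutoff)
  pvc <- fit_pvc(carotid, surround, blood)
  wb_idif <- correct_pvc(carotid, surround, pvc)
  pf <- fit_parent_fraction(blood)
  plasma <- metabolite_correct(wb_idif, pf)
  fn <- fit_triexponential(plasma)
  list(input_fn = fn, plasma_tac = plasma, wb_idif = wb_idif,
       carotid = carotid, surround = surround, pvc = pvc, parent_fit = pf)
}
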