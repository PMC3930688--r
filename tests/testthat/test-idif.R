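# Helper: wrap arbitrary arrays into a weight_maps object.
wmaps <- function(gray, white, blood) {
  structure(list(gray = gray, white = white, blood = blood),
            class = "weight_maps")
}

test_that("carotid extraction is a blood-weighted mean of selected voxels", {
  d <- c(2, 1, 1)
  sched <- frame_schedule(c(0, 60), c(60, 60))
  vox <- array(0, c(d, 2))
  vox[1, 1, 1, ] <- c(2, 2)
  vox[2, 1, 1, ] <- c(6, 6)
  img <- dynamic_image(vox, c(2, 2, 4.25), sched)
  mask <- mask_volume(array(TRUE, d))
  w <- wmaps(array(0, d), array(0, d), array(c(1, 3), d))
  out <- extract_carotid_tac(img, mask, w)
  expect_equal(out$values, c(5, 5))            # (1*2 + 3*6) / 4
  expect_equal(attr(out, "n_voxels"), 2L)
  # identical voxel TACs: any positive weights give that TAC back
  vox[2, 1, 1, ] <- c(2, 2)
  img2 <- dynamic_image(vox, c(2, 2, 4.25), sched)
  w2 <- wmaps(array(0, d), array(0, d), array(c(0.2, 5), d))
  expect_equal(extract_carotid_tac(img2, mask, w2)$values, c(2, 2))
  # blood fraction <= 0.5 excludes a voxel; empty selection errors
  w3 <- wmaps(array(c(3, 0), d), array(0, d), array(c(1, 3), d))
  expect_equal(extract_carotid_tac(img, mask, w3)$values, c(6, 6))
  w4 <- wmaps(array(3, d), array(0, d), array(1, d))
  expect_error(extract_carotid_tac(img, mask, w4), "threshold")
})

test_that("surround extraction averages low-blood voxels unweighted", {
  d <- c(3, 1, 1)
  sched <- frame_schedule(c(0, 60), c(60, 60))
  vox <- array(0, c(d, 2))
  vox[1, 1, 1, ] <- c(1, 2)
  vox[2, 1, 1, ] <- c(3, 4)
  vox[3, 1, 1, ] <- c(100, 100)
  img <- dynamic_image(vox, c(2, 2, 4.25), sched)
  mask <- mask_volume(array(TRUE, d))
  # third voxel has blood fraction 0.002 -> excluded (strictly < 0.001 rule)
  w <- wmaps(array(c(1, 1, 0.998), d), array(0, d),
             array(c(0, 0, 0.002), d))
  out <- extract_surround_tac(img, mask, w)
  expect_equal(out$values, c(2, 3))
  expect_equal(attr(out, "n_voxels"), 2L)
  w0 <- wmaps(array(0, d), array(0, d), array(1, d))
  expect_error(extract_surround_tac(img, mask, w0), "cutoff")
})

test_that("carotid TAC on the exact phantom equals the true whole-blood frames", {
  ph <- phantom_exact()
  tr <- ph$truth
  d <- dim(ph$image$voxels)[1:3]
  blood_w <- array(0, d)
  blood_w[tr$masks$carotid$indicator] <- 1
  w <- wmaps(array(0, d), array(0, d), blood_w)
  out <- extract_carotid_tac(ph$image, tr$masks$carotid, w)
  expect_equal(out$values, tr$wb_frames$values, tolerance = 1e-9)
})

test_that("PVC fit recovers exact coefficients and flags degenerate designs", {
  mids <- frame_mid_min(default_schedule())
  wb_curve <- input_model(input_params(), mids)$values
  surround_curve <- 3 + 0.5 * sqrt(mids)
  blood <- blood_samples(c(6, 20, 60, 87.5),
                         tac_at(tac(mids, wb_curve), c(6, 20, 60, 87.5)),
                         rep(0.8, 4), 0.04)
  carotid <- tac(mids, 0.55 * wb_curve + 0.25 * surround_curve)
  fit <- fit_pvc(carotid, tac(mids, surround_curve), blood)
  expect_equal(fit$RC, 0.55, tolerance = 1e-10)
  expect_equal(fit$SP, 0.25, tolerance = 1e-10)
  expect_equal(fit$n_samples, 4L)
  # carotid = whole blood -> (1, 0)
  fit2 <- fit_pvc(tac(mids, wb_curve), tac(mids, surround_curve), blood)
  expect_equal(fit2$RC, 1, tolerance = 1e-10)
  expect_equal(fit2$SP, 0, tolerance = 1e-10)
  # three samples solve the same system
  blood3 <- blood_samples(c(6, 20, 60),
                          tac_at(tac(mids, wb_curve), c(6, 20, 60)),
                          rep(0.8, 3), 0.04)
  fit3 <- fit_pvc(carotid, tac(mids, surround_curve), blood3)
  expect_equal(fit3$RC, 0.55, tolerance = 1e-10)
  expect_equal(fit3$SP, 0.25, tolerance = 1e-10)
  # collinear design: surround proportional to whole blood at samples
  blood_c <- blood_samples(c(6, 20, 60), c(4, 2, 1), rep(0.8, 3), 0.04)
  expect_error(fit_pvc(carotid, tac(mids, rep(0, 33)), blood_c),
               "collinear")
  # negative spill-in flagged, not fatal
  carotid_n <- tac(mids, 0.5 * wb_curve - 0.1 * surround_curve)
  expect_warning(fit_pvc(carotid_n, tac(mids, surround_curve), blood),
                 "negative spill")
})

test_that("PVC correction inverts the forward model", {
  mids <- frame_mid_min(default_schedule())
  wb <- input_model(input_params(), mids)$values
  surround <- tac(mids, 3 + 0.1 * mids)
  coefs <- structure(list(RC = 0.55, SP = 0.25), class = "pvc_coefficients")
  forward <- tac(mids, 0.55 * wb + 0.25 * surround$values)
  expect_equal(correct_pvc(forward, surround, coefs)$values, wb,
               tolerance = 1e-12)
  ident <- structure(list(RC = 1, SP = 0), class = "pvc_coefficients")
  expect_equal(correct_pvc(forward, surround, ident)$values,
               forward$values)
  bad <- structure(list(RC = -1, SP = 0), class = "pvc_coefficients")
  expect_error(correct_pvc(forward, surround, bad), "RC")
})

test_that("parent-fraction fit recovers exact monoexponentials and clamps", {
  t <- c(6, 20, 60, 90)
  b <- blood_samples(t, rep(1, 4), 0.8 * exp(-0.02 * t), 0.04)
  pf <- fit_parent_fraction(b)
  expect_equal(pf$a, 0.8, tolerance = 1e-6)
  expect_equal(pf$lambda, 0.02, tolerance = 1e-6)
  # constant fraction 1 -> a = 1, lambda = 0
  b2 <- blood_samples(t, rep(1, 4), rep(1, 4), 0.04)
  pf2 <- fit_parent_fraction(b2)
  expect_equal(pf2$a, 1, tolerance = 1e-8)
  expect_equal(pf2$lambda, 0, tolerance = 1e-8)
  # evaluation clamps to [0, 1]
  pf_over <- structure(list(a = 1.05, lambda = 0.01),
                       class = "parent_fraction_fit")
  expect_equal(parent_fraction_at(pf_over, 0), 1)
  expect_error(fit_parent_fraction(
    blood_samples(t, rep(1, 4), rep(0, 4), 0.04)), ">= 2")
})

test_that("metabolite correction is a pointwise product", {
  mids <- frame_mid_min(default_schedule())
  wb <- tac(mids, 10 * exp(-0.01 * mids))
  ident <- structure(list(a = 1, lambda = 0), class = "parent_fraction_fit")
  expect_equal(metabolite_correct(wb, ident)$values, wb$values)
  half <- structure(list(a = 0.5, lambda = 0), class = "parent_fraction_fit")
  expect_equal(metabolite_correct(wb, half)$values, wb$values / 2)
})

test_that("tri-exponential fit recovers well-separated decays", {
  mids <- frame_mid_min(default_schedule())
  A <- c(40, 20, 8)
  lam <- c(1.0, 0.1, 0.01)
  peak_t <- 0.75
  vals <- ifelse(mids <= peak_t, sum(A) * mids / peak_t,
                 colSums(A * exp(-outer(lam, mids - peak_t))))
  fn <- fit_triexponential(tac(mids, vals))
  grid <- seq(fn$peak_time, 90, by = 0.25)
  resid <- input_function_at(fn, grid) -
    colSums(A * exp(-outer(lam, grid - peak_t)))
  expect_lt(sqrt(mean(resid^2)), 1e-3 * max(vals))
  expect_true(all(input_function_at(fn, grid) >= 0))
  # single-exponential data: nested model handled gracefully
  vals1 <- ifelse(mids <= peak_t, 50 * mids / peak_t,
                  50 * exp(-0.05 * (mids - peak_t)))
  fn1 <- fit_triexponential(tac(mids, vals1))
  resid1 <- input_function_at(fn1, grid) -
    ifelse(grid <= peak_t, 50 * grid / peak_t,
           50 * exp(-0.05 * (grid - peak_t)))
  expect_lt(sqrt(mean(resid1^2)), 1e-3 * 50)
  # a curve with its maximum at the end cannot be fitted
  expect_error(fit_triexponential(tac(mids, mids)), "maximum at last")
})

test_that("pipeline curves scale linearly with the image, RC/SP invariant", {
  ph <- phantom_blurred()
  pt <- phantom_templates()
  tr <- ph$truth
  vtpl <- average_blood_weights(list(pt$weights))
  cm <- carotid_template_mask(vtpl)
  sm <- surround_template_mask(cm, ph$image$voxel_size_mm)
  blood <- sample_blood(tr)
  d1 <- derive_input_function(ph$image, cm, sm, pt$weights, blood)
  c_ <- 2.5
  img2 <- dynamic_image(c_ * ph$image$voxels, ph$image$voxel_size_mm,
                        ph$image$schedule)
  blood2 <- blood_samples(blood$times, c_ * blood$whole_blood,
                          blood$parent_fraction, blood$f_P)
  d2 <- derive_input_function(img2, cm, sm, pt$weights, blood2)
  expect_equal(d2$carotid$values, c_ * d1$carotid$values, tolerance = 1e-9)
  expect_equal(d2$surround$values, c_ * d1$surround$values, tolerance = 1e-9)
  expect_equal(d2$pvc$RC, d1$pvc$RC, tolerance = 1e-9)
  expect_equal(d2$pvc$SP, d1$pvc$SP, tolerance = 1e-9)
  expect_equal(d2$wb_idif$values, c_ * d1$wb_idif$values, tolerance = 1e-9)
  expect_equal(d2$plasma_tac$values, c_ * d1$plasma_tac$values,
               tolerance = 1e-9)
})

test_that("corrected plasma input matches truth on the blurred noiseless phantom", {
  ph <- phantom_blurred()
  pt <- phantom_templates()
  tr <- ph$truth
  vtpl <- average_blood_weights(list(pt$weights))
  cm <- carotid_template_mask(vtpl)
  sm <- surround_template_mask(cm, ph$image$voxel_size_mm)
  deriv <- derive_input_function(ph$image, cm, sm, pt$weights,
                                 sample_blood(tr))
  auc_est <- tac_auc(deriv$plasma_tac, 0, 90)
  auc_true <- tac_auc(tr$plasma_frames, 0, 90)
  expect_equal(auc_est / auc_true, 1, tolerance = 0.05)
  # monoexponential truth: metabolite correction reproduces the parent
  # fraction within the PVC fit error at the sample times
  pf_true <- phantom_parent_fraction(tr$spec, c(6, 20, 60, 90))
  pf_fit <- parent_fraction_at(deriv$parent_fit, c(6, 20, 60, 90))
  expect_equal(pf_fit, pf_true, tolerance = 1e-6)
})
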