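test_that("input model has the required shape and matches its quadrature oracle", {
  p <- input_params()
  expect_equal(input_model(p, 0)$values, 0)
  expect_error(input_model(p, c(-1, 0)), "negative")
  flat <- input_params(peak = 0)
  expect_true(all(input_model(flat, seq(0, 90, by = 1))$values == 0))
  # single early peak
  t <- seq(0, 90, by = 0.005)
  v <- input_model(p, t)$values
  expect_lt(t[which.max(v)], 3)
  expect_true(all(diff(v[t > p$t_peak]) <= 0))
  # trapezoid AUC on a fine grid vs closed-form antiderivative, <= 0.1%
  for (to in c(5, 30, 90)) {
    expect_equal(tac_auc(input_model(p, t), 0, to),
                 input_model_integral(p, to),
                 tolerance = 1e-3)
  }
})

test_that("kinetic_params validates and yields the closed-form V_T", {
  expect_error(kinetic_params(0.1, 0), "k2")
  expect_error(kinetic_params(0.1, 0.05, k3 = 0.1, k4 = 0), "k4")
  expect_error(kinetic_params(0.1, 0.05, vb = 0.5), "vb")
  expect_equal(analytic_vt(kinetic_params(0.1, 0.05, vb = 0)), 2)
  expect_equal(analytic_vt(kinetic_params(0.1, 0.05, 0.03, 0.06, 0)), 3)
})

test_that("tissue simulation matches an independent RK4 oracle", {
  p <- input_params()
  fine <- seq(0, 20, by = 0.25 / 60)
  cp <- input_model(p, fine)
  for (kp in list(kinetic_params(0.1, 0.05, vb = 0),
                  kinetic_params(0.35, 0.12, 0.05, 0.08, 0))) {
    ct <- simulate_tissue(cp, kp)
    oracle <- rk4_2tcm(cp, kp, dt_min = 0.25 / 60)
    idx <- fine >= 1          # skip the near-zero start for relative error
    expect_lt(max(abs(ct$values[idx] - oracle$values[idx]) /
                    max(oracle$values)), 1e-3)
  }
})

test_that("tissue simulation boundary behavior", {
  p <- input_params()
  fine <- seq(0, 10, by = 0.25 / 60)
  cp <- input_model(p, fine)
  zero <- simulate_tissue(cp, kinetic_params(0, 0.05, vb = 0))
  expect_true(all(zero$values == 0))
  expect_error(simulate_tissue(cp, kinetic_params(0.1, 0.05, vb = 0.05)),
               "whole_blood")
  # late-time C_T/C_p for the 1TCM example approaches the oracle's value
  fine90 <- seq(0, 90, by = 0.5 / 60)
  cp90 <- input_model(p, fine90)
  kp <- kinetic_params(0.1, 0.05, vb = 0)
  ct <- simulate_tissue(cp90, kp)
  oracle <- rk4_2tcm(cp90, kp, dt_min = 0.5 / 60)
  n <- length(fine90)
  expect_equal(ct$values[n] / cp90$values[n],
               oracle$values[n] / cp90$values[n], tolerance = 1e-3)
})

test_that("frame integration is exact for constants, linear and exponential curves", {
  s <- default_schedule()
  fine <- tac(seq(0, 90, by = 0.001), rep(7.5, 90001))
  expect_equal(integrate_frames(fine, s)$values, rep(7.5, 33))
  a <- 0.3
  lin <- tac(seq(0, 90, by = 0.001), a * seq(0, 90, by = 0.001))
  expect_equal(integrate_frames(lin, s)$values, a * frame_mid_min(s),
               tolerance = 1e-12)
  lam <- 0.05
  ex <- tac(seq(0, 90, by = 0.25 / 60), exp(-lam * seq(0, 90, by = 0.25 / 60)))
  t1 <- s$start_s / 60
  t2 <- (s$start_s + s$dur_s) / 60
  closed <- (exp(-lam * t1) - exp(-lam * t2)) / (lam * (t2 - t1))
  expect_lt(max(abs(integrate_frames(ex, s)$values - closed)), 1e-6)
  expect_error(integrate_frames(tac(seq(0, 50, by = 0.01),
                                    rep(1, 5001)), s), "support")
})

test_that("Gaussian PSF preserves constants and interior mass; fwhm 0 is identity", {
  v <- array(2.5, c(12, 12, 8))
  expect_equal(apply_psf(v, 7, c(2, 2, 4.25)), v, tolerance = 1e-12)
  pt <- array(0, c(32, 32, 20))
  pt[16, 16, 10] <- 3
  b <- apply_psf(pt, 7, c(2, 2, 4.25))
  expect_equal(sum(b), 3, tolerance = 1e-6)
  expect_identical(apply_psf(pt, 0, c(2, 2, 4.25)), pt)
  expect_error(apply_psf(pt, -1, c(2, 2, 4.25)), ">= 0")
})

test_that("phantom is deterministic and exact without blur and noise", {
  a <- build_phantom(mini_spec(seed = 11))
  b <- build_phantom(mini_spec(seed = 11))
  expect_identical(a$image$voxels, b$image$voxels)
  c_ <- build_phantom(mini_spec(seed = 12))
  expect_false(identical(a$image$voxels, c_$image$voxels))

  ph <- phantom_exact()
  tr <- ph$truth
  idx <- which(tr$masks$carotid$indicator)
  nf <- dim(ph$image$voxels)[4]
  vox_tac <- matrix(ph$image$voxels, ncol = nf)[idx[1], ]
  expect_equal(vox_tac, tr$wb_frames$values, tolerance = 1e-9)
})

test_that("PSF blur causes partial-volume loss at the carotid peak", {
  ph <- phantom_blurred()
  tr <- ph$truth
  nf <- dim(ph$image$voxels)[4]
  idx <- which(tr$masks$carotid$indicator)
  peak_img <- max(matrix(ph$image$voxels, ncol = nf)[idx, ])
  expect_lt(peak_img, max(tr$wb_frames$values))
})

test_that("analytic V_T agrees with Logan on the noiseless true curves within 2%", {
  ph <- phantom_exact()
  tr <- ph$truth
  for (tissue in c("gray", "white")) {
    # strip the fractional blood volume: the closed-form V_T describes the
    # tissue compartments, not the vb-admixed voxel signal
    vb <- tr$spec[[paste0("kin_", tissue)]]$vb
    meas <- tr$tissue_frames[[tissue]]
    ct <- tac(meas$times,
              (meas$values - vb * tr$wb_frames$values) / (1 - vb))
    lr <- logan_vt(ct, tr$plasma_fine, t_star = 30)
    expect_equal(lr$VT, tr$vt[[tissue]], tolerance = 0.02)
  }
})

test_that("probability maps threshold back to the ground-truth masks", {
  tr <- phantom_blurred()$truth
  expect_identical(unname(tr$gm_prob > 0.9),
                   unname(tr$masks$gray$indicator))
  expect_identical(unname(tr$wm_prob > 0.5),
                   unname(tr$masks$white$indicator))
})

test_that("frame noise variance scales inversely with frame duration", {
  spec <- mini_spec(noise = 0.1)
  base <- build_phantom(mini_spec(noise = 0))   # noiseless reference
  nf <- length(spec$schedule)
  idx <- which(base$truth$masks$gray$indicator)[1]
  n_draws <- 400
  draws <- matrix(NA_real_, n_draws, nf)
  for (i in seq_len(n_draws)) {
    sp <- mini_spec(noise = 0.1, seed = 1000L + i)
    draws[i, ] <- matrix(build_phantom(sp)$image$voxels, ncol = nf)[idx, ]
  }
  body <- base$truth$masks$brain$indicator
  a_f <- colMeans(matrix(base$image$voxels, ncol = nf)[which(body), ])
  expected_sd <- spec$noise * a_f / sqrt(spec$schedule$dur_s / 60)
  emp_sd <- apply(draws, 2, sd)
  expect_lt(max(abs(emp_sd^2 / expected_sd^2 - 1)), 0.25)
  # pooled across frames the variance ratio is tight
  expect_equal(mean(emp_sd^2 / expected_sd^2), 1, tolerance = 0.1)
})

test_that("cohort generation is reproducible and jitters geometry", {
  coh1 <- build_phantom_cohort(mini_spec(), 2, seed = 5)
  coh2 <- build_phantom_cohort(mini_spec(), 2, seed = 5)
  expect_identical(coh1[[1]]$image$voxels, coh2[[1]]$image$voxels)
  specs <- lapply(coh1, function(ph) ph$truth$spec)
  expect_false(specs[[1]]$input$peak == specs[[2]]$input$peak)
  expect_error(phantom_spec(carotid_centers = rbind(c(100, 2), c(3, 3))),
               "outside grid")
})
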