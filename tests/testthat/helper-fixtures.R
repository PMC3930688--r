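# Shared fixtures, built once per test run and cached. All synthetic; no
# data files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Default-spec noiseless, unblurred phantom (exact carotid voxels).
phantom_exact <- function() fixture("phantom_exact", function() {
  build_phantom(phantom_spec(noise = 0, fwhm_mm = 0))
})

# Default-spec noiseless, PSF-blurred phantom.
phantom_blurred <- function() fixture("phantom_blurred", function() {
  build_phantom(phantom_spec(noise = 0))
})

# Single-subject template set built from the blurred noiseless phantom with
# its ground-truth masks (stands in for the manual template step).
phantom_templates <- function() fixture("phantom_templates", function() {
  ph <- phantom_blurred()
  tr <- ph$truth
  std <- standardize_frames(ph$image)
  tmpl <- build_template_tacs(list(list(
    std = std,
    gray = gray_matter_mask(tr$gm_prob),
    white = white_matter_mask(tr$gm_prob, tr$wm_prob,
                              ph$image$voxel_size_mm),
    blood = tr$masks$carotid)))
  list(std = std, templates = tmpl,
       weights = solve_weights(std, tmpl))
})

# Small phantom spec for cheap repeated builds (noise studies).
mini_spec <- function(noise = 0.05, fwhm_mm = 7, seed = 1L) {
  sched <- frame_schedule(c(0, 30, 60, 120), c(30, 30, 60, 120))
  phantom_spec(grid_dim = c(16L, 16L, 8L), voxel_size_mm = c(2, 2, 4.25),
               schedule = sched,
               carotid_centers = rbind(c(5, 6), c(11, 6)),
               carotid_radius_mm = 2.5, carotid_z_range = 2:6,
               brain_center = c(8, 8, 4), brain_radii_mm = c(15, 14, 16),
               white_radii_mm = c(6, 5, 8),
               noise = noise, fwhm_mm = fwhm_mm, fine_dt_s = 1,
               seed = seed)
}

# Tiny 4D image for I/O and standardization unit tests.
toy_image <- function(dim3 = c(4, 4, 3), nframes = 4, seed = 1) {
  set.seed(seed)
  sched <- frame_schedule(seq(0, by = 60, length.out = nframes),
                          rep(60, nframes))
  dynamic_image(array(rnorm(prod(dim3) * nframes, mean = 10, sd = 2),
                      c(dim3, nframes)),
                voxel_size_mm = c(2, 2, 4.25), schedule = sched)
}

# Independent RK4 integrator for the 2TCM ODEs (oracle for the
# convolution-based simulator). State (C1, C2); plasma input interpolated.
rk4_2tcm <- function(input_plasma, kp, dt_min = 1 / 240) {
  t_end <- max(input_plasma$times)
  tt <- seq(0, t_end, by = dt_min)
  cp <- stats::approxfun(input_plasma$times, input_plasma$values,
                         rule = 2, yleft = 0)
  deriv <- function(t, s) {
    c(kp$K1 * cp(t) - (kp$k2 + kp$k3) * s[1] + kp$k4 * s[2],
      kp$k3 * s[1] - kp$k4 * s[2])
  }
  s <- c(0, 0)
  out <- numeric(length(tt))
  for (i in seq_along(tt)[-1]) {
    h <- tt[i] - tt[i - 1]
    k1 <- deriv(tt[i - 1], s)
    k2 <- deriv(tt[i - 1] + h / 2, s + h / 2 * k1)
    k3 <- deriv(tt[i - 1] + h / 2, s + h / 2 * k2)
    k4 <- deriv(tt[i - 1] + h, s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i] <- s[1] + s[2]
  }
  tac(tt, out)
}

# Exact minimum of || y - T w ||^2 over the grid {0, step, ..., hi}^3:
# (w1, w2) are enumerated; the grid-optimal w3 given (w1, w2) is one of the
# two grid neighbours of the continuous vertex of the convex parabola.
grid_nnls_oracle <- function(T, y, step = 0.01, hi = 2) {
  G <- crossprod(T)
  b <- as.numeric(crossprod(T, y))
  yty <- sum(y^2)
  w12 <- as.matrix(expand.grid(w1 = seq(0, hi, by = step),
                               w2 = seq(0, hi, by = step)))
  w3star <- (b[3] - G[1, 3] * w12[, 1] - G[2, 3] * w12[, 2]) / G[3, 3]
  cand <- cbind(pmin(pmax(floor(w3star / step) * step, 0), hi),
                pmin(pmax(ceiling(w3star / step) * step, 0), hi))
  rss_of <- function(w3) {
    yty - 2 * (b[1] * w12[, 1] + b[2] * w12[, 2] + b[3] * w3) +
      G[1, 1] * w12[, 1]^2 + G[2, 2] * w12[, 2]^2 + G[3, 3] * w3^2 +
      2 * (G[1, 2] * w12[, 1] * w12[, 2] + G[1, 3] * w12[, 1] * w3 +
             G[2, 3] * w12[, 2] * w3)
  }
  min(pmin(rss_of(cand[, 1]), rss_of(cand[, 2])))
}
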