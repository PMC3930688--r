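# Kinetic building blocks for the phantom: an arterial input-curve model
# (linear rise to a single early peak, tri-exponential washout), analytic
# two-tissue-compartment tissue kinetics via convolution, and
# duration-weighted frame integration.

#' Two-tissue-compartment rate constants
#'
#' @param K1 plasma-to-tissue delivery, mL/min/mL.
#' @param k2 tissue-to-plasma efflux, 1/min (must be > 0: V_T undefined
#'   otherwise).
#' @param k3,k4 exchange with the bound compartment, 1/min; `k3 = k4 = 0`
#'   reduces to the one-tissue model.
#' @param vb fractional blood volume, in `[0, 0.2]`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vb = 0.05) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("kinetic_params: all parameters must be finite and nonnegative")
  if (k2 <= 0)
    stop("kinetic_params: k2 must be > 0 (V_T undefined)")
  if (k3 > 0 && k4 == 0)
    stop("kinetic_params: k4 must be > 0 when k3 > 0 (irreversible binding)")
  if (vb > 0.2)
    stop("kinetic_params: vb outside [0, 0.2]")
  structure(as.list(vals), class = "kinetic_params")
}

#' Analytic total distribution volume of a kinetic_params set
#'
#' `V_T = (K1/k2) (1 + k3/k4)`, or `K1/k2` when `k3 = k4 = 0`.
#' @param kp a [kinetic_params()].
#' @return numeric, mL/cm^3.
#' @export
analytic_vt <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k3 == 0) kp$K1 / kp$k2 else (kp$K1 / kp$k2) * (1 + kp$k3 / kp$k4)
}

#' Parameters of the arterial whole-blood input model
#'
#' The curve is zero at injection, rises linearly to a single early peak at
#' `t_peak`, then decays as a sum of three exponentials whose amplitudes are
#' fractions of the peak value:
#' `C(t) = peak * sum(frac_j * exp(-lambda_j (t - t_peak)))` for t > t_peak.
#' Amplitude fractions are renormalized to sum to 1 so the curve is
#' continuous at the peak.
#' @param peak peak whole-blood activity, kBq/mL.
#' @param t_peak time of peak, minutes (default 0.75; before 3 min).
#' @param frac three amplitude fractions (renormalized to sum to 1 unless
#'   all are zero).
#' @param lambda three decay rates, 1/min.
#' @return list of validated parameters, class `input_params`.
#' @export
input_params <- function(peak = 80, t_peak = 0.75,
                         frac = c(0.65, 0.25, 0.10),
                         lambda = c(4, 0.25, 0.012)) {
  if (peak < 0 || t_peak <= 0 || any(frac < 0) || any(lambda < 0))
    stop("input_params: parameters must be nonnegative (t_peak > 0)")
  if (length(frac) != 3L || length(lambda) != 3L)
    stop("input_params: frac and lambda must each have length 3")
  s <- sum(frac)
  if (s > 0) frac <- frac / s
  structure(list(peak = peak, t_peak = t_peak, frac = frac, lambda = lambda),
            class = "input_params")
}

#' Evaluate the arterial whole-blood input model
#'
#' @param params an [input_params()].
#' @param times minutes, nonnegative.
#' @return a [tac()] with value 0 at t = 0 and a single peak at `t_peak`.
#' @export
input_model <- function(params, times) {
  stopifnot(inherits(params, "input_params"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("input_model: negative times")
  v <- numeric(length(times))
  rise <- times <= params$t_peak
  v[rise] <- params$peak * times[rise] / params$t_peak
  tt <- times[!rise] - params$t_peak
  if (length(tt))
    v[!rise] <- params$peak *
      colSums(params$frac * exp(-outer(params$lambda, tt)))
  tac(times, v)
}

#' Closed-form time integral of the input model
#'
#' Exact antiderivative of [input_model()] from 0 to each time; used as the
#' quadrature oracle for AUC checks and for exact frame integration of the
#' blood curve.
#' @inheritParams input_model
#' @return numeric vector of integrals, kBq/mL * min.
#' @export
input_model_integral <- function(params, times) {
  stopifnot(inherits(params, "input_params"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("input_model_integral: negative times")
  tp <- params$t_peak
  pk <- params$peak
  out <- numeric(length(times))
  rise <- times <= tp
  out[rise] <- pk * times[rise]^2 / (2 * tp)
  tt <- times[!rise] - tp
  if (length(tt)) {
    base <- pk * tp / 2
    dec <- vapply(tt, function(u) {
      sum(ifelse(params$lambda > 0,
                 params$frac / pmax(params$lambda, .Machine$double.xmin) *
                   (1 - exp(-params$lambda * u)),
                 params$frac * u))
    }, numeric(1))
    out[!rise] <- base + pk * dec
  }
  out
}

# Impulse response of the (reversible) two-tissue compartment model:
# h(t) = K1 [ phi1 exp(-a1 t) + phi2 exp(-a2 t) ], a1/a2 the roots of
# s^2 + (k2+k3+k4) s + k2 k4. For k3 = k4 = 0 this is K1 exp(-k2 t).
tissue_impulse <- function(kp, t) {
  if (kp$k3 == 0 && kp$k4 == 0) return(kp$K1 * exp(-kp$k2 * t))
  b <- kp$k2 + kp$k3 + kp$k4
  disc <- sqrt(max(b^2 - 4 * kp$k2 * kp$k4, 0))
  a1 <- (b + disc) / 2
  a2 <- (b - disc) / 2
  if (a1 - a2 < 1e-12) {            # repeated root: (c1 + c2 t) exp(-a t)
    return(kp$K1 * exp(-a1 * t) * (1 + (kp$k3 + kp$k4 - a1) * t))
  }
  phi1 <- (a1 - kp$k3 - kp$k4) / (a1 - a2)
  phi2 <- (kp$k3 + kp$k4 - a2) / (a1 - a2)
  kp$K1 * (phi1 * exp(-a1 * t) + phi2 * exp(-a2 * t))
}

#' Simulate a tissue time-activity curve from plasma input
#'
#' Solves the two-tissue compartment model by convolving the plasma parent
#' curve with the analytic impulse response (FFT convolution with trapezoid
#' end correction), then mixes in fractional blood volume:
#' `C_PET = (1 - vb) C_tissue + vb C_wb`.
#'
#' @param input_plasma a [tac()] on a fine regular grid (step <= 1 s
#'   recommended) starting at or near t = 0.
#' @param kp a [kinetic_params()].
#' @param whole_blood optional [tac()] on the same grid for the vb term;
#'   required when `kp$vb > 0`.
#' @return a [tac()] on the same grid.
#' @export
simulate_tissue <- function(input_plasma, kp, whole_blood = NULL) {
  stopifnot(inherits(input_plasma, "tac"), inherits(kp, "kinetic_params"))
  t <- input_plasma$times
  if (length(t) < 3L) stop("simulate_tissue: fine grid required")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("simulate_tissue: input grid must be regular")
  dt <- dt[1]
  if (dt > 1.5 / 60)
    warning("simulate_tissue: grid step > 1.5 s; convolution accuracy degrades")
  cp <- input_plasma$values
  h <- tissue_impulse(kp, t - t[1])
  n <- length(t)
  # linear convolution via FFT, rectangle rule, trapezoid end correction
  m <- stats::nextn(2L * n)
  fa <- stats::fft(c(cp, numeric(m - n)))
  fb <- stats::fft(c(h, numeric(m - n)))
  conv <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / m
  ct <- dt * (conv - 0.5 * (cp[1] * h + cp * h[1]))
  ct <- pmax(ct, 0)
  out <- (1 - kp$vb) * ct
  if (kp$vb > 0) {
    if (is.null(whole_blood))
      stop("simulate_tissue: whole_blood TAC required when vb > 0")
    stopifnot(inherits(whole_blood, "tac"))
    if (length(whole_blood$times) != n ||
        max(abs(whole_blood$times - t)) > 1e-9)
      stop("simulate_tissue: whole_blood grid must match input grid")
    out <- out + kp$vb * whole_blood$values
  }
  tac(t, out)
}

#' Duration-weighted frame integration of a fine curve
#'
#' Each frame value is the mean of the fine curve over the frame interval,
#' computed from the cumulative trapezoid integral with exact linear
#' interpolation at frame boundaries (exact for piecewise-linear curves).
#'
#' @param fine a [tac()] whose support covers every frame.
#' @param schedule a [frame_schedule()].
#' @return a [tac()] at mid-frame times.
#' @export
integrate_frames <- function(fine, schedule) {
  stopifnot(inherits(fine, "tac"), inherits(schedule, "frame_schedule"))
  t0 <- schedule$start_s / 60
  t1 <- (schedule$start_s + schedule$dur_s) / 60
  tol <- 1e-9
  if (min(t0) < fine$times[1] - tol ||
      max(t1) > fine$times[length(fine$times)] + tol)
    stop("integrate_frames: frame extends beyond fine-grid support")
  tt <- fine$times
  vv <- fine$values
  cum <- c(0, cumsum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2))
  cum_at <- function(x) {
    x <- pmin(pmax(x, tt[1]), tt[length(tt)])
    i <- findInterval(x, tt, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(tt) - 1L)
    frac <- x - tt[i]
    vx <- vv[i] + (vv[i + 1L] - vv[i]) * frac / (tt[i + 1L] - tt[i])
    cum[i] + frac * (vv[i] + vx) / 2
  }
  means <- (cum_at(t1) - cum_at(t0)) / (t1 - t0)
  tac(frame_mid_min(schedule), means)
}

#' Gaussian point-spread blur of a 3D volume
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` per axis,
#' expressed in voxel units from the voxel size. The discrete kernel is
#' row-normalized, so constants are preserved exactly and interior mass is
#' conserved. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm, >= 0.
#' @param voxel_size_mm length-3 voxel sizes, mm.
#' @return blurred 3D array.
#' @export
apply_psf <- function(volume, fwhm_mm, voxel_size_mm) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("apply_psf: volume must be 3D")
  if (fwhm_mm < 0) stop("apply_psf: fwhm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  d <- dim(volume)
  out <- volume
  for (ax in 1:3) {
    if (sigma_vox[ax] < 1e-8) next
    K <- .gauss_matrix(d[ax], sigma_vox[ax])
    out <- .apply_along(out, ax, K)
  }
  out
}

.gauss_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

.apply_along <- function(arr, axis, K) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- K %*% matrix(x, nrow = dp[1])
  dim(y) <- dp
  aperm(y, order(perm))
}
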