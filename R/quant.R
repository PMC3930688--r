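# Quantification: regional TAC extraction, Logan graphical analysis of the
# total distribution volume V_T (and V_T/f_P), and the descriptive
# curve-comparison statistics (sum of squared distances after a cutoff,
# exact sign-test tail probability, ratio and group summaries).

#' Regional mean time-activity curves
#'
#' Unweighted mean TAC per nonzero label; labels listed in the name table
#' but absent from the volume are omitted with a warning.
#'
#' @param img a [dynamic_image()].
#' @param labels a [region_labels()] on the image grid.
#' @return named list of [tac()]s (names from the label table when given,
#'   else `region_<k>`).
#' @export
regional_tacs <- function(img, labels) {
  stopifnot(inherits(img, "dynamic_image"), inherits(labels, "region_labels"))
  d <- dim(img$voxels)
  check_same_grid(d[1:3], dim(labels$labels), "regional_tacs")
  present <- sort(unique(as.vector(labels$labels)))
  present <- present[present > 0L]
  if (!is.null(labels$names)) {
    declared <- as.integer(names(labels$names))
    missing <- setdiff(declared, present)
    if (length(missing))
      warning(sprintf("regional_tacs: label(s) %s absent from volume; omitted",
                      paste(missing, collapse = ", ")))
  }
  mat <- matrix(img$voxels, ncol = d[4])
  mids <- frame_mid_min(img$schedule)
  out <- lapply(present, function(k) {
    tac(mids, colMeans(mat[which(labels$labels == k), , drop = FALSE]))
  })
  names(out) <- vapply(present, function(k) {
    if (!is.null(labels$names) && as.character(k) %in% names(labels$names))
      labels$names[[as.character(k)]] else sprintf("region_%d", k)
  }, character(1))
  out
}

# Cumulative integral of the input curve at arbitrary times. For an
# input_function the piecewise curve (raw rise + fitted tail) is integrated
# on a 1 s grid; for a plain TAC, trapezoid from (0, 0) through the samples.
.input_cum_integral <- function(input_fn, at_times) {
  t_end <- max(at_times)
  if (inherits(input_fn, "input_function")) {
    grid <- seq(0, t_end, by = 1 / 60)
    if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
    v <- input_function_at(input_fn, grid)
  } else if (inherits(input_fn, "tac")) {
    grid <- sort(unique(c(0, input_fn$times[input_fn$times <= t_end],
                          at_times)))
    it <- input_fn$times
    iv <- input_fn$values
    if (it[1] > 0) {
      it <- c(0, it)
      iv <- c(0, iv)
    }
    v <- stats::approx(it, iv, xout = grid, rule = 2)$y
  } else stop("logan_vt: input must be an input_function or a tac")
  cum <- c(0, cumsum(diff(grid) * (v[-1] + v[-length(v)]) / 2))
  stats::approx(grid, cum, xout = at_times, rule = 2)$y
}

#' Logan graphical analysis
#'
#' Ordinary least squares of `y(t) = int_0^t C_T / C_T(t)` on
#' `x(t) = int_0^t C_p / C_T(t)` over mid-frame times `t >= t_star`; the
#' slope estimates the total distribution volume V_T of a reversible
#' tracer. The tissue integral uses the trapezoid rule over mid-frame
#' samples with an initial triangle from (0, 0); the input integral uses
#' the piecewise input function on a 1 s grid (or the sampled curve when a
#' plain [tac()] is supplied).
#'
#' @param tissue a [tac()] at mid-frame times.
#' @param input_fn an `input_function` (preferred) or a [tac()].
#' @param t_star start of the linear segment, minutes (default 30).
#' @param f_P optional plasma free fraction; when given, `VT_fP = VT / f_P`
#'   is reported.
#' @return An object of class `logan_result`: `VT`, `intercept`, `t_star`,
#'   `n_points`, `r_squared`, `VT_fP`.
#' @export
logan_vt <- function(tissue, input_fn, t_star = 30, f_P = NULL) {
  stopifnot(inherits(tissue, "tac"))
  use <- which(tissue$times >= t_star)
  if (length(use) < 3L)
    stop(sprintf("logan_vt: only %d frames at or after t* = %g min (need 3)",
                 length(use), t_star))
  if (any(tissue$values[use] == 0))
    stop("logan_vt: tissue activity is zero at a used frame")
  tt <- c(0, tissue$times)
  vv <- c(0, tissue$values)
  cum_t <- cumsum(c(0, diff(tt) * (vv[-1] + vv[-length(vv)]) / 2))[-1]
  cum_p <- .input_cum_integral(input_fn, tissue$times)
  x <- cum_p[use] / tissue$values[use]
  y <- cum_t[use] / tissue$values[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(VT = slope, intercept = unname(fit$coefficients[1]),
                 t_star = t_star, n_points = length(use),
                 r_squared = r2,
                 VT_fP = if (is.null(f_P)) NA_real_ else slope / f_P),
            class = "logan_result")
}

#' @export
print.logan_result <- function(x, ...) {
  cat(sprintf(
    "<logan_result> VT = %.4g (t* = %g min, %d points, R^2 = %.4f)%s\n",
    x$VT, x$t_star, x$n_points, x$r_squared,
    if (is.na(x$VT_fP)) "" else sprintf(", VT/fP = %.4g", x$VT_fP)))
  invisible(x)
}

#' Sum of squared distances between two curves after a cutoff
#'
#' `sum_{t_i > t0} (a(t_i) - b(t_i))^2` over the sample times of `a`; `b`
#' is linearly interpolated onto `a`'s times when the grids differ.
#'
#' @param a,b [tac()]s.
#' @param t0 cutoff, minutes (default 10; strictly later samples count).
#' @return numeric, kBq^2/mL^2.
#' @export
ssd_after <- function(a, b, t0 = 10) {
  stopifnot(inherits(a, "tac"), inherits(b, "tac"))
  use <- a$times > t0
  if (!any(use))
    stop(sprintf("ssd_after: no samples after t0 = %g min", t0))
  bv <- if (length(b$times) == length(a$times) &&
            max(abs(b$times - a$times)) < 1e-9) b$values
        else tac_at(b, a$times)
  sum((a$values[use] - bv[use])^2)
}

#' Exact one-sided sign-test tail probability
#'
#' `P(X >= n_success)` for `X ~ Binomial(n_total, 1/2)`: the chance of at
#' least this many successes if either method were equally likely to win.
#'
#' @param n_success,n_total counts, `0 <= n_success <= n_total`.
#' @return probability in `[0, 1]`.
#' @export
sign_test_probability <- function(n_success, n_total) {
  if (n_success < 0 || n_total < 0 || n_success > n_total)
    stop("sign_test_probability: need 0 <= n_success <= n_total")
  stats::pbinom(n_success - 1, n_total, 0.5, lower.tail = FALSE)
}

#' Estimated-to-reference ratio summary
#'
#' Per-subject ratios `est / ref`, their mean and standard deviation, and
#' counts of subjects with `|ratio - 1|` below 5%, between 5 and 10%, and
#' above 10%.
#'
#' @param estimated,reference equal-length numeric vectors; `reference > 0`.
#' @return list: `ratios`, `mean`, `sd`, `n_lt5`, `n_5to10`, `n_gt10`.
#' @export
ratio_summary <- function(estimated, reference) {
  if (length(estimated) != length(reference))
    stop("ratio_summary: length mismatch")
  if (any(reference <= 0))
    stop("ratio_summary: reference values must be positive")
  r <- estimated / reference
  err <- abs(r - 1)
  list(ratios = r, mean = mean(r),
       sd = if (length(r) > 1L) stats::sd(r) else NA_real_,
       n_lt5 = sum(err < 0.05), n_5to10 = sum(err >= 0.05 & err <= 0.10),
       n_gt10 = sum(err > 0.10))
}

#' Descriptive group comparison of regional binding values
#'
#' Per-region means and standard deviations for two groups plus the percent
#' difference `(group2 - group1) / group1 * 100`. Purely descriptive; no
#' omnibus test is performed.
#'
#' @param group1,group2 numeric matrices, subjects x regions (vectors are
#'   treated as single-region columns).
#' @param region_names optional character vector of region names.
#' @return data.frame with columns `region`, `mean1`, `sd1`, `mean2`,
#'   `sd2`, `pct_diff`. Singleton groups report `NA` standard deviations.
#' @export
group_summary <- function(group1, group2, region_names = NULL) {
  g1 <- as.matrix(group1)
  g2 <- as.matrix(group2)
  if (nrow(g1) < 1L || nrow(g2) < 1L)
    stop("group_summary: both groups need at least one subject")
  if (ncol(g1) != ncol(g2))
    stop("group_summary: groups cover different region sets")
  nm <- if (is.null(region_names)) sprintf("region_%d", seq_len(ncol(g1)))
        else region_names
  sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  m1 <- colMeans(g1)
  m2 <- colMeans(g2)
  data.frame(region = nm, mean1 = m1, sd1 = apply(g1, 2, sd_or_na),
             mean2 = m2, sd2 = apply(g2, 2, sd_or_na),
             pct_diff = (m2 - m1) / m1 * 100, row.names = NULL)
}
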