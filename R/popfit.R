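same_grid <- function(a, b) {
  length(a$q) == length(b$q) && all(a$q == b$q)
}

require_sigma <- function(curve, what = "experimental curve") {
  if (!has_sigma(curve))
    stop(what, " has no error column; errors are required for chi-square fitting",
         call. = FALSE)
}

#' Align one curve onto another's q grid
#'
#' Linearly interpolates `curve_b` onto `curve_a`'s grid. Errors are
#' propagated through the interpolation weight `t` between bracketing points
#' as `sigma' = sqrt((1-t)^2 sigma_l^2 + t^2 sigma_r^2)`. Points of `curve_a`
#' outside `curve_b`'s range are dropped from both (reported via a message).
#' A warning is issued when the grids differ by more than `tol` anywhere,
#' since interpolation over large gaps ignores error correlation.
#'
#' @param curve_a reference [sans_curve()] (its grid is kept).
#' @param curve_b curve to interpolate.
#' @param tol grid-discrepancy warning threshold (1/Angstrom, default 1e-4).
#' @return list with elements `a` (possibly trimmed) and `b` (interpolated),
#'   both on the common grid.
#' @export
align_to_grid <- function(curve_a, curve_b, tol = 1e-4) {
  inside <- curve_a$q >= min(curve_b$q) & curve_a$q <= max(curve_b$q)
  if (!any(inside)) stop("curve q ranges are disjoint", call. = FALSE)
  if (!all(inside))
    message("align_to_grid: dropped ", sum(!inside),
            " point(s) outside the overlapping q range")
  qa <- curve_a$q[inside]
  if (same_grid(curve_a, curve_b) && all(inside)) {
    return(list(a = curve_a, b = curve_b))
  }
  gap <- vapply(qa, function(q) min(abs(curve_b$q - q)), 0)
  if (max(gap) > tol)
    warning("grid discrepancy up to ", format(max(gap), digits = 3),
            " 1/A exceeds ", tol, "; interpolating anyway", call. = FALSE)
  idx <- findInterval(qa, curve_b$q, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(curve_b$q) - 1L)
  ql <- curve_b$q[idx]; qr <- curve_b$q[idx + 1L]
  t <- (qa - ql) / (qr - ql)
  I_b <- (1 - t) * curve_b$I[idx] + t * curve_b$I[idx + 1L]
  sig_b <- if (has_sigma(curve_b)) {
    sqrt((1 - t)^2 * curve_b$sigma[idx]^2 + t^2 * curve_b$sigma[idx + 1L]^2)
  } else NULL
  a <- sans_curve(qa, curve_a$I[inside],
                  if (has_sigma(curve_a)) curve_a$sigma[inside] else NULL,
                  label = curve_label(curve_a))
  b <- sans_curve(qa, I_b, sig_b, label = curve_label(curve_b))
  list(a = a, b = b)
}

#' Optimal intensity scale factor
#'
#' Closed-form minimizer of the error-weighted squared residual between a
#' scaled model curve and an experimental curve:
#' `f = sum(M I / sigma^2) / sum(M^2 / sigma^2)`.
#'
#' @param model_I model [sans_curve()].
#' @param exp experimental [sans_curve()] with errors, same grid.
#' @return scale factor `f`.
#' @export
optimal_scale <- function(model_I, exp) {
  if (!same_grid(model_I, exp)) stop("curves are not on a common grid", call. = FALSE)
  require_sigma(exp)
  M <- model_I$I
  if (all(M == 0)) stop("all-zero model curve", call. = FALSE)
  w <- 1 / exp$sigma^2
  sum(M * exp$I * w) / sum(M^2 * w)
}

#' Reduced chi-square of a scaled model against data
#'
#' `chi2 = sum_i (f M_i - I_exp_i)^2 / (Nq sigma_i^2)`: the mean squared
#' error-normalized residual. No constant background term is included.
#'
#' @param model_I model [sans_curve()].
#' @param exp experimental [sans_curve()] with errors, same grid.
#' @param f scale factor.
#' @return chi-square value (>= 0).
#' @export
chi2 <- function(model_I, exp, f) {
  if (!same_grid(model_I, exp)) stop("curves are not on a common grid", call. = FALSE)
  require_sigma(exp)
  mean(((f * model_I$I - exp$I) / exp$sigma)^2)
}

#' Fit an experimental curve with a two-state mixture
#'
#' Scans the state-1 weight `w1` over a uniform grid in `[0, 1]`
#' (`w2 = 1 - w1`); at each weight the scale `f` is set by [optimal_scale()]
#' and the fit scored by [chi2()]. Returns the minimizing weight with the
#' full profile. Ties are resolved toward larger `w1`.
#'
#' @param I1,I2 theoretical state curves on the experimental grid.
#' @param exp experimental [sans_curve()] with errors.
#' @param grid_step weight-grid step (default 0.01).
#' @return object of class `two_state_fit` with fields `w1`, `w2`, `f`,
#'   `chi2`, `residuals` (tibble `q`, `residual`, error-normalized), and
#'   `profile` (tibble `w1`, `f`, `chi2`).
#' @export
two_state_fit <- function(I1, I2, exp, grid_step = 0.01) {
  if (!same_grid(I1, exp) || !same_grid(I2, exp))
    stop("align state curves to the experimental grid first", call. = FALSE)
  require_sigma(exp)
  if (max(abs(I1$I - I2$I)) <= 1e-12 * max(abs(I1$I)))
    warning("state curves are identical; weight profile is flat", call. = FALSE)
  w_grid <- seq(0, 1, by = grid_step)
  if (w_grid[length(w_grid)] != 1) w_grid <- c(w_grid, 1)
  prof <- purrr::map_dfr(w_grid, function(w) {
    M <- sans_curve(exp$q, w * I1$I + (1 - w) * I2$I)
    f <- optimal_scale(M, exp)
    tibble::tibble(w1 = w, f = f, chi2 = chi2(M, exp, f))
  })
  best <- max(which(prof$chi2 == min(prof$chi2)))
  w1 <- prof$w1[best]; f <- prof$f[best]
  M <- w1 * I1$I + (1 - w1) * I2$I
  structure(list(w1 = w1, w2 = 1 - w1, f = f, chi2 = prof$chi2[best],
                 residuals = tibble::tibble(q = exp$q,
                                            residual = (f * M - exp$I) / exp$sigma),
                 profile = prof),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> w1 = %.2f, w2 = %.2f, f = %.4g, chi2 = %.3f\n",
              x$w1, x$w2, x$f, x$chi2))
  invisible(x)
}

#' @export
tidy.two_state_fit <- function(x, ...) x$profile

#' @export
glance.two_state_fit <- function(x, ...) {
  tibble::tibble(w1 = x$w1, w2 = x$w2, f = x$f, chi2 = x$chi2)
}

#' @export
autoplot.two_state_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$w1, y = .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$w1, linetype = 2) +
    ggplot2::labs(x = expression(w[1]), y = expression(chi^2))
}

#' Average scale factor across two conditions
#'
#' Fits each condition with [two_state_fit()] and returns the arithmetic mean
#' of the two best-fit scale factors. This is the scale used for the
#' difference-curve fit.
#'
#' @param I1,I2 theoretical state curves on the experimental grid.
#' @param exp_a,exp_b experimental curves for the two conditions.
#' @param grid_step weight-grid step.
#' @return mean scale factor.
#' @export
compute_f_bar <- function(I1, I2, exp_a, exp_b, grid_step = 0.01) {
  fa <- two_state_fit(I1, I2, exp_a, grid_step)$f
  fb <- two_state_fit(I1, I2, exp_b, grid_step)$f
  (fa + fb) / 2
}

#' Fit the between-condition difference curve for a population shift
#'
#' Models the experimental intensity difference `exp_a - exp_b` as
#' `f_bar * delta_w * (I1 - I2)` and scans the population shift `delta_w`
#' over `[-1, 1]`; the fit quality is
#' `chi2_delta = sum_i (f_bar delta_w (I1_i - I2_i) - (Ia_i - Ib_i))^2 /
#' (Nq (sigma_a_i^2 + sigma_b_i^2))`. Ties are resolved toward the smallest
#' `|delta_w|`.
#'
#' @param I1,I2 theoretical state curves on the common experimental grid.
#' @param exp_a,exp_b experimental curves on a common grid (use
#'   [align_to_grid()] first), both with errors.
#' @param f_bar scale factor, typically from [compute_f_bar()].
#' @param grid_step shift-grid step (default 0.01).
#' @return object of class `difference_fit` with fields `delta_w`, `f_bar`,
#'   `chi2_delta`, `residuals`, `profile` (tibble `delta_w`, `chi2_delta`).
#' @export
difference_fit <- function(I1, I2, exp_a, exp_b, f_bar, grid_step = 0.01) {
  if (!same_grid(exp_a, exp_b) || !same_grid(I1, exp_a) || !same_grid(I2, exp_a))
    stop("all curves must share the experimental grid", call. = FALSE)
  require_sigma(exp_a); require_sigma(exp_b)
  stopifnot(f_bar > 0)
  dI <- I1$I - I2$I
  if (max(abs(dI)) <= 1e-12 * max(abs(I1$I)))
    stop("state curves are identical: difference fit is degenerate", call. = FALSE)
  d_exp <- exp_a$I - exp_b$I
  v <- exp_a$sigma^2 + exp_b$sigma^2
  dw_grid <- seq(-1, 1, by = grid_step)
  chi <- vapply(dw_grid, function(dw) mean((f_bar * dw * dI - d_exp)^2 / v), 0)
  prof <- tibble::tibble(delta_w = dw_grid, chi2_delta = chi)
  cand <- which(chi == min(chi))
  best <- cand[which.min(abs(dw_grid[cand]))]
  dw <- dw_grid[best]
  structure(list(delta_w = dw, f_bar = f_bar, chi2_delta = chi[best],
                 residuals = tibble::tibble(
                   q = exp_a$q,
                   residual = (f_bar * dw * dI - d_exp) / sqrt(v)),
                 profile = prof),
            class = "difference_fit")
}

#' @export
print.difference_fit <- function(x, ...) {
  cat(sprintf("<difference_fit> delta_w = %+.2f, f_bar = %.4g, chi2_delta = %.3f\n",
              x$delta_w, x$f_bar, x$chi2_delta))
  invisible(x)
}

#' @export
tidy.difference_fit <- function(x, ...) x$profile

#' @export
glance.difference_fit <- function(x, ...) {
  tibble::tibble(delta_w = x$delta_w, f_bar = x$f_bar,
                 chi2_delta = x$chi2_delta)
}

#' @export
autoplot.difference_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$delta_w, y = .data$chi2_delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$delta_w, linetype = 2) +
    ggplot2::labs(x = expression(delta * w), y = expression(chi[Delta * I]^2))
}
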