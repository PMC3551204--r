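#' Gaussian belief about the index among survivors
#'
#' The filtering state: conditional mean `m` and variance `gamma` of the
#' physiological index at age `t` among subjects still alive.
#'
#' @param m conditional mean (index units), finite.
#' @param gamma conditional variance (index units squared), >= 0.
#' @param t age in years.
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(m, gamma, t) {
  if (!is.finite(m)) stop("belief mean must be finite")
  if (!is.finite(gamma) || gamma < 0) stop("belief variance must be finite and >= 0")
  structure(list(m = m, gamma = gamma, t = t), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("gaussian_belief: m = %.6g, gamma = %.6g at age %g\n",
              x$m, x$gamma, x$t))
  invisible(x)
}

# Right-hand side of the coupled mean/variance dynamics among survivors.
# dm/dt: homeostatic pull toward f1 plus mortality-selection pull toward f0.
# dgamma/dt: linear-dynamics expansion plus Gaussian-conditioning shrinkage.
spm_mean_rhs <- function(t, m, gamma, p) {
  a <- eval_adaptive_capacity(t, p)
  Q <- eval_quadratic_term(t, p)
  f0 <- eval_norm(t, p)
  f1 <- eval_setpoint(t, p)
  c(dm = a * (m - f1) - 2 * gamma * Q * (m - f0),
    dgamma = 2 * a * gamma + p$sigma1^2 - 2 * Q * gamma^2)
}

#' Integrate the survivor mean-trajectory dynamics
#'
#' Solves the coupled ordinary differential equations for the mean
#' \eqn{m(t)} and variance \eqn{\gamma(t)} of the index among survivors,
#' \deqn{dm/dt = a(t)(m - f_1(t)) - 2\gamma(t) Q(t)(m - f_0(t)),}
#' \deqn{d\gamma/dt = 2 a(t) \gamma + \sigma_1^2 - 2 Q(t) \gamma^2,}
#' with a fixed-step classical Runge-Kutta (4th order) scheme. The mean
#' equation contains the two feedback mechanisms shaping population-average
#' trajectories: homeostatic adaptation toward the allostatic set point
#' f1(t), and mortality selection pulling survivors toward the norm f0(t).
#'
#' @param p an [spm_parameters()] object.
#' @param t0,t1 start and end ages (years), `t0 < t1`.
#' @param m0 initial mean (index units).
#' @param gamma0 initial variance, >= 0.
#' @param step integration step in years (<= 0.25 recommended; output is
#'   reported at every step).
#' @return A data frame with columns `t`, `m`, `gamma`.
#' @export
integrate_mean_trajectory <- function(p, t0, m0, gamma0, t1, step = 0.25) {
  stopifnot(t0 < t1, gamma0 >= 0, step > 0)
  n <- ceiling((t1 - t0) / step)
  h <- (t1 - t0) / n
  t <- numeric(n + 1); m <- numeric(n + 1); g <- numeric(n + 1)
  t[1] <- t0; m[1] <- m0; g[1] <- gamma0
  for (i in seq_len(n)) {
    ti <- t[i]; yi <- c(m[i], g[i])
    k1 <- spm_mean_rhs(ti, yi[1], yi[2], p)
    k2 <- spm_mean_rhs(ti + h / 2, yi[1] + h / 2 * k1[1], yi[2] + h / 2 * k1[2], p)
    k3 <- spm_mean_rhs(ti + h / 2, yi[1] + h / 2 * k2[1], yi[2] + h / 2 * k2[2], p)
    k4 <- spm_mean_rhs(ti + h, yi[1] + h * k3[1], yi[2] + h * k3[2], p)
    y <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)))
      stop(sprintf("mean-trajectory integration blew up at age %.3f", ti + h))
    t[i + 1] <- t0 + i * h
    m[i + 1] <- y[1]
    g[i + 1] <- max(y[2], 0)  # guard tiny negative overshoot near gamma = 0
  }
  data.frame(t = t, m = m, gamma = g)
}
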