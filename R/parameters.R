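#' Parameter set of the quadratic-hazard stochastic process model
#'
#' Bundles the free parameters of the one-index model together with the
#' fixed cubic coefficients of the physiological norm trajectory f0(t).
#' The model components are
#' \itemize{
#'   \item adaptive capacity (negative-feedback coefficient)
#'     \eqn{a(t) = a_Y + b_Y t}, required negative on the age window;
#'   \item diffusion scale \eqn{B(t) = \sigma_1}, constant;
#'   \item initial-value spread \eqn{\sigma_0} (standard deviation of the
#'     index at the first observation);
#'   \item quadratic hazard term \eqn{Q(t) = a_Q + b_Q t \ge 0};
#'   \item Gompertz baseline hazard
#'     \eqn{\mu_0(t) = a_{\mu 0} \exp(b_{\mu 0} t) \ge 0};
#'   \item allostatic offset \eqn{\Delta f_0(t) = a_{f0d} + b_{f0d} t},
#'     so that the set point is \eqn{f_1(t) = f_0(t) + \Delta f_0(t)};
#'   \item the norm \eqn{f_0(t)}, a raw cubic in age (years, not centred)
#'     with coefficients stored lowest degree first.
#' }
#'
#' @param a_Y,b_Y intercept (1/year) and slope (1/year^2) of the adaptive
#'   capacity line.
#' @param sigma1 diffusion scale (index units per sqrt-year), >= 0.
#' @param sigma0 standard deviation of the initial index value (index
#'   units), >= 0.
#' @param a_Q,b_Q intercept and slope of the quadratic hazard term.
#' @param a_mu0,b_mu0 level (1/year) and exponent slope (1/year) of the
#'   Gompertz baseline hazard.
#' @param a_f0d,b_f0d intercept (index units) and slope (units/year) of
#'   the allostatic offset.
#' @param f0_coeffs numeric vector of 4 cubic coefficients of f0(t),
#'   lowest degree first; fixed during likelihood maximisation.
#' @param age_window numeric length-2 vector, ages (years) over which the
#'   shape constraints are enforced.
#' @return An object of class `spm_parameters`.
#' @seealso [check_spm_parameters()], [eval_hazard()],
#'   [integrate_mean_trajectory()]
#' @export
spm_parameters <- function(a_Y, b_Y = 0, sigma1, sigma0,
                           a_Q, b_Q = 0, a_mu0, b_mu0,
                           a_f0d = 0, b_f0d = 0,
                           f0_coeffs, age_window = c(40, 110)) {
  stopifnot(length(f0_coeffs) == 4L, length(age_window) == 2L,
            age_window[1] < age_window[2])
  p <- list(a_Y = a_Y, b_Y = b_Y, sigma1 = sigma1, sigma0 = sigma0,
            a_Q = a_Q, b_Q = b_Q, a_mu0 = a_mu0, b_mu0 = b_mu0,
            a_f0d = a_f0d, b_f0d = b_f0d,
            f0_coeffs = as.numeric(f0_coeffs),
            age_window = as.numeric(age_window))
  for (nm in setdiff(names(p), c("f0_coeffs", "age_window")))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  structure(p, class = "spm_parameters")
}

#' @export
print.spm_parameters <- function(x, ...) {
  cat("Stochastic process model parameters\n")
  cat(sprintf("  a(t)   = %+.5g %+.5g t   (adaptive capacity)\n", x$a_Y, x$b_Y))
  cat(sprintf("  Q(t)   = %+.4g %+.4g t   (quadratic hazard)\n", x$a_Q, x$b_Q))
  cat(sprintf("  mu0(t) = %.4g exp(%.4g t) (baseline hazard)\n", x$a_mu0, x$b_mu0))
  cat(sprintf("  Df0(t) = %+.5g %+.5g t   (allostatic offset)\n", x$a_f0d, x$b_f0d))
  cat(sprintf("  sigma1 = %.5g, sigma0 = %.5g\n", x$sigma1, x$sigma0))
  cat(sprintf("  f0(t)  = cubic, coefficients (low->high): %s\n",
              paste(signif(x$f0_coeffs, 6), collapse = ", ")))
  cat(sprintf("  age window [%g, %g]\n", x$age_window[1], x$age_window[2]))
  invisible(x)
}

#' Evaluate the adaptive capacity line a(t)
#'
#' @param t age in years (vectorised).
#' @param p an [spm_parameters()] object.
#' @return The feedback rate \eqn{a_Y + b_Y t} (1/year). Negative values
#'   mean restoring feedback toward the set point.
#' @export
eval_adaptive_capacity <- function(t, p) p$a_Y + p$b_Y * t

#' Evaluate the quadratic hazard coefficient Q(t)
#' @inheritParams eval_adaptive_capacity
#' @return \eqn{a_Q + b_Q t}.
#' @export
eval_quadratic_term <- function(t, p) p$a_Q + p$b_Q * t

#' Evaluate the Gompertz baseline hazard mu0(t)
#' @inheritParams eval_adaptive_capacity
#' @return \eqn{a_{\mu 0} \exp(b_{\mu 0} t)} (1/year).
#' @export
eval_baseline_hazard <- function(t, p) p$a_mu0 * exp(p$b_mu0 * t)

#' Evaluate the physiological norm f0(t)
#' @inheritParams eval_adaptive_capacity
#' @return The cubic \eqn{c_0 + c_1 t + c_2 t^2 + c_3 t^3} (index units).
#' @export
eval_norm <- function(t, p) {
  cf <- p$f0_coeffs
  cf[1] + t * (cf[2] + t * (cf[3] + t * cf[4]))
}

#' Evaluate the allostatic set point f1(t) = f0(t) + Delta f0(t)
#' @inheritParams eval_adaptive_capacity
#' @return Index units.
#' @export
eval_setpoint <- function(t, p) eval_norm(t, p) + p$a_f0d + p$b_f0d * t

#' Conditional mortality rate given the index value
#'
#' The hazard is minimised when the index sits on the norm trajectory:
#' \eqn{\mu(t, y) = \mu_0(t) + Q(t) (y - f_0(t))^2}.
#'
#' @param t age in years.
#' @param y index value.
#' @param p an [spm_parameters()] object.
#' @return Mortality rate (1/year). Signals an error if Q(t) or mu0(t)
#'   is negative at `t`.
#' @export
eval_hazard <- function(t, y, p) {
  Q <- eval_quadratic_term(t, p)
  mu0 <- eval_baseline_hazard(t, p)
  if (any(Q < 0)) stop("Q(t) < 0 at age ", t[which(Q < 0)[1]])
  if (any(mu0 < 0)) stop("mu0(t) < 0 at age ", t[which(mu0 < 0)[1]])
  mu0 + Q * (y - eval_norm(t, p))^2
}

#' Default plausibility bounds for the set point f1(t), by index role
#'
#' @return Named list of length-2 numeric vectors (lower, upper), in the
#'   natural units of each index: BMI (kg/m^2), diastolic blood pressure
#'   (mmHg), serum cholesterol (mg/dl), ventricular rate (bpm).
#' @export
default_f1_bounds <- function() {
  list(BMI = c(15, 45), DBP = c(50, 120), SCH = c(120, 350), VR = c(40, 120))
}

#' Check the shape constraints of a parameter set
#'
#' Verifies, on a dense age grid over the age window, that a(t) < 0,
#' Q(t) >= 0, mu0(t) >= 0, sigma0 >= 0, sigma1 >= 0 and (optionally) that
#' f1(t) lies within per-index plausibility bounds.
#'
#' @param p an [spm_parameters()] object.
#' @param f1_bounds optional length-2 numeric vector (lower, upper) for
#'   f1(t); `NULL` skips the bound check.
#' @param grid_step spacing (years) of the checking grid.
#' @return Character vector of violated constraint descriptions;
#'   `character(0)` if the set is feasible.
#' @export
check_spm_parameters <- function(p, f1_bounds = NULL, grid_step = 0.5) {
  tt <- seq(p$age_window[1], p$age_window[2], by = grid_step)
  bad <- character(0)
  a <- eval_adaptive_capacity(tt, p)
  if (any(a >= 0))
    bad <- c(bad, sprintf("a(t) >= 0 at age %g (adaptive capacity must be negative)",
                          tt[which(a >= 0)[1]]))
  Q <- eval_quadratic_term(tt, p)
  if (any(Q < 0))
    bad <- c(bad, sprintf("Q(t) < 0 at age %g", tt[which(Q < 0)[1]]))
  if (p$a_mu0 < 0) bad <- c(bad, "a_mu0 < 0 (baseline hazard negative)")
  if (p$sigma0 < 0) bad <- c(bad, "sigma0 < 0")
  if (p$sigma1 < 0) bad <- c(bad, "sigma1 < 0")
  if (!is.null(f1_bounds)) {
    f1 <- eval_setpoint(tt, p)
    if (any(f1 < f1_bounds[1]))
      bad <- c(bad, sprintf("f1(t) < %g at age %g", f1_bounds[1],
                            tt[which(f1 < f1_bounds[1])[1]]))
    if (any(f1 > f1_bounds[2]))
      bad <- c(bad, sprintf("f1(t) > %g at age %g", f1_bounds[2],
                            tt[which(f1 > f1_bounds[2])[1]]))
  }
  bad
}

# flat free-parameter vector <-> spm_parameters (f0 and window carried along)
spm_par_names <- function() {
  c("a_Y", "b_Y", "sigma1", "sigma0", "a_Q", "b_Q",
    "a_mu0", "b_mu0", "a_f0d", "b_f0d")
}

spm_par_vector <- function(p) unlist(p[spm_par_names()])

spm_par_update <- function(p, theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 10L)
  p[spm_par_names()] <- as.list(theta)
  p
}

#' Write / read a parameter set as a flat key-value config file
#'
#' Serialises all fields under their canonical names. The format is
#' chosen by file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param p an [spm_parameters()] object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_spm_parameters()` returns `path` invisibly;
#'   `read_spm_parameters()` returns an [spm_parameters()] object.
#' @export
write_spm_parameters <- function(p, path) {
  x <- unclass(p)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension for '", path, "' (use .yaml or .json)")
  invisible(path)
}

#' @rdname write_spm_parameters
#' @export
read_spm_parameters <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unsupported extension for '", path, "'")
  do.call(spm_parameters, x)
}
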