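# Multiplicative-error likelihood and its analytic noise-scale profile.

#' Penalty value returned for infeasible evaluations
#'
#' A large finite value substituted for the objective when a trajectory is
#' infeasible (non-positive predictions or integration failure), so bounded
#' optimization can continue past pathological parameter regions. A fit whose
#' best value equals the penalty is flagged failed.
#'
#' @return `1e10`.
#' @export
grn_penalty <- function() 1e10

#' Negative log-likelihood of the multiplicative error model
#'
#' For observations `y` with model predictions `x` under
#' `y_i = x_i (1 + sigma Z_i)`, `Z ~ N(0,1)`, the negative log-likelihood is
#' (up to an additive constant)
#' `n log(sigma) + sum_i log(x_i) + (1 / (2 sigma^2)) sum_i ((y_i - x_i) / x_i)^2`.
#'
#' @param x positive model predictions.
#' @param y observations, same length.
#' @param sigma positive noise scale.
#' @return The negative log-likelihood, or [grn_penalty()] if any prediction
#'   is non-positive or non-finite (an infeasible trajectory).
#' @export
#' @examples
#' negative_log_likelihood(x = 1, y = 2, sigma = 1) # 0.5
negative_log_likelihood <- function(x, y, sigma) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have the same length.")
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (n == 0) abort("at least one observation is required.")
  if (any(!is.finite(x)) || any(x <= 0)) return(grn_penalty())
  n * log(sigma) + sum(log(x)) + sum(((y - x) / x)^2) / (2 * sigma^2)
}

#' Analytically profiled noise scale
#'
#' For fixed predictions the likelihood is maximized over `sigma` in closed
#' form: `sigma_hat^2 = (1/n) sum_i ((y_i - x_i) / x_i)^2`, floored at
#' `sigma_floor` to keep the profiled objective finite for perfect fits.
#'
#' @param x positive model predictions.
#' @param y observations.
#' @param sigma_floor lower bound on the returned scale.
#' @return The profiled noise scale `sigma_hat`.
#' @export
#' @examples
#' profile_sigma(x = c(1, 1), y = c(1.1, 0.9)) # 0.1
profile_sigma <- function(x, y, sigma_floor = 1e-6) {
  n <- length(x)
  if (length(y) != n || n == 0) abort("`x` and `y` must be nonempty and equal length.")
  max(sigma_floor, sqrt(mean(((y - x) / x)^2)))
}

# Profiled objective used by the optimizer.
profiled_nll <- function(x, y, sigma_floor = 1e-6) {
  if (any(!is.finite(x)) || any(x <= 0)) return(grn_penalty())
  s <- profile_sigma(x, y, sigma_floor)
  negative_log_likelihood(x, y, s)
}
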