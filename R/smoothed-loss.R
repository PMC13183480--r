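#' Check (quantile) loss
#'
#' `rho_tau(u) = (tau - 1(u < 0)) * u`: the asymmetric absolute loss whose
#' population minimizer is the level-`tau` quantile.
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return nonnegative numeric vector.
#' @export
check_loss <- function(u, tau) {
  stopifnot(tau > 0, tau < 1)
  (tau - (u < 0)) * u
}

#' Generalized Huber smoothing of the check loss
#'
#' Differentiable surrogate for the check loss: linear with slope `tau - 1`
#' below the knot `(tau - 1) * nu`, quadratic `u^2 / (2 nu)` between the
#' knots, and linear with slope `tau` above `tau * nu`. Value and derivative
#' are continuous at the knots, and the surrogate converges uniformly to the
#' check loss as `nu -> 0`.
#'
#' @param u numeric vector.
#' @param tau quantile level in (0, 1).
#' @param nu positive smoothing parameter.
#' @return list with numeric vectors `value` and `deriv`.
#' @export
gen_huber <- function(u, tau, nu) {
  stopifnot(tau > 0, tau < 1)
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) || nu <= 0) {
    stop("invalid smoothing: nu must be a positive scalar")
  }
  # on every piece the value equals u*H' - nu*H'^2/2 with the derivative
  # clamped to [tau - 1, tau]
  deriv <- pmax(tau - 1, pmin(tau, u / nu))
  list(value = u * deriv - nu * deriv^2 / 2, deriv = deriv)
}

#' Uniform bound on the smoothing gap
#'
#' Returns `nu * max(tau, 1 - tau)^2 / 2`, an upper bound on
#' `sup_u |H_{tau,nu}(u) - rho_tau(u)|`. The supremum is attained at the
#' outer knot of the longer linear piece.
#'
#' @inheritParams gen_huber
#' @return nonnegative scalar.
#' @export
smoothing_gap_bound <- function(tau, nu) {
  stopifnot(tau > 0, tau < 1, nu > 0)
  nu * max(tau, 1 - tau)^2 / 2
}

#' Geometric smoothing schedule
#'
#' Generates the zero-convergent sequence of smoothing parameters
#' `nu0, decay * nu0, decay^2 * nu0, ...`, truncated at `nu_min` (the last
#' element is exactly `nu_min`). The estimator anneals the generalized Huber
#' approximation along this sequence, warm-starting each stage from the
#' previous one.
#'
#' @param nu0 initial smoothing parameter (> 0).
#' @param decay multiplicative decay per stage, in (0, 1).
#' @param nu_min smallest smoothing parameter (> 0, <= `nu0`).
#' @return strictly decreasing positive numeric vector ending at `nu_min`.
#' @export
smoothing_schedule <- function(nu0 = 1, decay = 0.1, nu_min = 1e-4) {
  stopifnot(nu0 > 0, decay > 0, decay < 1, nu_min > 0)
  if (nu_min >= nu0) {
    return(nu_min)
  }
  k <- ceiling(log(nu_min / nu0) / log(decay))
  nus <- nu0 * decay^(0:k)
  nus[nus < nu_min] <- nu_min
  nus[length(nus)] <- nu_min
  unique(nus)
}
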