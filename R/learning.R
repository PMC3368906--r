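#' Prior estimate of the host encounter rate
#'
#' Females start life with a prior estimate fixed to the midpoint between
#' their lowest possible instantaneous encounter rate (0, while travelling
#' between patches) and their highest (`1/t1`, the reciprocal of the time
#' to find the first host on a fresh patch).
#'
#' @param t1 Time to first host on a fresh patch, time steps (`>= 1`).
#' @return `mu0 = (0 + 1/t1) / 2`, hosts per time step.
#' @examples
#' prior_estimate(5)  # 0.1
#' @export
prior_estimate <- function(t1) {
  if (!is.numeric(t1) || length(t1) != 1L || t1 < 1)
    stop("'t1' must be a single value >= 1")
  (0 + 1 / t1) / 2
}

#' Linear-operator update of the encounter-rate estimate
#'
#' At each time step the overall estimate is updated from the current
#' instantaneous rate by the linear operator
#' `mu_new = g3 * mu_prev + (1 - g3) * lambda_now`.  The memory factor
#' `g3` gives the weight of the past: `g3 = 1` never updates, `g3 = 0` is
#' memoryless.
#'
#' @param mu_prev Previous overall estimate (hosts per time step).
#' @param lambda_now Current instantaneous encounter rate (`>= 0`).
#' @param g3 Memory factor in `[0, 1]`.
#' @return Updated estimate.
#' @examples
#' update_estimate(0.1, 0.5, g3 = 0.8)  # 0.18
#' @export
update_estimate <- function(mu_prev, lambda_now, g3) {
  if (!is.numeric(g3) || any(g3 < 0) || any(g3 > 1))
    stop("'g3' must be in [0, 1]")
  if (any(lambda_now < 0)) stop("'lambda_now' must be non-negative")
  g3 * mu_prev + (1 - g3) * lambda_now
}

#' Current instantaneous host encounter rate
#'
#' The rate observed this time step: 0 while travelling between patches;
#' on a patch, the per-step gain increment, capped at the maximal rate
#' `1/t1` so the upper anchor of the estimate's domain is attainable.
#'
#' @param on_patch Logical: is the female on a host patch this step?
#' @param per_step_gain Gain increment accrued this step (`>= 0`).
#' @param rate_max Maximal instantaneous rate, `1/t1`.
#' @return Rate `lambda` in `[0, rate_max]`.
#' @export
current_lambda <- function(on_patch, per_step_gain, rate_max) {
  if (any(per_step_gain < 0)) stop("'per_step_gain' must be non-negative")
  if (!on_patch) return(0)
  min(per_step_gain, rate_max)
}

#' Allocation position targeted by the learned estimate
#'
#' The higher the estimated host encounter rate, the more a female invests
#' in egg load at the expense of longevity.  The estimate
#' `mu` in `[0, rate_max]` is mapped linearly onto the plasticity interval
#' `[hi, lo]`: `mu = 0` targets `hi` (the longevity end), `mu = rate_max`
#' targets `lo` (the egg end); estimates above `rate_max` clamp to `lo`.
#'
#' @param mu Current overall estimate (`>= 0`).
#' @param rate_max Maximal instantaneous rate, `1/t1`.
#' @param bounds Numeric `c(lo, hi)` from [plasticity_bounds()].
#' @return Target position in longevity units, within `bounds`.
#' @examples
#' allocation_target(0.1, rate_max = 0.2, bounds = c(400, 600))  # 500
#' @export
allocation_target <- function(mu, rate_max, bounds) {
  lo <- bounds[[1]]; hi <- bounds[[2]]
  if (lo > hi) stop("'bounds' must satisfy lo <= hi")
  if (mu < 0) stop("'mu' must be non-negative")
  f <- min(mu / rate_max, 1)
  hi - f * (hi - lo)
}
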