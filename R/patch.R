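#' Within-patch progeny gain curve
#'
#' A foraging female attacking hosts on a depletable patch produces a
#' cumulative number of progeny that saturates with time on the patch:
#' `N(t) = n0 * (1 - exp(-alpha * t))`, where `n0` is the initial number
#' of hosts in the patch and `alpha` the depletion rate per time step.
#' The saturating-exponential form is the standard gain/fitness function
#' for depletable patches; both the shape parameter and the curve object
#' itself are pluggable.
#'
#' @param n0 Initial number of hosts in the patch (> 0).
#' @param alpha Depletion rate per time step (> 0, default 0.01).
#' @return An object of class `"gain_curve"`.
#' @examples
#' gain_curve(100)
#' @export
gain_curve <- function(n0, alpha = 0.01) {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  structure(list(n0 = as.numeric(n0), alpha = as.numeric(alpha)),
            class = "gain_curve")
}

#' @export
print.gain_curve <- function(x, ...) {
  cat(sprintf("Patch gain curve: N(t) = %g * (1 - exp(-%g t))\n",
              x$n0, x$alpha))
  invisible(x)
}

#' Cumulative progeny gain on a patch
#'
#' @param curve A [gain_curve()].
#' @param t Time on patch, in time steps (vectorized, `t >= 0`).
#' @return Cumulative (real-valued) progeny at time `t`; 0 at `t = 0`,
#'   strictly increasing, asymptote `n0`.
#' @examples
#' cumulative_gain(gain_curve(100), 100)  # 100 * (1 - exp(-1))
#' @export
cumulative_gain <- function(curve, t) {
  stopifnot(inherits(curve, "gain_curve"))
  if (any(t < 0)) stop("'t' must be non-negative")
  curve$n0 * (1 - exp(-curve$alpha * t))
}

#' Instantaneous rate of progeny production
#'
#' Derivative of [cumulative_gain()]: `n0 * alpha * exp(-alpha * t)`,
#' strictly decreasing with time on the patch (patch depletion).
#'
#' @inheritParams cumulative_gain
#' @return Progeny per time step at time `t` (vectorized).
#' @export
instantaneous_rate <- function(curve, t) {
  stopifnot(inherits(curve, "gain_curve"))
  if (any(t < 0)) stop("'t' must be non-negative")
  curve$n0 * curve$alpha * exp(-curve$alpha * t)
}

#' Marginal-value-theorem patch leaving time
#'
#' The optimal residence time on a patch: the first (integer) time step at
#' which the local rate of progeny production falls to or below the
#' average rate of gain in the environment as a whole,
#' `N(t) / (t + travel_time)`.  Within one time step this is the argmax
#' over integer residence times of `N(t) / (t + travel_time)`.  For the
#' saturating-exponential gain the crossing point is independent of `n0`.
#'
#' @param curve A [gain_curve()].
#' @param travel_time Travel time between patches, in time steps (> 0).
#' @return Integer leaving time `t_star >= 1`.
#' @examples
#' mvt_leaving_time(gain_curve(100), travel_time = 100)
#' @export
mvt_leaving_time <- function(curve, travel_time) {
  stopifnot(inherits(curve, "gain_curve"))
  if (!is.numeric(travel_time) || length(travel_time) != 1L || travel_time <= 0)
    stop("'travel_time' must be a single positive number")
  # rate(t) <= N(t)/(t+T)  <=>  alpha*exp(-alpha*t)*(t+T) <= 1 - exp(-alpha*t);
  # n0 cancels.  The left side decreases, right side increases, so scan.
  a <- curve$alpha
  t <- 1L
  repeat {
    e <- exp(-a * t)
    if (a * e * (t + travel_time) <= 1 - e) return(t)
    t <- t + 1L
    if (t > 10000000L) stop("no MVT crossing found (degenerate gain curve)")
  }
}

#' Remaining-lifespan patch leaving rule
#'
#' Once a female has reached the MVT leaving time she leaves the patch only
#' if her remaining lifespan suffices to reach the next patch; otherwise
#' she remains and the rule is re-evaluated every subsequent time step.
#' This dynamic modifier approaches the prediction of a dynamic version of
#' the marginal value theorem.
#'
#' @param t_on_patch Time already spent on the current patch (time steps).
#' @param t_star MVT leaving time from [mvt_leaving_time()].
#' @param remaining_lifespan Time steps of life remaining.
#' @param travel_time Time steps needed to reach the next patch.
#' @return `TRUE` to leave, `FALSE` to stay.
#' @export
dynamic_leave_decision <- function(t_on_patch, t_star, remaining_lifespan,
                                   travel_time) {
  stopifnot(t_on_patch >= 0, t_star >= 0, remaining_lifespan >= 0,
            travel_time >= 0)
  t_on_patch >= t_star && remaining_lifespan >= travel_time
}

#' Time to find the first host on a fresh patch
#'
#' The smallest positive integer `t1` with `cumulative_gain(t1) >= 1`.
#' Its reciprocal `1/t1` is the highest possible instantaneous host
#' encounter rate, the upper anchor of the learning rule.
#'
#' @param curve A [gain_curve()].
#' @return Integer `t1 >= 1`.
#' @examples
#' time_to_first_host(gain_curve(25))    # 5
#' time_to_first_host(gain_curve(1000))  # 1
#' @export
time_to_first_host <- function(curve) {
  stopifnot(inherits(curve, "gain_curve"))
  if (curve$n0 < 1)
    stop("patch can never yield a host (asymptote below one)")
  # N(t) >= 1  <=>  t >= -log(1 - 1/n0)/alpha (n0 > 1); n0 = 1 never attains.
  if (curve$n0 == 1)
    stop("patch can never yield a host (asymptote below one)")
  t1 <- ceiling(-log(1 - 1 / curve$n0) / curve$alpha)
  # guard against ceiling landing one step off at representation boundaries
  while (t1 > 1L && cumulative_gain(curve, t1 - 1L) >= 1) t1 <- t1 - 1L
  while (cumulative_gain(curve, t1) < 1) t1 <- t1 + 1L
  as.integer(t1)
}
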