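#' Habitat configuration
#'
#' One environmental situation a female forages in: patch quality (initial
#' hosts per habitat patch), inter-patch travel time, the probability of
#' being born on a host-containing patch (environmental stability), and
#' the plasticity cost.  Smaller `n0`, longer `travel_time` and lower
#' `p_natal` together describe a more fragmented habitat.
#'
#' Three model-variant switches are carried with the habitat so they
#' propagate consistently through simulation, optimization and batch
#' runs: the plasticity-interval convention (`bounds`), the reallocation
#' cadence (`reallocate`) and the patch-leaving rate (`leave_rule`).
#' Defaults are the standard model.
#'
#' @param n0 Initial number of hosts per habitat patch (> 1).
#' @param travel_time Time steps spent travelling between patches (>= 1).
#' @param p_natal Probability of starting life on a host-containing patch,
#'   in `[0, 1]`.
#' @param cost Plasticity cost fraction in `[0, 1]`.
#' @param alpha Gain-curve depletion rate per time step (default 0.01).
#' @param bounds Plasticity interval centred on the scaled `g1`
#'   (`"centered"`, default) or extending one-sidedly from it (`"upper"`).
#' @param reallocate Re-aim the unspent budget every time step (`"step"`,
#'   default) or only at patch transitions (`"patch"`).
#' @param leave_rule Patch-leaving threshold: the female's learned
#'   estimate of the environment-wide rate (`"learned"`, default) or the
#'   analytic patch-independent MVT crossing time (`"mvt"`).  Under the
#'   learned rule residence times lengthen on better patches; under the
#'   analytic rule they are identical across patch qualities for this
#'   gain-curve family.
#' @param spec A [tradeoff_spec()].
#' @return An object of class `"habitat"`.
#' @examples
#' habitat(n0 = 100, travel_time = 300, p_natal = 0.5, cost = 0.2)
#' @export
habitat <- function(n0, travel_time, p_natal, cost, alpha = 0.01,
                    bounds = c("centered", "upper"),
                    reallocate = c("step", "patch"),
                    leave_rule = c("learned", "mvt"),
                    spec = tradeoff_spec()) {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 > 1,
            is.numeric(travel_time), length(travel_time) == 1L,
            travel_time >= 1,
            is.numeric(p_natal), length(p_natal) == 1L,
            p_natal >= 0, p_natal <= 1,
            is.numeric(cost), length(cost) == 1L, cost >= 0, cost <= 1,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            inherits(spec, "tradeoff_spec"))
  structure(
    list(n0 = as.numeric(n0),
         travel_time = as.integer(travel_time),
         p_natal = as.numeric(p_natal),
         cost = as.numeric(cost),
         alpha = as.numeric(alpha),
         bounds = match.arg(bounds),
         reallocate = match.arg(reallocate),
         leave_rule = match.arg(leave_rule),
         spec = spec),
    class = "habitat")
}

#' @export
print.habitat <- function(x, ...) {
  cat(sprintf(
    "Habitat: N0 = %g hosts/patch, T = %d steps travel, p = %g natal, c = %g cost (alpha = %g)\n",
    x$n0, x$travel_time, x$p_natal, x$cost, x$alpha))
  if (x$bounds != "centered" || x$reallocate != "step" ||
      x$leave_rule != "learned")
    cat(sprintf("  variants: bounds = %s, reallocate = %s, leave_rule = %s\n",
                x$bounds, x$reallocate, x$leave_rule))
  invisible(x)
}

# integer flags passed to the C++ engine
habitat_flags <- function(env) {
  c(bounds_upper  = as.integer(env$bounds == "upper"),
    realloc_patch = as.integer(env$reallocate == "patch"),
    leave_learned = as.integer(env$leave_rule == "learned"))
}
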