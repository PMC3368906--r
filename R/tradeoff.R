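#' Trade-off specification
#'
#' Defines the linear longevity--fecundity trade-off along which a female
#' parasitoid allocates her resource budget.  One endpoint is maximal
#' longevity (all resources to somatic maintenance), the other maximal egg
#' load (all resources to egg production).  The maximal phenotypic
#' plasticity equals the full extent of the trade-off expressed in
#' longevity units.
#'
#' @param max_longevity Maximal lifespan, in time steps (default 1000).
#' @param max_eggload Maximal egg load, in eggs (default 1000).
#' @return An object of class `"tradeoff_spec"`: a list with elements
#'   `max_longevity`, `max_eggload` and `max_plasticity`
#'   (`= max_longevity`).
#' @examples
#' tradeoff_spec()
#' @export
tradeoff_spec <- function(max_longevity = 1000, max_eggload = 1000) {
  stopifnot(is.numeric(max_longevity), length(max_longevity) == 1L,
            max_longevity > 0,
            is.numeric(max_eggload), length(max_eggload) == 1L,
            max_eggload > 0)
  structure(
    list(max_longevity = as.numeric(max_longevity),
         max_eggload   = as.numeric(max_eggload),
         max_plasticity = as.numeric(max_longevity)),
    class = "tradeoff_spec")
}

#' @export
print.tradeoff_spec <- function(x, ...) {
  cat("Longevity-fecundity trade-off:",
      sprintf("0..%g time steps vs 0..%g eggs\n",
              x$max_longevity, x$max_eggload))
  invisible(x)
}

#' Reproductive strategy triplet
#'
#' The heritable strategy of a female: `g1` is the initial position on the
#' trade-off (expressed in longevity units), `g2` the range of phenotypic
#' plasticity (in units along the trade-off) and `g3` the memory factor of
#' the learning rule (weight of the past, in \[0, 1\]).
#'
#' @param g1 Initial allocation position, longevity units in
#'   `[0, max_longevity]`.
#' @param g2 Plasticity range, trade-off units in `[0, max_plasticity]`.
#' @param g3 Memory factor, dimensionless in `[0, 1]`.
#' @param spec A [tradeoff_spec()].
#' @return An object of class `"strategy"`.
#' @examples
#' strategy(g1 = 600, g2 = 200, g3 = 0.9)
#' @export
strategy <- function(g1, g2, g3, spec = tradeoff_spec()) {
  stopifnot(inherits(spec, "tradeoff_spec"))
  if (!is.numeric(g1) || length(g1) != 1L || g1 < 0 || g1 > spec$max_longevity)
    stop("'g1' must be a single value in [0, ", spec$max_longevity, "]")
  if (!is.numeric(g2) || length(g2) != 1L || g2 < 0 || g2 > spec$max_plasticity)
    stop("'g2' must be a single value in [0, ", spec$max_plasticity, "]")
  if (!is.numeric(g3) || length(g3) != 1L || g3 < 0 || g3 > 1)
    stop("'g3' must be a single value in [0, 1]")
  structure(
    list(g1 = as.numeric(g1), g2 = as.numeric(g2), g3 = as.numeric(g3),
         spec = spec),
    class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf(
    "Strategy: G1 = %.4g (initial longevity), G2 = %.4g (plasticity range), G3 = %.4g (memory)\n",
    x$g1, x$g2, x$g3))
  invisible(x)
}

#' Cost-scaled effective trade-off frontier
#'
#' Phenotypic plasticity carries a linearly proportional cost `c` acting
#' symmetrically on longevity and egg load: both axes of the trade-off are
#' rescaled by `1 - c * g2 / max_plasticity`.  A cost of 0.5 with maximal
#' plasticity therefore constrains a female to half of both her maximal
#' possible lifetime and egg load.
#'
#' @param spec A [tradeoff_spec()].
#' @param g2 Plasticity range, trade-off units in `[0, max_plasticity]`.
#' @param cost Plasticity cost fraction in `[0, 1]`.
#' @return An object of class `"effective_frontier"`: list with `scale`,
#'   `eff_longevity`, `eff_eggload` and the generating `spec`.
#' @examples
#' effective_frontier(tradeoff_spec(), g2 = 1000, cost = 0.5)
#' @export
effective_frontier <- function(spec = tradeoff_spec(), g2, cost) {
  stopifnot(inherits(spec, "tradeoff_spec"))
  if (!is.numeric(g2) || length(g2) != 1L || g2 < 0 || g2 > spec$max_plasticity)
    stop("'g2' outside [0, max_plasticity]")
  if (!is.numeric(cost) || length(cost) != 1L || cost < 0 || cost > 1)
    stop("'cost' outside [0, 1]")
  scale <- 1 - cost * (g2 / spec$max_plasticity)
  structure(
    list(scale = scale,
         eff_longevity = scale * spec$max_longevity,
         eff_eggload   = scale * spec$max_eggload,
         spec = spec),
    class = "effective_frontier")
}

#' @export
print.effective_frontier <- function(x, ...) {
  cat(sprintf(
    "Effective frontier: scale = %.4g (%.4g time steps x %.4g eggs)\n",
    x$scale, x$eff_longevity, x$eff_eggload))
  invisible(x)
}

#' Split of the resource budget at a position on the frontier
#'
#' A position along the effective frontier (in longevity units) fixes both
#' components of the allocation: the lifespan equals the position and the
#' egg load is the complementary share of the (cost-scaled) budget.
#'
#' @param position Position in longevity units, in `[0, eff_longevity]`.
#' @param frontier An [effective_frontier()].
#' @return Named numeric vector `c(lifespan =, eggload =)`.
#' @examples
#' fr <- effective_frontier(g2 = 0, cost = 0.5)
#' allocation_at(250, fr)
#' @export
allocation_at <- function(position, frontier) {
  stopifnot(inherits(frontier, "effective_frontier"))
  if (!is.numeric(position) || length(position) != 1L ||
      position < 0 || position > frontier$eff_longevity)
    stop("'position' outside [0, eff_longevity]")
  c(lifespan = position,
    eggload  = frontier$eff_eggload * (1 - position / frontier$eff_longevity))
}

#' Reachable interval of allocation positions
#'
#' The plasticity range `g2`, rescaled by the frontier cost factor, defines
#' the interval of positions a female can move between during her life.
#' By default the interval is centred on the cost-scaled `g1`; the
#' one-sided convention (interval extending from `g1` toward the longevity
#' end) is available via `mode = "upper"`.  The interval is shifted, not
#' truncated, at the frontier edges, so its width is always
#' `min(g2 * scale, eff_longevity)`.
#'
#' @param g1 Initial position, longevity units on the unscaled trade-off.
#' @param g2 Plasticity range, trade-off units on the unscaled trade-off.
#' @param frontier An [effective_frontier()] (normally built from the same
#'   `g2`).
#' @param mode `"centered"` (default) or `"upper"`.
#' @return Named numeric vector `c(lo =, hi =)`, a sub-interval of
#'   `[0, eff_longevity]`.
#' @examples
#' fr <- effective_frontier(g2 = 200, cost = 0)
#' plasticity_bounds(g1 = 500, g2 = 200, fr)
#' plasticity_bounds(g1 = 0, g2 = 200, fr)   # shifted to (0, 200)
#' @export
plasticity_bounds <- function(g1, g2, frontier, mode = c("centered", "upper")) {
  stopifnot(inherits(frontier, "effective_frontier"))
  mode <- match.arg(mode)
  spec <- frontier$spec
  if (g1 < 0 || g1 > spec$max_longevity) stop("'g1' outside [0, max_longevity]")
  if (g2 < 0 || g2 > spec$max_plasticity) stop("'g2' outside [0, max_plasticity]")
  scale <- frontier$scale
  eff_l <- frontier$eff_longevity
  w  <- min(g2 * scale, eff_l)
  g1s <- g1 * scale
  lo <- if (mode == "centered") g1s - w / 2 else g1s
  if (lo < 0) lo <- 0
  if (lo + w > eff_l) lo <- eff_l - w
  c(lo = lo, hi = lo + w)
}
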