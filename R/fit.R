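#' Optimal reproductive strategy for a habitat
#'
#' Fits the strategy triplet (G1 initial position on the
#' longevity--fecundity trade-off, G2 plasticity range, G3 memory factor)
#' that maximizes mean progeny per generation in a given habitat, by
#' steady-state genetic-algorithm search with multiple restarts.
#'
#' @param env A [habitat()].
#' @param control A [ga_control()].
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   so the fit is exactly reproducible.
#' @return An object of class `"strategy_fit"` with components
#'   `strategy`, `fitness`, `history` (per-cycle best fitness of the
#'   winning restart), `restart_fitness`, `env`, `control`, `call`.
#' @seealso [coef.strategy_fit()], [simulate.strategy_fit()],
#'   [plot.strategy_fit()].
#' @examples
#' fit <- optimal_strategy(habitat(100, 300, 1, 0.2),
#'                         ga_control(pop_size = 20, cycles = 50,
#'                                    restarts = 1),
#'                         seed = 1)
#' coef(fit)
#' @export
optimal_strategy <- function(env, control = ga_control(), seed = NULL) {
  stopifnot(inherits(env, "habitat"), inherits(control, "ga_control"))
  if (!is.null(seed)) set.seed(seed)
  fn <- make_sim_fitness(env, control$fitness_generations)
  run <- best_of_restarts(fn, control, env$spec)
  structure(
    list(strategy = run$best$strategy,
         fitness = run$best$fitness,
         history = run$history,
         restart_fitness = run$restart_fitness,
         restart = run$restart,
         env = env, control = control, seed = seed,
         call = match.call()),
    class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat("Optimal strategy fit\n")
  print(x$env)
  print(x$strategy)
  cat(sprintf("Fitness: %.3f progeny/generation (best of %d restarts)\n",
              x$fitness, length(x$restart_fitness)))
  invisible(x)
}

#' @export
coef.strategy_fit <- function(object, ...) {
  c(g1 = object$strategy$g1, g2 = object$strategy$g2,
    g3 = object$strategy$g3)
}

#' @export
summary.strategy_fit <- function(object, ...) {
  structure(
    list(fit = object,
         coef = coef(object),
         frontier = effective_frontier(object$env$spec,
                                       object$strategy$g2,
                                       object$env$cost)),
    class = "summary.strategy_fit")
}

#' @export
print.summary.strategy_fit <- function(x, ...) {
  print(x$fit)
  fr <- x$frontier
  cat(sprintf(
    "Plasticity cost scales the frontier to %.1f%% (%.1f steps x %.1f eggs)\n",
    100 * fr$scale, fr$eff_longevity, fr$eff_eggload))
  b <- plasticity_bounds(x$coef[["g1"]], x$coef[["g2"]], fr,
                         mode = x$fit$env$bounds)
  cat(sprintf("Reachable positions: [%.1f, %.1f] longevity units\n",
              b[["lo"]], b[["hi"]]))
  cat(sprintf("Restart fitnesses: %s\n",
              paste(sprintf("%.2f", x$fit$restart_fitness), collapse = ", ")))
  invisible(x)
}

#' Simulate generations under a fitted strategy
#'
#' @param object A `"strategy_fit"`.
#' @param nsim Number of generations to simulate.
#' @param seed Optional integer passed to `set.seed()`.
#' @param detail Passed to [simulate_generation()]; with `"trace"` a list
#'   of per-generation results is returned instead of a progeny vector.
#' @param ... Unused.
#' @return Integer vector of progeny per generation, or a list of
#'   detailed results.
#' @export
simulate.strategy_fit <- function(object, nsim = 1, seed = NULL,
                                  detail = c("progeny", "audit", "trace"),
                                  ...) {
  detail <- match.arg(detail)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(nsim), function(i)
    simulate_generation(object$strategy, object$env, detail = detail))
  if (detail == "progeny") unlist(res) else res
}

#' Plot GA convergence of a strategy fit
#'
#' Best fitness after each steady-state cycle of the winning restart.
#'
#' @param x A `"strategy_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.strategy_fit <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "s",
                 xlab = "GA cycle", ylab = "Best fitness (progeny/generation)",
                 main = "Steady-state GA convergence", ...)
  invisible(x)
}
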