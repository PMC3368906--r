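#' Genetic-algorithm settings
#'
#' Controls for the steady-state (GENITOR-style) optimizer: a population
#' of real-coded chromosomes, one offspring per cycle replacing the
#' current worst, linear rank-biased parent selection.  Defaults are the
#' study settings: 100 chromosomes, 500 cycles, 2.5% per-gene mutation,
#' 60% recombination, 10 restarts, fitness averaged over 20 generations.
#'
#' @param pop_size Population size.
#' @param cycles Number of steady-state cycles (one offspring each).
#' @param mutation_rate Per-gene probability of a uniform redraw.
#' @param recombination_rate Probability the offspring is produced by
#'   blend crossover (else it clones the fitter parent).
#' @param restarts Independent optimizations; the best is kept.
#' @param fitness_generations Generations averaged per fitness evaluation.
#' @param rank_bias Linear ranking selection pressure in `(1, 2]`.
#' @return An object of class `"ga_control"`.
#' @export
ga_control <- function(pop_size = 100, cycles = 500, mutation_rate = 0.025,
                       recombination_rate = 0.60, restarts = 10,
                       fitness_generations = 20, rank_bias = 1.5) {
  stopifnot(pop_size >= 2, cycles >= 1, mutation_rate >= 0,
            mutation_rate <= 1, recombination_rate >= 0,
            recombination_rate <= 1, restarts >= 1,
            fitness_generations >= 1, rank_bias > 1, rank_bias <= 2)
  structure(
    list(pop_size = as.integer(pop_size), cycles = as.integer(cycles),
         mutation_rate = mutation_rate,
         recombination_rate = recombination_rate,
         restarts = as.integer(restarts),
         fitness_generations = as.integer(fitness_generations),
         rank_bias = rank_bias),
    class = "ga_control")
}

#' Decode genes in \[0,1\] to a strategy
#'
#' Chromosomes store the three genes on `[0, 1]`; decoding maps them onto
#' the strategy ranges (`g1` to `[0, max_longevity]`, `g2` to
#' `[0, max_plasticity]`, `g3` unchanged).  Exact at both endpoints.
#'
#' @param genes Numeric length-3 vector in `[0, 1]^3`.
#' @param spec A [tradeoff_spec()].
#' @return A [strategy()].
#' @export
decode_genes <- function(genes, spec = tradeoff_spec()) {
  stopifnot(length(genes) == 3L, all(genes >= 0), all(genes <= 1))
  strategy(g1 = genes[[1]] * spec$max_longevity,
           g2 = genes[[2]] * spec$max_plasticity,
           g3 = genes[[3]], spec = spec)
}

#' Encode a strategy to genes in \[0,1\]
#'
#' Inverse of [decode_genes()].
#'
#' @param strat A [strategy()].
#' @return Numeric length-3 vector in `[0, 1]^3`.
#' @export
encode_strategy <- function(strat) {
  stopifnot(inherits(strat, "strategy"))
  spec <- strat$spec
  c(strat$g1 / spec$max_longevity, strat$g2 / spec$max_plasticity, strat$g3)
}

# Whitley's linear-rank sampling: returns a 0-based rank index
# (0 = best) for bias b in (1, 2].
sample_rank <- function(n, bias) {
  u <- stats::runif(1)
  idx <- n * (bias - sqrt(bias * bias - 4 * (bias - 1) * u)) /
    (2 * (bias - 1))
  i <- floor(idx)
  if (i >= n) i <- n - 1
  as.integer(i)
}

#' Steady-state GA optimization of a strategy
#'
#' GENITOR-style loop: each cycle two parents are drawn with linear
#' rank-biased probability from the fitness-sorted population; one
#' offspring is produced by per-gene blend (arithmetic) crossover with
#' probability `recombination_rate` (otherwise it clones the fitter
#' parent), mutated per gene with probability `mutation_rate` (uniform
#' redraw), evaluated once, and replaces the current worst chromosome.
#' The best evaluated fitness never decreases across cycles.
#'
#' @param fitness_fn Function mapping a [strategy()] to a finite numeric
#'   fitness.  Stochastic fitness functions are evaluated once per
#'   chromosome, at creation (no re-evaluation); use
#'   [make_sim_fitness()] for the lifetime simulator.
#' @param control A [ga_control()].
#' @param spec A [tradeoff_spec()] used for decoding.
#' @return List of class `"ga_run"`: `best` (list with `genes`,
#'   `strategy`, `fitness`), `history` (best fitness after each cycle),
#'   `evaluations`.
#' @examples
#' set.seed(7)
#' surf <- function(s) -(s$g1 - 500)^2
#' run <- evolve(surf, ga_control(pop_size = 30, cycles = 100, restarts = 1))
#' run$best$strategy
#' @export
evolve <- function(fitness_fn, control = ga_control(),
                   spec = tradeoff_spec()) {
  stopifnot(is.function(fitness_fn), inherits(control, "ga_control"))
  n <- control$pop_size
  genes <- matrix(stats::runif(3 * n), nrow = n, ncol = 3)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    fit[i] <- fitness_fn(decode_genes(genes[i, ], spec))
    if (!is.finite(fit[i]))
      stop("non-finite fitness for genes (",
           paste(signif(genes[i, ], 6), collapse = ", "), ")")
  }
  history <- numeric(control$cycles)
  for (cy in seq_len(control$cycles)) {
    ord <- order(fit, decreasing = TRUE)
    i1 <- ord[sample_rank(n, control$rank_bias) + 1L]
    i2 <- ord[sample_rank(n, control$rank_bias) + 1L]
    fitter <- if (fit[i1] >= fit[i2]) i1 else i2
    if (stats::runif(1) < control$recombination_rate) {
      w <- stats::runif(3)
      child <- w * genes[i1, ] + (1 - w) * genes[i2, ]
    } else {
      child <- genes[fitter, ]
    }
    mut <- stats::runif(3) < control$mutation_rate
    if (any(mut)) child[mut] <- stats::runif(sum(mut))
    f <- fitness_fn(decode_genes(child, spec))
    if (!is.finite(f))
      stop("non-finite fitness for genes (",
           paste(signif(child, 6), collapse = ", "), ")")
    worst <- ord[n]
    genes[worst, ] <- child
    fit[worst] <- f
    history[cy] <- max(fit)
  }
  best <- which.max(fit)
  structure(
    list(best = list(genes = genes[best, ],
                     strategy = decode_genes(genes[best, ], spec),
                     fitness = fit[best]),
         history = history,
         evaluations = n + control$cycles),
    class = "ga_run")
}

#' Best of several independent GA restarts
#'
#' To avoid local optima the optimization is repeated `control$restarts`
#' times from independent random populations; the solution with the
#' highest fitness across restarts is returned.
#'
#' @inheritParams evolve
#' @return A `"ga_run"` (the winning restart) with extra elements
#'   `restart_fitness` (best fitness of every restart) and `restart`
#'   (index of the winner).
#' @export
best_of_restarts <- function(fitness_fn, control = ga_control(),
                             spec = tradeoff_spec()) {
  stopifnot(inherits(control, "ga_control"))
  runs <- vector("list", control$restarts)
  for (r in seq_len(control$restarts))
    runs[[r]] <- evolve(fitness_fn, control, spec)
  fits <- vapply(runs, function(r) r$best$fitness, numeric(1))
  win <- which.max(fits)
  out <- runs[[win]]
  out$restart_fitness <- fits
  out$restart <- win
  out
}

#' Simulation-backed fitness function for the GA
#'
#' Wraps [fitness()] over a fixed habitat so [evolve()] can optimize the
#' strategy triplet.  Each call consumes RNG draws from the current
#' stream, giving every chromosome a fresh stochastic evaluation.
#'
#' @param env A [habitat()].
#' @param n_generations Generations averaged per evaluation (default 20).
#' @return A function `strategy -> mean progeny per generation`.
#' @export
make_sim_fitness <- function(env, n_generations = 20) {
  stopifnot(inherits(env, "habitat"))
  force(n_generations)
  function(strat) fitness(strat, env, n_generations = n_generations)
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf("GA run: best fitness %.3f after %d evaluations\n",
              x$best$fitness, x$evaluations))
  print(x$best$strategy)
  invisible(x)
}
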