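#' Initialize a female at the start of a generation
#'
#' Computes the cost-scaled frontier, plasticity bounds, patch constants
#' (time to first host, MVT leaving time) and the prior encounter-rate
#' estimate, then places the female at her scaled `g1` position.  With
#' probability `p_natal` she starts foraging on a fresh host patch,
#' otherwise she starts life travelling (one Bernoulli draw from the
#' current RNG stream).
#'
#' This is the reference R implementation; the compiled engine used by
#' [fitness()] performs the identical arithmetic.
#'
#' @param strat A [strategy()].
#' @param env A [habitat()].
#' @return An object of class `"female_state"`: mutable life state plus
#'   the derived per-environment constants.
#' @examples
#' set.seed(1)
#' init_female(strategy(600, 200, 0.9), habitat(100, 300, 0.5, 0.2))
#' @export
init_female <- function(strat, env) {
  stopifnot(inherits(strat, "strategy"), inherits(env, "habitat"))
  spec <- env$spec
  fr <- effective_frontier(spec, strat$g2, env$cost)
  if (fr$scale <= 0)
    stop("plasticity cost consumes the whole budget (scale <= 0)")
  b  <- plasticity_bounds(strat$g1, strat$g2, fr, mode = env$bounds)
  p0 <- min(max(strat$g1 * fr$scale, b[["lo"]]), b[["hi"]])
  curve <- gain_curve(env$n0, env$alpha)
  t1 <- time_to_first_host(curve)
  rate_max <- 1 / t1
  t_star <- mvt_leaving_time(curve, env$travel_time)
  u <- stats::runif(1)
  foraging <- u < env$p_natal
  structure(
    list(time_lived = 0L,
         rem_life = p0,
         eggs_remaining = fr$eff_eggload * (1 - p0 / fr$eff_longevity),
         progeny = 0L,
         acc = 0,
         mu = prior_estimate(t1),
         phase = if (foraging) "foraging" else "travelling",
         travel_rem = if (foraging) 0L else env$travel_time,
         patch_clock = 0L,
         lambda = NA_real_,
         # per-environment constants
         strat = strat, env = env, frontier = fr,
         lo = b[["lo"]], hi = b[["hi"]],
         t1 = t1, rate_max = rate_max, t_star = t_star),
    class = "female_state")
}

#' @export
print.female_state <- function(x, ...) {
  cat(sprintf(
    "Female at t = %d (%s): position %.2f, %.2f eggs left, %d progeny, mu = %.4f\n",
    x$time_lived, x$phase, x$time_lived + x$rem_life, x$eggs_remaining,
    x$progeny, x$mu))
  invisible(x)
}

#' Is a female still alive?
#'
#' A female is alive while her remaining allocated lifespan covers at
#' least one more time step.
#'
#' @param state A `"female_state"`.
#' @return Logical.
#' @export
is_alive <- function(state) state$rem_life >= 1

# re-aim the unspent budget at the learned target position; time already
# lived and eggs already laid are irrevocable
reallocate_female <- function(state) {
  fr <- state$frontier
  target <- allocation_target(state$mu, state$rate_max,
                              c(state$lo, state$hi))
  unspent <- state$rem_life / fr$eff_longevity +
    state$eggs_remaining / fr$eff_eggload
  at <- target - state$time_lived
  if (at < 0) at <- 0
  at_max <- unspent * fr$eff_longevity
  if (at > at_max) at <- at_max
  state$rem_life <- at
  state$eggs_remaining <- (unspent - at / fr$eff_longevity) * fr$eff_eggload
  state
}

#' Advance a female by one time step
#'
#' One step of the discrete-time life: (1) the clock advances and one
#' time step of lifespan budget is consumed; (2) a foraging female
#' accrues the per-step gain increment into a fractional egg accumulator
#' and lays whole eggs (bounded by her remaining egg allocation; surplus
#' hosts encountered while egg-limited are lost); (3) the instantaneous
#' encounter rate is observed and the linear-operator estimate updated;
#' (4) the unspent budget is re-aimed at the learned target position
#' within the plasticity bounds; (5) once the patch-leaving threshold is
#' reached (local gain rate at or below the learned environment-wide
#' estimate, or the analytic MVT time under `leave_rule = "mvt"`) the
#' female leaves the patch if her remaining lifespan covers the travel,
#' otherwise she stays.
#'
#' @param state A living `"female_state"`.
#' @return The updated state (with `$lambda` the rate observed this step).
#' @export
step_female <- function(state) {
  if (!is_alive(state)) stop("cannot step a dead female")
  env <- state$env
  state$time_lived <- state$time_lived + 1L
  state$rem_life <- state$rem_life - 1
  lambda <- 0
  arrived <- FALSE
  if (state$phase == "travelling") {
    state$travel_rem <- state$travel_rem - 1L
    if (state$travel_rem <= 0L) {
      state$phase <- "foraging"; state$patch_clock <- 0L; state$acc <- 0
      arrived <- TRUE
    }
  } else {
    state$patch_clock <- state$patch_clock + 1L
    pc <- as.numeric(state$patch_clock)
    dn <- env$n0 * (exp(-env$alpha * (pc - 1)) - exp(-env$alpha * pc))
    state$acc <- state$acc + dn
    k <- floor(state$acc)
    kmax <- floor(state$eggs_remaining)
    limited <- k > kmax
    if (limited) k <- kmax
    if (k > 0) {
      state$acc <- state$acc - k
      state$eggs_remaining <- state$eggs_remaining - k
      state$progeny <- state$progeny + as.integer(k)
    }
    if (limited) state$acc <- state$acc - floor(state$acc)
    lambda <- current_lambda(TRUE, dn, state$rate_max)
  }
  state$mu <- update_estimate(state$mu, lambda, state$strat$g3)
  if (env$reallocate == "step") state <- reallocate_female(state)
  left <- FALSE
  if (state$phase == "foraging" && state$patch_clock >= 1L) {
    if (env$leave_rule == "learned") {
      pc <- as.numeric(state$patch_clock)
      dn <- env$n0 * (exp(-env$alpha * (pc - 1)) - exp(-env$alpha * pc))
      at_threshold <- dn <= state$mu
    } else {
      at_threshold <- state$patch_clock >= state$t_star
    }
    if (at_threshold &&
        state$rem_life >= env$travel_time) {
      state$phase <- "travelling"
      state$travel_rem <- env$travel_time
      state$patch_clock <- 0L
      state$acc <- 0
      left <- TRUE
    }
  }
  if (env$reallocate == "patch" && (arrived || left))
    state <- reallocate_female(state)
  state$lambda <- lambda
  state
}

#' Simulate one generation (one female's whole life)
#'
#' Runs a female from birth to death (running out of time; a female out
#' of eggs but with lifespan left keeps living and may trade longevity
#' back into eggs through her plasticity) and returns her lifetime
#' progeny count.
#'
#' @param strat A [strategy()].
#' @param env A [habitat()].
#' @param detail `"progeny"` (default) returns the integer progeny count;
#'   `"audit"` adds the final budget bookkeeping; `"trace"` additionally
#'   returns a one-row-per-time-step data frame (time, phase, position,
#'   mu, eggs_remaining, rem_life, progeny, lambda), suitable for
#'   [utils::write.csv()].
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation); both consume one RNG draw and produce identical
#'   results.
#' @return Integer progeny, or a list for `detail != "progeny"`.
#' @examples
#' set.seed(42)
#' simulate_generation(strategy(600, 200, 0.9), habitat(100, 300, 1, 0.2))
#' @export
simulate_generation <- function(strat, env,
                                detail = c("progeny", "audit", "trace"),
                                engine = c("cpp", "R")) {
  stopifnot(inherits(strat, "strategy"), inherits(env, "habitat"))
  detail <- match.arg(detail)
  engine <- match.arg(engine)
  if (engine == "cpp") {
    fl <- habitat_flags(env)
    res <- sim_generation_cpp(strat$g1, strat$g2, strat$g3,
                              env$n0, env$travel_time, env$p_natal,
                              env$cost, env$alpha,
                              env$spec$max_longevity, env$spec$max_eggload,
                              fl[["bounds_upper"]], fl[["realloc_patch"]],
                              fl[["leave_learned"]],
                              trace = (detail == "trace"))
    if (detail == "progeny") return(res$progeny)
    return(res)
  }
  st <- init_female(strat, env)
  tr <- if (detail == "trace") vector("list", 2048L)
  i <- 0L
  while (is_alive(st)) {
    st <- step_female(st)
    i <- i + 1L
    if (detail == "trace") {
      if (i > length(tr)) tr <- c(tr, vector("list", length(tr)))
      tr[[i]] <- c(time = st$time_lived,
                   phase = as.numeric(st$phase == "foraging"),
                   position = st$time_lived + st$rem_life,
                   mu = st$mu,
                   eggs_remaining = st$eggs_remaining,
                   rem_life = st$rem_life,
                   progeny = st$progeny,
                   lambda = st$lambda)
    }
  }
  if (detail == "progeny") return(st$progeny)
  out <- list(progeny = st$progeny,
              time_lived = st$time_lived,
              rem_life = st$rem_life,
              eggs_remaining = st$eggs_remaining,
              eff_longevity = st$frontier$eff_longevity,
              eff_eggload = st$frontier$eff_eggload,
              t1 = st$t1, t_star = st$t_star,
              lo = st$lo, hi = st$hi, mu = st$mu)
  if (detail == "trace")
    out$trace <- as.data.frame(do.call(rbind, tr[seq_len(i)]))
  out
}

#' Fitness of a strategy in a habitat
#'
#' The arithmetic average number of progeny produced per generation over
#' `n_generations` independent generations (each generation redraws the
#' Bernoulli natal-patch start; no state carries over).
#'
#' @inheritParams simulate_generation
#' @param n_generations Number of generations averaged (default 20).
#' @return Mean progeny per generation (real).
#' @examples
#' set.seed(42)
#' fitness(strategy(600, 200, 0.9), habitat(100, 300, 0.5, 0.2))
#' @export
fitness <- function(strat, env, n_generations = 20,
                    engine = c("cpp", "R")) {
  stopifnot(inherits(strat, "strategy"), inherits(env, "habitat"),
            n_generations >= 1)
  engine <- match.arg(engine)
  if (engine == "cpp") {
    fl <- habitat_flags(env)
    return(sim_fitness_cpp(strat$g1, strat$g2, strat$g3,
                           env$n0, env$travel_time, env$p_natal,
                           env$cost, env$alpha,
                           env$spec$max_longevity, env$spec$max_eggload,
                           fl[["bounds_upper"]], fl[["realloc_patch"]],
                           fl[["leave_learned"]], as.integer(n_generations)))
  }
  mean(vapply(seq_len(n_generations), function(i)
    as.numeric(simulate_generation(strat, env, engine = "R")), numeric(1)))
}
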