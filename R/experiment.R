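#' Factorial design grid of habitat configurations
#'
#' Level sets for the four environmental factors.  The defaults are the
#' study grid: 7 patch qualities x 5 travel times x 5 natal-patch
#' probabilities x 5 plasticity costs = 875 situations.
#'
#' @param n0 Patch-quality levels (hosts per patch).
#' @param travel_time Travel-time levels (time steps).
#' @param p_natal Natal-patch probability levels.
#' @param cost Plasticity-cost levels.
#' @param alpha Gain-curve rate shared by all cells.
#' @return An object of class `"design_grid"`.
#' @examples
#' nrow(full_design(design_grid()))  # 875
#' @export
design_grid <- function(n0 = c(25, 50, 100, 250, 500, 750, 1000),
                        travel_time = c(100, 200, 300, 400, 500),
                        p_natal = c(0, 0.25, 0.5, 0.75, 1),
                        cost = c(0.1, 0.2, 0.3, 0.4, 0.5),
                        alpha = 0.01) {
  if (!length(n0) || !length(travel_time) || !length(p_natal) ||
      !length(cost))
    stop("every factor needs at least one level")
  structure(list(n0 = sort(unique(n0)),
                 travel_time = sort(unique(travel_time)),
                 p_natal = sort(unique(p_natal)),
                 cost = sort(unique(cost)),
                 alpha = alpha),
            class = "design_grid")
}

#' A reduced grid for scaled-down runs
#'
#' Extreme levels of patch quality, travel time and plasticity cost, with
#' the natal-patch probability at `{0, 0.5, 1}` (24 cells).  The
#' intermediate `p` level is kept because phenotypic plasticity is mainly
#' selected for under environmental uncertainty: with `p` fixed at 0 or 1
#' the start of life is certain and the plasticity trends flatten out.
#'
#' @inheritParams design_grid
#' @return A `"design_grid"`.
#' @export
small_design_grid <- function(alpha = 0.01) {
  design_grid(n0 = c(25, 1000), travel_time = c(100, 500),
              p_natal = c(0, 0.5, 1), cost = c(0.1, 0.5), alpha = alpha)
}

#' Full-factorial sequence of habitats
#'
#' Cartesian product of the grid levels, in a fixed deterministic order:
#' `n0` varies fastest, then `travel_time`, then `p_natal`, then `cost`
#' (standard [expand.grid()] order).
#'
#' @param grid A [design_grid()].
#' @return A data frame with one row per situation (`cell`, `n0`,
#'   `travel_time`, `p_natal`, `cost`), of class
#'   `c("habitat_design", "data.frame")`; the grid is kept as an
#'   attribute.
#' @export
full_design <- function(grid = design_grid()) {
  stopifnot(inherits(grid, "design_grid"))
  d <- expand.grid(n0 = grid$n0, travel_time = grid$travel_time,
                   p_natal = grid$p_natal, cost = grid$cost,
                   KEEP.OUT.ATTRS = FALSE)
  d <- cbind(cell = seq_len(nrow(d)), d)
  attr(d, "grid") <- grid
  class(d) <- c("habitat_design", class(d))
  d
}

#' Habitat object for one design row
#'
#' @param design A [full_design()] data frame.
#' @param i Row index.
#' @param ... Passed to [habitat()] (e.g. model-variant switches).
#' @return A [habitat()].
#' @export
design_habitat <- function(design, i, ...) {
  grid <- attr(design, "grid")
  habitat(n0 = design$n0[i], travel_time = design$travel_time[i],
          p_natal = design$p_natal[i], cost = design$cost[i],
          alpha = if (is.null(grid)) 0.01 else grid$alpha, ...)
}

#' Deterministic per-cell seed
#'
#' Maps a master seed and a cell index to a reproducible per-cell seed by
#' a fixed linear congruential map modulo `2^31 - 1` (documented so runs
#' can be reproduced cell by cell).
#'
#' @param master_seed Integer master seed.
#' @param cell Integer cell index (1-based).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
cell_seed <- function(master_seed, cell) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 + as.numeric(cell) * 16807
  as.integer(s %% m + 1)
}

#' Batch optimization over a factorial design
#'
#' Runs [optimal_strategy()] (best of `control$restarts` GA restarts) on
#' every cell of the design.  Per-cell seeds derive deterministically
#' from `master_seed` via [cell_seed()], so the result table is
#' reproducible and invariant to the order cells are run in.  If
#' `out_file` is given the table is appended cell by cell as CSV and an
#' interrupted run resumes, skipping cells already present.
#'
#' @param design A [full_design()] data frame.
#' @param control A [ga_control()].
#' @param master_seed Integer master seed (default 1).
#' @param out_file Optional CSV path for incremental output / resume.
#' @param quiet Suppress per-cell progress messages.
#' @param ... Passed to [design_habitat()] (model-variant switches).
#' @return A data frame of class `c("strategy_results", "data.frame")`:
#'   one row per cell with the factors, `g1_opt`, `g2_opt`, `g3_opt`,
#'   `best_fitness`, `seed` and `restarts_used`.
#' @export
run_design <- function(design, control = ga_control(), master_seed = 1,
                       out_file = NULL, quiet = FALSE, ...) {
  stopifnot(inherits(design, "data.frame"),
            inherits(control, "ga_control"))
  done <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    done <- utils::read.csv(out_file)
    if (!quiet && nrow(done))
      message("resuming: ", nrow(done), " cells already done")
  }
  rows <- vector("list", nrow(design))
  failed <- integer(0)
  for (i in seq_len(nrow(design))) {
    cell <- design$cell[i]
    if (!is.null(done) && cell %in% done$cell) {
      rows[[i]] <- done[done$cell == cell, , drop = FALSE]
      next
    }
    env <- design_habitat(design, i, ...)
    sd <- cell_seed(master_seed, cell)
    fit <- tryCatch(optimal_strategy(env, control, seed = sd),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, cell)
      warning("cell ", cell, " failed: ", conditionMessage(fit))
      next
    }
    rows[[i]] <- data.frame(
      cell = cell, n0 = design$n0[i], travel_time = design$travel_time[i],
      p_natal = design$p_natal[i], cost = design$cost[i],
      g1_opt = fit$strategy$g1, g2_opt = fit$strategy$g2,
      g3_opt = fit$strategy$g3, best_fitness = fit$fitness,
      seed = sd, restarts_used = control$restarts)
    if (!is.null(out_file))
      utils::write.table(rows[[i]], out_file, sep = ",",
                         col.names = !file.exists(out_file),
                         row.names = FALSE, append = file.exists(out_file))
    if (!quiet)
      message(sprintf("cell %d/%d: g1 = %.0f g2 = %.0f g3 = %.2f W = %.1f",
                      cell, nrow(design), fit$strategy$g1, fit$strategy$g2,
                      fit$strategy$g3, fit$fitness))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  class(out) <- c("strategy_results", class(out))
  out
}

# check a results table covers its implied factorial design exactly once
check_balanced <- function(results) {
  fac <- c("n0", "travel_time", "p_natal", "cost")
  stopifnot(all(fac %in% names(results)))
  lev <- lapply(results[fac], function(x) sort(unique(x)))
  want <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE)
  key <- function(d) paste(d$n0, d$travel_time, d$p_natal, d$cost, sep = "/")
  have <- key(results)
  if (anyDuplicated(have))
    stop("results table has duplicated cells: ",
         paste(utils::head(have[duplicated(have)], 5), collapse = "; "))
  miss <- setdiff(key(want), have)
  if (length(miss))
    stop("results table is incomplete; missing cells (n0/T/p/c): ",
         paste(utils::head(miss, 10), collapse = "; "),
         if (length(miss) > 10) " ..." else "")
  invisible(lev)
}

#' Factorial ANOVA of optimized strategy parameters
#'
#' Fixed-effects 4-way ANOVA of one optimized parameter with all four
#' main effects and all six two-way interactions, the factors treated as
#' categorical.  The design must be complete and balanced with one
#' observation (the best-of-restarts optimum) per cell; on the default
#' 875-cell grid this gives main-effect dfs (6, 4, 4, 4), interaction
#' dfs (24, 24, 24, 16, 16, 16) and residual df 736.  With one
#' observation per cell the sequential sums of squares coincide with
#' Type II/III.
#'
#' @param results A [run_design()] table (or any data frame with the four
#'   factor columns and the response).
#' @param response One of `"g1_opt"`, `"g2_opt"`, `"g3_opt"` (or any
#'   numeric column of `results`).
#' @return A data frame (`effect`, `df`, `sum_sq`, `mean_sq`,
#'   `F`, `p`) including the residual row; the underlying
#'   [stats::aov()] fit is attached as attribute `"fit"`.
#' @export
anova_table <- function(results, response = c("g1_opt", "g2_opt", "g3_opt")) {
  response <- if (is.character(response)) response[1] else
    stop("'response' must be a column name")
  if (!response %in% names(results))
    stop("unknown response '", response, "'")
  check_balanced(results)
  d <- data.frame(y = results[[response]],
                  N0 = factor(results$n0),
                  T_ = factor(results$travel_time),
                  P = factor(results$p_natal),
                  C = factor(results$cost))
  fit <- stats::aov(y ~ (N0 + T_ + P + C)^2, data = d)
  an <- stats::anova(fit)
  out <- data.frame(effect = rownames(an),
                    df = an$Df, sum_sq = an$`Sum Sq`,
                    mean_sq = an$`Mean Sq`, F = an$`F value`,
                    p = an$`Pr(>F)`)
  out$effect <- sub("^T_", "travel_time", out$effect)
  out$effect <- sub(":T_", ":travel_time", out$effect)
  out$effect <- sub("^N0", "patch_quality", out$effect)
  out$effect <- sub(":N0", ":patch_quality", out$effect)
  out$effect <- sub("^P\\b", "p_natal", out$effect)
  out$effect <- sub(":P\\b", ":p_natal", out$effect)
  out$effect <- sub("^C\\b", "cost", out$effect)
  out$effect <- sub(":C\\b", ":cost", out$effect)
  out$effect <- sub("^Residuals\\s*$", "residual", trimws(out$effect))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Per-level mean and standard error of an optimized parameter
#'
#' Summarizes a results table by the levels of one factor: mean, SE and
#' cell count per level, mirroring the usual mean +/- SE trend figures.
#'
#' @param results A [run_design()] table.
#' @param factor Name of the factor column (`"n0"`, `"travel_time"`,
#'   `"p_natal"` or `"cost"`).
#' @param response Name of the response column.
#' @return A data frame (`level`, `mean`, `se`, `n`) of class
#'   `c("trend_summary", "data.frame")`; `se` is `NA` for single-cell
#'   levels.
#' @export
trend_summary <- function(results, factor, response) {
  if (!factor %in% names(results)) stop("unknown factor '", factor, "'")
  if (!response %in% names(results)) stop("unknown response '", response, "'")
  lev <- sort(unique(results[[factor]]))
  out <- do.call(rbind, lapply(lev, function(l) {
    y <- results[[response]][results[[factor]] == l]
    data.frame(level = l, mean = mean(y),
               se = if (length(y) > 1) stats::sd(y) / sqrt(length(y))
                    else NA_real_,
               n = length(y))
  }))
  attr(out, "factor") <- factor
  attr(out, "response") <- response
  class(out) <- c("trend_summary", class(out))
  out
}

#' Plot a mean +/- SE trend
#'
#' @param x A [trend_summary()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trend_summary <- function(x, ...) {
  ylim <- range(c(x$mean - x$se, x$mean + x$se, x$mean), na.rm = TRUE)
  graphics::plot(x$level, x$mean, type = "b", pch = 19, ylim = ylim,
                 xlab = attr(x, "factor"), ylab = attr(x, "response"),
                 ...)
  ok <- !is.na(x$se) & x$se > 0
  if (any(ok))
    graphics::arrows(x$level[ok], x$mean[ok] - x$se[ok],
                     x$level[ok], x$mean[ok] + x$se[ok],
                     angle = 90, code = 3, length = 0.04)
  invisible(x)
}
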