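# shared fixtures, built in code

# the study factor levels
LEVELS_N0 <- c(25, 50, 100, 250, 500, 750, 1000)
LEVELS_T  <- c(100, 200, 300, 400, 500)
LEVELS_P  <- c(0, 0.25, 0.5, 0.75, 1)
LEVELS_C  <- c(0.1, 0.2, 0.3, 0.4, 0.5)

rand_strategy <- function() {
  strategy(g1 = runif(1, 0, 1000), g2 = runif(1, 0, 1000), g3 = runif(1))
}

rand_habitat <- function(...) {
  habitat(n0 = sample(LEVELS_N0, 1), travel_time = sample(LEVELS_T, 1),
          p_natal = sample(LEVELS_P, 1), cost = sample(LEVELS_C, 1), ...)
}

# exhaustive-search oracle for the MVT leaving time: integer argmax of the
# whole-visit average gain rate N(t) / (t + T)
mvt_oracle <- function(n0, alpha, travel_time, t_max = 5000) {
  t <- seq_len(t_max)
  g <- n0 * (1 - exp(-alpha * t))
  t[which.max(g / (t + travel_time))]
}

# final budget bookkeeping of one simulated life, as fractions of the
# cost-scaled budget
budget_audit <- function(aud) {
  c(time  = aud$time_lived / aud$eff_longevity,
    eggs  = aud$progeny / aud$eff_eggload,
    unspent = aud$rem_life / aud$eff_longevity +
      aud$eggs_remaining / aud$eff_eggload)
}

# a tiny balanced results table (placeholder response) for ANOVA structure
# checks without running the GA
placeholder_results <- function(grid = design_grid(), seed = 1) {
  d <- full_design(grid)
  set.seed(seed)
  d$g1_opt <- runif(nrow(d), 0, 1000)
  d$g2_opt <- runif(nrow(d), 0, 1000)
  d$g3_opt <- runif(nrow(d))
  d
}
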