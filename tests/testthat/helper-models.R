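# Shared toy fixtures, built in code.

# One-species exponential decay with an inert extra term (k_dead = 0), used
# for closed-form sensitivity oracles: s(T) = s0 * exp(-k*T).
linear_decay_model <- function(k = 0.5, s0 = 1, horizon = 2) {
  ode_model(
    name = "linear_decay",
    species = "s",
    params = c(k = k, k_dead = 0),
    init = c(s = s0),
    horizon = horizon,
    rhs = function(t, y, p, ch) {
      list(-ch[["decay"]] * p[["k"]] * y[[1L]] +
             ch[["dead_term"]] * p[["k_dead"]] * y[[1L]])
    },
    channels = c("decay", "dead_term")
  )
}

# readout for the decay model: s at the horizon
decay_readout <- function(model) {
  traj <- integrate_model(model, n_out = 201L)
  unname(traj$states[nrow(traj$states), "s"])
}

# hand-built trajectory objects
make_trajectory <- function(times, ..., model_ref = "toy") {
  states <- cbind(...)
  structure(list(times = times, states = states, model_ref = model_ref),
            class = "trajectory")
}

# triangular pulse: rises 0 -> 1 over [0, 1], falls 1 -> 0 over [1, 2]
triangle_trajectory <- function(by = 0.01) {
  tt <- seq(0, 2, by = by)
  make_trajectory(tt, y = pmin(tt, 2 - tt))
}

# the printed mutation panel joined to the printed phenotype table
fixture_scores_lengths <- function() {
  t3 <- table3_mutations()
  t2 <- table2_cell_lengths()
  merge(t3, t2[!is.na(t2$residue_change), ], by = c("protein", "residue_change"))
}
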