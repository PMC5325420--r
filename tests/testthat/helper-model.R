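# Shared test helpers.

# Coarse but convergent settings for the slower screen-level tests; the
# acceptance tests use the standard h = 0.01.
quick_cfg <- function(...) {
  screen_config(h = 0.05, ...)
}

quick_sim <- function(module_id, regimen = drug_regimen(),
                      stimulus = "S0", scale = 1, h = 0.05, horizon = 100,
                      ...) {
  simulate_module(build_module(module_id, scale),
                  stimuli = stimulus_library(horizon)[[stimulus]],
                  regimen = regimen, horizon = horizon, h = h, ...)
}

# Independent reference solution: the model equations re-written from
# scratch in dense-matrix form and integrated with deSolve's adaptive
# lsoda at tight tolerances. Used to cross-check both the hand-written
# right-hand side and the fixed-step RK4 integrator.
oracle_solve <- function(topology, regimen = drug_regimen(),
                         g1 = function(t) 0, g2 = function(t) 0,
                         times = seq(0, 100, by = 1)) {
  V <- topology$V
  K <- topology$K
  entries <- regimen$entries
  rhs <- function(t, X, parms) {
    g <- rep(1, 5)
    if (nrow(entries)) {
      for (r in seq_len(nrow(entries))) {
        if (t >= entries$t_on[r]) {
          tg <- entries$target[r]
          g[tg] <- g[tg] + entries$dose[r] / 0.1
        }
      }
    }
    dX <- numeric(5)
    for (i in 1:5) {
      acc <- 0
      for (j in 1:5) {
        v <- V[j, i]
        if (v > 0) acc <- acc + v * (1 - X[i]) / (g[i] * K[j, i] + (1 - X[i])) * X[j]
        if (v < 0) acc <- acc + v * X[i] / (g[i] * K[j, i] + X[i]) * X[j]
      }
      dX[i] <- acc - 0.2 * X[i]
    }
    s1 <- g1(t); s2 <- g2(t)
    if (s1 > 0) dX[1] <- dX[1] + 0.2 * s1 / (0.5 + s1)
    if (s2 > 0) dX[3] <- dX[3] + 0.2 * s2 / (0.5 + s2)
    list(dX)
  }
  deSolve::ode(y = rep(0, 5), times = times, func = rhs, parms = NULL,
               method = "lsoda", rtol = 1e-10, atol = 1e-12)
}
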