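#' Drug modulation factor for one species
#'
#' A targeted drug acts as a competitive inhibitor of its target's
#' activation: every Michaelis constant of reactions activating species i is
#' multiplied by g_i = 1 + Drug_i / K_D_i, where Drug_i is the summed dose of
#' all regimen entries targeting i that are active at time t. With no active
#' entry g_i = 1 and the kinetics are untouched.
#'
#' @param species Species name or index.
#' @param regimen A `drug_regimen`.
#' @param t Time at which to evaluate (entries are active once `t >= t_on`).
#' @param params A `kinetic_parameters` object (supplies `K_D`).
#' @return The scalar factor g_i >= 1.
#' @export
#' @examples
#' p <- default_parameters()
#' drug_factor("B", drug_regimen("B", doses = 1), t = 0, p)  # 1 + 1/0.1 = 11
drug_factor <- function(species, regimen, t, params = default_parameters()) {
  i <- species_index(species)
  stopifnot(length(i) == 1L, t >= 0)
  .drug_factors(regimen, t, params)[i]
}

# Vector of g_i for all five species at time t.
.drug_factors <- function(regimen, t, params) {
  g <- rep(1, 5L)
  e <- regimen$entries
  if (nrow(e) == 0L) return(g)
  if (any(e$dose < 0)) stop("drug doses must be >= 0")
  act <- e$t_on <= t
  if (any(act)) {
    dose <- vapply(1:5, function(i) sum(e$dose[act & e$target == i]),
                   numeric(1))
    g <- g + dose / params$K_D
  }
  g
}

# Precompute the right-hand side of the module ODEs as a closure f(t, X).
#
# dX_i/dt = sum_j flux_{j,i} - d_i X_i + f_i(t), where for an activating edge
# (V_{j,i} > 0) flux = V_{j,i} * (1 - X_i) / (g_i K_{j,i} + (1 - X_i)) * X_j
# and for an inhibiting edge (V_{j,i} < 0), under the default "deactivation"
# convention, the saturating substrate is the active fraction:
# flux = V_{j,i} * X_i / (g_i K_{j,i} + X_i) * X_j. The "literal" convention
# uses (1 - X_i) saturation for every edge regardless of sign (and can drive
# states negative). The input functions are Michaelis-Menten in the stimuli,
# f_1 = V_A G1(t) / (K_A + G1(t)) and f_3 = V_C G2(t) / (K_C + G2(t)); the
# drug factor modulates only the protein-protein activation constants
# K_{j,i}, not the growth-factor inputs.
.compile_rhs <- function(topology, params, stimuli, regimen,
                         inhibition = c("deactivation", "literal")) {
  inhibition <- match.arg(inhibition)
  deact <- inhibition == "deactivation"
  V <- topology$V
  K <- topology$K
  idx <- which(V != 0, arr.ind = TRUE)
  e_from <- idx[, 1L]
  e_to <- idx[, 2L]
  e_V <- V[idx]
  e_K <- K[idx]
  pos <- e_V > 0
  neg <- !pos
  ne <- length(e_V)
  agg <- matrix(0, 5L, ne)
  agg[cbind(e_to, seq_len(ne))] <- 1
  d <- params$d
  V_A <- params$V_A; K_A <- params$K_A
  V_C <- params$V_C; K_C <- params$K_C

  ent <- regimen$entries
  g_const <- nrow(ent) == 0L || all(ent$t_on <= 0)
  g0 <- .drug_factors(regimen, 0, params)
  g_at <- if (g_const) function(t) g0 else function(t) .drug_factors(regimen, t, params)

  seg1 <- stimuli$G1$segments
  seg2 <- stimuli$G2$segments
  stim <- function(seg, t) {
    hit <- t >= seg$t_start & t < seg$t_end
    if (any(hit)) seg$amplitude[which(hit)[1L]] else 0
  }

  # t_input decouples the sampling time of the discontinuous inputs
  # (stimulus segments, drug onsets) from the stage time: the integrator
  # samples them once per step at the step midpoint, so that every RK4 step
  # integrates a smooth constant-input system and retains fourth-order
  # accuracy when breakpoints fall on the step grid.
  function(t, X, t_input = t) {
    g <- g_at(t_input)
    s <- numeric(ne)
    xt <- X[e_to]
    if (deact) {
      s[pos] <- 1 - xt[pos]
      s[neg] <- xt[neg]
    } else {
      s <- 1 - xt
    }
    flux <- e_V * s / (e_K * g[e_to] + s) * X[e_from]
    g1 <- stim(seg1, t_input)
    g2 <- stim(seg2, t_input)
    f1 <- if (g1 > 0) V_A * g1 / (K_A + g1) else 0
    f3 <- if (g2 > 0) V_C * g2 / (K_C + g2) else 0
    dX <- drop(agg %*% flux) - d * X
    dX[1L] <- dX[1L] + f1
    dX[3L] <- dX[3L] + f3
    dX
  }
}

#' Evaluate the module ODE right-hand side
#'
#' Computes dX/dt at one state and time for a topology, parameter set,
#' stimulus pair and drug regimen. Activating edges follow saturating
#' Michaelis-Menten kinetics on the inactive fraction `1 - X_i`; inhibiting
#' edges, under the default `"deactivation"` convention, deactivate the
#' active fraction `X_i` (which keeps states nonnegative). The `"literal"`
#' convention applies the inactive-fraction saturation to every edge.
#'
#' @param X Numeric state vector of length 5 (activation fractions of
#'   A, B, C, D, O).
#' @param t Time.
#' @param topology A `module_topology`.
#' @param params A `kinetic_parameters`.
#' @param stimuli List with `G1` and `G2` `stimulus_profile`s (one entry of
#'   [stimulus_library()]).
#' @param regimen A `drug_regimen`.
#' @param inhibition `"deactivation"` (default) or `"literal"`.
#' @return Numeric derivative vector of length 5.
#' @export
signaling_rhs <- function(X, t, topology, params = default_parameters(),
                          stimuli = stimulus_library()[["S0"]],
                          regimen = drug_regimen(),
                          inhibition = c("deactivation", "literal")) {
  if (!all(is.finite(X))) stop("state vector contains non-finite values")
  stopifnot(length(X) == 5L)
  rhs <- .compile_rhs(topology, params, stimuli, regimen, inhibition)
  rhs(t, X)
}

#' Simulate a module with fixed-step fourth-order Runge-Kutta
#'
#' Integrates the module kinetics from `X0` (all species inactive by
#' default) over `[0, horizon]` with the classical RK4 scheme at fixed step
#' `h`. Defaults are horizon 100 and h = 0.01 in the model's
#' non-dimensional time. The piecewise-constant inputs (stimulus segments,
#' drug onsets) are sampled once per step at the step midpoint, so steps
#' whose boundaries coincide with input breakpoints integrate a smooth
#' constant-input system and the scheme keeps its fourth-order accuracy.
#'
#' @inheritParams signaling_rhs
#' @param horizon Final time (> 0).
#' @param h Step size (> 0; `horizon / h` must be integral within rounding).
#' @param X0 Initial state (default: all zero).
#' @return An object of class `crosstalk_trajectory`: list with `times`
#'   (uniform grid), `states` (matrix, one row per grid point, columns
#'   A, B, C, D, O) and `metadata` (module id, crosstalk scale, regimen and
#'   stimulus labels, inhibition convention, horizon, step).
#' @export
#' @examples
#' traj <- simulate_module(build_module(0), horizon = 10, h = 0.1)
#' tail(traj$states, 2)
simulate_module <- function(topology, params = default_parameters(),
                            stimuli = stimulus_library()[["S0"]],
                            regimen = drug_regimen(),
                            horizon = 100, h = 0.01, X0 = rep(0, 5L),
                            inhibition = c("deactivation", "literal")) {
  inhibition <- match.arg(inhibition)
  stopifnot(horizon > 0, h > 0, length(X0) == 5L, all(is.finite(X0)))
  n <- round(horizon / h)
  if (abs(n * h - horizon) > 1e-8 * horizon) {
    stop("horizon must be an integral number of steps h")
  }
  rhs <- .compile_rhs(topology, params, stimuli, regimen, inhibition)

  times <- seq(0, by = h, length.out = n + 1L)
  states <- matrix(NA_real_, n + 1L, 5L,
                   dimnames = list(NULL, names(SPECIES)))
  X <- as.numeric(X0)
  states[1L, ] <- X
  h2 <- h / 2
  for (k in seq_len(n)) {
    t <- times[k]
    tm <- t + h2  # inputs sampled mid-step (see .compile_rhs)
    k1 <- rhs(t, X, tm)
    k2 <- rhs(t + h2, X + h2 * k1, tm)
    k3 <- rhs(t + h2, X + h2 * k2, tm)
    k4 <- rhs(t + h, X + h * k3, tm)
    X <- X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(X))) {
      stop(sprintf("integration blew up at t = %g (non-finite state)",
                   times[k + 1L]))
    }
    states[k + 1L, ] <- X
  }

  structure(
    list(
      times = times,
      states = states,
      metadata = list(
        module_id = topology$module_id,
        crosstalk_scale = topology$crosstalk_scale,
        regimen = regimen_label(regimen),
        stimulus_g1 = stimuli$G1$name,
        stimulus_g2 = stimuli$G2$name,
        inhibition = inhibition,
        horizon = horizon, h = h
      )
    ),
    class = "crosstalk_trajectory"
  )
}

#' Integrated signaling output
#'
#' The time integral of the output species O over `[0, horizon]`, computed
#' by the composite trapezoidal rule on the trajectory grid. This is the
#' model's surrogate for cumulative pathway activity and the raw material of
#' the efficacy and synergy indices.
#'
#' @param traj A `crosstalk_trajectory`.
#' @param horizon Upper integration limit (default 100); the trajectory must
#'   cover it.
#' @return Nonnegative scalar IO.
#' @export
integrated_output <- function(traj, horizon = 100) {
  tmax <- traj$times[length(traj$times)]
  if (tmax < horizon - 1e-9) {
    stop(sprintf("trajectory ends at t = %g, before the horizon %g",
                 tmax, horizon))
  }
  sel <- traj$times <= horizon + 1e-9
  pracma::trapz(traj$times[sel], traj$states[sel, 5L])
}

#' Tidy a trajectory into long form
#'
#' @param x A `crosstalk_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `time`, `species`, `value`, `module_id`,
#'   `regimen`, `stimulus`.
#' @export
as.data.frame.crosstalk_trajectory <- function(x, ...) {
  md <- x$metadata
  stim <- if (identical(md$stimulus_g1, md$stimulus_g2)) md$stimulus_g1 else
    paste0(md$stimulus_g1, "/", md$stimulus_g2)
  data.frame(
    time = rep(x$times, times = 5L),
    species = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states),
    module_id = md$module_id,
    regimen = md$regimen,
    stimulus = stim
  )
}

#' @export
print.crosstalk_trajectory <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Trajectory of module %s (%s drug regimen, stimulus %s/%s)\n",
    md$module_id, md$regimen, md$stimulus_g1, md$stimulus_g2))
  cat(sprintf("  %d points on [0, %g], h = %g\n",
              length(x$times), md$horizon, md$h))
  cat(sprintf("  final state: %s\n",
              paste(sprintf("%s=%.4f", colnames(x$states),
                            x$states[nrow(x$states), ]), collapse = ", ")))
  invisible(x)
}
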