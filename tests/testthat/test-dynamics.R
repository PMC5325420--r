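test_that("drug factor inflates Michaelis constants by 1 + dose/K_D, summing shared targets", {
  p <- default_parameters()
  none <- drug_regimen()
  for (s in c("A", "B", "O")) {
    expect_equal(drug_factor(s, none, 0, p), 1)
  }
  drB <- drug_regimen("B", doses = 1)
  expect_equal(drug_factor("B", drB, 0, p), 11)      # 1 + 1 / 0.1
  expect_equal(drug_factor("A", drB, 0, p), 1)       # off-target untouched
  drBB <- drug_regimen(c("B", "B"), doses = 1)
  expect_equal(drug_factor("B", drBB, 0, p), 21)     # doses sum: 1 + 2 / 0.1
  # onset time gates activity
  late <- drug_regimen("B", doses = 1, t_on = 50)
  expect_equal(drug_factor("B", late, 10, p), 1)
  expect_equal(drug_factor("B", late, 50, p), 11)
})

test_that("right-hand side matches hand-evaluated Michaelis-Menten terms", {
  top <- build_module(0)
  off <- stimulus_library()$S6  # silent at t = 0
  X <- c(0.5, 0, 0, 0, 0)
  dX <- signaling_rhs(X, t = 0, top, stimuli = off)
  # activation of B by A: 0.4 * (1 - 0)/(0.8 + 1) * 0.5 = 1/9
  expect_equal(dX[2], 0.4 * 1 / 1.8 * 0.5, tolerance = 1e-12)
  # degradation of A only (no stimulus active at t = 0)
  expect_equal(dX[1], -0.2 * 0.5)
  expect_equal(dX[c(3, 4, 5)], c(0, 0, 0))

  # B-targeting drug at dose 1: g_B = 11 rescales K in the A -> B term
  dXd <- signaling_rhs(X, 0, top, stimuli = off, regimen = drug_regimen("B"))
  expect_equal(dXd[2], 0.4 * 1 / (11 * 0.8 + 1) * 0.5, tolerance = 1e-12)

  # quiescent fixed point
  expect_equal(signaling_rhs(rep(0, 5), 0, top, stimuli = off), rep(0, 5))
  expect_error(signaling_rhs(c(NaN, 0, 0, 0, 0), 0, top), "non-finite")
})

test_that("receptor species relaxes to its closed-form fixed point under sustained stimulus", {
  # under G1 = 1: dX_A/dt = 0.2 * 1 / 1.5 - 0.2 X_A, fixed point 2/3
  traj <- quick_sim(0, stimulus = "S1", h = 0.01, horizon = 100)
  expect_equal(unname(traj$states[nrow(traj$states), "A"]), 2 / 3,
               tolerance = 1e-6)
})

test_that("the fixed-step RK4 trajectory agrees with an independent adaptive reference", {
  skip_if_not_installed("deSolve")
  top <- build_module(7)
  reg <- drug_regimen("B")
  ref <- oracle_solve(top, reg, g1 = function(t) as.numeric(t < 30),
                      g2 = function(t) as.numeric(t < 30),
                      times = seq(0, 100, by = 10))
  traj <- quick_sim(7, regimen = reg, h = 0.01)
  at <- match(ref[, "time"], traj$times)
  expect_lt(max(abs(traj$states[at, ] - ref[, -1])), 1e-5)
})

test_that("module 0 is symmetric: A and C, B and D have identical time courses", {
  traj <- quick_sim(0, h = 0.01)
  expect_lt(max(abs(traj$states[, "A"] - traj$states[, "C"])), 1e-12)
  expect_lt(max(abs(traj$states[, "B"] - traj$states[, "D"])), 1e-12)
})

test_that("trajectories stay inside [0, 1] and start from the configured state", {
  for (m in c(0, 2, 5, 6, 8)) {
    traj <- quick_sim(m, regimen = drug_regimen("B"))
    expect_true(all(traj$states >= 0), info = paste("module", m))
    expect_true(all(traj$states <= 1), info = paste("module", m))
    expect_equal(traj$states[1, ], c(A = 0, B = 0, C = 0, D = 0, O = 0))
  }
  # zero stimulus from a zero state is an exact fixed point
  quiet <- simulate_module(build_module(4), stimuli = stimulus_library()$S6,
                           horizon = 10, h = 0.1)
  expect_true(all(quiet$states == 0))
})

test_that("a zero-dose regimen reproduces the untreated trajectory exactly", {
  t1 <- quick_sim(3, regimen = drug_regimen(), h = 0.05)
  t2 <- quick_sim(3, regimen = drug_regimen("B", doses = 0), h = 0.05)
  expect_identical(t1$states, t2$states)
})

test_that("raising the dose on the direct target never raises its activation", {
  prev <- quick_sim(0, regimen = drug_regimen("B", doses = 0))$states[, "B"]
  for (dose in c(0.5, 1, 2, 5)) {
    cur <- quick_sim(0, regimen = drug_regimen("B", doses = dose))$states[, "B"]
    expect_lt(max(cur - prev), 1e-12)
    prev <- cur
  }
})

test_that("trajectories converge to module 0 as the crosstalk scale vanishes", {
  ref <- quick_sim(0)$states
  for (m in c(2, 5, 7)) {
    gaps <- vapply(c(1, 0.1, 0.01, 0.001, 1e-4), function(s)
      max(abs(quick_sim(m, scale = s)$states - ref)), numeric(1))
    expect_true(all(diff(gaps) < 0), info = paste("module", m))
    expect_lt(gaps[length(gaps)], 1e-3)
  }
})

test_that("RK4 shows fourth-order global error on the closed-form relaxation", {
  # single uncoupled species: dX/dt = f - d X with constant f = 0.2/1.5
  top <- module_topology(V = matrix(0, 5, 5), K = matrix(0, 5, 5))
  exact <- function(t) (0.2 / 1.5) / 0.2 * (1 - exp(-0.2 * t))
  err <- function(h) {
    traj <- simulate_module(top, stimuli = stimulus_library()$S1,
                            horizon = 10, h = h)
    max(abs(traj$states[, "A"] - exact(traj$times)))
  }
  ratio <- err(0.4) / err(0.2)
  expect_gt(ratio, 12)  # ~16 for a fourth-order scheme
  expect_lt(ratio, 20)
})

test_that("halving the step perturbs the states by less than 1e-6", {
  a <- quick_sim(5, regimen = drug_regimen("B"), h = 0.02)
  b <- quick_sim(5, regimen = drug_regimen("B"), h = 0.01)
  at <- match(a$times, b$times)
  expect_lt(max(abs(a$states - b$states[at, ])), 1e-6)
})

test_that("the literal inhibition convention matches the default on inhibition-free modules", {
  for (m in c(0, 1, 3, 5)) {
    a <- quick_sim(m, regimen = drug_regimen("B"), inhibition = "deactivation")
    b <- quick_sim(m, regimen = drug_regimen("B"), inhibition = "literal")
    expect_identical(a$states, b$states, info = paste("module", m))
  }
  # ... and differs where inhibitory edges exist
  a <- quick_sim(4, inhibition = "deactivation")
  b <- quick_sim(4, inhibition = "literal")
  expect_gt(max(abs(a$states - b$states)), 1e-6)
})

test_that("integrated output is the trapezoidal integral of the output species", {
  traj <- quick_sim(0, h = 0.5)
  n <- length(traj$times)
  # constant output
  traj$states[, "O"] <- 1
  expect_equal(integrated_output(traj, 100), 100)
  traj$states[, "O"] <- 0
  expect_equal(integrated_output(traj, 100), 0)
  # linear ramp is trapezoid-exact
  traj$states[, "O"] <- traj$times / 100
  expect_equal(integrated_output(traj, 100), 50)
  # truncation at an interior horizon
  expect_equal(integrated_output(traj, 50), 12.5)
  expect_error(integrated_output(traj, 200), "before the horizon")
})

test_that("simulation guards its numeric preconditions", {
  expect_error(simulate_module(build_module(0), horizon = 10, h = 0.3),
               "integral number of steps")
  expect_error(simulate_module(build_module(0), horizon = -1, h = 0.1))
  expect_error(simulate_module(build_module(0), X0 = c(Inf, 0, 0, 0, 0),
                               horizon = 1, h = 0.1))
})

test_that("trajectories tidy into long form with full provenance", {
  traj <- quick_sim(2, regimen = drug_regimen("B"), h = 1)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 5 * length(traj$times))
  expect_setequal(unique(df$species), c("A", "B", "C", "D", "O"))
  expect_equal(unique(df$module_id), 2)
  expect_equal(unique(df$regimen), "B")
  expect_equal(unique(df$stimulus), "S0")
})
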