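test_that("all registered modules share the backbone and carry the right crosstalk signs", {
  # from, to, expected sign of V (per module legend)
  expected <- list(
    `0` = NULL,
    `1` = rbind(c("A", "D", +1)),
    `2` = rbind(c("A", "D", -1)),
    `3` = rbind(c("B", "C", +1)),
    `4` = rbind(c("B", "C", -1)),
    `5` = rbind(c("B", "C", +1), c("D", "A", +1)),
    `6` = rbind(c("B", "C", -1), c("D", "A", -1)),
    `7` = rbind(c("B", "C", -1), c("D", "A", +1)),
    `8` = rbind(c("B", "C", +1), c("D", "A", -1))
  )
  backbone <- rbind(c("A", "B"), c("B", "O"), c("C", "D"), c("D", "O"))
  for (m in 0:8) {
    top <- build_module(m)
    for (r in 1:4) {
      expect_equal(top$V[backbone[r, 1], backbone[r, 2]], 0.4,
                   info = paste("module", m, "backbone", r))
      expect_equal(top$K[backbone[r, 1], backbone[r, 2]], 0.8)
    }
    exp_ct <- expected[[as.character(m)]]
    expect_equal(nrow(top$crosstalk_edges), NROW(exp_ct),
                 info = paste("module", m, "crosstalk count"))
    for (r in seq_len(NROW(exp_ct))) {
      v <- top$V[exp_ct[r, 1], exp_ct[r, 2]]
      expect_true(sign(v) == as.numeric(exp_ct[r, 3]),
                  info = paste("module", m, "edge", exp_ct[r, 1], exp_ct[r, 2]))
    }
    # only backbone + declared crosstalk entries are nonzero
    expect_equal(sum(top$V != 0), 4L + NROW(exp_ct))
    expect_length(validate_topology(top), 0)
  }
})

test_that("module 6's mutual inhibition is asymmetric: D -| A full strength, B -| C half", {
  top <- build_module(6)
  expect_equal(top$V["D", "A"], -1)
  expect_equal(top$V["B", "C"], -0.5)
  expect_lt(top$V["D", "A"], top$V["B", "C"])  # stronger inhibition on A
  # the ratio is configurable
  expect_equal(build_module(6, m6_weak_ratio = 0.25)$V["B", "C"], -0.25)
})

test_that("crosstalk scale rescales crosstalk edges only, continuously to module 0", {
  m0 <- build_module(0)
  for (m in c(1, 2, 5, 6, 8)) {
    sc <- build_module(m, crosstalk_scale = 10)
    base <- build_module(m)
    ij <- sc$crosstalk_edges
    expect_equal(sc$V[ij], 10 * base$V[ij])
    # backbone untouched
    off <- sc$V; off[ij] <- 0
    baseoff <- base$V; baseoff[ij] <- 0
    expect_identical(off, baseoff)
    # scale -> 0 degenerates to module 0
    tiny <- build_module(m, crosstalk_scale = 1e-12)
    expect_equal(unname(tiny$V), unname(m0$V), tolerance = 1e-10)
  }
  expect_error(build_module(9), "0..8")
  expect_error(build_module(1, crosstalk_scale = 0))
})

test_that("standard parameters match the printed defaults", {
  p <- default_parameters()
  expect_equal(p$d, rep(0.2, 5))
  expect_equal(p$K_D, rep(0.1, 5))
  expect_equal(c(p$V_A, p$K_A, p$V_C, p$K_C), c(0.2, 0.5, 0.2, 0.5))
  expect_equal(c(p$V_act, p$V_inh, p$K_default), c(0.4, -1, 0.8))
})

test_that("stimulus library covers S0-S6 and evaluates piecewise", {
  lib <- stimulus_library()
  expect_setequal(names(lib), paste0("S", 0:6))
  s0 <- lib$S0$G1
  expect_equal(stimulus_value(s0, c(0, 15, 29.99)), c(1, 1, 1))
  expect_equal(stimulus_value(s0, c(30, 50, 100)), c(0, 0, 0))
  expect_equal(stimulus_value(lib$S5$G2, 10), 0.5)
  expect_equal(stimulus_value(lib$S6$G1, c(10, 25)), c(0, 1))
  # double pulse: on, off, on again
  expect_equal(stimulus_value(lib$S3$G1, c(5, 20, 45)), c(1, 0, 1))
  # staircase ramp rises towards 1
  ramp <- stimulus_value(lib$S4$G1, c(2, 12, 27))
  expect_true(all(diff(ramp) > 0) && max(ramp) == 1)
  # malformed profiles are rejected at construction
  expect_error(stimulus_profile("x", "G1",
    data.frame(t_start = c(0, 5), t_end = c(10, 15), amplitude = 1)),
    "overlap")
  expect_error(stimulus_profile("x", "G1",
    data.frame(t_start = 0, t_end = 10, amplitude = -1)))
})

test_that("validate_topology reports breaches without throwing", {
  top <- build_module(3)
  top$K["B", "C"] <- 0
  v <- validate_topology(top)
  expect_length(v, 1)
  expect_match(v, "K\\[2,3\\]")

  top2 <- build_module(0)
  top2$V["B", "O"] <- 0
  expect_match(validate_topology(top2), "B->O")

  top3 <- build_module(1)
  top3$V["A", "D"] <- 0  # annotated crosstalk edge with no rate
  expect_length(validate_topology(top3), 1)
  expect_match(validate_topology(top3), "crosstalk edge A->D")
})

test_that("drug regimens validate doses and label themselves", {
  expect_equal(regimen_label(drug_regimen()), "none")
  expect_equal(regimen_label(drug_regimen(c("B", "D"))), "B+D")
  expect_equal(regimen_label(drug_regimen(c("B", "B"))), "B+B")
  expect_error(drug_regimen("B", doses = -1), ">= 0")
  expect_error(species_index("Z"), "unknown species")
  expect_equal(species_index(c("A", "O")), c(1L, 5L))
})
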