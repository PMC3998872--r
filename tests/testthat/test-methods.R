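test_that("GIMME penalizes below-threshold reactions and meets the growth floor", {
  e1 <- make_e1()
  # gene levels 10 and 1; the 4/9 quantile puts the cutoff exactly at 5
  p <- expression_profile(c(g1 = 10, g2 = 1))
  cfg <- method_config(gimme_cutoff_pct = 400 / 9)
  r <- gimme(e1, p, cfg)
  expect_equal(r$status, "optimal")
  expect_equal(r$diagnostics$threshold, 5, tolerance = 1e-9)
  # only R2 is penalized (weight 4); all flux routes through R1
  expect_equal(unname(r$diagnostics$weights[c("R1", "R2")]), c(0, 4))
  expect_lt(abs(r$flux$values[["R2"]]), 1e-7)
  expect_equal(r$score, 0, tolerance = 1e-7)
  expect_gte(r$flux$objective_value, 0.9 * 10 - 1e-6)
  # all scores above the threshold: any zero-penalty solution at >= 90%
  r2 <- gimme(e1, expression_profile(c(g1 = 10, g2 = 10)), cfg)
  expect_equal(r2$score, 0, tolerance = 1e-9)
  expect_gte(r2$flux$objective_value, 9 - 1e-6)
  # objective_fraction 1 pins growth at the FBA optimum
  r3 <- gimme(e1, p, method_config(gimme_cutoff_pct = 400 / 9,
                                   objective_fraction = 1))
  expect_equal(r3$flux$objective_value, 10, tolerance = 1e-5)
})

test_that("GIMME penalty is non-increasing as the cutoff percentile drops", {
  toy <- build_toy_model()
  ds <- generate_dataset(2, seed = 4)
  prof <- ds$conditions[[1]]$expression
  prev <- Inf
  for (pct in c(90, 60, 25, 5)) {
    r <- gimme(toy, prof, toy_config(gimme_cutoff_pct = pct))
    expect_equal(r$status, "optimal")
    expect_lte(r$score, prev + 1e-9)
    prev <- r$score
  }
})

test_that("iMAT consistency equals exhaustive pattern enumeration", {
  br <- make_branch()
  r <- imat(br, branch_profile(), method_config())
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$diagnostics$class[c("RH", "RL")]),
               c("high", "low"))
  oracle <- imat_enum_score(br, "RH", "RL", eps = 1)
  expect_equal(r$score, oracle)
  expect_equal(r$score, 2)  # high branch active AND low branch silent
  expect_gte(r$flux$values[["RH"]], 1 - 1e-6)
  expect_lt(abs(r$flux$values[["RL"]]), 1e-7)
})

test_that("iMAT handles all-intermediate and structurally blocked cases", {
  br <- make_branch()
  # constant expression: every reaction intermediate, score 0
  r0 <- imat(br, expression_profile(c(gH = 5, gL = 5)), method_config())
  expect_equal(r0$score, 0)
  # high reaction with no path to the boundary: reward unattainable
  blocked <- metabolic_model(c("A", "B", "D"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "RH", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = "gH"),
    list(id = "RH2", stoichiometry = c(A = -1, D = 1), lb = 0, ub = 1000,
         gpr = "gH2"),
    list(id = "EXB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE)))
  pr <- expression_profile(c(gH = 10, gH2 = 9, f1 = 1, f2 = 2, f3 = 3,
                             f4 = 4, f5 = 5, f6 = 6))
  rb <- imat(blocked, pr, method_config())
  cls <- rb$diagnostics$class
  expect_equal(unname(cls[c("RH", "RH2")]), c("high", "high"))
  oracle <- imat_enum_score(blocked, c("RH", "RH2"), character(0), eps = 1)
  expect_equal(rb$score, oracle)
  expect_equal(rb$score, 1)  # total - 1: the blocked branch cannot fire
})

test_that("iMAT activation works in reverse for reversible reactions", {
  m <- metabolic_model(c("A"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "RREV", stoichiometry = c(A = -1), lb = -1000, ub = 1000,
         gpr = "gH"),
    list(id = "RB", stoichiometry = c(A = -1), lb = 0, ub = 1000,
         objective = TRUE)))
  # force zero uptake: activation only satisfiable with RREV negative
  m <- set_bounds(m, "EX_in", ub = 0)
  pr <- expression_profile(c(gH = 10, f1 = 2, f2 = 4, f3 = 5))
  r <- imat(m, pr, method_config())
  expect_equal(r$score, 1)
  expect_lte(r$flux$values[["RREV"]], -1 + 1e-6)
})

test_that("E-Flux turns normalized expression into capacities and rescales", {
  e1 <- make_e1()
  p <- expression_profile(c(g1 = 10, g2 = 5))
  cfg <- method_config(glucose_exchange_id = "EX_in")
  ms <- measurement_set("EX_in", 7.5, "uptake")
  r <- eflux(e1, p, cfg, ms)
  expect_equal(unname(r$diagnostics$bounds[c("R1", "R2")]), c(1, 0.5))
  expect_equal(unname(r$flux$values[["EX_in"]]), 7.5, tolerance = 1e-9)
  # equal scores: reduces to FBA on the unit-bounded network, rescaled
  peq <- expression_profile(c(g1 = 6, g2 = 6))
  req <- eflux(e1, peq, cfg, ms)
  unit <- e1
  unit$rxn$ub <- rep(1, 4)
  sol_unit <- fba(unit)
  expect_equal(req$flux$objective_value,
               7.5 * sol_unit$objective_value /
                 sol_unit$values[["EX_in"]], tolerance = 1e-6)
  # zero glucose flux in the solution is reported as failure
  dead <- set_bounds(e1, "EX_in", ub = 0)
  rz <- eflux(dead, p, cfg, ms)
  expect_equal(rz$status, "failed")
})

test_that("pairwise MADE agreement equals brute-force state enumeration", {
  cfg <- method_config()
  # two isozymes, one up-regulated, one unchanged
  e1 <- make_e1()
  ref <- expression_profile(c(g1 = 2, g2 = 5))
  tst <- expression_profile(c(g1 = 8, g2 = 5))
  r <- made_pairwise(e1, ref, tst, cfg)
  oracle <- made_enum_score(e1, c("g1", "g2"),
                            c(g1 = 1, g2 = 0), 0.9)
  expect_equal(r$status, "optimal")
  expect_equal(r$score, oracle)
  # single gene gating the only path: the 0 -> 1 transition would kill
  # reference growth, so the optimum sacrifices that gene's agreement
  ch <- make_chain()
  r2 <- made_pairwise(ch, expression_profile(c(g1 = 2)),
                      expression_profile(c(g1 = 8)), cfg)
  oracle2 <- made_enum_score(ch, "g1", c(g1 = 1), 0.9)
  expect_equal(r2$score, oracle2)
  expect_equal(r2$score, 0)
  expect_equal(r2$diagnostics$states$ref, 1)
  expect_equal(r2$diagnostics$states$test, 1)
  # identical profiles: all transitions d = 0, everything stays on
  r3 <- made_pairwise(e1, ref, ref, cfg)
  expect_equal(r3$score, 2)
  expect_true(all(r3$diagnostics$states$d == 0))
})

test_that("Lee-12 matches normalized fluxes to normalized expression", {
  ch <- make_chain()
  cfg <- method_config(glucose_exchange_id = "EX_in",
                       transporter_genes = "gt")
  ms <- measurement_set("EX_in", 10, "uptake")
  # chain expression 8, transporter 10 -> target |v|/10 = 0.8 -> v = 8
  p <- expression_profile(c(gt = 10, g1 = 8))
  r <- lee12(ch, p, cfg, ms)
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$flux$values[["R2"]]), 8, tolerance = 1e-6)
  expect_equal(r$score, 0, tolerance = 1e-7)
  # zero targets: scored fluxes collapse to zero
  p0 <- expression_profile(c(gt = 10, g1 = 0))
  r0 <- lee12(ch, p0, cfg, ms)
  expect_lt(sum(abs(r0$flux$values)), 1e-7)
  # unreachable target: flux saturates its bound, residual positive
  p2 <- expression_profile(c(gt = 10, g1 = 20))
  r2 <- lee12(ch, p2, cfg, ms)
  expect_equal(unname(r2$flux$values[["R2"]]), 10, tolerance = 1e-6)
  expect_equal(r2$score, 1, tolerance = 1e-6)  # |10/10 - 2|
  # transporter missing from the profile is a configuration error
  expect_error(lee12(ch, expression_profile(c(g1 = 5)), cfg, ms),
               "transporter")
})

test_that("GX-FBA builds its reference from FVA midpoints and scales bounds", {
  ch <- make_chain()
  # unconstrained chain: FVA range of R2 is [0, 10], midpoint 5
  cfg <- method_config(gxfba_fc_min = 0.5)
  ref_p <- expression_profile(c(g1 = 2))
  tst_p <- expression_profile(c(g1 = 8))  # fold change 4
  r <- gxfba(ch, ref_p, tst_p, cfg)
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$diagnostics$v_ref[["R2"]]), 5, tolerance = 1e-6)
  expect_equal(unname(r$diagnostics$fold_change[["R2"]]), 4)
  expect_equal(r$diagnostics$active, "R2")
  # wide chain: up-regulated bound = F * v_ref = 4 * 5 = 20 binds
  wide <- make_chain(ex_ub = 1000)
  msr <- measurement_set("EX_in", 10, "uptake")
  rw <- gxfba(wide, ref_p, tst_p, cfg, measurements_ref = msr)
  expect_equal(unname(rw$diagnostics$v_ref[["R2"]]), 10, tolerance = 1e-2)
  expect_equal(unname(rw$flux$values[["R2"]]), 40, tolerance = 1e-1)
  # objective coefficient log2(4)/10 = 0.2, so score = 0.2 * 40 = 8
  expect_equal(rw$score, 8, tolerance = 1e-2)
  # no differential expression: empty active set, degenerate objective
  rf <- gxfba(ch, ref_p, ref_p, cfg)
  expect_equal(rf$status, "failed")
  # zero reference expression excludes the reaction
  rz <- gxfba(ch, expression_profile(c(g1 = 0)), tst_p, cfg)
  expect_equal(rz$status, "failed")
  expect_true("R2" %in% rz$diagnostics$excluded)
})

test_that("optimal method results satisfy mass balance and constraints", {
  ds <- generate_dataset(3, seed = 2)
  toy <- ds$model
  cfg <- toy_config()
  cond <- ds$conditions[[3]]  # knockout mutant under moderate oxygen
  ref <- ds$conditions[[1]]   # reference chemostat condition
  adj <- fit_fluxes_to_model(toy, cond$measurements)
  for (m in method_names()) {
    r <- run_method(m, toy, cfg, cond$expression, adj, "uptake_only",
                    profile_ref = ref$expression,
                    measurements_ref = ref$measurements)
    expect_equal(r$status, "optimal", info = m)
    v <- r$flux$values[toy$rxn$id]
    expect_lt(max(abs(toy$S %*% v)), 1e-5)
    if (m != "eflux") {
      # scenario fixes the uptakes within the tolerance band
      up <- adj[adj$role == "uptake", ]
      dlt <- pmax(1e-6, 1e-3 * abs(up$value)) + 1e-6
      expect_true(all(abs(v[up$id] - up$value) <= dlt), info = m)
    } else {
      expect_equal(unname(v[["EX_glc"]]),
                   adj$value[adj$id == "EX_glc"], tolerance = 1e-6)
    }
  }
})
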