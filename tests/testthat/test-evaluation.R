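test_that("flux projection reconciles measurements with the model", {
  # two-reaction chain: measured (5, 7) must average to (6, 6)
  chain <- metabolic_model(c("A"), list(
    list(id = "R1", stoichiometry = c(A = 1), lb = 0, ub = 1000),
    list(id = "R2", stoichiometry = c(A = -1), lb = 0, ub = 1000,
         objective = TRUE)))
  adj <- fit_fluxes_to_model(chain, measurement_set(
    c("R1", "R2"), c(5, 7), c("uptake", "secretion")))
  expect_equal(adj$value, c(6, 6), tolerance = 1e-6)
  # feasible measurements come back unchanged
  adj2 <- fit_fluxes_to_model(chain, measurement_set(
    c("R1", "R2"), c(4, 4), c("uptake", "secretion")))
  expect_equal(adj2$value, c(4, 4), tolerance = 1e-6)
  # a measurement beyond the bound is clipped to it
  capped <- set_bounds(chain, "R1", ub = 10)
  adj3 <- fit_fluxes_to_model(capped, measurement_set(
    c("R1", "R2"), c(15, 15), c("uptake", "secretion")))
  expect_lte(max(adj3$value), 10 + 1e-8)
  expect_equal(adj3$value, c(10, 10), tolerance = 1e-6)
})

test_that("flux projection matches the active-set QP oracle", {
  e1 <- make_e1()
  set.seed(17)
  for (k in 1:10) {
    m <- measurement_set(c("EX_in", "R1", "RB"),
                         round(stats::runif(3, -2, 12), 2),
                         c("uptake", "intracellular", "growth"))
    got <- fit_fluxes_to_model(e1, m)
    oracle <- qp_enum_fit(e1, m)
    expect_equal(got$value, unname(oracle$v[match(m$id, e1$rxn$id)]),
                 tolerance = 1e-4)
  }
})

test_that("projected fluxes are feasible and closer than random points", {
  toy <- build_toy_model()
  ds <- generate_dataset(2, seed = 3)
  meas <- ds$conditions[[1]]$measurements
  meas$value <- meas$value * 1.3 + 0.5  # push off the feasible space
  adj <- fit_fluxes_to_model(toy, meas)
  # embed back: the adjusted vector extends to a feasible distribution
  full <- fit_fluxes_to_model(toy, adj)
  expect_equal(full$value, adj$value, tolerance = 1e-5)
  d_adj <- sum((adj$value - meas$value)^2)
  bc <- fluxbench:::base_constraints(toy)
  set.seed(4)
  for (k in 1:50) {
    cost <- stats::rnorm(nrow(toy$rxn))
    r <- fluxbench:::lp_solve(cost, bc$A, bc$rhs, bc$sense, bc$lb, bc$ub,
                              maximize = TRUE)
    d_rand <- sum((r$x[match(meas$id, toy$rxn$id)] - meas$value)^2)
    expect_gte(d_rand, d_adj - 1e-6)
  }
})

test_that("futile-cycle removal cancels circulation down to the net need", {
  m <- metabolic_model(c("A", "B"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "Rf", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "Rb", stoichiometry = c(B = -1, A = 1), lb = 0, ub = 1000),
    list(id = "RB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE)))
  # input flux: 1 unit of net conversion carried as 10 forward / 9 back
  flux <- flux_distribution(c(EX_in = 1, Rf = 10, Rb = 9, RB = 1), 1)
  out <- remove_futile_cycles(m, flux)
  expect_equal(unname(out$values[c("Rf", "Rb")]), c(1, 0),
               tolerance = 1e-8)
  expect_equal(unname(out$values[c("EX_in", "RB")]), c(1, 1))
  expect_equal(out$objective_value, flux$objective_value)
  expect_lte(sum(abs(out$values)), sum(abs(flux$values)))
})

test_that("futile-cycle removal is a no-op on loop-free networks", {
  e1 <- make_e1()
  expect_equal(futile_cycle_set(e1), character(0))
  p <- pfba(e1)
  expect_identical(remove_futile_cycles(e1, p)$values, p$values)
})

test_that("three-reaction internal cycles are reduced to the boundary need", {
  m <- metabolic_model(c("A", "B", "C"), list(
    list(id = "EX_A", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "RAB", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "RBC", stoichiometry = c(B = -1, C = 1), lb = 0, ub = 1000),
    list(id = "RCA", stoichiometry = c(C = -1, A = 1), lb = 0, ub = 1000),
    list(id = "EXB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE)))
  expect_setequal(futile_cycle_set(m), c("RAB", "RBC", "RCA"))
  # pure circulation of 5 on top of a net flow of 2
  flux <- flux_distribution(c(EX_A = 2, RAB = 7, RBC = 5, RCA = 5,
                              EXB = 2), 2)
  out <- remove_futile_cycles(m, flux)
  expect_equal(unname(out$values[c("RAB", "RBC", "RCA")]), c(2, 0, 0),
               tolerance = 1e-8)
  expect_equal(unname(out$values[c("EX_A", "EXB")]), c(2, 2))
})

test_that("cycle removal never touches exchanges, objective, or total flux", {
  toy <- build_toy_model()
  cs <- futile_cycle_set(toy)
  expect_setequal(cs, c("SH1", "SH2"))
  base <- pfba(set_bounds(toy, "EX_o2", ub = 6))
  # inject circulation through the shuttle
  inflated <- base
  inflated$values[c("SH1", "SH2")] <- inflated$values[c("SH1", "SH2")] + 40
  out <- remove_futile_cycles(toy, inflated, cs)
  ex <- toy$rxn$id[toy$rxn$is_exchange]
  expect_equal(out$values[ex], inflated$values[ex])
  expect_equal(out$objective_value, inflated$objective_value)
  expect_lte(sum(abs(out$values)), sum(abs(inflated$values)))
  expect_lt(sum(abs(out$values[c("SH1", "SH2")])), 1e-7)
})

test_that("normalized error has its closed forms and scale invariance", {
  ms <- measurement_set(c("r1", "r2"), c(1, 3),
                        c("intracellular", "intracellular"))
  expect_equal(normalized_error(c(r1 = 1, r2 = 3), ms), 0)
  expect_equal(normalized_error(c(r1 = 0, r2 = 0), ms), 1)
  expect_equal(normalized_error(c(r1 = 1, r2 = 1), ms), 2 / sqrt(10),
               tolerance = 1e-12)
  # missing predictions count as zero flux
  expect_equal(normalized_error(c(r1 = 1), ms), 3 / sqrt(10))
  # alternative normalization divides by the squared norm
  expect_equal(normalized_error(c(r1 = 1, r2 = 1), ms,
                                normalization = "norm_sq"), 2 / 10)
  zero <- measurement_set("r1", 0, "growth")
  expect_warning(e <- normalized_error(c(r1 = 1), zero), "zero norm")
  expect_true(is.na(e))
  set.seed(21)
  for (k in 1:100) {
    n <- sample(2:6, 1)
    u <- stats::rnorm(n); v <- stats::rnorm(n)
    alpha <- stats::runif(1, 0.01, 50)
    names(u) <- names(v) <- paste0("r", seq_len(n))
    msk <- measurement_set(names(v), v, "intracellular")
    msk_a <- measurement_set(names(v), alpha * v, "intracellular")
    expect_equal(normalized_error(alpha * u, msk_a),
                 normalized_error(u, msk), tolerance = 1e-9)
  }
})

test_that("evaluate_method composes the pipeline and captures failures", {
  ds <- generate_dataset(2, seed = 6)
  toy <- ds$model
  cond <- ds$conditions[[1]]
  adj <- fit_fluxes_to_model(toy, cond$measurements)
  rec <- evaluate_method(toy, "pfba", toy_config(), cond$expression, adj,
                         "uptake_only", condition = cond$label)
  expect_equal(rec$status, "ok")
  # independent composition of the four stages
  mc <- apply_measurements(toy, adj, "uptake_only")
  flux <- remove_futile_cycles(toy, pfba(mc))
  expect_equal(rec$error, normalized_error(flux, adj), tolerance = 1e-12)
  expect_equal(rec$n_compared, nrow(adj))
  # perfect information: measurements generated by pFBA itself
  expect_lt(rec$error, 2e-3)
  # an infeasible constraint set is recorded, not raised
  bad <- adj
  bad$value[bad$id == "BIOMASS"] <- 5
  rec2 <- evaluate_method(toy, "pfba", toy_config(), cond$expression, bad,
                          "full_physiology")
  expect_equal(rec2$status, "failed")
  expect_true(is.na(rec2$error))
})

test_that("evaluation is deterministic across repeated runs", {
  ds <- generate_dataset(2, seed = 6)
  toy <- ds$model
  cond <- ds$conditions[[2]]
  adj <- fit_fluxes_to_model(toy, cond$measurements)
  r1 <- evaluate_method(toy, "gimme", toy_config(), cond$expression, adj,
                        "uptake_only")
  r2 <- evaluate_method(toy, "gimme", toy_config(), cond$expression, adj,
                        "uptake_only")
  expect_identical(r1, r2)
})

test_that("summaries average over ok records and count failures", {
  recs <- data.frame(
    method = "m", condition = c("a", "b", "c"), scenario = "s",
    error = c(0.2, 0.4, NA), status = c("ok", "ok", "failed"),
    n_compared = c(3, 3, NA))
  s <- summarize_errors(recs)
  expect_equal(s$mean_error, 0.3)
  expect_equal(s$median_error, 0.3)
  expect_equal(s$n_failed, 1)
  all_fail <- within(recs, status <- "failed")
  s2 <- summarize_errors(all_fail)
  expect_true(is.na(s2$mean_error))
  expect_equal(s2$n_failed, 3)
  one <- recs[2, ]
  s3 <- summarize_errors(one)
  expect_equal(s3$median_error, 0.4)
  expect_equal(s3$mean_error, 0.4)
})
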