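test_that("model construction validates structure", {
  e1 <- make_e1()
  expect_s3_class(e1, "metabolic_model")
  expect_equal(e1$objective_reaction, "RB")
  expect_equal(e1$rxn$is_exchange, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(metabolic_model(c("A"), list(
    list(id = "R1", stoichiometry = c(B = 1), lb = 0, ub = 1,
         objective = TRUE))), "undeclared metabolite")
  expect_error(metabolic_model(c("A"), list(
    list(id = "R1", stoichiometry = c(A = 1), lb = 0, ub = 1,
         objective = TRUE),
    list(id = "R1", stoichiometry = c(A = -1), lb = 0, ub = 1))),
    "duplicate")
  expect_error(metabolic_model(c("A"), list(
    list(id = "R1", stoichiometry = c(A = 1), lb = 5, ub = 1,
         objective = TRUE))), "lower bound")
})

test_that("JSON round trip preserves the model", {
  e1 <- make_e1()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(e1, path)
  back <- load_model(path)
  expect_equal(back$rxn, e1$rxn)
  expect_equal(back$S, e1$S)
  expect_equal(back$metabolites, e1$metabolites)
})

test_that("SBML export loads back identical to the JSON model", {
  m <- build_toy_model()
  pj <- withr::local_tempfile(fileext = ".json")
  px <- withr::local_tempfile(fileext = ".xml")
  write_model(m, pj, "json")
  write_model(m, px, "sbml")
  from_json <- load_model(pj)
  from_sbml <- load_model(px)
  expect_equal(from_sbml$metabolites, from_json$metabolites)
  expect_equal(from_sbml$S, from_json$S)
  expect_equal(from_sbml$rxn$lb, from_json$rxn$lb)
  expect_equal(from_sbml$rxn$ub, from_json$rxn$ub)
  # GPR strings may differ in parenthesization; compare parsed structure
  for (k in seq_len(nrow(m$rxn))) {
    expect_equal(format(parse_gpr(from_sbml$rxn$gpr[k])),
                 format(parse_gpr(from_json$rxn$gpr[k])))
  }
  expect_equal(from_sbml$objective_reaction, from_json$objective_reaction)
})

test_that("malformed model files raise informative parse errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_model(bad), "malformed")
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list("A"), reactions = list(
    list(id = "R1", stoichiometry = list(Zz = 1), lb = 0, ub = 1,
         objective = TRUE))), bad2, auto_unbox = TRUE)
  expect_error(load_model(bad2), "undeclared metabolite.*Zz")
  expect_error(load_model("does-not-exist.json"), "not found")
})

test_that("measurement scenarios constrain the model as specified", {
  e1 <- make_e1()
  m <- apply_measurements(e1, measurement_set("EX_in", 7, "uptake"),
                          "uptake_only")
  i <- match("EX_in", m$rxn$id)
  delta <- max(1e-6, 1e-3 * 7)
  expect_equal(m$rxn$lb[i], 7 - delta)
  expect_equal(m$rxn$ub[i], 7 + delta)
  expect_false(m$growth_fixed)

  mf <- apply_measurements(e1, measurement_set("RB", 4, "growth"),
                           "full_physiology")
  expect_true(mf$growth_fixed)
  expect_equal(fba(mf)$objective_value, 4, tolerance = 1e-2)

  # uptake-only applies the uptake but leaves growth free
  ms <- measurement_set(c("EX_in", "RB"), c(7, 4), c("uptake", "growth"))
  mu <- apply_measurements(e1, ms, "uptake_only")
  expect_false(mu$growth_fixed)
  expect_equal(fba(mu)$objective_value, 7, tolerance = 1e-2)

  m9 <- apply_measurements(e1, measurement_set("EX_in", 10, "uptake"),
                           "min_growth_90")
  expect_equal(m9$rxn$lb[match("RB", m9$rxn$id)], 9, tolerance = 1e-2)

  expect_error(apply_measurements(e1, measurement_set("NOPE", 1, "uptake"),
                                  "uptake_only"), "NOPE")
})

test_that("uptake measurements can act as upper bounds", {
  e1 <- make_e1()
  m <- apply_measurements(e1, measurement_set("EX_in", 7, "uptake"),
                          "uptake_only", uptake_as = "upper")
  i <- match("EX_in", m$rxn$id)
  expect_equal(m$rxn$lb[i], 0)
  expect_equal(m$rxn$ub[i], 7 + max(1e-6, 7e-3))
})

test_that("gene deletion closes reactions via GPR logic", {
  e1 <- make_e1()
  d <- delete_genes(e1, "g1")
  expect_equal(d$rxn$ub[match("R1", d$rxn$id)], 0)
  expect_equal(fba(d)$objective_value, 10)  # isozyme R2 still open
  expect_equal(delete_genes(e1, character(0)), e1)
  # OR rule survives single deletion
  e2 <- make_e1(gpr1 = "g1 or g2")
  d2 <- delete_genes(e2, "g1")
  expect_gt(d2$rxn$ub[match("R1", d2$rxn$id)], 0)
  expect_warning(delete_genes(e1, "unknown_gene"), "not present")
})

test_that("gene deletion is idempotent and monotone", {
  toy <- build_toy_model()
  once <- delete_genes(toy, c("ldhA", "adhE"))
  twice <- delete_genes(once, c("ldhA", "adhE"))
  expect_equal(once, twice)
  sets <- list(c("adhE"), c("adhE", "ldhA", "ldhB"),
               c("adhE", "ldhA", "ldhB", "pta"))
  m_anaer <- set_bounds(toy, "EX_o2", ub = 0)
  prev <- Inf
  for (s in sets) {
    z <- fba(delete_genes(m_anaer, s))$objective_value
    if (is.na(z)) z <- 0
    expect_lte(z, prev + 1e-9)
    prev <- z
  }
})
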