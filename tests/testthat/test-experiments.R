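test_that("shuffle noise interpolates between data and permutation", {
  p <- expression_profile(c(a = 1, b = 2, c = 3, d = 4, e = 5))
  expect_equal(add_noise(p, 0, seed = 99)$levels, p$levels)
  y1 <- add_noise(p, 1, seed = 7)$levels
  expect_equal(sort(unname(y1)), sort(unname(p$levels)))
  # elementwise convex combination with the same seeded shuffle
  lam <- 0.5
  r <- fluxbench:::with_seed(123, sample(unname(p$levels)))
  y <- add_noise(p, lam, seed = 123)$levels
  expect_equal(unname(y), (1 - lam) * unname(p$levels) + lam * r)
  # exact mean preservation at every noise level
  for (lam in seq(0, 1, by = 0.25)) {
    expect_equal(mean(add_noise(p, lam, seed = 11)$levels),
                 mean(p$levels), tolerance = 1e-12)
  }
})

test_that("robustness analysis is reproducible with zero variance at lambda 0", {
  ds <- generate_dataset(2, seed = 5)
  toy <- ds$model
  cond <- ds$conditions[[1]]
  adj <- fit_fluxes_to_model(toy, cond$measurements)
  rb <- robustness_analysis(toy, "eflux", toy_config(), cond$expression,
                            adj, n_steps = 3, n_reps = 6, seed = 31)
  expect_equal(nrow(rb), 3)
  expect_equal(rb$lambda, c(0, 0.5, 1))
  expect_equal(rb$var_error[1], 0)
  expect_equal(rb$n_ok + rb$n_failed, rep(6, 3))
  # the lambda = 0 level equals the single-shot evaluation
  one <- evaluate_method(toy, "eflux", toy_config(), cond$expression, adj,
                         "uptake_only")
  expect_equal(rb$mean_error[1], one$error, tolerance = 1e-12)
  rb2 <- robustness_analysis(toy, "eflux", toy_config(), cond$expression,
                             adj, n_steps = 3, n_reps = 6, seed = 31)
  expect_identical(rb, rb2)
  # default grid spans [0, 1] in 10 equally spaced levels
  rb10 <- robustness_analysis(toy, "pfba", toy_config(), cond$expression,
                              adj, n_steps = 10, n_reps = 1, seed = 1)
  expect_equal(rb10$lambda, seq(0, 1, length.out = 10))
  expect_equal(diff(rb10$lambda), rep(1 / 9, 9), tolerance = 1e-12)
})

test_that("sweep grids follow the protocol ranges and spacings", {
  expect_equal(fluxbench:::sweep_grid("gimme", "objective_fraction"),
               seq(0, 1, length.out = 20))
  expect_equal(fluxbench:::sweep_grid("made", "objective_fraction"),
               seq(0, 1, length.out = 20))
  g <- fluxbench:::sweep_grid("imat", "imat_eps")
  expect_equal(length(g), 20)
  expect_equal(g[1], 0.1)
  expect_equal(g[20], 10)
  ratios <- g[-1] / g[-20]
  expect_equal(ratios, rep(ratios[1], 19), tolerance = 1e-9)
  lo <- fluxbench:::sweep_grid("imat", "imat_low_pct")
  expect_equal(range(lo), c(0, 75))
  hi <- fluxbench:::sweep_grid("imat", "imat_high_pct")
  expect_equal(range(hi), c(25, 100))
  expect_equal(range(fluxbench:::sweep_grid("gimme", "gimme_cutoff_pct")),
               c(0, 100))
  expect_error(fluxbench:::sweep_grid("eflux", "objective_fraction"),
               "not swept")
})

test_that("objective-fraction sweep is flat when growth is measured", {
  ds <- generate_dataset(2, seed = 5)
  sw <- sensitivity_sweep(ds$model, "gimme", "objective_fraction",
                          ds$conditions[1], toy_config(),
                          scenario = "full_physiology", n_grid = 5)
  expect_equal(nrow(sw), 5)
  expect_equal(sw$mean_error, rep(sw$mean_error[1], 5), tolerance = 1e-9)
})

test_that("the benchmark driver validates inputs and is deterministic", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, seed = 1, dir = dir)
  cf <- list(model = file.path(dir, "model.json"),
             expression = file.path(dir, "expression.tsv"),
             measurements = file.path(dir, "measurements.tsv"),
             methods = c("pfba", "eflux"),
             scenarios = c("uptake_only", "full_physiology"),
             output_dir = file.path(dir, "out"),
             config = list(glucose_exchange_id = "EX_glc",
                           transporter_genes = c("ptsG", "crr")))
  res <- run_benchmark(cf)
  expect_equal(nrow(res), 2 * 3 * 2)  # methods x conditions x scenarios
  expect_true(file.exists(file.path(dir, "out", "results.tsv")))
  expect_true(file.exists(file.path(dir, "out", "summary.json")))
  res2 <- run_benchmark(cf)
  expect_identical(res, res2)
  # unknown method fails before any solve
  bad <- cf; bad$methods <- c("pfba", "mystery")
  expect_error(run_benchmark(bad), "unknown method")
  bad2 <- cf; bad2$measurements <- "missing.tsv"
  expect_error(run_benchmark(bad2), "not found")
  # YAML config path round trip
  cfy <- cf
  yml <- file.path(dir, "bench.yaml")
  yaml::write_yaml(cfy, yml)
  res3 <- run_benchmark(yml)
  expect_equal(res3, res)
})
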