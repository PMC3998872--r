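# Robustness protocol, parameter-sensitivity sweeps, and the benchmark
# driver.

# evaluate expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               2147483647)
}

#' Add shuffle noise to an expression profile
#'
#' The gene expression vector `x` is randomly shuffled to produce a
#' random vector `r` with the same value distribution, and the noisy
#' vector is the convex combination `y = (1 - lambda) * x + lambda * r`.
#' `lambda = 0` returns the original data, `lambda = 1` completely
#' random data; the value mean is preserved exactly at every level.
#'
#' @param profile an `expression_profile`.
#' @param lambda noise weight in `[0, 1]`.
#' @param seed integer seed for the shuffle.
#' @return an `expression_profile`.
#' @export
add_noise <- function(profile, lambda, seed = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  x <- as_levels(profile)
  r <- with_seed(seed, sample(unname(x)))
  y <- (1 - lambda) * x + lambda * r
  expression_profile(y, if (inherits(profile, "expression_profile"))
    profile$condition else "condition")
}

#' Noise-robustness analysis of a method
#'
#' For each of `n_steps` equally spaced noise levels in `[0, 1]`,
#' `n_reps` independently shuffled noisy profiles are generated and
#' evaluated; the mean and variance of the prediction error are reported
#' per level (failed computations excluded, counted separately). Fully
#' reproducible from the seed; each (level, rep) pair reshuffles with its
#' own derived child seed.
#'
#' @param model a `metabolic_model`.
#' @param method method name.
#' @param cfg a [method_config()].
#' @param profile base `expression_profile`.
#' @param measurements adjusted `measurement_set`.
#' @param scenario constraint scenario.
#' @param n_steps number of lambda levels (endpoints included).
#' @param n_reps evaluations per level.
#' @param seed master seed.
#' @param profile_ref,measurements_ref reference condition (pairwise
#'   methods); the reference profile is left noise free.
#' @param cycle_set optional precomputed [futile_cycle_set()].
#' @return data frame: lambda, mean_error, var_error, n_ok, n_failed.
#' @export
robustness_analysis <- function(model, method, cfg = method_config(),
                                profile = NULL, measurements = NULL,
                                scenario = "uptake_only", n_steps = 10,
                                n_reps = 100, seed = 1,
                                profile_ref = NULL,
                                measurements_ref = NULL,
                                cycle_set = NULL) {
  stopifnot(n_steps >= 2, n_reps >= 1)
  if (is.null(cycle_set)) cycle_set <- futile_cycle_set(model)
  lambdas <- seq(0, 1, length.out = n_steps)
  out <- lapply(seq_along(lambdas), function(i) {
    errs <- rep(NA_real_, n_reps)
    for (j in seq_len(n_reps)) {
      noisy <- add_noise(profile, lambdas[i],
                         seed = child_seed(seed, (i - 1) * n_reps + j))
      rec <- evaluate_method(model, method, cfg, noisy, measurements,
                             scenario, profile_ref = profile_ref,
                             measurements_ref = measurements_ref,
                             cycle_set = cycle_set)
      if (rec$status == "ok") errs[j] <- rec$error
    }
    ok <- !is.na(errs)
    data.frame(lambda = lambdas[i],
               mean_error = if (any(ok)) mean(errs[ok]) else NA_real_,
               var_error = if (sum(ok) > 1) stats::var(errs[ok]) else
                 if (any(ok)) 0 else NA_real_,
               n_ok = sum(ok), n_failed = sum(!ok))
  })
  do.call(rbind, out)
}

sweep_grid <- function(method, parameter, n_grid = 20) {
  key <- paste(method, parameter, sep = ".")
  grids <- list(
    "gimme.objective_fraction" = seq(0, 1, length.out = n_grid),
    "made.objective_fraction" = seq(0, 1, length.out = n_grid),
    "gimme.gimme_cutoff_pct" = seq(0, 100, length.out = n_grid),
    "imat.imat_eps" = 10^seq(log10(0.1), log10(10), length.out = n_grid),
    "imat.imat_low_pct" = seq(0, 75, length.out = n_grid),
    "imat.imat_high_pct" = seq(25, 100, length.out = n_grid))
  if (is.null(grids[[key]])) {
    stop("parameter '", parameter, "' is not swept for method '", method,
         "'")
  }
  grids[[key]]
}

#' Parameter-sensitivity sweep
#'
#' Varies one parameter of a parameterized method over its protocol
#' range (20 grid points by default) while the others stay at their
#' defaults, and reports the prediction error averaged over all supplied
#' conditions at each grid value. Ranges: objective fraction linear in
#' `[0, 1]` (GIMME, MADE); GIMME cutoff percentile linear in `[0, 100]`;
#' iMAT activation threshold log-spaced in `[0.1, 10]`; iMAT low/high
#' percentile linear in `[0, 75]` / `[25, 100]`.
#'
#' @param model a `metabolic_model`.
#' @param method `"gimme"`, `"imat"` or `"made"`.
#' @param parameter the [method_config()] field to vary.
#' @param conditions list of condition entries, each with `expression`,
#'   `measurements` and `label` (a `toy_dataset$conditions` works).
#' @param cfg base configuration (defaults for the fixed parameters).
#' @param scenario constraint scenario.
#' @param n_grid grid size.
#' @param reference optional reference condition entry (MADE).
#' @return data frame: value, mean_error, n_ok, n_failed per grid point.
#' @export
sensitivity_sweep <- function(model, method, parameter, conditions,
                              cfg = method_config(),
                              scenario = "uptake_only", n_grid = 20,
                              reference = NULL) {
  grid <- sweep_grid(method, parameter, n_grid)
  cycle_set <- futile_cycle_set(model)
  out <- lapply(grid, function(val) {
    cfg2 <- cfg
    cfg2[[parameter]] <- val
    recs <- lapply(conditions, function(cond) {
      evaluate_method(model, method, cfg2, cond$expression,
                      cond$measurements, scenario,
                      condition = cond$label,
                      profile_ref = reference$expression,
                      measurements_ref = reference$measurements,
                      cycle_set = cycle_set)
    })
    recs <- do.call(rbind, recs)
    ok <- recs$status == "ok"
    data.frame(value = val,
               mean_error = if (any(ok)) mean(recs$error[ok]) else NA_real_,
               n_ok = sum(ok), n_failed = sum(!ok))
  })
  do.call(rbind, out)
}

#' Run a full benchmark from a configuration file
#'
#' The YAML configuration names the model, the expression and measurement
#' tables, the methods, scenarios and seed, plus optional method-config
#' overrides, e.g.:
#'
#' ```yaml
#' model: model.json
#' expression: expression.tsv
#' measurements: measurements.tsv
#' methods: [pfba, gimme, eflux]
#' scenarios: [uptake_only, full_physiology]
#' reference_condition: glc_10
#' seed: 1
#' output_dir: results
#' config:
#'   glucose_exchange_id: EX_glc
#'   transporter_genes: [ptsG, crr]
#' ```
#'
#' Inputs and method names are validated before any solve. Measurements
#' are projected onto the model once per condition
#' ([fit_fluxes_to_model()]), then every method x condition x scenario
#' cell is evaluated. Writes `results.tsv` (long format), `summary.json`
#' and `benchmark.log` to the output directory.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the results data frame, invisibly.
#' @export
run_benchmark <- function(config) {
  cf <- if (is.character(config)) {
    base <- dirname(config)
    cf <- yaml::read_yaml(config)
    for (f in c("model", "expression", "measurements")) {
      if (!is.null(cf[[f]]) && !file.exists(cf[[f]])) {
        cf[[f]] <- file.path(base, cf[[f]])
      }
    }
    cf
  } else config
  for (f in c("model", "expression", "measurements")) {
    if (is.null(cf[[f]])) stop("benchmark config missing field '", f, "'")
    if (is.character(cf[[f]]) && !file.exists(cf[[f]])) {
      stop("benchmark input not found: ", cf[[f]])
    }
  }
  methods <- unlist(cf$methods)
  unknown <- setdiff(methods, method_names())
  if (length(unknown) > 0) {
    stop("unknown method: ", paste(unknown, collapse = ", "))
  }
  scenarios <- unlist(cf$scenarios)
  if (is.null(scenarios)) scenarios <- "uptake_only"
  bad_sc <- setdiff(scenarios, c("uptake_only", "full_physiology",
                                 "min_growth_90"))
  if (length(bad_sc) > 0) {
    stop("unknown scenario: ", paste(bad_sc, collapse = ", "))
  }
  model <- if (is.character(cf$model)) load_model(cf$model) else cf$model
  profiles <- if (is.character(cf$expression)) {
    read_expression(cf$expression)
  } else cf$expression
  meas <- if (is.character(cf$measurements)) {
    read_measurements(cf$measurements)
  } else cf$measurements
  conds <- intersect(names(profiles), names(meas))
  if (length(conds) == 0) {
    stop("no shared conditions between expression and measurement tables")
  }
  cfg <- do.call(method_config, cf$config %||% list())
  ref_cond <- cf$reference_condition %||% conds[1]
  if (!ref_cond %in% conds) stop("unknown reference condition: ", ref_cond)
  log_lines <- c(paste("benchmark started", format(Sys.time())),
                 paste("conditions:", paste(conds, collapse = ", ")),
                 paste("reference:", ref_cond))
  adjusted <- lapply(conds, function(cn)
    fit_fluxes_to_model(model, meas[[cn]]))
  names(adjusted) <- conds
  cycle_set <- futile_cycle_set(model)
  records <- list()
  for (sc in scenarios) {
    for (me in methods) {
      for (cn in conds) {
        rec <- evaluate_method(model, me, cfg, profiles[[cn]],
                               adjusted[[cn]], sc, condition = cn,
                               profile_ref = profiles[[ref_cond]],
                               measurements_ref = adjusted[[ref_cond]],
                               cycle_set = cycle_set)
        log_lines <- c(log_lines, paste(me, cn, sc, rec$status,
                                        format(rec$error, digits = 6)))
        records[[length(records) + 1]] <- rec
      }
    }
  }
  results <- do.call(rbind, records)
  if (!is.null(cf$output_dir)) {
    dir.create(cf$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(cf$output_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_errors(results)
    jsonlite::write_json(summ, file.path(cf$output_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(cf$output_dir, "benchmark.log"))
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
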