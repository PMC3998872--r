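# Synthetic toy fixtures: a small central-carbon-style network with known
# ground-truth fluxes, expression profiles correlated with those fluxes,
# and measurement subsets mimicking a 13C-flux study (uptake, secretion,
# growth, and a central intracellular subset).

#' Build the canonical toy metabolic network
#'
#' A fixed (seedless) ~20-reaction network emulating the comparison
#' surface of a central-carbon flux study: glucose and oxygen uptake,
#' lumped glycolysis (EMP) with a lower-yield alternative route (ED), a
#' gluconeogenic back-reaction, fermentation exits (lactate, ethanol,
#' acetate), pyruvate oxidation plus a lumped TCA cycle, oxidative
#' phosphorylation, ATP maintenance, a biomass objective drawing
#' precursors and ATP, and a two-reaction internal shuttle that can carry
#' futile-cycle flux. Every enzymatic conversion carries a GPR with at
#' least one AND complex and one OR isozyme pair. Oxygen limitation
#' reproduces overflow metabolism: with ample oxygen the optimum is fully
#' respiratory, with low oxygen fermentation products are secreted.
#'
#' @return a `metabolic_model`.
#' @export
build_toy_model <- function() {
  metabolic_model(
    metabolites = c("glc", "g6p", "pyr", "accoa", "lac", "eth", "ac",
                    "o2", "co2", "atp", "nadh", "pyrsh", "cap"),
    reactions = list(
      list(id = "EX_glc", stoichiometry = c(glc = 1), lb = 0, ub = 10),
      list(id = "EX_o2", stoichiometry = c(o2 = 1), lb = 0, ub = 1000),
      list(id = "PTS", stoichiometry = c(glc = -1, atp = -1, g6p = 1),
           lb = 0, ub = 1000, gpr = "ptsG and crr"),
      list(id = "EMP",
           stoichiometry = c(g6p = -1, pyr = 2, atp = 3, nadh = 2),
           lb = 0, ub = 1000, gpr = "pgi and pfkA"),
      list(id = "ED",
           stoichiometry = c(g6p = -1, pyr = 1, co2 = 3, nadh = 4),
           lb = 0, ub = 1000, gpr = "edd or eda"),
      list(id = "GNG",
           stoichiometry = c(pyr = -2, atp = -5, nadh = -2, g6p = 1),
           lb = 0, ub = 1000, gpr = "fbp"),
      list(id = "LDH", stoichiometry = c(pyr = -1, nadh = -1, lac = 1),
           lb = 0, ub = 1000, gpr = "ldhA or ldhB"),
      list(id = "ADH",
           stoichiometry = c(pyr = -1, nadh = -2, eth = 1, co2 = 1),
           lb = 0, ub = 1000, gpr = "adhE"),
      list(id = "PTA",
           stoichiometry = c(pyr = -1, ac = 1, co2 = 1, nadh = 1, atp = 1),
           lb = 0, ub = 1000, gpr = "pta and ackA"),
      list(id = "PDH",
           stoichiometry = c(pyr = -1, accoa = 1, co2 = 1, nadh = 1),
           lb = 0, ub = 1000, gpr = "aceE and lpd"),
      list(id = "TCA",
           stoichiometry = c(accoa = -1, co2 = 2, nadh = 3, atp = 1),
           lb = 0, ub = 1000, gpr = "gltA and icd"),
      list(id = "NOX", stoichiometry = c(nadh = -1, o2 = -0.5, atp = 2),
           lb = 0, ub = 1000, gpr = "nuoA and cyoB"),
      list(id = "SH1", stoichiometry = c(pyr = -1, pyrsh = 1),
           lb = 0, ub = 1000, gpr = "sfcA"),
      list(id = "SH2", stoichiometry = c(pyrsh = -1, pyr = 1),
           lb = 0, ub = 1000, gpr = "maeB"),
      list(id = "ATPM", stoichiometry = c(atp = -1), lb = 1, ub = 1000),
      # lumped macromolecule polymerization: growth demands substantial
      # synthesis flux, as in genome-scale reconstructions where biomass
      # formation drains hundreds of biosynthetic reactions
      list(id = "POLY", stoichiometry = c(atp = -0.5, cap = 1),
           lb = 0, ub = 1000, gpr = "rplA"),
      list(id = "BIOMASS",
           stoichiometry = c(g6p = -6, pyr = -3, accoa = -9, cap = -150),
           lb = 0, ub = 1000, objective = TRUE),
      list(id = "EX_lac", stoichiometry = c(lac = -1), lb = 0, ub = 1000),
      list(id = "EX_eth", stoichiometry = c(eth = -1), lb = 0, ub = 1000),
      list(id = "EX_ac", stoichiometry = c(ac = -1), lb = 0, ub = 1000),
      list(id = "EX_co2", stoichiometry = c(co2 = -1), lb = 0, ub = 1000)
    ))
}

#' Glucose transporter genes of the toy network
#' @return character vector (the PTS complex genes).
#' @export
toy_transporter_genes <- function() c("ptsG", "crr")

#' Default method configuration for the toy network
#' @param ... overrides passed to [method_config()].
#' @return a `method_config` wired to the toy network's glucose exchange
#'   and transporter genes.
#' @export
toy_config <- function(...) {
  method_config(glucose_exchange_id = "EX_glc",
                transporter_genes = toy_transporter_genes(), ...)
}

#' Ground-truth fluxes for a fixture condition
#'
#' The condition's truth is the pFBA flux distribution of the (optionally
#' perturbed) model under the given uptake constraints.
#'
#' @param model a `metabolic_model`.
#' @param uptakes a `measurement_set` of uptake-role entries.
#' @param knockout optional gene ids deleted before simulation.
#' @param bounds optional named list `id -> c(lb, ub)` of bound edits.
#' @return a `flux_distribution`.
#' @export
ground_truth_fluxes <- function(model, uptakes, knockout = NULL,
                                bounds = NULL) {
  m <- apply_measurements(model, uptakes, "uptake_only")
  if (!is.null(knockout)) m <- delete_genes(m, knockout)
  if (!is.null(bounds)) {
    for (id in names(bounds)) {
      m <- set_bounds(m, id, lb = bounds[[id]][1], ub = bounds[[id]][2])
    }
  }
  sol <- pfba(m)
  if (sol$status != "optimal") {
    stop("fixture misconfigured: ground truth infeasible")
  }
  sol
}

#' Synthesize an expression profile correlated with a flux distribution
#'
#' Per reaction with a GPR, the target score is `|v_r| + 1` (the offset
#' keeps genes of zero-flux reactions measurable and gives percentile
#' thresholds spread at zero flux). Gene levels are assigned by inverting
#' the GPR mapping: AND members are all set to the target; OR members are
#' all set to the target under `or_mode = "max"` or split equally under
#' `"sum"`, so the forward mapping reproduces the target exactly.
#' Multiplicative log-normal noise with log-sd `noise_sd` is then applied
#' per gene.
#'
#' @param model a `metabolic_model`.
#' @param truth a `flux_distribution`.
#' @param noise_sd log-normal noise level (0 = noise free).
#' @param seed integer seed (deterministic output).
#' @param or_mode isozyme inversion convention.
#' @param condition condition label.
#' @return an `expression_profile` covering every gene in the model.
#' @export
synth_expression <- function(model, truth, noise_sd = 0, seed = 1,
                             or_mode = c("max", "sum"),
                             condition = "condition") {
  or_mode <- match.arg(or_mode)
  levels <- c()
  assign_rule <- function(rule, value) {
    if (rule$type == "gene") {
      levels[rule$gene] <<- value
    } else if (rule$type == "and") {
      for (ch in rule$children) assign_rule(ch, value)
    } else {
      v <- if (or_mode == "sum") value / length(rule$children) else value
      for (ch in rule$children) assign_rule(ch, v)
    }
  }
  for (k in seq_len(nrow(model$rxn))) {
    g <- model$rxn$gpr[k]
    if (!nzchar(g)) next
    target <- abs(truth$values[[model$rxn$id[k]]]) + 1
    assign_rule(parse_gpr(g), target)
  }
  if (noise_sd > 0) {
    levels <- with_seed(seed, {
      levels * stats::rlnorm(length(levels), meanlog = 0, sdlog = noise_sd)
    })
  }
  expression_profile(levels, condition)
}

#' Generate a toy benchmark dataset
#'
#' Produces `n_conditions` conditions cycling through three archetypes
#' that emulate the shapes of published multi-omics studies: a
#' chemostat-like glucose series (varied uptake under ample oxygen), an
#' oxygenation series at full glucose uptake (spanning anaerobiosis to
#' overflow), and gene-perturbation mutants under moderate oxygen
#' limitation. Each condition carries its ground-truth pFBA flux, an
#' expression profile correlated with it (`|v| + 1`, plus noise), and a
#' measurement subset (glucose/oxygen uptake, secretion rates, growth,
#' and a central-carbon intracellular subset).
#'
#' @param n_conditions number of conditions (>= 1).
#' @param seed master seed; the generated object is bit-reproducible from
#'   `(n_conditions, seed)`.
#' @param noise_sd expression noise level, see [synth_expression()].
#' @param dir optional directory: when given, writes `model.json`,
#'   `expression.tsv`, `measurements.tsv` and `truth.tsv` (the truth
#'   table is for testing only, it is not a benchmark input).
#' @return a `toy_dataset`: list with `model`, `conditions` (each with
#'   `label`, `measurements`, `expression`, `truth`), and `seed`.
#' @export
generate_dataset <- function(n_conditions = 6, seed = 1, noise_sd = 0,
                             dir = NULL) {
  stopifnot(n_conditions >= 1)
  model <- build_toy_model()
  measured_ids <- list(
    uptake = c("EX_glc", "EX_o2"),
    secretion = c("EX_lac", "EX_eth", "EX_ac"),
    growth = "BIOMASS",
    intracellular = c("EMP", "ED", "PDH", "TCA", "LDH", "ADH", "PTA"))
  glc_series <- c(10, 4, 7, 8.5, 5.5)
  o2_series <- c(6, 0, 12, 3, 20)
  ko_series <- list("pta", "adhE", "ldhA", "nuoA", "aceE")
  conditions <- list()
  for (k in seq_len(n_conditions)) {
    arch <- (k - 1) %% 3
    rep_i <- ((k - 1) %/% 3) %% 5 + 1
    if (arch == 0) {
      label <- paste0("glc_", glc_series[rep_i])
      m0 <- set_bounds(model, "EX_glc", ub = glc_series[rep_i])
      knockout <- NULL
    } else if (arch == 1) {
      label <- paste0("o2_", o2_series[rep_i])
      m0 <- set_bounds(model, "EX_o2", ub = o2_series[rep_i])
      knockout <- NULL
    } else {
      label <- paste0("ko_", ko_series[[rep_i]])
      m0 <- set_bounds(model, "EX_o2", ub = 8)
      knockout <- ko_series[[rep_i]]
    }
    if (!is.null(knockout)) m0 <- delete_genes(m0, knockout)
    truth <- pfba(m0)
    if (truth$status != "optimal") {
      stop("fixture misconfigured: condition ", label, " infeasible")
    }
    ids <- unlist(measured_ids, use.names = FALSE)
    roles <- rep(names(measured_ids), lengths(measured_ids))
    meas <- measurement_set(ids, unname(truth$values[ids]), roles)
    expr <- synth_expression(model, truth, noise_sd = noise_sd,
                             seed = child_seed(seed, k),
                             condition = label)
    conditions[[label]] <- list(label = label, measurements = meas,
                                expression = expr, truth = truth)
  }
  ds <- structure(list(model = model, conditions = conditions,
                       seed = seed), class = "toy_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.toy_dataset <- function(x, ...) {
  cat("toy_dataset:", length(x$conditions), "conditions (seed",
      x$seed, ")\n")
  invisible(x)
}

#' Write a toy dataset to disk
#' @param ds a `toy_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(ds$model, file.path(dir, "model.json"))
  write_expression(lapply(ds$conditions, `[[`, "expression"),
                   file.path(dir, "expression.tsv"))
  write_measurements(lapply(ds$conditions, `[[`, "measurements"),
                     file.path(dir, "measurements.tsv"))
  truth <- data.frame(reaction_id = ds$model$rxn$id,
                      stringsAsFactors = FALSE)
  for (nm in names(ds$conditions)) {
    truth[[nm]] <- unname(ds$conditions[[nm]]$truth$values[truth$reaction_id])
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a toy dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return a `toy_dataset` (truth included when `truth.tsv` is present).
#' @export
read_dataset <- function(dir) {
  model <- load_model(file.path(dir, "model.json"))
  profiles <- read_expression(file.path(dir, "expression.tsv"))
  meas <- read_measurements(file.path(dir, "measurements.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth_tab <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, check.names = FALSE)
  } else NULL
  conditions <- list()
  for (nm in names(meas)) {
    truth <- if (!is.null(truth_tab) && nm %in% names(truth_tab)) {
      v <- stats::setNames(truth_tab[[nm]], truth_tab$reaction_id)
      flux_distribution(v, unname(v[model$objective_reaction]), "optimal")
    } else NULL
    conditions[[nm]] <- list(label = nm, measurements = meas[[nm]],
                             expression = profiles[[nm]], truth = truth)
  }
  structure(list(model = model, conditions = conditions, seed = NA),
            class = "toy_dataset")
}
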