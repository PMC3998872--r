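# LP-based integration methods: GIMME, E-Flux, Lee-12.

#' GIMME: expression-weighted minimal inactive-reaction usage
#'
#' Minimizes the usage of reactions expressed below a cutoff threshold,
#' weighted by how far below the threshold they are, while requiring a
#' minimum fraction of the maximum biological objective. Continuous
#' expression values are used as weights: `w_r = max(t - x_r, 0)` with `t`
#' the cutoff-percentile threshold and `x_r` the GPR-mapped reaction
#' score; the LP is `min sum w_r |v_r|` subject to steady state, bounds,
#' and `growth >= objective_fraction * max growth`. When the growth rate
#' is already fixed by measurement constraints the growth requirement is
#' dropped (it has no effect). Among penalty-optimal solutions the
#' minimal total flux one is reported.
#'
#' @param model a (scenario-constrained) `metabolic_model`.
#' @param profile an `expression_profile`.
#' @param cfg a [method_config()].
#' @return a `method_result`; `score` is the attained penalty.
#' @export
gimme <- function(model, profile, cfg = method_config()) {
  levels <- as_levels(profile)
  x <- map_expression(model, profile,
                      or_mode = default_or_mode(cfg, "gimme", "max"))
  pool <- if (cfg$threshold_level == "gene") levels else x[!is.na(x)]
  t_cut <- stats::quantile(pool, cfg$gimme_cutoff_pct / 100, names = FALSE,
                           type = 7)
  w <- pmax(t_cut - x, 0)
  w[is.na(w)] <- 0
  extra <- growth_floor_rows(model, cfg$objective_fraction)
  if (is.character(extra)) return(failed_result(lp_status(extra)))
  res <- solve_weighted_l1(model, w, extra, tie_break = TRUE)
  if (res$status != "optimal") return(failed_result(lp_status(res$status)))
  method_result(flux_distribution(res$flux,
                                  unname(res$flux[model$objective_reaction]),
                                  "optimal"),
                score = res$objval,
                diagnostics = list(threshold = t_cut, weights = w))
}

#' E-Flux: expression levels as flux capacities
#'
#' Gene expression is normalized by the maximum expression level across
#' all genes and mapped to reaction upper bounds ("pipe capacities"); the
#' biomass objective is then maximized on the unit-scaled network.
#' Exchange-rate measurement constraints are not applied (they would make
#' the adimensional network infeasible); instead the resulting flux
#' distribution is rescaled so that glucose uptake matches the measured
#' value.
#'
#' @param model a `metabolic_model` (unconstrained).
#' @param profile an `expression_profile`.
#' @param cfg a [method_config()]; `glucose_exchange_id` is required.
#' @param measurements `measurement_set` providing the measured glucose
#'   uptake used for rescaling.
#' @return a `method_result`; `diagnostics$bounds` holds the normalized
#'   capacities.
#' @export
eflux <- function(model, profile, cfg = method_config(),
                  measurements = NULL) {
  if (is.null(cfg$glucose_exchange_id)) {
    stop("eflux requires cfg$glucose_exchange_id")
  }
  u_meas <- measured_value(measurements, cfg$glucose_exchange_id)
  if (is.null(u_meas)) {
    stop("eflux requires a measured glucose uptake rate for rescaling")
  }
  levels <- as_levels(profile)
  x <- map_expression(model, profile,
                      or_mode = default_or_mode(cfg, "eflux", "sum"))
  cap <- x / max(levels)
  cap[is.na(cap)] <- 1
  m2 <- model
  m2$rxn$ub <- ifelse(model$rxn$ub > 0, cap, 0)
  m2$rxn$lb <- ifelse(model$rxn$lb < 0, -cap, 0)
  sol <- fba(m2)
  if (sol$status != "optimal") {
    return(failed_result(sol$status, diagnostics = list(bounds = cap)))
  }
  u_sol <- unname(sol$values[cfg$glucose_exchange_id])
  if (abs(u_sol) < 1e-9) {
    return(failed_result("failed",
                         diagnostics = list(bounds = cap,
                                            reason = "zero glucose flux")))
  }
  scale <- u_meas / u_sol
  vals <- sol$values * scale
  method_result(flux_distribution(vals,
                                  unname(vals[model$objective_reaction]),
                                  "optimal"),
                score = sol$objective_value,
                diagnostics = list(bounds = cap, scale = scale))
}

#' Lee-12: match absolute fluxes to normalized expression
#'
#' Replaces the biological objective by the distance between the flux
#' distribution and the expression data: the flux vector is normalized by
#' the glucose uptake rate and the expression vector by the expression of
#' the glucose transporters, and `sum_r | |v_r|/u_glc - x_r_hat |` is
#' minimized over the scored reactions subject to steady state, bounds
#' and the applied measurement constraints. Absolute fluxes are
#' linearized by splitting reversible reactions into forward and reverse
#' components. Among distance-optimal solutions the minimal total flux
#' one is reported.
#'
#' @param model a (scenario-constrained) `metabolic_model`.
#' @param profile an `expression_profile`.
#' @param cfg a [method_config()]; `glucose_exchange_id` and
#'   `transporter_genes` are required.
#' @param measurements `measurement_set` providing the glucose uptake.
#' @return a `method_result`; `score` is the attained distance.
#' @export
lee12 <- function(model, profile, cfg = method_config(),
                  measurements = NULL) {
  if (is.null(cfg$glucose_exchange_id) || is.null(cfg$transporter_genes)) {
    stop("lee12 requires cfg$glucose_exchange_id and cfg$transporter_genes")
  }
  levels <- as_levels(profile)
  tg <- intersect(cfg$transporter_genes, names(levels))
  t_score <- sum(levels[tg])
  if (length(tg) == 0 || !is.finite(t_score) || t_score <= 0) {
    stop("lee12: glucose transporter expression missing or zero")
  }
  u_glc <- measured_value(measurements, cfg$glucose_exchange_id)
  if (is.null(u_glc)) {
    i <- rxn_index(model, cfg$glucose_exchange_id)
    u_glc <- model$rxn$ub[i]  # fall back to the imposed uptake bound
  }
  if (!is.finite(u_glc) || u_glc <= 0) {
    stop("lee12: glucose uptake rate unavailable")
  }
  x <- map_expression(model, profile,
                      or_mode = default_or_mode(cfg, "lee12", "sum"))
  xhat <- x / t_score
  scored <- which(!is.na(xhat))
  ns <- length(scored)
  if (ns == 0) return(failed_result("failed"))
  n <- nrow(model$rxn)
  lb <- model$rxn$lb; ub <- model$rxn$ub
  # variables: vf (n), vr (n), resid (ns); net flux v = vf - vr
  lbf <- pmax(lb, 0); ubf <- pmax(ub, 0)
  lbr <- pmax(-ub, 0); ubr <- pmax(-lb, 0)
  S <- model$S
  m <- nrow(S)
  A <- cbind(S, -S, matrix(0, m, ns))
  rhs <- rep(0, m); sense <- rep("=", m)
  # residual rows: resid >= (vf+vr)/u - xhat ; resid >= xhat - (vf+vr)/u
  for (k in seq_len(ns)) {
    j <- scored[k]
    row1 <- rep(0, 2 * n + ns); row1[j] <- -1 / u_glc
    row1[n + j] <- -1 / u_glc; row1[2 * n + k] <- 1
    row2 <- rep(0, 2 * n + ns); row2[j] <- 1 / u_glc
    row2[n + j] <- 1 / u_glc; row2[2 * n + k] <- 1
    A <- rbind(A, row1, row2)
    rhs <- c(rhs, -xhat[j], xhat[j])
    sense <- c(sense, ">=", ">=")
  }
  # net-flux bounds where both split halves are open
  both <- which(ubf > 0 & ubr > 0)
  for (j in both) {
    row <- rep(0, 2 * n + ns); row[j] <- 1; row[n + j] <- -1
    A <- rbind(A, row, row)
    rhs <- c(rhs, lb[j], ub[j])
    sense <- c(sense, ">=", "<=")
  }
  lbv <- c(lbf, lbr, rep(0, ns))
  ubv <- c(ubf, ubr, rep(Inf, ns))
  cost <- c(rep(0, 2 * n), rep(1, ns))
  res <- lp_solve(cost, A, rhs, sense, lbv, ubv, maximize = FALSE)
  if (res$status != "optimal") return(failed_result(lp_status(res$status)))
  res <- refine_parsimonious(res, cost, A, rhs, sense, lbv, ubv,
                             maximize = FALSE, n_flux = 2 * n)
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)],
                       model$rxn$id)
  method_result(flux_distribution(v, unname(v[model$objective_reaction]),
                                  "optimal"),
                score = res$objval,
                diagnostics = list(xhat = xhat, u_glc = u_glc,
                                   transporter_score = t_score))
}
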