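# GX-FBA: differential expression defines the objective and bounds of the
# perturbed state relative to an FVA-derived reference flux distribution.

#' GX-FBA: relative expression guides the perturbed flux state
#'
#' A reference flux distribution is taken as the midpoint of the flux
#' variability (FVA) range of each reaction under the reference-condition
#' constraints. For every reaction with a nonzero reference flux and
#' expression in both conditions, the fold change
#' `F_r = x_test,r / x_ref,r` is computed; reactions with
#' `|log2 F_r| >= fc_min` form the active set. The perturbed-state LP
#' maximizes `sum (log2 F_r / v_ref,r) * v_r` over the active set, with
#' each active reaction's upper bound moved to `F_r * v_ref,r` (a relaxed
#' cap for up-regulation, a shrunk cap for down-regulation), subject to
#' the perturbed model's constraints. Among optima the minimal total flux
#' solution is reported.
#'
#' @param model a `metabolic_model` (unconstrained).
#' @param profile_ref,profile_test reference and test
#'   `expression_profile`s.
#' @param cfg a [method_config()].
#' @param measurements_ref reference-condition `measurement_set` (uptake
#'   bounds for the FVA reference).
#' @param measurements_test test-condition `measurement_set`.
#' @param scenario scenario for the test-condition constraints.
#' @param fva_ref optional precomputed reference FVA ranges (the
#'   `ranges` data frame from [fva()]), reused across invocations since
#'   the FVA step dominates the cost.
#' @return a `method_result`; `diagnostics` records the reference fluxes,
#'   fold changes and exclusions.
#' @export
gxfba <- function(model, profile_ref, profile_test, cfg = method_config(),
                  measurements_ref = NULL, measurements_test = NULL,
                  scenario = "uptake_only", fva_ref = NULL) {
  m_ref <- if (is.null(measurements_ref)) model
  else apply_measurements(model, measurements_ref, "uptake_only",
                          uptake_as = cfg$uptake_as)
  if (is.null(fva_ref)) {
    fv <- fva(m_ref)
    if (fv$status != "optimal") return(failed_result(lp_status(fv$status)))
    fva_ref <- fv$ranges
  }
  v_ref <- stats::setNames((fva_ref$min + fva_ref$max) / 2, fva_ref$id)
  v_ref <- v_ref[model$rxn$id]
  or_mode <- default_or_mode(cfg, "gxfba", "max")
  x_ref <- map_expression(model, profile_ref, or_mode = or_mode)
  x_test <- map_expression(model, profile_test, or_mode = or_mode)
  excluded <- character(0)
  scored <- !is.na(x_ref) & !is.na(x_test) & abs(v_ref) > cfg$gxfba_zeta
  zero_ref <- scored & x_ref <= 0
  if (any(zero_ref)) excluded <- c(excluded, model$rxn$id[zero_ref])
  neg_ref <- scored & !zero_ref & v_ref < 0
  if (any(neg_ref)) excluded <- c(excluded, model$rxn$id[neg_ref])
  eligible <- scored & !zero_ref & !neg_ref
  Fc <- stats::setNames(rep(NA_real_, length(v_ref)), model$rxn$id)
  Fc[eligible] <- x_test[eligible] / x_ref[eligible]
  active <- which(eligible & abs(log2(Fc)) >= cfg$gxfba_fc_min)
  if (length(active) == 0) {
    return(failed_result("failed",
                         diagnostics = list(reason = "empty active set",
                                            excluded = excluded)))
  }
  m_t <- if (is.null(measurements_test)) model
  else apply_measurements(model, measurements_test, scenario,
                          uptake_as = cfg$uptake_as)
  n <- nrow(m_t$rxn)
  cost <- rep(0, n)
  uncapped <- character(0)
  for (j in active) {
    cost[j] <- log2(Fc[j]) / v_ref[j]
    cap <- min(m_t$rxn$ub[j], Fc[j] * v_ref[j])
    if (cap >= m_t$rxn$lb[j]) {
      m_t$rxn$ub[j] <- cap
    } else {
      # the fold-change cap contradicts a fixed measurement; the hard
      # constraint wins and the cap is skipped for this reaction
      uncapped <- c(uncapped, model$rxn$id[j])
    }
  }
  bc <- base_constraints(m_t)
  res <- lp_solve(cost, bc$A, bc$rhs, bc$sense, bc$lb, bc$ub,
                  maximize = TRUE)
  if (res$status != "optimal") return(failed_result(lp_status(res$status)))
  res <- refine_parsimonious(res, cost, bc$A, bc$rhs, bc$sense, bc$lb,
                             bc$ub, maximize = TRUE, n_flux = n)
  v <- stats::setNames(res$x, m_t$rxn$id)
  method_result(flux_distribution(v, unname(v[model$objective_reaction]),
                                  "optimal"),
                score = res$objval,
                diagnostics = list(v_ref = v_ref, fold_change = Fc,
                                   active = model$rxn$id[active],
                                   excluded = excluded,
                                   uncapped = uncapped))
}
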