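# Base constraint-based solvers. All formulations share the steady-state
# polytope {v : S v = 0, lb <= v <= ub}; absolute-value objectives are
# linearized with auxiliary variables t_r >= |v_r|.

#' Construct a flux distribution
#' @param values named numeric vector of fluxes (reaction id -> flux).
#' @param objective_value flux through the objective reaction, or `NA`.
#' @param status `"optimal"`, `"infeasible"` or `"failed"`.
#' @return a `flux_distribution`.
#' @export
flux_distribution <- function(values = numeric(0), objective_value = NA_real_,
                              status = "optimal") {
  structure(list(values = values, objective_value = objective_value,
                 status = status), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution [", x$status, "] objective = ",
      format(x$objective_value), "\n", sep = "")
  invisible(x)
}

failed_flux <- function(status) flux_distribution(status = status)

# steady-state constraint block of a model
base_constraints <- function(model) {
  m <- nrow(model$S)
  list(A = model$S, rhs = rep(0, m), sense = rep("=", m),
       lb = model$rxn$lb, ub = model$rxn$ub)
}

lp_status <- function(s) {
  switch(s, optimal = "optimal", infeasible = "infeasible", "failed")
}

#' Flux balance analysis
#'
#' Maximizes flux through the model's objective (biomass) reaction subject
#' to the steady-state mass balance `S v = 0` and the flux bounds.
#' Infeasibility is reported through the returned status, never as an
#' error, so benchmark runs can record failed computations.
#'
#' @param model a `metabolic_model`.
#' @return a `flux_distribution`.
#' @export
fba <- function(model) {
  bc <- base_constraints(model)
  n <- nrow(model$rxn)
  cost <- as.numeric(model$rxn$objective)
  res <- lp_solve(cost, bc$A, bc$rhs, bc$sense, bc$lb, bc$ub, maximize = TRUE)
  if (res$status != "optimal") return(failed_flux(lp_status(res$status)))
  flux_distribution(stats::setNames(res$x, model$rxn$id), res$objval,
                    "optimal")
}

# min sum_r weights_r * |v_r| over the steady-state polytope, with optional
# extra constraint rows over v. With tie_break, the weighted optimum is
# pinned and total absolute flux minimized among the remaining optima,
# making the returned distribution unique up to isozyme splits.
# Returns the lp_solve result with $flux.
solve_weighted_l1 <- function(model, weights, extra = NULL,
                              tie_break = FALSE) {
  bc <- base_constraints(model)
  n <- nrow(model$rxn)
  wpos <- if (tie_break) seq_len(n) else which(weights != 0)
  na <- length(wpos)
  # columns: v (n) then t (na)
  A <- cbind(bc$A, matrix(0, nrow(bc$A), na))
  rhs <- bc$rhs
  sense <- bc$sense
  if (!is.null(extra) && length(extra$rhs) > 0) {
    A <- rbind(A, cbind(extra$A, matrix(0, length(extra$rhs), na)))
    rhs <- c(rhs, extra$rhs)
    sense <- c(sense, extra$sense)
  }
  if (na > 0) {
    Tm <- matrix(0, na, n)
    Tm[cbind(seq_len(na), wpos)] <- 1
    A <- rbind(A,
               cbind(-Tm, diag(na)),   # t - v >= 0
               cbind(Tm, diag(na)))    # t + v >= 0
    rhs <- c(rhs, rep(0, 2 * na))
    sense <- c(sense, rep(">=", 2 * na))
  }
  lb <- c(bc$lb, rep(0, na))
  ub <- c(bc$ub, pmax(abs(bc$lb[wpos]), abs(bc$ub[wpos])))
  cost <- c(rep(0, n), weights[wpos])
  res <- lp_solve(cost, A, rhs, sense, lb, ub, maximize = FALSE)
  if (tie_break && res$status == "optimal") {
    band <- 1e-7 * max(1, abs(res$objval))
    A2 <- rbind(A, cost)
    rhs2 <- c(rhs, res$objval + band)
    sense2 <- c(sense, "<=")
    cost2 <- c(rep(0, n), rep(1, na))
    res2 <- lp_solve(cost2, A2, rhs2, sense2, lb, ub, maximize = FALSE)
    if (res2$status == "optimal") {
      res$x <- res2$x
    }
  }
  res$flux <- if (res$status == "optimal") {
    stats::setNames(res$x[seq_len(n)], model$rxn$id)
  } else NULL
  res
}

#' Parsimonious flux balance analysis
#'
#' Two stages: fix the objective at the FBA optimum (within tolerance),
#' then minimize the total absolute flux (Manhattan norm) — the principle
#' of parsimonious enzyme usage. When the growth rate has been supplied as
#' a measurement constraint (`model$growth_fixed`), the first stage is
#' skipped and the result is simply the minimal flux distribution
#' complying with the imposed constraints.
#'
#' @param model a `metabolic_model`.
#' @param skip_fba force skipping the growth-maximization stage.
#' @return a `flux_distribution`; `objective_value` is the flux through
#'   the objective reaction.
#' @export
pfba <- function(model, skip_fba = isTRUE(model$growth_fixed)) {
  extra <- NULL
  if (!skip_fba) {
    sol <- fba(model)
    if (sol$status != "optimal") return(sol)
    z <- sol$objective_value
    extra <- list(A = matrix(as.numeric(model$rxn$objective), 1),
                  rhs = z - 1e-7 * max(1, abs(z)), sense = ">=")
  }
  res <- solve_weighted_l1(model, rep(1, nrow(model$rxn)), extra)
  if (res$status != "optimal") return(failed_flux(lp_status(res$status)))
  flux_distribution(res$flux,
                    unname(res$flux[model$objective_reaction]), "optimal")
}

#' Flux variability analysis
#'
#' Minimum and maximum feasible flux per reaction under the model's
#' constraints. By default no fraction-of-optimum requirement is imposed
#' (an unbiased envelope, as needed for the GX-FBA reference state); set
#' `fraction_of_optimum` to additionally require
#' `objective >= fraction * FBA optimum`.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to analyze (default: all).
#' @param fraction_of_optimum optional fraction in `[0, 1]`.
#' @return list with `status` and `ranges`, a data frame
#'   (id, min, max); `status` is `"infeasible"` and `ranges` `NULL` when
#'   the constraint set admits no flux.
#' @export
fva <- function(model, reactions = NULL, fraction_of_optimum = NULL) {
  if (is.null(reactions)) reactions <- model$rxn$id
  idx <- rxn_index(model, reactions)
  bc <- base_constraints(model)
  A <- bc$A; rhs <- bc$rhs; sense <- bc$sense
  if (!is.null(fraction_of_optimum)) {
    sol <- fba(model)
    if (sol$status != "optimal") return(list(status = sol$status,
                                             ranges = NULL))
    A <- rbind(A, as.numeric(model$rxn$objective))
    rhs <- c(rhs, fraction_of_optimum * sol$objective_value)
    sense <- c(sense, ">=")
  }
  n <- nrow(model$rxn)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    cost <- rep(0, n)
    cost[idx[k]] <- 1
    rmin <- lp_solve(cost, A, rhs, sense, bc$lb, bc$ub, maximize = FALSE)
    rmax <- lp_solve(cost, A, rhs, sense, bc$lb, bc$ub, maximize = TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal") {
      st <- lp_status(if (rmin$status != "optimal") rmin$status
                      else rmax$status)
      return(list(status = st, ranges = NULL))
    }
    lo[k] <- rmin$objval
    hi[k] <- rmax$objval
  }
  list(status = "optimal",
       ranges = data.frame(id = reactions, min = lo, max = hi,
                           stringsAsFactors = FALSE))
}
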