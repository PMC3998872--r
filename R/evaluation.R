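# Evaluation pipeline: reconcile measurements with the model, strip
# futile cycles from predictions, and score predictions with the
# normalized Euclidean error.

#' Project measured fluxes onto the model's solution space
#'
#' Experimental flux distributions (from 13C labeling) rarely lie exactly
#' in the feasible space of a stoichiometric model; comparing against
#' them directly would charge every method the same systematic error.
#' This solves the quadratic program
#' `min sum_measured (v_r - m_r)^2` subject to `S v = 0` and the model
#' bounds (unmeasured fluxes free), and returns the measured entries of
#' the nearest feasible flux distribution.
#'
#' @param model a `metabolic_model`.
#' @param measured a `measurement_set`.
#' @return the adjusted `measurement_set` (same ids and roles).
#' @export
fit_fluxes_to_model <- function(model, measured) {
  idx <- rxn_index(model, measured$id)
  n <- nrow(model$rxn)
  w <- rep(1e-10, n)         # ridge keeps the quadratic form positive definite
  w[idx] <- 1
  m_vec <- rep(0, n)
  m_vec[idx] <- measured$value
  Dmat <- diag(2 * w)
  dvec <- 2 * w * m_vec
  lb <- model$rxn$lb; ub <- model$rxn$ub
  fin_l <- which(is.finite(lb)); fin_u <- which(is.finite(ub))
  Amat <- cbind(t(model$S),
                diag(n)[, fin_l, drop = FALSE],
                -diag(n)[, fin_u, drop = FALSE])
  bvec <- c(rep(0, nrow(model$S)), lb[fin_l], -ub[fin_u])
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(model$S)),
    error = function(e) stop("flux projection failed (model infeasible?): ",
                             conditionMessage(e)))
  adjusted <- measured
  adjusted$value <- sol$solution[idx]
  adjusted
}

#' Identify reactions capable of carrying futile-cycle flux
#'
#' A futile cycle can circulate flux with every exchange reaction closed.
#' The cycle-capable set is found structurally: close all exchanges and
#' run FVA; reactions with a nonzero feasible range participate in at
#' least one internal cycle. The set depends only on the model, so cache
#' it across evaluations.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
futile_cycle_set <- function(model) {
  closed <- model
  ex <- which(model$rxn$is_exchange)
  closed$rxn$lb[ex] <- 0
  closed$rxn$ub[ex] <- 0
  internal <- model$rxn$id[-ex]
  if (length(internal) == 0) return(character(0))
  fv <- fva(closed, internal)
  if (fv$status != "optimal") return(character(0))
  fv$ranges$id[fv$ranges$min < -1e-9 | fv$ranges$max > 1e-9]
}

#' Remove futile-cycle flux from a prediction
#'
#' Most integration methods are prone to degenerate solutions carrying
#' arbitrary circulating flux through futile cycles, which inflates the
#' prediction error without changing the phenotype. This post-processing
#' step fixes every non-cycle flux (exchanges included) at its input
#' value and minimizes the total absolute flux over the cycle-capable
#' reactions.
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_distribution` with `status = "optimal"`.
#' @param cycle_set optional precomputed [futile_cycle_set()].
#' @return a `flux_distribution`; exchange and non-cycle fluxes are
#'   identical to the input.
#' @export
remove_futile_cycles <- function(model, flux, cycle_set = NULL) {
  if (flux$status != "optimal") return(flux)
  if (is.null(cycle_set)) cycle_set <- futile_cycle_set(model)
  if (length(cycle_set) == 0) return(flux)
  in_cycle <- model$rxn$id %in% cycle_set
  solve_fixed <- function(band) {
    m2 <- model
    fixed <- which(!in_cycle)
    vals <- flux$values[model$rxn$id[fixed]]
    m2$rxn$lb[fixed] <- vals - band
    m2$rxn$ub[fixed] <- vals + band
    w <- as.numeric(in_cycle)
    solve_weighted_l1(m2, w)
  }
  res <- solve_fixed(0)
  if (res$status != "optimal") {
    res <- solve_fixed(pmax(1e-6, 1e-6 * abs(flux$values)))
  }
  if (res$status != "optimal") {
    warning("futile-cycle removal infeasible; returning input flux")
    return(flux)
  }
  out <- flux$values
  out[in_cycle] <- res$flux[in_cycle]
  flux_distribution(out, unname(out[model$objective_reaction]), "optimal")
}

#' Normalized prediction error
#'
#' The normalized Euclidean distance `||u - v|| / ||v||` between the
#' predicted fluxes `u` and the measured fluxes `v` over the compared
#' reactions. Identical vectors score 0 and an all-zero prediction
#' scores 1; the measure is proportional to the square root of the
#' summed square error scaled by the magnitude of the measured vector,
#' making it comparable across conditions. Setting
#' `normalization = "norm_sq"` divides by `||v||^2` instead.
#'
#' @param pred a `flux_distribution` or named numeric vector.
#' @param meas a `measurement_set`.
#' @param compared reaction ids to compare (default: all measured).
#' @param normalization `"norm"` (default) or `"norm_sq"`.
#' @return nonnegative error, or `NA` (with a warning) when the measured
#'   vector has zero norm.
#' @export
normalized_error <- function(pred, meas, compared = meas$id,
                             normalization = c("norm", "norm_sq")) {
  normalization <- match.arg(normalization)
  u_all <- if (inherits(pred, "flux_distribution")) pred$values else pred
  stopifnot(all(compared %in% meas$id))
  v <- meas$value[match(compared, meas$id)]
  u <- u_all[compared]
  u[is.na(u)] <- 0
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    warning("measured vector has zero norm; error undefined")
    return(NA_real_)
  }
  dist <- sqrt(sum((u - v)^2))
  if (normalization == "norm") dist / nv else dist / nv^2
}

#' Evaluate one method on one condition
#'
#' The full pipeline: apply the scenario's measurement constraints, run
#' the method, remove futile cycles, and compute the normalized error of
#' the prediction against all measured rates (constrained entries
#' included: under `full_physiology` they contribute about zero, which is
#' exactly the expected error drop). Failures are captured in the
#' record, never raised.
#'
#' @param model a `metabolic_model`.
#' @param method a method name, see [method_names()].
#' @param cfg a [method_config()].
#' @param profile test-condition `expression_profile`.
#' @param measurements adjusted `measurement_set` (see
#'   [fit_fluxes_to_model()]).
#' @param scenario constraint scenario.
#' @param condition condition label for the record.
#' @param profile_ref,measurements_ref reference condition for the
#'   pairwise methods.
#' @param cycle_set optional precomputed [futile_cycle_set()].
#' @return a one-row data frame (an error record): method, condition,
#'   scenario, error, status, n_compared.
#' @export
evaluate_method <- function(model, method, cfg = method_config(),
                            profile = NULL, measurements = NULL,
                            scenario = "uptake_only",
                            condition = "condition",
                            profile_ref = NULL, measurements_ref = NULL,
                            cycle_set = NULL) {
  record <- function(error, status, n_compared = NA_integer_) {
    data.frame(method = method, condition = condition, scenario = scenario,
               error = error, status = status, n_compared = n_compared,
               stringsAsFactors = FALSE)
  }
  res <- tryCatch(
    run_method(method, model, cfg, profile, measurements, scenario,
               profile_ref = profile_ref,
               measurements_ref = measurements_ref),
    error = function(e) failed_result("failed",
                                      diagnostics = conditionMessage(e)))
  if (res$status != "optimal") return(record(NA_real_, "failed"))
  flux <- remove_futile_cycles(model, res$flux, cycle_set)
  err <- normalized_error(flux, measurements)
  if (is.na(err)) return(record(NA_real_, "failed"))
  record(err, "ok", length(measurements$id))
}

#' Summarize error records
#'
#' Statistics are computed over `ok` records only; failed computations
#' are excluded from the averages and counted separately.
#'
#' @param records data frame of error records (rows from
#'   [evaluate_method()]), optionally with extra grouping columns.
#' @param by grouping columns (default method and scenario).
#' @return data frame with mean, median, quartiles, n and failure count
#'   per group.
#' @export
summarize_errors <- function(records, by = c("method", "scenario")) {
  by <- intersect(by, names(records))
  key <- interaction(records[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    ok <- g$status == "ok"
    e <- g$error[ok]
    stats <- if (length(e) > 0) {
      q <- stats::quantile(e, c(.25, .5, .75), names = FALSE)
      data.frame(mean_error = mean(e), q1 = q[1], median_error = q[2],
                 q3 = q[3])
    } else {
      data.frame(mean_error = NA_real_, q1 = NA_real_,
                 median_error = NA_real_, q3 = NA_real_)
    }
    cbind(g[1, by, drop = FALSE], stats,
          data.frame(n_ok = sum(ok), n_failed = sum(!ok)))
  }))
  rownames(out) <- NULL
  out
}
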