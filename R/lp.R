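#' @useDynLib fluxbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `cost' x` subject to `A x (sense) rhs` and
#' `lb <= x <= ub`. This is the workhorse behind FBA, pFBA, FVA and all
#' integration methods; it wraps the package's dense two-phase simplex.
#'
#' @param cost numeric objective coefficients.
#' @param A constraint matrix (dense; rows are constraints).
#' @param rhs right-hand sides.
#' @param sense character vector per row: `"<="`, `"="`, `">="`.
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize maximize instead of minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` and `objval`.
#' @keywords internal
lp_solve <- function(cost, A, rhs, sense, lb, ub, maximize = FALSE) {
  n <- length(cost)
  A <- matrix(as.numeric(A), nrow = length(rhs), ncol = n)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)))
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  # shift to y = x - lb >= 0; finite upper bounds become explicit rows
  rhs2 <- rhs - as.numeric(A %*% lb)
  ubf <- which(is.finite(ub))
  nub <- length(ubf)
  if (nub > 0) {
    Aub <- matrix(0, nrow = nub, ncol = n)
    Aub[cbind(seq_len(nub), ubf)] <- 1
    A2 <- rbind(A, Aub)
    rhs2 <- c(rhs2, ub[ubf] - lb[ubf])
    sense2 <- c(sense, rep("<=", nub))
  } else {
    A2 <- A
    sense2 <- sense
  }
  sn <- match(sense2, c("<=", "=", ">=")) - 2L
  if (anyNA(sn)) stop("unknown constraint sense")
  cc <- if (maximize) -cost else cost
  res <- .simplex_core(cc, A2, rhs2, sn)
  status <- c("optimal", "infeasible", "unbounded", "maxit")[res$status + 1L]
  if (status != "optimal") {
    return(list(status = status, x = rep(NA_real_, n), objval = NA_real_))
  }
  x <- res$x + lb
  list(status = "optimal", x = x, objval = sum(cost * x))
}

#' Solve a mixed-binary linear program by branch and bound
#'
#' Depth-first branch and bound over the LP relaxation solved with
#' [lp_solve()]. Integer variables are expected to be binary (bounds within
#' `[0, 1]`); this covers the iMAT and MADE formulations.
#'
#' @inheritParams lp_solve
#' @param int_idx indices of binary variables.
#' @param int_tol integrality tolerance.
#' @param integral_objective set when every attainable objective value is
#'   integral (consistency/agreement counts): nodes whose relaxation
#'   cannot beat the incumbent by a full unit are pruned.
#' @return as [lp_solve()]; `x` has integral values at `int_idx`.
#' @keywords internal
milp_solve <- function(cost, A, rhs, sense, lb, ub, maximize = FALSE,
                       int_idx = integer(0), int_tol = 1e-6,
                       integral_objective = FALSE) {
  if (length(int_idx) == 0) {
    return(lp_solve(cost, A, rhs, sense, lb, ub, maximize))
  }
  sgn <- if (maximize) 1 else -1   # compare on sgn * objval, higher is better
  best <- list(status = "infeasible", x = rep(NA_real_, length(cost)),
               objval = NA_real_)
  best_val <- -Inf
  gap <- if (integral_objective) 1 - 1e-6 else 1e-9
  accept <- function(rel) {
    val <- sgn * rel$objval
    if (val > best_val + 1e-9) {
      best_val <<- val
      rel$x[int_idx] <- round(rel$x[int_idx])
      best <<- rel
    }
  }
  root <- TRUE
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(cost, A, rhs, sense, node$lb, node$ub, maximize)
    if (rel$status != "optimal") next
    if (sgn * rel$objval <= best_val + gap) next  # bound
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= int_tol)) {
      accept(rel)
      next
    }
    if (root) {
      # rounding heuristic: a quick incumbent tightens all later bounds
      root <- FALSE
      l2 <- node$lb; u2 <- node$ub
      l2[int_idx] <- u2[int_idx] <- round(rel$x[int_idx])
      h <- lp_solve(cost, A, rhs, sense, l2, u2, maximize)
      if (h$status == "optimal") accept(h)
      if (sgn * rel$objval <= best_val + gap) next
    }
    j <- int_idx[which.max(frac)]
    lo <- node; lo$ub[j] <- floor(rel$x[j])
    hi <- node; hi$lb[j] <- ceiling(rel$x[j])
    # explore the branch nearest the relaxation value first
    if (rel$x[j] - floor(rel$x[j]) > 0.5) {
      stack <- c(stack, list(lo), list(hi))
    } else {
      stack <- c(stack, list(hi), list(lo))
    }
  }
  best
}
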