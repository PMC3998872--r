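# Independent oracles: brute-force enumeration and boot::simplex-based LP
# formulations, kept deliberately separate from the package's solver path.

# maximize cost'v over {S v = 0, lb <= v <= ub} by enumerating basic
# feasible solutions (vertices): fix (n - m) variables at a bound, solve
# the remaining square system. Only for tiny networks.
vertex_enum_lp <- function(S, lb, ub, cost, maximize = TRUE, tol = 1e-8) {
  n <- ncol(S)
  qrS <- qr(S)
  m <- qrS$rank
  Sr <- S[qrS$pivot[seq_len(m)], , drop = FALSE]
  if (qrS$rank < nrow(S)) {
    Sr <- qr.R(qr(t(S)))  # fallback; not expected for the fixtures
    Sr <- S[seq_len(m), , drop = FALSE]
  }
  best <- NULL
  free_sets <- utils::combn(n, m, simplify = FALSE)
  for (freev in free_sets) {
    fixedv <- setdiff(seq_len(n), freev)
    B <- Sr[, freev, drop = FALSE]
    if (abs(det(B)) < tol) next
    grid <- expand.grid(rep(list(c(1, 2)), length(fixedv)))
    for (gi in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fixedv] <- ifelse(unlist(grid[gi, ]) == 1, lb[fixedv], ub[fixedv])
      rhs <- -Sr[, fixedv, drop = FALSE] %*% v[fixedv]
      v[freev] <- solve(B, rhs)
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        val <- sum(cost * v)
        if (is.null(best) || (maximize && val > best$val) ||
            (!maximize && val < best$val)) {
          best <- list(val = val, v = v)
        }
      }
    }
  }
  best
}

# boot::simplex solve of max/min cost'v over {S v = 0, lb <= v <= ub},
# finite bounds required; shifted so variables are nonnegative.
boot_lp <- function(S, lb, ub, cost, maximize = TRUE,
                    extra_A = NULL, extra_b = NULL, extra_dir = NULL) {
  stopifnot(requireNamespace("boot", quietly = TRUE))
  n <- ncol(S)
  A1 <- diag(n); b1 <- ub - lb                       # x <= ub - lb
  A3 <- S; b3 <- as.numeric(-S %*% lb)               # S x = -S lb
  A2 <- NULL; b2 <- NULL
  if (!is.null(extra_A)) {
    for (i in seq_along(extra_b)) {
      bi <- extra_b[i] - sum(extra_A[i, ] * lb)
      if (extra_dir[i] == "<=") {
        A1 <- rbind(A1, extra_A[i, ]); b1 <- c(b1, bi)
      } else if (extra_dir[i] == ">=") {
        A2 <- rbind(A2, extra_A[i, ]); b2 <- c(b2, bi)
      } else {
        A3 <- rbind(A3, extra_A[i, ]); b3 <- c(b3, bi)
      }
    }
  }
  res <- boot::simplex(a = cost, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = maximize)
  if (res$solved != 1) return(NULL)
  v <- res$soln + lb
  list(val = sum(cost * v), v = v)
}

# exhaustive iMAT oracle: enumerate activity patterns of the classified
# reactions and count the best achievable consistency score.
imat_enum_score <- function(model, high_ids, low_ids, eps = 1) {
  n <- nrow(model$rxn)
  bc <- list(A = model$S, rhs = rep(0, nrow(model$S)),
             sense = rep("=", nrow(model$S)))
  feasible <- function(lb, ub) {
    r <- fluxbench:::lp_solve(rep(0, n), bc$A, bc$rhs, bc$sense, lb, ub)
    r$status == "optimal"
  }
  hi <- match(high_ids, model$rxn$id)
  lo <- match(low_ids, model$rxn$id)
  # options per high reaction: inactive / forward-active / reverse-active
  opts_h <- lapply(hi, function(j) {
    o <- list(0L, 1L)
    if (model$rxn$lb[j] < 0) o <- c(o, list(2L))
    o
  })
  opts_l <- lapply(lo, function(j) list(0L, 1L))  # free / forced zero
  grid <- expand.grid(c(opts_h, opts_l))
  best <- 0L
  for (gi in seq_len(nrow(grid))) {
    lb <- model$rxn$lb; ub <- model$rxn$ub
    sc <- 0L
    for (k in seq_along(hi)) {
      st <- grid[gi, k][[1]]
      if (st == 1L) { lb[hi[k]] <- max(lb[hi[k]], eps); sc <- sc + 1L }
      if (st == 2L) { ub[hi[k]] <- min(ub[hi[k]], -eps); sc <- sc + 1L }
    }
    for (k in seq_along(lo)) {
      st <- grid[gi, length(hi) + k][[1]]
      if (st == 1L) { lb[lo[k]] <- 0; ub[lo[k]] <- 0; sc <- sc + 1L }
    }
    if (sc > best && feasible(lb, ub)) best <- sc
  }
  best
}

# exhaustive pairwise-MADE oracle: enumerate binary gene-state pairs,
# require both conditions to reach the growth floor, maximize agreement.
made_enum_score <- function(model, genes, d, fraction = 0.9,
                            model_ref = model, model_test = model) {
  max_growth <- function(mm) {
    s <- fba(mm)
    if (s$status != "optimal") NA_real_ else s$objective_value
  }
  z_ref <- max_growth(model_ref); z_test <- max_growth(model_test)
  grows <- function(mm, states, z) {
    off <- genes[states == 0]
    m2 <- suppressWarnings(delete_genes(mm, off))
    s <- fba(m2)
    s$status == "optimal" && s$objective_value >= fraction * z - 1e-6
  }
  ng <- length(genes)
  combos <- expand.grid(rep(list(0:1), 2 * ng))
  best <- -1L
  for (gi in seq_len(nrow(combos))) {
    b_ref <- unlist(combos[gi, seq_len(ng)])
    b_test <- unlist(combos[gi, ng + seq_len(ng)])
    agree <- sum((d > 0 & b_ref == 0 & b_test == 1) |
                   (d < 0 & b_ref == 1 & b_test == 0) |
                   (d == 0 & b_ref == b_test))
    if (agree <= best) next
    if (grows(model_ref, b_ref, z_ref) && grows(model_test, b_test, z_test))
      best <- agree
  }
  best
}

# QP oracle for the measured-flux projection: active-set enumeration over
# the box bounds, equality-constrained least squares per active set.
qp_enum_fit <- function(model, measured, tol = 1e-7) {
  n <- nrow(model$rxn)
  idx <- match(measured$id, model$rxn$id)
  lb <- model$rxn$lb; ub <- model$rxn$ub
  S <- model$S
  w <- rep(0, n); w[idx] <- 1
  m_vec <- rep(0, n); m_vec[idx] <- measured$value
  best <- NULL
  sets <- expand.grid(rep(list(0:2), n))  # 0 free, 1 at lb, 2 at ub
  for (gi in seq_len(nrow(sets))) {
    act <- unlist(sets[gi, ])
    if (any(act == 1 & !is.finite(lb)) || any(act == 2 & !is.finite(ub)))
      next
    Aeq <- S; beq <- rep(0, nrow(S))
    for (j in which(act > 0)) {
      row <- rep(0, n); row[j] <- 1
      Aeq <- rbind(Aeq, row)
      beq <- c(beq, if (act[j] == 1) lb[j] else ub[j])
    }
    # minimize (v-m)' W (v-m) + ridge s.t. Aeq v = beq via KKT
    W <- diag(w + 1e-9)
    K <- rbind(cbind(2 * W, t(Aeq)),
               cbind(Aeq, matrix(0, nrow(Aeq), nrow(Aeq))))
    rhs <- c(2 * (w + 1e-9) * m_vec, beq)
    sol <- tryCatch(qr.solve(K, rhs, tol = 1e-12), error = function(e) NULL)
    if (is.null(sol)) next
    v <- sol[seq_len(n)]
    if (any(v < lb - tol) || any(v > ub + tol)) next
    val <- sum(w * (v - m_vec)^2)
    if (is.null(best) || val < best$val - 1e-12) best <- list(val = val, v = v)
  }
  best
}
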