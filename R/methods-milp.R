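# MILP-based integration methods: iMAT and pairwise MADE.

#' iMAT: maximize consistency with discretized expression
#'
#' Reactions are classified `high`/`intermediate`/`low` from gene-level
#' percentile thresholds propagated through tri-valued GPR logic. A MILP
#' then finds a flux distribution maximizing the number of satisfied
#' class predictions: a `high` reaction is satisfied when it carries at
#' least the activation threshold `eps` of flux (in either direction for
#' reversible reactions, two OR-ed indicators), a `low` reaction when it
#' carries none. No biomass objective is imposed. Among
#' consistency-optimal solutions the minimal total flux one is reported.
#'
#' @param model a (scenario-constrained) `metabolic_model`.
#' @param profile an `expression_profile`.
#' @param cfg a [method_config()].
#' @return a `method_result`; `score` is the consistency count and
#'   `diagnostics$class` the reaction classification.
#' @export
imat <- function(model, profile, cfg = method_config()) {
  levels <- as_levels(profile)
  gcls <- discretize(levels, cfg$imat_low_pct, cfg$imat_high_pct)
  rcls <- map_classes(model, gcls$class)
  H <- which(!is.na(rcls) & rcls == "high")
  L <- which(!is.na(rcls) & rcls == "low")
  n <- nrow(model$rxn)
  lb <- model$rxn$lb; ub <- model$rxn$ub
  eps <- cfg$imat_eps
  Hrev <- H[lb[H] < 0]
  # columns: v (n) | yp (per H) | ym (per Hrev) | z (per L)
  nyp <- length(H); nym <- length(Hrev); nz <- length(L)
  ncol_tot <- n + nyp + nym + nz
  col_yp <- n + seq_len(nyp)
  col_ym <- n + nyp + seq_len(nym)
  col_z <- n + nyp + nym + seq_len(nz)
  rows <- list(); rhs <- c(); sense <- c()
  m <- nrow(model$S)
  Srows <- cbind(model$S, matrix(0, m, ncol_tot - n))
  add_row <- function(cols, coefs, s, r) {
    row <- rep(0, ncol_tot)
    row[cols] <- coefs
    rows[[length(rows) + 1]] <<- row
    sense <<- c(sense, s)
    rhs <<- c(rhs, r)
  }
  for (k in seq_along(H)) {
    j <- H[k]
    # yp = 1 => v_j >= eps (forward activation)
    add_row(c(j, col_yp[k]), c(1, -(eps - lb[j])), ">=", lb[j])
  }
  for (k in seq_along(Hrev)) {
    j <- Hrev[k]
    # ym = 1 => v_j <= -eps (reverse activation)
    add_row(c(j, col_ym[k]), c(1, ub[j] + eps), "<=", ub[j])
    add_row(c(col_yp[match(j, H)], col_ym[k]), c(1, 1), "<=", 1)
  }
  for (k in seq_along(L)) {
    j <- L[k]
    # z = 1 => v_j = 0
    add_row(c(j, col_z[k]), c(1, ub[j]), "<=", ub[j])
    add_row(c(j, col_z[k]), c(1, lb[j]), ">=", lb[j])
  }
  A <- rbind(Srows, do.call(rbind, rows))
  rhs <- c(rep(0, m), rhs)
  sense <- c(rep("=", m), sense)
  lbv <- c(lb, rep(0, ncol_tot - n))
  ubv <- c(ub, rep(1, ncol_tot - n))
  cost <- c(rep(0, n), rep(1, ncol_tot - n))
  int_idx <- seq.int(n + 1, ncol_tot)
  if (ncol_tot == n) int_idx <- integer(0)
  res <- milp_solve(cost, A, rhs, sense, lbv, ubv, maximize = TRUE,
                    int_idx = int_idx, integral_objective = TRUE)
  if (res$status != "optimal") {
    return(failed_result(lp_status(res$status),
                         diagnostics = list(class = rcls)))
  }
  score <- round(res$objval)
  res <- refine_parsimonious(res, cost, A, rhs, sense, lbv, ubv,
                             maximize = TRUE, n_flux = n,
                             int_idx = int_idx)
  v <- stats::setNames(res$x[seq_len(n)], model$rxn$id)
  method_result(flux_distribution(v, unname(v[model$objective_reaction]),
                                  "optimal"),
                score = score,
                diagnostics = list(class = rcls,
                                   thresholds = gcls$thresholds))
}

# recursively encode a pruned GPR rule as upper-bound gate constraints;
# returns the column index whose value upper-bounds rule truth.
# add_aux() allocates a continuous [0,1] column; add_row(cols, coefs, sense,
# rhs) appends a constraint. Gene leaves resolve through gene_col.
encode_rule_gate <- function(rule, gene_col, add_aux, add_row) {
  if (rule$type == "gene") return(gene_col[[rule$gene]])
  kid_cols <- vapply(rule$children, encode_rule_gate, numeric(1),
                     gene_col = gene_col, add_aux = add_aux,
                     add_row = add_row)
  a <- add_aux()
  if (rule$type == "and") {
    for (cc in kid_cols) add_row(c(a, cc), c(1, -1), "<=", 0)
  } else {
    add_row(c(a, kid_cols), c(1, rep(-1, length(kid_cols))), "<=", 0)
  }
  a
}

#' Pairwise MADE: maximize agreement with differential expression
#'
#' For each gene measured in both conditions the desired transition is
#' `d_g = sign(x_test,g - x_ref,g)`. A MILP over binary gene states for
#' the reference and test conditions maximizes the number of genes whose
#' state change matches `d_g` (unit weighting), subject to both
#' conditions' models carrying a flux distribution with at least
#' `objective_fraction` of their respective maximum growth, with gene
#' states propagated to reaction availability through the GPR rules.
#' The reported flux is the test-condition pFBA solution in the
#' state-constrained model.
#'
#' @param model a `metabolic_model` (unconstrained).
#' @param profile_ref,profile_test reference and test
#'   `expression_profile`s over a shared gene universe.
#' @param cfg a [method_config()].
#' @param measurements_test optional test-condition `measurement_set`.
#' @param measurements_ref optional reference-condition `measurement_set`.
#' @param scenario scenario for applying the measurements.
#' @return a `method_result`; `score` is the agreement count,
#'   `diagnostics$states` the fitted gene states.
#' @export
made_pairwise <- function(model, profile_ref, profile_test,
                          cfg = method_config(), measurements_test = NULL,
                          measurements_ref = NULL,
                          scenario = "uptake_only") {
  x_ref <- as_levels(profile_ref); x_test <- as_levels(profile_test)
  m_test <- if (is.null(measurements_test)) model
  else apply_measurements(model, measurements_test, scenario,
                          uptake_as = cfg$uptake_as)
  m_ref <- if (is.null(measurements_ref)) model
  else apply_measurements(model, measurements_ref, scenario,
                          uptake_as = cfg$uptake_as)
  genes <- intersect(intersect(names(x_ref), names(x_test)),
                     model_genes(model))
  d <- sign(x_test[genes] - x_ref[genes])
  n <- nrow(model$rxn)
  ng <- length(genes)
  if (ng == 0) return(failed_result("failed"))
  models <- list(ref = m_ref, test = m_test)
  floors <- lapply(models, function(mm)
    growth_floor_rows(mm, cfg$objective_fraction))
  for (fl in floors) {
    if (is.character(fl)) return(failed_result(lp_status(fl)))
  }
  # column layout: v_ref | v_test | b_ref | b_test | agree | aux...
  ncols <- 2 * n + 2 * ng + ng
  rows <- list(); rhs <- c(); sense <- c()
  lbv <- c(models$ref$rxn$lb, models$test$rxn$lb, rep(0, 3 * ng))
  ubv <- c(models$ref$rxn$ub, models$test$rxn$ub, rep(1, 3 * ng))
  add_row <- function(cols, coefs, s, r) {
    rows[[length(rows) + 1]] <<- list(cols = cols, coefs = coefs)
    sense <<- c(sense, s); rhs <<- c(rhs, r)
  }
  add_aux <- function() {
    ncols <<- ncols + 1
    lbv <<- c(lbv, 0); ubv <<- c(ubv, 1)
    ncols
  }
  for (ci in 1:2) {
    mm <- models[[ci]]
    off <- (ci - 1) * n
    for (i in seq_len(nrow(mm$S))) {
      nzj <- which(mm$S[i, ] != 0)
      add_row(off + nzj, mm$S[i, nzj], "=", 0)
    }
    fl <- floors[[ci]]
    if (!is.null(fl)) {
      nzj <- which(fl$A[1, ] != 0)
      add_row(off + nzj, fl$A[1, nzj], fl$sense, fl$rhs)
    }
    gene_col <- as.list(stats::setNames(2 * n + (ci - 1) * ng +
                                          seq_len(ng), genes))
    for (k in seq_len(n)) {
      g <- mm$rxn$gpr[k]
      if (!nzchar(g)) next
      rule <- prune_missing(parse_gpr(g), genes)
      if (rule$type == "empty") next
      gate <- encode_rule_gate(rule, gene_col, add_aux, add_row)
      if (mm$rxn$ub[k] > 0) {
        add_row(c(off + k, gate), c(1, -mm$rxn$ub[k]), "<=", 0)
      }
      if (mm$rxn$lb[k] < 0) {
        add_row(c(off + k, gate), c(1, -mm$rxn$lb[k]), ">=", 0)
      }
    }
  }
  col_bref <- 2 * n + seq_len(ng)
  col_btest <- 2 * n + ng + seq_len(ng)
  col_agree <- 2 * n + 2 * ng + seq_len(ng)
  for (k in seq_len(ng)) {
    if (d[k] > 0) {        # desired off -> on
      add_row(c(col_agree[k], col_bref[k]), c(1, 1), "<=", 1)
      add_row(c(col_agree[k], col_btest[k]), c(1, -1), "<=", 0)
    } else if (d[k] < 0) { # desired on -> off
      add_row(c(col_agree[k], col_bref[k]), c(1, -1), "<=", 0)
      add_row(c(col_agree[k], col_btest[k]), c(1, 1), "<=", 1)
    } else {               # desired unchanged
      add_row(c(col_agree[k], col_btest[k], col_bref[k]),
              c(1, 1, -1), "<=", 1)
      add_row(c(col_agree[k], col_btest[k], col_bref[k]),
              c(1, -1, 1), "<=", 1)
    }
  }
  A <- matrix(0, length(rows), ncols)
  for (i in seq_along(rows)) A[i, rows[[i]]$cols] <- rows[[i]]$coefs
  cost <- rep(0, ncols)
  cost[col_agree] <- 1
  res <- milp_solve(cost, A, rhs, sense, lbv, ubv, maximize = TRUE,
                    int_idx = c(col_bref, col_btest),
                    integral_objective = TRUE)
  if (res$status != "optimal") return(failed_result(lp_status(res$status)))
  b_ref <- round(res$x[col_bref]); b_test <- round(res$x[col_btest])
  names(b_ref) <- names(b_test) <- genes
  off_genes <- genes[b_test == 0]
  m_fit <- delete_genes(m_test, off_genes)
  flux <- pfba(m_fit)
  if (flux$status != "optimal") return(failed_result(flux$status))
  method_result(flux, score = round(res$objval),
                diagnostics = list(states = data.frame(
                  gene = genes, d = unname(d), ref = unname(b_ref),
                  test = unname(b_test))))
}
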