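# Shared micro-networks built in code.

# E1: uptake-limited linear chain with isozyme-like parallel branch.
#   EX_in: 0 -> A (ub 10); R1, R2: A -> B; RB: B -> 0 (objective)
make_e1 <- function(gpr1 = "g1", gpr2 = "g2") {
  metabolic_model(c("A", "B"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "R1", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = gpr1),
    list(id = "R2", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = gpr2),
    list(id = "RB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE)))
}

# single-path chain: EX_in -> R2 -> RB
make_chain <- function(ex_ub = 10) {
  metabolic_model(c("A", "B"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = ex_ub),
    list(id = "R2", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = "g1"),
    list(id = "RB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE)))
}

# E1 plus an unbounded reversible futile pair A <-> B
make_e1_futile <- function() {
  metabolic_model(c("A", "B"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "R1", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "Rf", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
    list(id = "Rb", stoichiometry = c(B = -1, A = 1), lb = 0, ub = 1000),
    list(id = "RB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE)))
}

# branch network for iMAT: one high branch, one low branch
#   EX_in: 0 -> A; RH: A -> B (high); RL: A -> C (low); EXB, EXC exits
make_branch <- function() {
  metabolic_model(c("A", "B", "C"), list(
    list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "RH", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = "gH"),
    list(id = "RL", stoichiometry = c(A = -1, C = 1), lb = 0, ub = 1000,
         gpr = "gL"),
    list(id = "EXB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         objective = TRUE),
    list(id = "EXC", stoichiometry = c(C = -1), lb = 0, ub = 1000)))
}

# expression profile whose 25/75 percentiles classify gH high, gL low
branch_profile <- function() {
  expression_profile(c(gL = 1, f1 = 4, f2 = 6, gH = 10), "branch")
}

toy_flat_profile <- function(level = 5) {
  g <- model_genes(build_toy_model())
  expression_profile(stats::setNames(rep(level, length(g)), g), "flat")
}
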