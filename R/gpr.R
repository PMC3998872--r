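# Gene-protein-reaction (GPR) rules: parsing, pruning, and the mapping of
# gene-level expression onto reactions. AND encodes enzyme complexes
# (limited by their scarcest subunit -> min), OR encodes isozymes
# (interchangeable -> max or sum).

#' Parse a GPR rule
#'
#' Accepts boolean expressions over gene identifiers with `and` / `or`
#' (case-insensitive) and parentheses. The empty string parses to the empty
#' rule (reaction without gene association).
#'
#' @param text the rule, e.g. `"g1 and (g2 or g3)"`.
#' @return a `gpr_rule`: a tree of nodes with `type` in
#'   `"gene"`, `"and"`, `"or"`, `"empty"`.
#' @export
parse_gpr <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) {
    return(structure(list(type = "empty"), class = "gpr_rule"))
  }
  toks <- regmatches(text, gregexpr("[(]|[)]|[^()[:space:]]+", text))[[1]]
  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos] }
  fail <- function(what) {
    stop("GPR syntax error at token ", pos + 1L, " ('",
         if (is.na(peek())) "<end>" else peek(), "'): expected ", what)
  }
  is_op <- function(t) !is.na(t) && tolower(t) %in% c("and", "or")
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("gene or '('")
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) fail("')'")
      advance()
      return(node)
    }
    if (t == ")" || is_op(t)) fail("gene or '('")
    advance()
    structure(list(type = "gene", gene = t), class = "gpr_rule")
  }
  parse_and <- function() {
    kids <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      kids <- c(kids, list(parse_factor()))
    }
    if (length(kids) == 1) kids[[1]]
    else structure(list(type = "and", children = kids), class = "gpr_rule")
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1) kids[[1]]
    else structure(list(type = "or", children = kids), class = "gpr_rule")
  }
  node <- parse_or()
  if (!is.na(peek())) fail("end of rule")
  node
}

#' @export
format.gpr_rule <- function(x, ...) {
  switch(x$type,
         empty = "",
         gene = x$gene,
         {
           parts <- vapply(x$children, function(ch) {
             s <- format(ch)
             if (ch$type %in% c("and", "or")) paste0("(", s, ")") else s
           }, character(1))
           paste(parts, collapse = paste0(" ", x$type, " "))
         })
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a rule
#' @param rule a `gpr_rule`.
#' @return character vector of gene identifiers.
#' @export
gpr_genes <- function(rule) {
  switch(rule$type,
         empty = character(0),
         gene = rule$gene,
         unique(unlist(lapply(rule$children, gpr_genes))))
}

#' Evaluate a rule
#' @param rule a `gpr_rule`.
#' @param predicate function(gene_id) -> logical.
#' @return logical; the empty rule evaluates to `TRUE` (no gene dependency).
#' @export
eval_gpr <- function(rule, predicate) {
  switch(rule$type,
         empty = TRUE,
         gene = isTRUE(predicate(rule$gene)),
         and = all(vapply(rule$children, eval_gpr, logical(1),
                          predicate = predicate)),
         or = any(vapply(rule$children, eval_gpr, logical(1),
                         predicate = predicate)))
}

#' Remove unmeasured genes from a rule
#'
#' Genes without a measurement are removed from the formula (rather than
#' assigned an arbitrary expression value); operator nodes left with a
#' single child collapse, and a fully unmeasured rule becomes the empty
#' rule, leaving the reaction unscored.
#'
#' @param rule a `gpr_rule`.
#' @param measured character vector of measured gene identifiers.
#' @return the pruned `gpr_rule`.
#' @export
prune_missing <- function(rule, measured) {
  empty <- structure(list(type = "empty"), class = "gpr_rule")
  if (rule$type == "empty") return(empty)
  if (rule$type == "gene") {
    return(if (rule$gene %in% measured) rule else empty)
  }
  kids <- lapply(rule$children, prune_missing, measured = measured)
  kids <- kids[vapply(kids, function(k) k$type != "empty", logical(1))]
  if (length(kids) == 0) return(empty)
  if (length(kids) == 1) return(kids[[1]])
  structure(list(type = rule$type, children = kids), class = "gpr_rule")
}

#' Construct an expression profile
#'
#' Gene-level expression for one condition, in arbitrary nonnegative
#' platform units (microarray intensities, TPM, or protein abundances —
#' profiles are treated generically).
#'
#' @param levels named nonnegative numeric vector (gene -> level).
#' @param condition condition label.
#' @return an `expression_profile`.
#' @export
expression_profile <- function(levels, condition = "condition") {
  stopifnot(!is.null(names(levels)), all(nzchar(names(levels))))
  if (any(!is.finite(levels)) || any(levels < 0)) {
    stop("expression levels must be finite and nonnegative")
  }
  structure(list(levels = levels, condition = condition),
            class = "expression_profile")
}

as_levels <- function(x) {
  if (inherits(x, "expression_profile")) x$levels else x
}

#' Map gene expression onto reactions
#'
#' Per reaction: prune unmeasured genes from the GPR, then combine levels
#' with AND -> min (enzyme complexes) and OR -> `max` or `sum` (isozymes).
#' Reactions with no rule, or whose rule prunes away entirely, get `NA`.
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile` (or named numeric vector).
#' @param or_mode `"max"` or `"sum"` for isozymes.
#' @return named numeric vector of reaction scores (`NA` where unscored).
#' @export
map_expression <- function(model, profile, or_mode = c("max", "sum")) {
  or_mode <- match.arg(or_mode)
  levels <- as_levels(profile)
  measured <- names(levels)
  or_fun <- if (or_mode == "max") max else sum
  score_rule <- function(rule) {
    switch(rule$type,
           gene = unname(levels[[rule$gene]]),
           and = min(vapply(rule$children, score_rule, numeric(1))),
           or = or_fun(vapply(rule$children, score_rule, numeric(1))))
  }
  out <- rep(NA_real_, nrow(model$rxn))
  names(out) <- model$rxn$id
  for (k in seq_len(nrow(model$rxn))) {
    g <- model$rxn$gpr[k]
    if (!nzchar(g)) next
    rule <- prune_missing(parse_gpr(g), measured)
    if (rule$type == "empty") next
    out[k] <- score_rule(rule)
  }
  out
}

#' Discretize expression into low / intermediate / high classes
#'
#' Thresholds are the `low_pct` and `high_pct` linear-interpolation
#' percentiles of the supplied values. Comparisons are strict: values
#' below the low threshold are `low`, above the high threshold `high`,
#' everything else (ties included) `intermediate`.
#'
#' @param x named numeric vector (gene levels or reaction scores); `NA`s
#'   are ignored for threshold computation and classified `NA`.
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct <= high_pct`.
#' @return list with `class` (named character) and `thresholds`.
#' @export
discretize <- function(x, low_pct = 25, high_pct = 75) {
  x <- as_levels(x)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct <= high_pct)
  vals <- x[!is.na(x)]
  if (length(vals) == 0) stop("no measured values to discretize")
  thr <- stats::quantile(vals, c(low_pct, high_pct) / 100, names = FALSE,
                         type = 7)
  cls <- rep(NA_character_, length(x))
  names(cls) <- names(x)
  cls[!is.na(x) & x < thr[1]] <- "low"
  cls[!is.na(x) & x > thr[2]] <- "high"
  cls[!is.na(x) & x >= thr[1] & x <= thr[2]] <- "intermediate"
  list(class = cls, thresholds = c(low = thr[1], high = thr[2]))
}

#' Map gene classes onto reactions through tri-valued GPR logic
#'
#' Gene classes (low < intermediate < high) propagate through the boolean
#' rule with AND -> min and OR -> max, the tri-valued scheme used for
#' discretizing reaction activity. Unmeasured genes are pruned first.
#'
#' @param model a `metabolic_model`.
#' @param gene_class named character vector over genes with values
#'   `"low"`, `"intermediate"`, `"high"`.
#' @return named character vector of reaction classes (`NA` if unscored).
#' @export
map_classes <- function(model, gene_class) {
  ord <- c(low = -1, intermediate = 0, high = 1)
  num <- ord[gene_class]
  names(num) <- names(gene_class)
  measured <- names(gene_class)[!is.na(gene_class)]
  class_rule <- function(rule) {
    switch(rule$type,
           gene = unname(num[[rule$gene]]),
           and = min(vapply(rule$children, class_rule, numeric(1))),
           or = max(vapply(rule$children, class_rule, numeric(1))))
  }
  out <- rep(NA_character_, nrow(model$rxn))
  names(out) <- model$rxn$id
  for (k in seq_len(nrow(model$rxn))) {
    g <- model$rxn$gpr[k]
    if (!nzchar(g)) next
    rule <- prune_missing(parse_gpr(g), measured)
    if (rule$type == "empty") next
    out[k] <- names(ord)[class_rule(rule) + 2]
  }
  out
}

# ---- tabular I/O ------------------------------------------------------------

#' Read an expression table
#'
#' Tab-separated, first column gene id, one column per condition, header
#' row; blank cells are treated as missing and dropped from that
#' condition's profile.
#'
#' @param path TSV path.
#' @return named list of `expression_profile`, one per condition column.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  out <- list()
  for (cn in names(tab)[-1]) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    keep <- !is.na(v)
    out[[cn]] <- expression_profile(stats::setNames(v[keep], genes[keep]), cn)
  }
  out
}

#' Write an expression table
#' @param profiles named list of `expression_profile`.
#' @param path TSV path.
#' @export
write_expression <- function(profiles, path) {
  genes <- sort(unique(unlist(lapply(profiles, function(p) names(p$levels)))))
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(profiles)) {
    tab[[nm]] <- unname(profiles[[nm]]$levels[genes])
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measurement table
#'
#' Tab-separated with columns `reaction_id`, `role`, then one column per
#' condition.
#'
#' @param path TSV path.
#' @return named list of `measurement_set`, one per condition column.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "role") %in% names(tab)))
  conds <- setdiff(names(tab), c("reaction_id", "role"))
  out <- list()
  for (cn in conds) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    keep <- !is.na(v)
    out[[cn]] <- measurement_set(tab$reaction_id[keep], v[keep],
                                 tab$role[keep])
  }
  out
}

#' Write a measurement table
#' @param sets named list of `measurement_set` sharing reaction ids/roles.
#' @param path TSV path.
#' @export
write_measurements <- function(sets, path) {
  base <- sets[[1]][, c("id", "role")]
  tab <- data.frame(reaction_id = base$id, role = base$role,
                    stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    m <- sets[[nm]]
    tab[[nm]] <- m$value[match(tab$reaction_id, m$id)]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
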