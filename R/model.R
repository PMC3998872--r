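#' Construct a metabolic model
#'
#' The central container: a stoichiometric matrix over declared metabolites,
#' per-reaction flux bounds (mmol/gDW/h), boolean gene-protein-reaction (GPR)
#' rules, and a designated objective (biomass) reaction.
#'
#' @param metabolites character vector of metabolite identifiers.
#' @param reactions a list of reaction descriptions, each a list with fields
#'   `id`, `stoichiometry` (named numeric, metabolite -> signed coefficient),
#'   `lb`, `ub`, `gpr` (string, may be `""`), `objective` (logical).
#' @return an object of class `metabolic_model` with fields `metabolites`,
#'   `rxn` (data frame: id, lb, ub, gpr, objective, is_exchange), `S`
#'   (metabolites x reactions matrix) and `objective_reaction`.
#' @examples
#' m <- metabolic_model(
#'   metabolites = c("A", "B"),
#'   reactions = list(
#'     list(id = "EX_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
#'     list(id = "R1", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
#'     list(id = "RB", stoichiometry = c(B = -1), lb = 0, ub = 1000,
#'          objective = TRUE)))
#' fba(m)$objective_value
#' @export
metabolic_model <- function(metabolites, reactions) {
  ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  S <- matrix(0, nrow = length(metabolites), ncol = length(ids),
              dimnames = list(metabolites, ids))
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$stoichiometry
    st <- st[vapply(st, function(x) !is.null(x) && x != 0, logical(1))]
    if (length(st) == 0) next
    unknown <- setdiff(names(st), metabolites)
    if (length(unknown) > 0) {
      stop("reaction '", ids[k], "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    S[names(st), k] <- as.numeric(st)
  }
  num_or <- function(r, f, d) if (is.null(r[[f]])) d else as.numeric(r[[f]])
  rxn <- data.frame(
    id = ids,
    lb = vapply(reactions, num_or, numeric(1), f = "lb", d = -1000),
    ub = vapply(reactions, num_or, numeric(1), f = "ub", d = 1000),
    gpr = vapply(reactions, function(r)
      if (is.null(r$gpr)) "" else as.character(r$gpr), character(1)),
    objective = vapply(reactions, function(r)
      isTRUE(r$objective), logical(1)),
    stringsAsFactors = FALSE
  )
  if (any(rxn$lb > rxn$ub)) {
    bad <- rxn$id[rxn$lb > rxn$ub]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  if (sum(rxn$objective) != 1) {
    stop("model must declare exactly one objective reaction")
  }
  rxn$is_exchange <- colSums(S != 0) == 1
  structure(list(metabolites = metabolites, rxn = rxn, S = S,
                 objective_reaction = ids[rxn$objective],
                 growth_fixed = FALSE),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model: ", length(x$metabolites), " metabolites, ",
      nrow(x$rxn), " reactions (", sum(x$rxn$is_exchange), " exchange)\n",
      "objective: ", x$objective_reaction, "\n", sep = "")
  invisible(x)
}

#' Genes appearing in a model's GPR rules
#' @param model a `metabolic_model`.
#' @return character vector of gene identifiers.
#' @export
model_genes <- function(model) {
  rules <- model$rxn$gpr[nzchar(model$rxn$gpr)]
  sort(unique(unlist(lapply(rules, function(g) gpr_genes(parse_gpr(g))))))
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$rxn$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Set bounds on a reaction
#' @param model a `metabolic_model`.
#' @param id reaction identifier.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lb)) model$rxn$lb[i] <- lb
  if (!is.null(ub)) model$rxn$ub[i] <- ub
  model
}

# ---- JSON / SBML I/O --------------------------------------------------------

#' Load a metabolic model from file
#'
#' Reads the package's JSON dialect or an SBML Level 3 document using the
#' `fbc` package conventions (flux bound parameters, gene-product
#' associations, active objective).
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to file
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON model '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("JSON model must contain 'metabolites' and 'reactions' arrays")
  }
  reactions <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without an 'id' field in ", path)
    r$stoichiometry <- unlist(r$stoichiometry)
    r
  })
  metabolic_model(unlist(doc$metabolites), reactions)
}

write_model_json <- function(model, path) {
  rl <- lapply(seq_len(nrow(model$rxn)), function(k) {
    st <- model$S[, k]
    st <- st[st != 0]
    list(id = model$rxn$id[k], stoichiometry = as.list(st),
         lb = model$rxn$lb[k], ub = model$rxn$ub[k],
         gpr = model$rxn$gpr[k], objective = model$rxn$objective[k])
  })
  jsonlite::write_json(list(metabolites = model$metabolites, reactions = rl),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

gpr_to_fbc <- function(node, rule) {
  if (rule$type == "gene") {
    xml2::xml_add_child(node, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_id(rule$gene)))
  } else {
    op <- xml2::xml_add_child(node,
                              if (rule$type == "and") "fbc:and" else "fbc:or")
    for (ch in rule$children) gpr_to_fbc(op, ch)
  }
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")
  cmp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "c", constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    xml2::xml_add_child(sp, "species", id = paste0("M_", sbml_id(m)),
                        name = m, compartment = "c", constant = "false",
                        boundaryCondition = "false",
                        hasOnlySubstanceUnits = "false")
  }
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_len(nrow(model$rxn))) {
    rid <- sbml_id(model$rxn$id[k])
    xml2::xml_add_child(pl, "parameter", id = paste0("lb_", rid),
                        value = format(model$rxn$lb[k], digits = 17),
                        constant = "true")
    xml2::xml_add_child(pl, "parameter", id = paste0("ub_", rid),
                        value = format(model$rxn$ub[k], digits = 17),
                        constant = "true")
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(model$rxn))) {
    rid <- sbml_id(model$rxn$id[k])
    rx <- xml2::xml_add_child(
      rl, "reaction", id = paste0("R_", rid), name = model$rxn$id[k],
      reversible = tolower(model$rxn$lb[k] < 0), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", rid),
      "fbc:upperFluxBound" = paste0("ub_", rid))
    st <- model$S[, k]
    rea <- st[st < 0]; pro <- st[st > 0]
    if (length(rea) > 0) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(rea)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sbml_id(m)),
                            stoichiometry = format(-rea[[m]], digits = 17),
                            constant = "true")
      }
    }
    if (length(pro) > 0) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(pro)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sbml_id(m)),
                            stoichiometry = format(pro[[m]], digits = 17),
                            constant = "true")
      }
    }
    if (nzchar(model$rxn$gpr[k])) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      gpr_to_fbc(ga, parse_gpr(model$rxn$gpr[k]))
    }
  }
  ob <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  o1 <- xml2::xml_add_child(ob, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fo <- xml2::xml_add_child(o1, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_",
                                              sbml_id(model$objective_reaction)),
                      "fbc:coefficient" = "1")
  gp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model_genes(model)) {
    xml2::xml_add_child(gp, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_id(g)),
                        "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
}

xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  nm <- names(at)
  hit <- which(nm == name | sub("^[^:]+:", "", nm) == name)
  if (length(hit) == 0) NA_character_ else at[[hit[1]]]
}

fbc_to_gpr <- function(node, gene_labels) {
  ln <- xml2::xml_name(node)  # xml_name strips the prefix
  if (ln == "geneProductRef") {
    gid <- xattr(node, "geneProduct")
    lab <- gene_labels[[gid]]
    return(if (is.null(lab) || is.na(lab)) sub("^G_", "", gid) else lab)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_to_gpr, character(1), gene_labels = gene_labels)
  op <- if (ln == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e)))
  find <- function(x, tag) {
    xml2::xml_find_all(x, paste0(".//*[local-name()='", tag, "']"))
  }
  species <- find(doc, "species")
  met_ids <- vapply(species, function(s) xattr(s, "id"), character(1))
  met_names <- vapply(species, function(s) {
    nm <- xattr(s, "name"); if (is.na(nm)) sub("^M_", "", xattr(s, "id")) else nm
  }, character(1))
  names(met_names) <- met_ids
  pars <- find(doc, "parameter")
  parval <- vapply(pars, function(p) as.numeric(xattr(p, "value")), numeric(1))
  names(parval) <- vapply(pars, function(p) xattr(p, "id"), character(1))
  gps <- find(doc, "geneProduct")
  gene_labels <- as.list(vapply(gps, function(g) {
    lab <- xattr(g, "label"); if (is.na(lab)) sub("^G_", "", xattr(g, "id"))
    else lab
  }, character(1)))
  names(gene_labels) <- vapply(gps, function(g) xattr(g, "id"), character(1))
  objs <- find(doc, "fluxObjective")
  obj_rxn <- if (length(objs) > 0) xattr(objs[[1]], "reaction") else NA
  reactions <- lapply(find(doc, "reaction"), function(rx) {
    rid <- xattr(rx, "id")
    nm <- xattr(rx, "name")
    st <- numeric(0)
    for (sr in find(rx, "speciesReference")) {
      coef <- as.numeric(xattr(sr, "stoichiometry"))
      parent <- xml2::xml_name(xml2::xml_parent(sr))
      if (parent == "listOfReactants") coef <- -coef
      sp_name <- met_names[[xattr(sr, "species")]]
      st[sp_name] <- (if (sp_name %in% names(st)) st[[sp_name]] else 0) + coef
    }
    lbp <- xattr(rx, "lowerFluxBound"); ubp <- xattr(rx, "upperFluxBound")
    gpr <- ""
    ga <- find(rx, "geneProductAssociation")
    if (length(ga) > 0) {
      kids <- xml2::xml_children(ga[[1]])
      if (length(kids) > 0) gpr <- fbc_to_gpr(kids[[1]], gene_labels)
    }
    list(id = if (is.na(nm)) sub("^R_", "", rid) else nm,
         stoichiometry = st,
         lb = if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else -1000,
         ub = if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000,
         gpr = gpr,
         objective = !is.na(obj_rxn) && identical(rid, obj_rxn))
  })
  metabolic_model(unname(met_names), reactions)
}

# ---- Measurements -----------------------------------------------------------

#' Construct a measurement set
#'
#' Measured fluxes for one condition, each tagged with a physiological role.
#' Used both as model constraints (scenario dependent) and as the ground
#' truth the normalized prediction error is computed against.
#'
#' @param ids reaction identifiers.
#' @param values measured fluxes (mmol/gDW/h; growth in 1/h).
#' @param roles one of `"uptake"`, `"secretion"`, `"growth"`,
#'   `"intracellular"` per entry.
#' @return a `measurement_set` (data frame with columns id, value, role).
#' @export
measurement_set <- function(ids, values, roles) {
  roles <- match.arg(roles, c("uptake", "secretion", "growth",
                              "intracellular"), several.ok = TRUE)
  if (length(roles) == 1) roles <- rep(roles, length(ids))
  stopifnot(length(ids) == length(values), length(roles) == length(ids))
  if (anyDuplicated(ids)) stop("each reaction may appear only once")
  structure(data.frame(id = as.character(ids), value = as.numeric(values),
                       role = roles, stringsAsFactors = FALSE),
            class = c("measurement_set", "data.frame"))
}

#' Apply measurement constraints to a model
#'
#' Implements the benchmark's three constraint scenarios: `uptake_only`
#' fixes the measured uptake rates (the "given only the measured glucose and
#' oxygen uptake rates" setting), `full_physiology` fixes the complete set
#' of measured uptake, growth and secretion rates (intracellular
#' measurements are never constraints — they remain the prediction
#' target), and `min_growth_90` fixes the uptakes and additionally imposes
#' a minimum growth rate of 90% of the maximum theoretical growth under
#' those uptakes.
#'
#' Fixing uses a symmetric tolerance band `value +/- delta` with
#' `delta = max(1e-6, 1e-3 * |value|)` so that floating-point measurements
#' cannot render the model infeasible. With `uptake_as = "upper"` uptake
#' values become upper bounds instead of fixed bands.
#'
#' @param model a `metabolic_model`.
#' @param measurements a `measurement_set`.
#' @param scenario `"uptake_only"`, `"full_physiology"` or `"min_growth_90"`.
#' @param uptake_as `"fixed"` (band, default) or `"upper"`.
#' @return the constrained model; `growth_fixed` is set when the growth
#'   rate was fixed, which downstream methods use to drop their own growth
#'   requirements.
#' @export
apply_measurements <- function(model, measurements,
                               scenario = c("uptake_only", "full_physiology",
                                            "min_growth_90"),
                               uptake_as = c("fixed", "upper")) {
  scenario <- match.arg(scenario)
  uptake_as <- match.arg(uptake_as)
  missing_ids <- setdiff(measurements$id, model$rxn$id)
  if (length(missing_ids) > 0) {
    stop("measured reaction id(s) absent from model: ",
         paste(missing_ids, collapse = ", "))
  }
  fix_one <- function(model, id, value, as_upper = FALSE) {
    delta <- max(1e-6, 1e-3 * abs(value))
    i <- rxn_index(model, id)
    if (as_upper) {
      model$rxn$ub[i] <- value + delta
    } else {
      model$rxn$lb[i] <- value - delta
      model$rxn$ub[i] <- value + delta
    }
    model
  }
  which_rows <- switch(scenario,
                       uptake_only = which(measurements$role == "uptake"),
                       min_growth_90 = which(measurements$role == "uptake"),
                       full_physiology = which(measurements$role %in%
                                                 c("uptake", "secretion",
                                                   "growth")))
  for (k in which_rows) {
    model <- fix_one(model, measurements$id[k], measurements$value[k],
                     as_upper = uptake_as == "upper" &&
                       measurements$role[k] == "uptake")
  }
  if (scenario == "full_physiology" &&
      any(measurements$role == "growth")) {
    model$growth_fixed <- TRUE
  }
  if (scenario == "min_growth_90") {
    sol <- fba(model)
    if (sol$status != "optimal") {
      stop("cannot establish maximum growth for min_growth_90 scenario")
    }
    i <- rxn_index(model, model$objective_reaction)
    model$rxn$lb[i] <- max(model$rxn$lb[i], 0.9 * sol$objective_value)
  }
  model
}

#' Delete genes from a model
#'
#' Reactions whose GPR rule evaluates to false once the deleted genes are
#' absent have their bounds closed to `[0, 0]`, emulating the knockout
#' prior to simulation.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene identifiers.
#' @return the modified model.
#' @export
delete_genes <- function(model, genes) {
  if (length(genes) == 0) return(model)
  known <- model_genes(model)
  unknown <- setdiff(genes, known)
  if (length(unknown) > 0) {
    warning("gene(s) not present in any GPR: ",
            paste(unknown, collapse = ", "))
  }
  for (k in seq_len(nrow(model$rxn))) {
    g <- model$rxn$gpr[k]
    if (!nzchar(g)) next
    rule <- parse_gpr(g)
    if (!eval_gpr(rule, function(gene) !(gene %in% genes))) {
      model$rxn$lb[k] <- 0
      model$rxn$ub[k] <- 0
    }
  }
  model
}
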