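#' Construct a stoichiometric model
#'
#' A constraint-based metabolic model: a sparse stoichiometric matrix
#' \code{S} (metabolites x reactions), per-reaction flux bounds, an objective
#' reaction (typically biomass growth), gene-reaction rules and optional
#' exchange-role annotations. Steady-state flux vectors \code{v} satisfy
#' \code{S v = 0} and \code{lb <= v <= ub}; additional linear coupling
#' inequalities \code{A v <= b} can be attached (see
#' [apply_constraints()]).
#'
#' @param id model identifier.
#' @param S numeric matrix (or anything coercible via [Matrix::Matrix()])
#'   with metabolite row names and reaction column names.
#' @param lb,ub numeric vectors of lower/upper flux bounds
#'   (mmol gDW^-1 h^-1), one per reaction. Reversibility is derived from
#'   \code{lb < 0}.
#' @param objective reaction id whose flux is maximized by [fba()].
#' @param gene_rules named character vector of boolean gene-reaction rules
#'   (e.g. \code{"g1"}, \code{"g1 or g2"}, \code{"g1 and g2"}); \code{""}
#'   for reactions with no associated gene. Unnamed reactions default to "".
#' @param exchanges named character vector mapping physiological roles
#'   (\code{"glucose"}, \code{"oxygen"}, \code{"co2"}, \code{"ethanol"},
#'   \code{"glycerol"}, \code{"biomass"}, ...) to exchange-reaction ids.
#' @param is_exchange logical vector flagging exchange reactions; if
#'   \code{NULL}, reactions involving exactly one metabolite are flagged.
#' @param coupling optional list with matrix \code{A} (columns = reactions)
#'   and vector \code{b} encoding extra inequalities \code{A v <= b}.
#'
#' @return an object of class \code{"stoich_model"}.
#' @export
stoichiometric_model <- function(id, S, lb, ub, objective,
                                 gene_rules = NULL, exchanges = character(),
                                 is_exchange = NULL, coupling = NULL) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  rxns <- colnames(S)
  mets <- rownames(S)
  if (is.null(rxns) || is.null(mets))
    stop("S must have metabolite row names and reaction column names")
  n <- ncol(S)
  if (length(lb) != n || length(ub) != n)
    stop("lb and ub must have one entry per reaction")
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (any(lb > ub))
    stop("lb > ub for reaction(s): ",
         paste(rxns[lb > ub], collapse = ", "))
  if (!objective %in% rxns)
    stop("objective reaction '", objective, "' not in model")
  rules <- stats::setNames(rep("", n), rxns)
  if (!is.null(gene_rules)) {
    unknown <- setdiff(names(gene_rules), rxns)
    if (length(unknown))
      stop("gene rule for unknown reaction(s): ", paste(unknown, collapse = ", "))
    rules[names(gene_rules)] <- gene_rules
  }
  if (is.null(is_exchange))
    is_exchange <- Matrix::colSums(S != 0) == 1
  is_exchange <- stats::setNames(as.logical(is_exchange), rxns)
  if (length(exchanges)) {
    missing_ex <- setdiff(unname(exchanges), rxns)
    if (length(missing_ex))
      stop("exchange role maps to unknown reaction(s): ",
           paste(missing_ex, collapse = ", "))
  }
  if (!is.null(coupling)) {
    coupling$A <- as.matrix(coupling$A)
    if (ncol(coupling$A) != n || nrow(coupling$A) != length(coupling$b))
      stop("coupling dimensions do not match the model")
  }
  structure(list(id = id, S = S, mets = mets, rxns = rxns,
                 lb = stats::setNames(lb, rxns), ub = stats::setNames(ub, rxns),
                 objective = objective, gene_rules = rules,
                 exchanges = exchanges, is_exchange = is_exchange,
                 coupling = coupling),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$mets),
      "   reactions: ", length(x$rxns),
      "   (", sum(x$is_exchange), " exchange, ",
      sum(x$lb < 0), " reversible)\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  if (!is.null(x$coupling))
    cat("  coupling inequalities: ", nrow(x$coupling$A), "\n", sep = "")
  invisible(x)
}

#' Set flux bounds on a reaction
#'
#' @param model a \code{stoich_model}.
#' @param rxn reaction id.
#' @param lb,ub new bounds; \code{NULL} leaves the bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  if (!rxn %in% model$rxns) stop("unknown reaction: ", rxn)
  if (!is.null(lb)) model$lb[rxn] <- lb
  if (!is.null(ub)) model$ub[rxn] <- ub
  if (model$lb[rxn] > model$ub[rxn])
    stop("lb > ub on ", rxn)
  model
}

rev_flags <- function(model) model$lb < 0

exchange_ids <- function(model) model$rxns[model$is_exchange]

role_rxn <- function(model, role, required = TRUE) {
  id <- unname(model$exchanges[role])
  if ((is.null(id) || is.na(id)) && required)
    stop("model has no exchange reaction mapped to role '", role, "'")
  if (is.null(id) || is.na(id)) NULL else id
}

#' Read a stoichiometric model from disk
#'
#' Two on-disk formats are supported. The JSON dialect stores a model as
#' \code{{id, metabolites, reactions: [{id, name, stoichiometry, lb, ub,
#' gene_rule, is_exchange}], objective, exchanges}} with
#' \code{stoichiometry} a metabolite -> coefficient map (negative =
#' consumed). SBML is read following level-3 flux-balance (fbc)
#' conventions: species, reactions with reactant/product lists, flux-bound
#' parameters, gene-product associations and the active maximization
#' objective.
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"}; guessed from the file
#'   extension when omitted.
#' @return a \code{stoich_model}.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rx <- doc$reactions
  if (is.null(rx) || !length(rx)) stop("model file has no reactions")
  rxn_ids <- vapply(rx, function(r) r$id, "")
  mets <- unique(unlist(lapply(rx, function(r) names(r$stoichiometry))))
  declared <- unlist(doc$metabolites)
  if (!is.null(declared)) {
    dangling <- setdiff(mets, declared)
    if (length(dangling))
      stop("reactions reference undeclared metabolite(s): ",
           paste(dangling, collapse = ", "))
    mets <- declared
  }
  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  for (r in rx)
    for (m in names(r$stoichiometry))
      S[m, r$id] <- as.numeric(r$stoichiometry[[m]])
  lb <- vapply(rx, function(r) as.numeric(r$lb), 0)
  ub <- vapply(rx, function(r) as.numeric(r$ub), 0)
  rules <- vapply(rx, function(r) if (is.null(r$gene_rule)) "" else r$gene_rule, "")
  is_ex <- vapply(rx, function(r) isTRUE(r$is_exchange), NA)
  if (anyNA(is_ex)) is_ex <- NULL
  if (is.null(doc$objective)) stop("model file declares no objective reaction")
  stoichiometric_model(
    id = if (is.null(doc$id)) basename(path) else doc$id,
    S = S, lb = lb, ub = ub, objective = doc$objective,
    gene_rules = stats::setNames(rules, rxn_ids),
    exchanges = unlist(doc$exchanges),
    is_exchange = is_ex)
}

#' Write a stoichiometric model to disk
#'
#' @param model a \code{stoich_model}.
#' @param path output file.
#' @param format \code{"json"} or \code{"sbml"} (level 3 + fbc version 2).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  Sd <- as.matrix(model$S)
  rx <- lapply(model$rxns, function(r) {
    col <- Sd[, r]
    nz <- col[col != 0]
    list(id = r, name = r,
         stoichiometry = as.list(nz),
         lb = unname(model$lb[r]), ub = unname(model$ub[r]),
         gene_rule = unname(model$gene_rules[r]),
         is_exchange = unname(model$is_exchange[r]))
  })
  doc <- list(id = model$id, metabolites = model$mets, reactions = rx,
              objective = model$objective,
              exchanges = as.list(model$exchanges))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_safe <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  Sd <- as.matrix(model$S)
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">', sbml_safe(model$id)),
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "<listOfSpecies>",
    sprintf('<species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            sbml_safe(model$mets)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="lb_%s" value="%.17g" constant="true"/>',
            sbml_safe(model$rxns), model$lb),
    sprintf('<parameter id="ub_%s" value="%.17g" constant="true"/>',
            sbml_safe(model$rxns), model$ub),
    "</listOfParameters>")
  genes <- unique(unlist(regmatches(model$gene_rules,
                                    gregexpr("[A-Za-z0-9_.-]+", model$gene_rules))))
  genes <- setdiff(genes, c("and", "or", "AND", "OR"))
  if (length(genes))
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                       sbml_safe(genes), esc(genes)),
               "</fbc:listOfGeneProducts>")
  lines <- c(lines, "<listOfReactions>")
  for (r in model$rxns) {
    col <- Sd[, r]
    reac <- col[col < 0]; prod <- col[col > 0]
    rl <- sprintf('<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
                  sbml_safe(r), tolower(model$lb[r] < 0), sbml_safe(r), sbml_safe(r))
    if (length(reac))
      rl <- c(rl, "<listOfReactants>",
              sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                      sbml_safe(names(reac)), -reac),
              "</listOfReactants>")
    if (length(prod))
      rl <- c(rl, "<listOfProducts>",
              sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                      sbml_safe(names(prod)), prod),
              "</listOfProducts>")
    rule <- model$gene_rules[r]
    if (nzchar(rule))
      rl <- c(rl, "<fbc:geneProductAssociation>", gpr_to_sbml(rule),
              "</fbc:geneProductAssociation>")
    lines <- c(lines, rl, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            sbml_safe(model$objective)),
    "</fbc:listOfFluxObjectives>", "</fbc:objective>", "</fbc:listOfObjectives>",
    "</model>", "</sbml>")
  writeLines(lines, path)
}

# flat rules only: "a", "a or b", "a and b" (no nesting needed for this tier)
gpr_to_sbml <- function(rule) {
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  refs <- function(g) sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>', sbml_safe(g))
  if (length(toks) == 1) return(refs(toks))
  op <- tolower(toks[2])
  genes <- toks[seq(1, length(toks), by = 2)]
  tag <- if (op == "or") "fbc:or" else "fbc:and"
  c(sprintf("<%s>", tag), refs(genes), sprintf("</%s>", tag))
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rnodes)) stop("SBML file has no reactions")
  rxn_ids <- xml2::xml_attr(rnodes, "id")
  S <- matrix(0, length(species), length(rnodes),
              dimnames = list(species, rxn_ids))
  lb <- ub <- numeric(length(rnodes))
  rules <- character(length(rnodes))
  for (i in seq_along(rnodes)) {
    nd <- rnodes[[i]]
    for (sr in xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      if (!sp %in% species) stop("dangling metabolite reference: ", sp)
      S[sp, i] <- S[sp, i] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      if (!sp %in% species) stop("dangling metabolite reference: ", sp)
      S[sp, i] <- S[sp, i] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb[i] <- pvals[[xml2::xml_attr(nd, "fbc:lowerFluxBound", ns)]]
    ub[i] <- pvals[[xml2::xml_attr(nd, "fbc:upperFluxBound", ns)]]
    gpa <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation", ns)
    if (!inherits(gpa, "xml_missing")) {
      gp <- xml2::xml_attr(xml2::xml_find_all(gpa, ".//fbc:geneProductRef", ns), "geneProduct")
      gp <- sub("^G_", "", gp)
      op <- if (!inherits(xml2::xml_find_first(gpa, "./fbc:or", ns), "xml_missing"))
        " or " else " and "
      rules[i] <- paste(gp, collapse = op)
    }
  }
  objr <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:listOfFluxObjectives/fbc:fluxObjective", ns),
    "fbc:reaction", ns)
  if (is.na(objr)) stop("SBML file declares no flux objective")
  if (!objr %in% rxn_ids) stop("objective reaction '", objr, "' absent from model")
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  stoichiometric_model(id = if (is.na(mid)) basename(path) else mid,
                       S = S, lb = lb, ub = ub, objective = objr,
                       gene_rules = stats::setNames(rules, rxn_ids))
}
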