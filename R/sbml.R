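## SBML Level 3 Version 1 + FBC v2 input/output.
##
## The dialect written here is the strict-FBC subset used to exchange
## constraint-based models: species carry fbc:charge/fbc:chemicalFormula,
## flux bounds are shared Parameters, GPRs are fbc:geneProductAssociation
## trees, and the active objective is an fbc:objective with a single flux
## objective. Package-specific reaction flags, subsystems and database
## annotations ride in <notes> under fixed "strainforge:" keys so that a
## write/read round trip is lossless.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

sbmlSafeId <- function(id, what) {
  bad <- grepl("[^A-Za-z0-9_]", id)
  if (any(bad)) {
    stop("unrepresentable ", what, " id(s) for SBML: ",
         paste(id[bad], collapse = ", "))
  }
  id
}

fmtNum <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[!is.finite(x) & x > 0] <- "INF"
  out[!is.finite(x) & x < 0] <- "-INF"
  out
}

notesLines <- function(flags = character(), subsystem = "",
                       annotations = list()) {
  lines <- character()
  for (f in idSort(flags)) lines <- c(lines, paste0("strainforge:flag=", f))
  if (nzchar(subsystem)) {
    lines <- c(lines, paste0("strainforge:subsystem=", subsystem))
  }
  for (db in idSort(names(annotations))) {
    lines <- c(lines, paste0("strainforge:annotation:", db, "=",
                             paste(idSort(annotations[[db]]), collapse = ",")))
  }
  lines
}

parseNotes <- function(lines) {
  flags <- sub("^strainforge:flag=", "",
               grep("^strainforge:flag=", lines, value = TRUE))
  subsystem <- sub("^strainforge:subsystem=", "",
                   grep("^strainforge:subsystem=", lines, value = TRUE))
  ann <- list()
  for (ln in grep("^strainforge:annotation:", lines, value = TRUE)) {
    body <- sub("^strainforge:annotation:", "", ln)
    db <- sub("=.*$", "", body)
    ann[[db]] <- strsplit(sub("^[^=]*=", "", body), ",", fixed = TRUE)[[1]]
  }
  list(flags = flags,
       subsystem = if (length(subsystem)) subsystem[1] else "",
       annotations = ann)
}

#' Write a model as SBML Level 3 (FBC v2)
#'
#' @param model a [GEM]; must have an objective reaction.
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readSBML()]
#' @export
writeSBML <- function(model, path) {
  if (!nzchar(model@objective)) {
    cand <- model@reactions$id[hasFlag(model, model@reactions$id, "biomass")]
    stop("model has no objective reaction; biomass-flagged candidates: ",
         if (length(cand)) paste(cand, collapse = ", ") else "<none>")
  }
  sbmlSafeId(model@metabolites$id, "metabolite")
  sbmlSafeId(model@reactions$id, "reaction")
  sbmlSafeId(model@genes, "gene")

  doc <- xml2::xml_new_root("sbml",
    "xmlns" = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbmlSafeId(model@id, "model"),
                             "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in model@compartments) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  met <- model@metabolites
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(ls, "species",
      id = paste0("M_", met$id[i]), name = met$name[i],
      compartment = met$compartment[i], hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false",
      "fbc:charge" = as.character(met$charge[i]))
    if (!is.na(met$formula[i]) && nzchar(met$formula[i])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula[i])
    }
    addNotes(sp, notesLines(annotations = met$annotations[[i]]))
  }

  lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model@genes) {
    xml2::xml_add_child(lg, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", g), "fbc:label" = g)
  }

  rxn <- model@reactions
  vals <- sort(unique(c(rxn$lb, rxn$ub)))
  pid <- stats::setNames(sprintf("sf_bound_%d", seq_along(vals)), fmtNum(vals))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(vals)) {
    xml2::xml_add_child(lp, "parameter", id = pid[[k]],
                        value = fmtNum(vals[k]), constant = "true",
                        sboTerm = "SBO:0000626")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rxn))) {
    nd <- xml2::xml_add_child(lr, "reaction",
      id = paste0("R_", rxn$id[i]), name = rxn$name[i],
      reversible = if (rxn$lb[i] < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = pid[[fmtNum(rxn$lb[i])]],
      "fbc:upperFluxBound" = pid[[fmtNum(rxn$ub[i])]])
    addNotes(nd, notesLines(rxn$flags[[i]], rxn$subsystem[i],
                            rxn$annotations[[i]]))
    st <- reactionStoich(model, rxn$id[i])
    rea <- st[st < 0]
    prod <- st[st > 0]
    if (length(rea)) {
      lre <- xml2::xml_add_child(nd, "listOfReactants")
      for (mi in names(rea)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", mi),
                            stoichiometry = fmtNum(-rea[[mi]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(nd, "listOfProducts")
      for (mi in names(prod)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", mi),
                            stoichiometry = fmtNum(prod[[mi]]),
                            constant = "true")
      }
    }
    if (nzchar(rxn$gpr[i])) {
      ga <- xml2::xml_add_child(nd, "fbc:geneProductAssociation")
      addGPRNode(ga, gprParse(rxn$gpr[i]))
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model@objective),
                      "fbc:coefficient" = "1")

  xml2::write_xml(doc, path)
  invisible(path)
}

addNotes <- function(node, lines) {
  if (!length(lines)) return(invisible(NULL))
  nt <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(nt, "body", xmlns = XHTML_NS)
  for (ln in lines) xml2::xml_add_child(body, "p", ln)
  invisible(NULL)
}

addGPRNode <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", tree))
  } else {
    nd <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (a in tree$args) addGPRNode(nd, a)
  }
  invisible(NULL)
}

#' Read an SBML Level 3 (FBC v2) model
#'
#' Restores everything [writeSBML()] emits: stoichiometry, bounds, GPRs,
#' formulas, charges, annotations, flags and the active objective.
#'
#' @param path SBML file path.
#' @return a [GEM].
#' @export
readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in '", path, "': ", conditionMessage(e))
  })
  ns <- xml2::xml_ns(doc)
  core <- names(ns)[ns == SBML_NS][1]
  fbc <- names(ns)[ns == FBC_NS][1]
  if (is.na(core)) stop("not an SBML Level 3 document: ", path)
  if (is.na(fbc)) stop("missing FBC v2 package declaration in: ", path)
  q <- function(tag) paste0(core, ":", tag)
  qf <- function(tag) paste0(fbc, ":", tag)
  mdl <- xml2::xml_find_first(doc, paste0("./", q("model")), ns)
  if (inherits(mdl, "xml_missing")) stop("SBML document has no <model>")
  stripPrefix <- function(x, pre) sub(paste0("^", pre), "", x)

  params <- xml2::xml_find_all(mdl, paste0(".//", q("parameter")), ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  readNotes <- function(node) {
    ps <- xml2::xml_find_all(
      node, paste0("./", q("notes"), "//*[local-name()='p']"), ns)
    parseNotes(xml2::xml_text(ps))
  }

  sps <- xml2::xml_find_all(mdl, paste0(".//", q("species")), ns)
  metAnn <- vector("list", length(sps))
  met <- data.frame(
    id = stripPrefix(xml2::xml_attr(sps, "id"), "M_"),
    name = xml2::xml_attr(sps, "name"),
    compartment = xml2::xml_attr(sps, "compartment"),
    formula = xml2::xml_attr(sps, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sps, "charge"))),
    stringsAsFactors = FALSE)
  met$charge[is.na(met$charge)] <- 0L
  for (i in seq_along(sps)) metAnn[[i]] <- readNotes(sps[[i]])$annotations
  met$annotations <- metAnn
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]

  gps <- xml2::xml_find_all(mdl, paste0(".//", qf("geneProduct")), ns)
  geneIds <- stripPrefix(xml2::xml_attr(gps, "id"), "G_")

  rnodes <- xml2::xml_find_all(mdl, paste0(".//", q("reaction")), ns)
  nR <- length(rnodes)
  rid <- stripPrefix(xml2::xml_attr(rnodes, "id"), "R_")
  rname <- xml2::xml_attr(rnodes, "name")
  rname[is.na(rname)] <- rid[is.na(rname)]
  lbp <- xml2::xml_attr(rnodes, "lowerFluxBound")
  ubp <- xml2::xml_attr(rnodes, "upperFluxBound")
  badp <- setdiff(stats::na.omit(c(lbp, ubp)), names(pval))
  if (length(badp)) {
    stop("flux-bound parameter(s) not declared: ", paste(badp, collapse = ", "))
  }
  lb <- ifelse(is.na(lbp), -1000, pval[lbp])
  ub <- ifelse(is.na(ubp), 1000, pval[ubp])

  triplets_i <- integer(); triplets_j <- integer(); triplets_x <- numeric()
  gpr <- character(nR)
  flags <- vector("list", nR)
  subsys <- character(nR)
  rann <- vector("list", nR)
  metIndex <- stats::setNames(seq_len(nrow(met)), met$id)
  for (j in seq_len(nR)) {
    nd <- rnodes[[j]]
    nt <- readNotes(nd)
    flags[[j]] <- nt$flags
    subsys[j] <- nt$subsystem
    rann[[j]] <- nt$annotations
    addRefs <- function(tag, sign) {
      refs <- xml2::xml_find_all(
        nd, paste0("./", q(tag), "/", q("speciesReference")), ns)
      if (!length(refs)) return(invisible(NULL))
      sp <- stripPrefix(xml2::xml_attr(refs, "species"), "M_")
      co <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      unknown <- setdiff(sp, met$id)
      if (length(unknown)) {
        stop("reaction '", rid[j], "' references undeclared species: ",
             paste(unknown, collapse = ", "))
      }
      triplets_i <<- c(triplets_i, metIndex[sp])
      triplets_j <<- c(triplets_j, rep(j, length(sp)))
      triplets_x <<- c(triplets_x, sign * co)
      invisible(NULL)
    }
    addRefs("listOfReactants", -1)
    addRefs("listOfProducts", +1)
    ga <- xml2::xml_find_first(nd, paste0("./", qf("geneProductAssociation")),
                               ns)
    gpr[j] <- if (inherits(ga, "xml_missing")) "" else {
      gprFromNode(xml2::xml_child(ga), fbc)
    }
  }

  S <- Matrix::sparseMatrix(i = triplets_i, j = triplets_j, x = triplets_x,
                            dims = c(nrow(met), nR))
  rxn <- data.frame(id = rid, name = rname, lb = unname(lb), ub = unname(ub),
                    gpr = gpr, subsystem = subsys, stringsAsFactors = FALSE)
  rxn$flags <- flags
  rxn$annotations <- rann

  fo <- xml2::xml_find_first(
    mdl, paste0(".//", qf("objective"), "/", qf("listOfFluxObjectives"),
                "/", qf("fluxObjective")), ns)
  if (inherits(fo, "xml_missing")) {
    cand <- rid[vapply(flags, function(f) "biomass" %in% f, logical(1))]
    stop("SBML model declares no objective; biomass-flagged candidates: ",
         if (length(cand)) paste(cand, collapse = ", ") else "<none>")
  }
  objective <- stripPrefix(xml2::xml_attr(fo, "reaction"), "R_")

  newGEM(id = xml2::xml_attr(mdl, "id"), metabolites = met, reactions = rxn,
         stoichiometry = S, genes = geneIds, objective = objective)
}

gprFromNode <- function(node, fbc) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, function(k) {
    s <- gprFromNode(k, fbc)
    if (xml2::xml_name(k) %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", nm, " "))
}
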