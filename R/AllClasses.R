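#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' GEM: a compartmentalized genome-scale metabolic model
#'
#' The central data structure of the package: a stoichiometric network with
#' gene-protein-reaction (GPR) associations, flux bounds and a declared
#' objective reaction, as exchanged in SBML Level 3 (FBC v2).
#'
#' @slot id model identifier.
#' @slot metabolites `data.frame` with columns `id` (compartment-suffixed,
#'   BiGG style, e.g. `"glc__D_e"`), `name`, `compartment`, `formula`
#'   (chemical formula string, `NA` when unknown; pseudo-elements `R`/`X`
#'   allowed), `charge` (integer), and a list-column `annotations`
#'   (per metabolite, a named list mapping database keys such as `"chebi"`
#'   to character vectors of identifiers).
#' @slot reactions `data.frame` with columns `id`, `name`, `lb`, `ub`
#'   (flux bounds, mmol/gDW/h), `gpr` (boolean gene expression string,
#'   `""` when none), `subsystem`, plus list-columns `flags` (character
#'   vectors drawn from `gap_filled`, `restored_disconnected`, `biomass`,
#'   `exempt_from_balance`) and `annotations`.
#' @slot stoichiometry sparse matrix (metabolites x reactions); negative
#'   coefficients are consumed species.
#' @slot genes character vector of all gene ids in the model.
#' @slot objective id of the objective (usually biomass) reaction.
#' @slot compartments character vector of compartment codes.
#'
#' @seealso [readSBML()], [writeSBML()], [modelStats()], [solveFBA()]
#' @export
setClass("GEM",
  representation(
    id = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "dgCMatrix",
    genes = "character",
    objective = "character",
    compartments = "character"
  )
)

setValidity("GEM", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  rn <- rownames(S); if (is.null(rn)) rn <- character(0)
  cn <- colnames(S); if (is.null(cn)) cn <- character(0)
  if (!identical(rn, met$id)) {
    msg <- c(msg, "stoichiometry rows do not match metabolite ids")
  }
  if (!identical(cn, rxn$id)) {
    msg <- c(msg, "stoichiometry columns do not match reaction ids")
  }
  if (nrow(rxn) > 0L && any(rxn$lb > rxn$ub)) {
    msg <- c(msg, "reaction lower bound exceeds upper bound")
  }
  if (length(object@objective) == 1L && nzchar(object@objective) &&
      !(object@objective %in% rxn$id)) {
    msg <- c(msg, sprintf("objective '%s' is not a reaction", object@objective))
  }
  gpr_genes <- unique(unlist(lapply(rxn$gpr, gprGenes), use.names = FALSE))
  if (length(setdiff(gpr_genes, object@genes)) > 0L) {
    msg <- c(msg, "GPR references genes absent from the gene set")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationCondition: a medium plus reaction-bound overrides
#'
#' Describes one simulation environment: maximum uptake rates for medium
#' components (applied to exchange-reaction lower bounds), a set of
#' unconstrained exchanges (typically water and protons), explicit
#' reaction-bound overrides (e.g. capping pyruvate-formate lyase), and an
#' optional objective override.
#'
#' @slot medium named numeric; names are exchange reaction ids, values are
#'   maximum uptake magnitudes (mmol/gDW/h, non-negative).
#' @slot unconstrained character vector of exchange ids left effectively
#'   unbounded (lower bound -1000).
#' @slot overrides named list of `c(lb, ub)` pairs keyed by reaction id,
#'   applied after the medium.
#' @slot objectiveOverride reaction id, or `character(0)` to keep the
#'   model's objective.
#'
#' @seealso [simulationCondition()], [applyCondition()], [buildCDM()]
#' @export
setClass("SimulationCondition",
  representation(
    medium = "numeric",
    unconstrained = "character",
    overrides = "list",
    objectiveOverride = "character"
  )
)

setValidity("SimulationCondition", function(object) {
  msg <- character()
  if (length(object@medium) && is.null(names(object@medium))) {
    msg <- c(msg, "medium must be a named numeric vector")
  }
  if (any(object@medium < 0)) msg <- c(msg, "uptake magnitudes must be >= 0")
  bad <- vapply(object@overrides, function(b) length(b) != 2L || b[1] > b[2],
                logical(1))
  if (any(bad)) msg <- c(msg, "overrides must be c(lb, ub) with lb <= ub")
  if (length(msg)) msg else TRUE
})

#' FluxSolution: the result of an FBA or pFBA solve
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @slot objectiveValue optimal objective flux (h^-1 for a biomass
#'   objective); `NA` unless optimal.
#' @slot fluxes named numeric of reaction fluxes; empty unless optimal.
#'
#' @export
setClass("FluxSolution",
  representation(
    status = "character",
    objectiveValue = "numeric",
    fluxes = "numeric"
  )
)

#' PanModel: union network plus strain x reaction presence matrix
#'
#' @slot union a [GEM] holding one copy of every reaction/metabolite seen in
#'   any strain (bounds unioned across strains).
#' @slot presence logical matrix, strains in rows, union reaction ids in
#'   columns.
#'
#' @seealso [buildPanModel()], [presenceMatrix()]
#' @export
setClass("PanModel",
  representation(union = "GEM", presence = "matrix")
)

setValidity("PanModel", function(object) {
  if (!identical(colnames(object@presence), reactionIds(object@union))) {
    return("presence columns must equal union reaction ids")
  }
  TRUE
})
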