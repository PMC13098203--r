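## Post-carve refinement of a draft strain model: biomass installation,
## gap-fill pruning and restoration of gene-evidenced disconnected
## reactions. Carving prioritizes network connectivity, so drafts carry
## gene-less gap-filled reactions (poor evidence for strain comparison) and
## omit gene-evidenced reactions that happen to be disconnected; refinement
## reverses both while preserving growth under the gap-fill conditions.

#' Read a carving reaction-score table (TSV)
#'
#' Expects at least columns `reaction` and `score`; a positive score means
#' genomic evidence was found for the reaction during carving.
#'
#' @param path TSV file path.
#' @return named numeric vector of scores keyed by reaction id.
#' @export
readReactionScores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction", "score") %in% names(df))) {
    stop("score TSV must have columns: reaction, score")
  }
  if (anyDuplicated(df$reaction)) {
    stop("duplicated reaction row(s) in score table: ",
         paste(unique(df$reaction[duplicated(df$reaction)]), collapse = ", "))
  }
  sc <- suppressWarnings(as.numeric(df$score))
  if (anyNA(sc)) {
    stop("non-numeric score(s) for: ",
         paste(df$reaction[is.na(sc)], collapse = ", "))
  }
  stats::setNames(sc, df$reaction)
}

emptyRefinementLog <- function() {
  list(pruned_metabolic = character(), pruned_transport = character(),
       pruned_exchanges = character(), restored = character(),
       biomass_swapped = FALSE)
}

#' Prune unused gap-filled reactions
#'
#' One pFBA per condition decides which gap-filled reactions carry flux.
#' A gap-filled metabolic reaction is removed iff its flux stays below
#' tolerance in every condition. A gap-filled transport reaction is removed
#' iff it is flux-less in every condition *and* none of the metabolites it
#' moves is produced or consumed by any GPR-bearing reaction (gene-less
#' transporters for gene-evidenced metabolites are kept: transporter genes
#' are notoriously under-annotated). Exchange reactions whose metabolite no
#' longer participates in any non-exchange reaction are then dropped.
#' Pruning must not change the growth optimum of any condition (checked to
#' 1e-6).
#'
#' @param model a [GEM] whose gap-filled reactions carry the `gap_filled`
#'   flag (and empty GPRs).
#' @param conditions list of [SimulationCondition]; each must support
#'   positive growth pre-pruning.
#' @return list with `model` and `log`.
#' @export
pruneGapfill <- function(model, conditions) {
  log <- emptyRefinementLog()
  rxn <- model@reactions
  gf <- rxn$id[vapply(rxn$flags, function(f) "gap_filled" %in% f, logical(1))]
  pre <- vapply(conditions, function(cd) {
    s <- solveFBA(model, cd)
    if (s@status != "optimal" || s@objectiveValue <= FLUX_TOL) {
      stop("condition infeasible (or zero growth) before pruning; ",
           "gap-filled inputs should guarantee growth")
    }
    s@objectiveValue
  }, numeric(1))
  if (!length(gf)) return(list(model = model, log = log))

  used <- stats::setNames(logical(length(gf)), gf)
  for (cd in conditions) {
    sol <- solvePFBA(model, cd)
    used <- used | abs(sol@fluxes[gf]) > FLUX_TOL
  }
  cls <- classifyReactions(model)
  gprRxns <- rxn$id[nzchar(rxn$gpr)]
  geneMets <- unique(unlist(lapply(gprRxns, function(r) {
    names(reactionStoich(model, r))
  }), use.names = FALSE))
  dropIds <- character()
  for (r in gf[!used[gf]]) {
    if (cls[[r]] == "metabolic") {
      dropIds <- c(dropIds, r)
      log$pruned_metabolic <- c(log$pruned_metabolic, r)
    } else if (cls[[r]] == "transport") {
      mets <- names(reactionStoich(model, r))
      if (!any(mets %in% geneMets)) {
        dropIds <- c(dropIds, r)
        log$pruned_transport <- c(log$pruned_transport, r)
      }
    }
  }
  model <- removeReactions(model, dropIds)

  ## drop exchanges left disconnected from the rest of the network
  cls <- classifyReactions(model)
  nonEx <- model@stoichiometry[, cls != "exchange", drop = FALSE]
  connected <- Matrix::rowSums(nonEx != 0) > 0
  exDrop <- character()
  for (r in model@reactions$id[cls == "exchange"]) {
    m <- names(reactionStoich(model, r))
    if (!connected[[m]]) exDrop <- c(exDrop, r)
  }
  if (length(exDrop)) {
    model <- removeReactions(model, exDrop)
    log$pruned_exchanges <- exDrop
  }

  post <- vapply(conditions, function(cd) solveFBA(model, cd)@objectiveValue,
                 numeric(1))
  if (any(abs(post - pre) > 1e-6)) {
    stop("internal error: pruning changed a growth optimum by > 1e-6")
  }
  list(model = model, log = log)
}

#' Restore gene-evidenced reactions dropped for lack of connectivity
#'
#' Every universal reaction with a positive carving score that is absent
#' from the strain model is copied in (with its GPR, bounds and any missing
#' metabolites) and flagged `restored_disconnected`. Such reactions usually
#' cannot carry flux, but they matter for reaction presence/absence
#' comparison and pathway-completeness queries.
#'
#' @param model a strain [GEM].
#' @param universal the universal [GEM] the strain was carved from.
#' @param scores named score vector from [readReactionScores()].
#' @return list with `model` and `log`.
#' @export
restoreScoredReactions <- function(model, universal, scores) {
  absentFromUniversal <- setdiff(names(scores), universal@reactions$id)
  if (length(absentFromUniversal)) {
    stop("scored reaction(s) absent from the universal model: ",
         paste(absentFromUniversal, collapse = ", "))
  }
  log <- emptyRefinementLog()
  toAdd <- setdiff(names(scores)[scores > 0], model@reactions$id)
  for (r in toAdd) {
    st <- reactionStoich(universal, r)
    newMets <- setdiff(names(st), model@metabolites$id)
    if (length(newMets)) {
      ui <- match(newMets, universal@metabolites$id)
      model <- addMetabolites(model, universal@metabolites[ui, , drop = FALSE])
    }
    ui <- match(r, universal@reactions$id)
    model <- addReaction(model, r, st,
      name = universal@reactions$name[ui],
      lb = universal@reactions$lb[ui], ub = universal@reactions$ub[ui],
      gpr = universal@reactions$gpr[ui],
      subsystem = universal@reactions$subsystem[ui],
      flags = union(universal@reactions$flags[[ui]], "restored_disconnected"),
      annotations = universal@reactions$annotations[[ui]])
  }
  log$restored <- toAdd
  list(model = model, log = log)
}

#' Install a species-specific biomass reaction
#'
#' Removes any reaction currently flagged `biomass`, adds the supplied
#' biomass pseudo-reaction (flagged `biomass` and `exempt_from_balance`)
#' and makes it the objective. Installing the same spec twice is a no-op.
#'
#' @param model a [GEM].
#' @param spec list with `id` and `stoich` (named coefficients, consumed
#'   precursors negative, including the growth-associated ATP hydrolysis).
#' @return the model with the new objective.
#' @export
installBiomass <- function(model, spec) {
  missing <- setdiff(names(spec$stoich), model@metabolites$id)
  if (length(missing)) {
    stop("biomass precursor(s) absent from model: ",
         paste(missing, collapse = ", "))
  }
  old <- model@reactions$id[vapply(model@reactions$flags,
                                   function(f) "biomass" %in% f, logical(1))]
  if (spec$id %in% old) {
    st <- reactionStoich(model, spec$id)
    target <- spec$stoich[spec$stoich != 0]
    if (length(st) == length(target) &&
        setequal(names(st), names(target)) &&
        all(abs(st[names(target)] - target) < 1e-12)) {
      model@objective <- spec$id
      return(model)  # identical spec already installed
    }
  }
  model <- removeReactions(model, old)
  model <- addReaction(model, spec$id, spec$stoich,
                       name = "Biomass", lb = 0, ub = UNCONSTRAINED_BOUND,
                       flags = c("biomass", "exempt_from_balance"))
  model@objective <- spec$id
  model
}

#' Full refinement of a draft strain model
#'
#' Order: biomass installation (so pruning sees the final objective), then
#' gap-fill pruning, then restoration of scored reactions (restored
#' dead-ends can never be pruned). The result must keep positive growth
#' under every condition.
#'
#' @param draft draft strain [GEM] (gap-filled reactions flagged).
#' @param universal universal [GEM].
#' @param scores carving score vector.
#' @param conditions list of [SimulationCondition] used for pruning.
#' @param biomass biomass spec (see [installBiomass()]).
#' @return list with `model` and concatenated `log`.
#' @export
refineStrain <- function(draft, universal, scores, conditions, biomass) {
  model <- installBiomass(draft, biomass)
  pr <- pruneGapfill(model, conditions)
  rs <- restoreScoredReactions(pr$model, universal, scores)
  log <- pr$log
  log$restored <- rs$log$restored
  log$biomass_swapped <- TRUE
  for (cd in conditions) {
    s <- solveFBA(rs$model, cd)
    if (s@status != "optimal" || s@objectiveValue <= FLUX_TOL) {
      stop("refined model lost growth under a gap-fill condition")
    }
  }
  list(model = rs$model, log = log)
}
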