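## Pan-model construction and cohort-level curation discovery:
## energy-generating cycles (EGCs) and redundant transport variants.
## EGCs in carved cohorts are typically caused by multiple variants of the
## same membrane transport reaction with different proton stoichiometry,
## which together with the F-ATPase form a thermodynamically impossible
## proton pump; they are detected per energy currency by maximizing a
## dissipation reaction with every exchange closed.

#' Build a pan-model from a cohort of strain models
#'
#' The union keeps one copy per reaction id (bounds unioned across
#' strains); the presence matrix records which strain carries which
#' reaction. Strains must share an id namespace — the same id with
#' different stoichiometry across strains is an error.
#'
#' @param models named list of [GEM]s (names default to model ids).
#' @return a [PanModel].
#' @export
buildPanModel <- function(models) {
  if (is.null(names(models))) {
    names(models) <- vapply(models, modelId, character(1))
  }
  union <- models[[1]]
  seenKey <- stats::setNames(
    vapply(reactionIds(union),
           function(r) normalizeStoich(reactionStoich(union, r))$key,
           character(1)),
    reactionIds(union))
  conflicts <- character()
  for (mdl in models[-1]) {
    for (r in reactionIds(mdl)) {
      st <- reactionStoich(mdl, r)
      key <- normalizeStoich(st)$key
      if (r %in% names(seenKey)) {
        if (!identical(key, seenKey[[r]])) conflicts <- c(conflicts, r)
        i <- match(r, union@reactions$id)
        j <- match(r, mdl@reactions$id)
        union@reactions$lb[i] <- min(union@reactions$lb[i],
                                     mdl@reactions$lb[j])
        union@reactions$ub[i] <- max(union@reactions$ub[i],
                                     mdl@reactions$ub[j])
      } else {
        newMets <- setdiff(names(st), union@metabolites$id)
        if (length(newMets)) {
          mi <- match(newMets, mdl@metabolites$id)
          union <- addMetabolites(union, mdl@metabolites[mi, , drop = FALSE])
        }
        j <- match(r, mdl@reactions$id)
        union <- addReaction(union, r, st,
          name = mdl@reactions$name[j], lb = mdl@reactions$lb[j],
          ub = mdl@reactions$ub[j], gpr = mdl@reactions$gpr[j],
          subsystem = mdl@reactions$subsystem[j],
          flags = mdl@reactions$flags[[j]],
          annotations = mdl@reactions$annotations[[j]])
        seenKey[r] <- key
      }
    }
  }
  if (length(conflicts)) {
    stop("same reaction id with different stoichiometry across strains: ",
         paste(unique(conflicts), collapse = ", "))
  }
  pres <- matrix(FALSE, nrow = length(models), ncol = nrow(union@reactions),
                 dimnames = list(names(models), union@reactions$id))
  for (s in names(models)) {
    pres[s, reactionIds(models[[s]])] <- TRUE
  }
  methods::new("PanModel", union = union, presence = pres)
}

#' Default energy-currency dissipation reactions
#'
#' Reads the packaged currency table (BiGG namespace): ATP, GTP, NADH,
#' NADPH, FADH2 hydrolysis/oxidation plus the transmembrane proton
#' gradient. Currencies whose metabolites a model lacks are skipped at
#' detection time.
#'
#' @param path optional TSV with columns `currency`, `equation`.
#' @return data.frame with columns `currency`, `equation`.
#' @export
defaultCurrencies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "energy_currencies.tsv",
                        package = "strainforge")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Detect energy-generating cycles
#'
#' All exchange bounds are closed; for each currency, its dissipation
#' reaction is temporarily added (bounded at 1000 so that a true EGC shows
#' as a large finite flux) and maximized. Nonzero dissipation with every
#' exchange closed means energy from nothing — a thermodynamically
#' infeasible loop. The pFBA support (reactions with |flux| > 1e-6) names
#' the offending cycle.
#'
#' @param model a [GEM].
#' @param currencies data.frame from [defaultCurrencies()].
#' @return data.frame: currency, flux, support (comma-joined reaction ids,
#'   dissipation reaction excluded).
#' @export
detectEnergyGeneratingCycles <- function(model,
                                         currencies = defaultCurrencies()) {
  ex <- names(which(isExchange(model)))
  model@reactions$lb[model@reactions$id %in% ex] <- 0
  model@reactions$ub[model@reactions$id %in% ex] <- 0
  out <- data.frame(currency = character(), flux = numeric(),
                    support = character(), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(currencies))) {
    pr <- parseReactionString(currencies$equation[k])
    if (length(setdiff(names(pr$stoich), model@metabolites$id))) {
      next  # currency not represented in this model
    }
    did <- paste0("SF_DISS_", currencies$currency[k])
    m2 <- addReaction(model, did, pr$stoich, lb = 0, ub = UNCONSTRAINED_BOUND)
    m2@objective <- did
    sol <- solvePFBA(m2)
    flux <- if (sol@status == "optimal") sol@objectiveValue else 0
    support <- character()
    if (flux > FLUX_TOL) {
      f <- sol@fluxes
      support <- setdiff(names(f)[abs(f) > FLUX_TOL], did)
    }
    out <- rbind(out, data.frame(
      currency = currencies$currency[k], flux = flux,
      support = paste(support, collapse = ","), stringsAsFactors = FALSE))
  }
  out
}

#' Group redundant transport variants
#'
#' Transport reactions that become stoichiometrically identical after
#' deleting proton species (any compartment) from both sides are grouped;
#' singleton groups are dropped. Such variant sets — the same carrier
#' modeled with different proton stoichiometry in different source
#' reconstructions — are the typical cause of proton-gradient EGCs.
#' Which member to keep is a curation decision left to a patch file.
#'
#' @param model a [GEM].
#' @param protonBase base id of the proton species (default `"h"`).
#' @return list of character vectors (reaction id groups).
#' @export
findTransportVariants <- function(model, protonBase = "h") {
  cls <- classifyReactions(model)
  tids <- names(cls)[cls == "transport"]
  keys <- vapply(tids, function(r) {
    st <- reactionStoich(model, r)
    st <- st[baseMetaboliteId(names(st)) != protonBase]
    if (!length(st)) return(NA_character_)
    normalizeStoich(st)$key
  }, character(1))
  keys <- keys[!is.na(keys)]
  groups <- split(names(keys), keys)
  unname(groups[vapply(groups, length, integer(1)) >= 2L])
}
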