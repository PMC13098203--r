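## Comparative simulation suite: chemically defined medium (CDM)
## construction, fermentation profiling, PFL scans, ATP yields per carbon
## source, leave-one-out nutrient essentiality, casein/milk growth,
## catabolic-capacity tests and cross-feeding screens.
##
## Conventions follow the standard anaerobic set-up for lactococci: every
## non-carbon medium component is capped at 1 mmol/gDW/h, water and protons
## are unconstrained, and the carbon source is bounded at a C-mol
## equivalent of 20 mmol/gDW/h glucose (120 C-mmol/gDW/h).

CMOL_FLUX <- 120  # C-mmol/gDW/h supplied by the carbon source

MAIN_PRODUCTS <- c("lac__D", "for", "ac", "etoh", "co2")

#' Packaged CDM component table
#'
#' Columns `exchange_id` and `class` (`amino_acid`, `vitamin`, `mineral`,
#' `base`, `nucleobase`, `free`). The default table is the toy-universe
#' medium; a benchmark-grade CDM is supplied the same way via `path`.
#'
#' @param path optional TSV path overriding the packaged table.
#' @return data.frame.
#' @export
cdmComponents <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cdm_components.tsv",
                        package = "strainforge")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a CDM simulation condition around one carbon source
#'
#' Non-carbon components get maximum uptake 1 mmol/gDW/h; the carbon
#' source gets `120 / carbons` (the C-mol equivalent of 20 mmol/gDW/h
#' glucose); water and protons (class `free`) are unconstrained; every
#' other exchange stays closed.
#'
#' @param substrate carbon-source exchange id, e.g. `"EX_glc__D_e"`.
#' @param carbons carbon atoms per substrate molecule (>= 1).
#' @param components component table from [cdmComponents()].
#' @param overrides optional bound overrides passed through.
#' @return a [SimulationCondition].
#' @export
buildCDM <- function(substrate, carbons, components = cdmComponents(),
                     overrides = list()) {
  if (carbons < 1) stop("carbons must be >= 1")
  free <- components$exchange_id[components$class == "free"]
  fixed <- setdiff(components$exchange_id, c(free, substrate))
  med <- stats::setNames(rep(1, length(fixed)), fixed)
  med[substrate] <- CMOL_FLUX / carbons
  simulationCondition(medium = med, unconstrained = free,
                      overrides = overrides)
}

#' Simplified medium for ATP-yield and catabolic-capacity tests
#'
#' Amino acids, vitamins and minerals are removed — they are not needed
#' for carbon catabolism, and a sulfur or nitrogen source would let
#' biosynthetic proton sinks couple to the ATPase and distort the yield.
#' Only the substrate, base components and the free set (water, protons)
#' remain.
#'
#' @inheritParams buildCDM
#' @param uptake substrate uptake bound; default 1 mmol/gDW/h as used for
#'   per-mol yield accounting.
#' @return a [SimulationCondition].
#' @export
buildSimplifiedMedium <- function(substrate, components = cdmComponents(),
                                  uptake = 1, overrides = list()) {
  free <- components$exchange_id[components$class == "free"]
  keep <- setdiff(components$exchange_id[components$class == "base"],
                  substrate)
  med <- stats::setNames(rep(1, length(keep)), keep)
  med[substrate] <- uptake
  simulationCondition(medium = med, unconstrained = free,
                      overrides = overrides)
}

#' Homolactate override: cap pyruvate-formate lyase
#'
#' Under anaerobic conditions the homolactic/mixed-acid shift is governed
#' by PFL; capping its flux at 0.1 mmol/gDW/h forces lactate to become the
#' main product while leaving a trickle of acetyl-CoA for anabolism.
#'
#' @param cap upper bound on PFL flux.
#' @param pfl PFL reaction id.
#' @param closePDH also close pyruvate dehydrogenase (used for strict
#'   2-ATP-per-glucose homolactate accounting).
#' @param pdh PDH reaction id.
#' @return named override list for [simulationCondition()].
#' @export
homolactateOverrides <- function(cap = 0.1, pfl = "PFL", closePDH = FALSE,
                                 pdh = "PDH") {
  ov <- list(c(0, cap))
  names(ov) <- pfl
  if (closePDH) ov[[pdh]] <- c(0, 0)
  ov
}

#' Fermentation profile of one strain under one condition
#'
#' Runs pFBA and reports secreted products (positive exchange fluxes above
#' tolerance, excluding water and protons), split into main products and
#' byproducts.
#'
#' @param model a [GEM].
#' @param cond a [SimulationCondition].
#' @param mainProducts base metabolite ids counted as main fermentation
#'   products.
#' @return list with `growth_rate`, `secretion` (named numeric over
#'   exchange ids), `main_products`, `byproducts`, `growing`.
#' @export
fermentationProfile <- function(model, cond, mainProducts = MAIN_PRODUCTS) {
  sol <- solvePFBA(model, cond)
  if (sol@status != "optimal") {
    return(list(growth_rate = 0, secretion = numeric(),
                main_products = character(), byproducts = character(),
                growing = FALSE))
  }
  ex <- names(which(isExchange(model)))
  f <- sol@fluxes[ex]
  mets <- vapply(ex, function(r) names(reactionStoich(model, r)), character(1))
  base <- baseMetaboliteId(mets)
  sec <- f[f > FLUX_TOL & !(base %in% c("h", "h2o"))]
  secBase <- base[match(names(sec), ex)]
  list(growth_rate = sol@objectiveValue,
       secretion = sec,
       main_products = idSort(unique(secBase[secBase %in% mainProducts])),
       byproducts = idSort(unique(secBase[!(secBase %in% mainProducts)])),
       growing = sol@objectiveValue > FLUX_TOL)
}

#' Scan growth and product formation over PFL upper bounds
#'
#' @param model a [GEM].
#' @param cond a [SimulationCondition].
#' @param grid PFL upper bounds; default 25 log-spaced points over
#'   0.1 - 60 mmol/gDW/h.
#' @param pfl PFL reaction id.
#' @param productExchanges exchange ids reported per grid point.
#' @return data.frame: bound, growth_rate, one column per product exchange.
#' @export
pflScan <- function(model, cond,
                    grid = exp(seq(log(0.1), log(60), length.out = 25)),
                    pfl = "PFL",
                    productExchanges = c("EX_lac__D_e", "EX_for_e",
                                         "EX_ac_e", "EX_etoh_e")) {
  if (!(pfl %in% model@reactions$id)) stop("PFL reaction absent: ", pfl)
  rows <- lapply(grid, function(b) {
    cd <- cond
    cd@overrides[[pfl]] <- c(0, b)
    sol <- solvePFBA(model, cd)
    fl <- stats::setNames(rep(NA_real_, length(productExchanges)),
                          productExchanges)
    g <- 0
    if (sol@status == "optimal") {
      g <- sol@objectiveValue
      hit <- intersect(productExchanges, names(sol@fluxes))
      fl[hit] <- sol@fluxes[hit]
    }
    c(bound = b, growth_rate = g, fl)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Leave-one-out nutrient essentiality
#'
#' For each component, both bounds of its exchange are set to zero and
#' relative growth (vs the full medium) recorded; a component is essential
#' when relative growth drops below 10%. A component whose exchange the
#' model lacks cannot be taken up at all, so its relative growth is 1 by
#' definition (no phantom essentiality).
#'
#' @param model a [GEM].
#' @param cond a [SimulationCondition] (the full medium).
#' @param components exchange ids to test; defaults to the whole medium.
#' @return data.frame: component, relative_growth, essential.
#' @export
essentialityScan <- function(model, cond, components = names(cond@medium)) {
  ref <- solvePFBA(model, cond)
  if (ref@status != "optimal" || ref@objectiveValue <= FLUX_TOL) {
    stop("reference condition does not support growth")
  }
  rel <- vapply(components, function(comp) {
    if (!(comp %in% model@reactions$id)) return(1)
    cd <- cond
    cd@medium <- cd@medium[names(cd@medium) != comp]
    cd@unconstrained <- setdiff(cd@unconstrained, comp)
    cd@overrides[[comp]] <- c(0, 0)
    sol <- solveFBA(model, cd)
    if (sol@status != "optimal") 0 else sol@objectiveValue / ref@objectiveValue
  }, numeric(1))
  data.frame(component = components, relative_growth = unname(rel),
             essential = unname(rel) < 0.10, stringsAsFactors = FALSE)
}

#' Default casein amino-acid composition
#'
#' Packaged table with columns `amino_acid` (cytosolic metabolite base id)
#' and `fraction`. Cysteine's fraction is 0.003 — an order of magnitude
#' below its share of the biomass amino-acid composition, which is what
#' limits growth on casein for cysteine auxotrophs.
#'
#' @param path optional TSV overriding the packaged table.
#' @return data.frame.
#' @export
caseinComposition <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "casein_composition.tsv",
                        package = "strainforge")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a casein-peptide specification
#'
#' The peptide is normalized so 1 mol peptide corresponds to 1 mol of
#' amino-acid residues; the uptake bound should therefore equal the total
#' free-amino-acid supply of the CDM it replaces (residue-supply parity,
#' leaving composition skew as the only difference).
#'
#' @param composition data.frame from [caseinComposition()].
#' @param uptake_bound peptide uptake bound (mmol/gDW/h).
#' @return list with `fractions`, `uptake_bound`.
#' @export
caseinSpec <- function(composition = caseinComposition(), uptake_bound = 4) {
  fr <- stats::setNames(composition$fraction, composition$amino_acid)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("casein fractions must be >= 0 and sum to 1")
  }
  list(fractions = fr, uptake_bound = uptake_bound)
}

#' Attach casein-peptide machinery to a model
#'
#' Adds the extracellular and cytosolic casein-peptide species, an
#' exchange, an uptake transport, and an intracellular hydrolysis reaction
#' cleaving 1 peptide (+ water) into amino acids in the spec's fractions.
#' The recorded reaction ids are returned in the `casein_ids` attribute so
#' [detachCasein()] can restore the original model.
#'
#' @param model a [GEM].
#' @param spec a [caseinSpec()].
#' @return the extended model (attribute `casein_ids`).
#' @export
attachCasein <- function(model, spec) {
  aaC <- paste0(names(spec$fractions), "_c")
  missing <- setdiff(aaC, model@metabolites$id)
  if (length(missing)) {
    stop("amino acid(s) absent from model: ", paste(missing, collapse = ", "))
  }
  addedMets <- character()
  for (mid in c("cas_e", "cas_c")) {
    if (!(mid %in% model@metabolites$id)) {
      df <- data.frame(id = mid, name = "Casein peptide (synthetic average)",
                       compartment = compartmentOf(mid),
                       formula = NA_character_, charge = 0L,
                       stringsAsFactors = FALSE)
      model <- addMetabolites(model, df)
      addedMets <- c(addedMets, mid)
    }
  }
  added <- character()
  if (!("EX_cas_e" %in% model@reactions$id)) {
    model <- addReaction(model, "EX_cas_e", c(cas_e = -1),
                         name = "Casein peptide exchange",
                         lb = 0, ub = UNCONSTRAINED_BOUND,
                         flags = "exempt_from_balance")
    added <- c(added, "EX_cas_e")
  }
  hyd <- c(cas_c = -1, h2o_c = -1)
  hyd[aaC] <- unname(spec$fractions)
  model <- addReaction(model, "CASt", c(cas_e = -1, cas_c = 1),
                       name = "Casein peptide uptake", lb = 0,
                       ub = spec$uptake_bound)
  model <- addReaction(model, "CASH", hyd,
                       name = "Casein peptide hydrolysis", lb = 0,
                       ub = UNCONSTRAINED_BOUND)
  added <- c(added, "CASt", "CASH")
  attr(model, "casein_ids") <- added
  attr(model, "casein_mets") <- addedMets
  model
}

#' Remove casein machinery added by [attachCasein()]
#' @param model a model carrying the `casein_ids` attribute.
#' @return the restored model.
#' @export
detachCasein <- function(model) {
  ids <- attr(model, "casein_ids")
  if (is.null(ids)) stop("model has no attached casein machinery")
  mets <- attr(model, "casein_mets")
  model <- removeReactions(model, ids)
  if (length(mets)) {
    keep <- !(model@metabolites$id %in% mets)
    model@metabolites <- model@metabolites[keep, , drop = FALSE]
    rownames(model@metabolites) <- NULL
    model@stoichiometry <- model@stoichiometry[keep, , drop = FALSE]
  }
  attr(model, "casein_ids") <- NULL
  attr(model, "casein_mets") <- NULL
  model
}

#' Milk-like condition: casein replaces free amino acids
#'
#' @param substrate carbon-source exchange id (lactose for milk).
#' @param carbons carbon atoms of the substrate.
#' @param components CDM component table.
#' @param caseinUptake peptide uptake bound; defaults to the number of
#'   amino-acid components (residue-supply parity with the CDM).
#' @param extra named numeric of additional medium components (e.g. free
#'   cysteine supplementation).
#' @return a [SimulationCondition].
#' @export
buildMilkCDM <- function(substrate, carbons, components = cdmComponents(),
                         caseinUptake = NULL, extra = numeric()) {
  aa <- components$exchange_id[components$class == "amino_acid"]
  if (is.null(caseinUptake)) caseinUptake <- length(aa)
  keep <- components[!(components$exchange_id %in% aa), , drop = FALSE]
  cond <- buildCDM(substrate, carbons, keep)
  cond@medium["EX_cas_e"] <- caseinUptake
  if (length(extra)) cond@medium[names(extra)] <- extra
  cond
}

#' Can a strain extract ATP from a nutrient?
#'
#' Minimal medium (minerals + base + free set) plus the nutrient at
#' 1 mmol/gDW/h; the ATP-maintenance flux is maximized. The strain is
#' capable iff the optimum and the nutrient uptake both exceed tolerance.
#' A missing exchange reaction is itself incapacity (no transporter).
#'
#' @param model a [GEM].
#' @param nutrientExchange exchange id of the nutrient.
#' @param components CDM component table (for the mineral/base backbone).
#' @param atpm ATP maintenance reaction id.
#' @return list with `capable` and `atp_flux`.
#' @export
catabolicCapacity <- function(model, nutrientExchange,
                              components = cdmComponents(), atpm = "ATPM") {
  if (!(nutrientExchange %in% model@reactions$id)) {
    return(list(capable = FALSE, atp_flux = 0))
  }
  cond <- buildSimplifiedMedium(nutrientExchange, components, uptake = 1)
  if (!(atpm %in% model@reactions$id)) {
    model <- addReaction(model, atpm,
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      name = "ATP maintenance", lb = 0, ub = UNCONSTRAINED_BOUND)
  }
  cond@objectiveOverride <- atpm
  sol <- solvePFBA(model, cond)
  if (sol@status != "optimal") return(list(capable = FALSE, atp_flux = 0))
  uptake <- -sol@fluxes[[nutrientExchange]]
  list(capable = sol@objectiveValue > FLUX_TOL && uptake > FLUX_TOL,
       atp_flux = sol@objectiveValue)
}

#' Restrict a metabolite's uptake to a single transporter
#'
#' Closes (bounds 0,0) every transport reaction that moves the named
#' extracellular species except `keep`. Used e.g. to test whether strains
#' can still use maltose when only the maltose PTS is allowed.
#'
#' @param model a [GEM].
#' @param metabolite extracellular species id (e.g. `"malt_e"`).
#' @param keep transport reaction id to leave open.
#' @return the restricted model.
#' @export
restrictTransport <- function(model, metabolite, keep) {
  cls <- classifyReactions(model)
  movers <- names(cls)[cls == "transport" & vapply(names(cls), function(r) {
    metabolite %in% names(reactionStoich(model, r))
  }, logical(1))]
  if (!(keep %in% movers)) {
    stop("'", keep, "' is not a transport reaction moving ", metabolite)
  }
  for (r in setdiff(movers, keep)) model <- setBounds(model, r, 0, 0)
  model
}

#' Cross-feeding screen over a cohort
#'
#' For each strain and candidate product: the product's uptake is opened at
#' 1 mmol/gDW/h (raised to 2 when the product is already a medium
#' component) and growth re-solved; the strain consumes the product iff its
#' uptake flux is positive and growth increases. Production flags come from
#' the baseline fermentation profile.
#'
#' @param models named list of [GEM]s.
#' @param cond baseline [SimulationCondition].
#' @param products exchange ids of candidate cross-feeding metabolites.
#' @return data.frame: strain, product, produced, consumed, uptake_flux,
#'   growth_gain.
#' @export
crossfeedScreen <- function(models, cond, products) {
  if (is.null(names(models))) {
    names(models) <- vapply(models, modelId, character(1))
  }
  out <- list()
  for (s in names(models)) {
    mdl <- models[[s]]
    base <- fermentationProfile(mdl, cond)
    for (p in products) {
      produced <- p %in% names(base$secretion)
      if (!(p %in% mdl@reactions$id)) {
        out[[length(out) + 1L]] <- data.frame(
          strain = s, product = p, produced = produced, consumed = FALSE,
          uptake_flux = 0, growth_gain = 0, stringsAsFactors = FALSE)
        next
      }
      cd <- cond
      cd@medium[p] <- if (p %in% names(cond@medium)) 2 else 1
      sol <- solvePFBA(mdl, cd)
      uptake <- 0; gain <- 0
      if (sol@status == "optimal") {
        uptake <- -sol@fluxes[[p]]
        gain <- sol@objectiveValue - base$growth_rate
      }
      out[[length(out) + 1L]] <- data.frame(
        strain = s, product = p, produced = produced,
        consumed = uptake > FLUX_TOL && gain > FLUX_TOL,
        uptake_flux = uptake, growth_gain = gain, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
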