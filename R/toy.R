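## Deterministic toy-universe generator: a balanced ~110-reaction bacterial
## core network emulating the pathway alternatives that distinguish dairy
## lactococci (PTS vs permease sugar uptake, tagatose-6P vs Leloir
## galactose routes, xylose/ribose pentose routes, sulfate assimilation,
## arginine deiminase, citrate lyase), with derived strain variants,
## carving-score tables and manifests. It is the desk-scale substrate for
## every other module: small enough that ATP yields are hand-derivable
## (3 ATP per glucose for mixed-acid fermentation, 2 for homolactate), yet
## structured enough to exercise refinement, pan-curation, simulation and
## comparison end to end.

toyMetaboliteDefs <- function() {
  d <- function(base, formula, charge, name, chebi = NA_character_) {
    list(base = base, formula = formula, charge = charge, name = name,
         chebi = chebi)
  }
  list(
    d("glc__D", "C6H12O6", 0L, "D-Glucose", "CHEBI:17634"),
    d("gal", "C6H12O6", 0L, "D-Galactose", "CHEBI:28061"),
    d("lcts", "C12H22O11", 0L, "Lactose", "CHEBI:17716"),
    d("malt", "C12H22O11", 0L, "Maltose", "CHEBI:17306"),
    d("xyl__D", "C5H10O5", 0L, "D-Xylose", "CHEBI:65327"),
    d("rib__D", "C5H10O5", 0L, "D-Ribose", "CHEBI:47013"),
    d("cit", "C6H5O7", -3L, "Citrate", "CHEBI:16947"),
    d("arg__L", "C6H15N4O2", 1L, "L-Arginine", "CHEBI:32682"),
    d("orn", "C5H13N2O2", 1L, "Ornithine", "CHEBI:46911"),
    d("glu__L", "C5H8NO4", -1L, "L-Glutamate", "CHEBI:29985"),
    d("leu__L", "C6H13NO2", 0L, "L-Leucine", "CHEBI:57427"),
    d("cys__L", "C3H7NO2S", 0L, "L-Cysteine", "CHEBI:35235"),
    d("met__L", "C5H11NO2S", 0L, "L-Methionine", "CHEBI:57844"),
    d("so4", "O4S", -2L, "Sulfate", "CHEBI:16189"),
    d("nh4", "H4N", 1L, "Ammonium", "CHEBI:28938"),
    d("nh3", "H3N", 0L, "Ammonia", "CHEBI:16134"),
    d("pi", "HO4P", -2L, "Phosphate", "CHEBI:43474"),
    d("h", "H", 1L, "Proton", "CHEBI:24636"),
    d("h2o", "H2O", 0L, "Water", "CHEBI:15377"),
    d("co2", "CO2", 0L, "Carbon dioxide", "CHEBI:16526"),
    d("for", "CHO2", -1L, "Formate", "CHEBI:15740"),
    d("ac", "C2H3O2", -1L, "Acetate", "CHEBI:30089"),
    d("etoh", "C2H6O", 0L, "Ethanol", "CHEBI:16236"),
    d("lac__D", "C3H5O3", -1L, "D-Lactate", "CHEBI:16004"),
    d("cas", NA_character_, 0L, "Casein peptide (synthetic average)"),
    d("g6p", "C6H11O9P", -2L, "D-Glucose 6-phosphate"),
    d("fdp", "C6H10O12P2", -4L, "Fructose 1,6-bisphosphate"),
    d("dhap", "C3H5O6P", -2L, "Dihydroxyacetone phosphate"),
    d("g3p", "C3H5O6P", -2L, "Glyceraldehyde 3-phosphate"),
    d("pep", "C3H2O6P", -3L, "Phosphoenolpyruvate"),
    d("pyr", "C3H3O3", -1L, "Pyruvate"),
    d("accoa", "C23H34N7O17P3S", -4L, "Acetyl-CoA"),
    d("coa", "C21H32N7O16P3S", -4L, "Coenzyme A"),
    d("nad", "C21H26N7O14P2", -1L, "NAD+"),
    d("nadh", "C21H27N7O14P2", -2L, "NADH"),
    d("atp", "C10H12N5O13P3", -4L, "ATP", "CHEBI:30616"),
    d("adp", "C10H12N5O10P2", -3L, "ADP"),
    d("actp", "C2H3O5P", -2L, "Acetyl phosphate"),
    d("gal6p", "C6H11O9P", -2L, "D-Galactose 6-phosphate"),
    d("lac6p", "C12H21O14P", -2L, "Lactose 6-phosphate"),
    d("malt6p", "C12H21O14P", -2L, "Maltose 6-phosphate"),
    d("xylu__D", "C5H10O5", 0L, "D-Xylulose"),
    d("xu5p__D", "C5H9O8P", -2L, "D-Xylulose 5-phosphate"),
    d("r5p", "C5H9O8P", -2L, "Ribose 5-phosphate"),
    d("h2s", "H2S", 0L, "Hydrogen sulfide"),
    d("glyc1", "C6H11O9P", -2L, "Storage intermediate (synthetic)"),
    d("glyc2", "C6H12O6", 0L, "Storage dead-end (synthetic)")
  )
}

## species present extracellularly (everything else is cytosol-only)
TOY_EXTRACELLULAR <- c("glc__D", "gal", "lcts", "malt", "xyl__D", "rib__D",
                       "cit", "arg__L", "orn", "glu__L", "leu__L", "cys__L",
                       "met__L", "so4", "nh4", "nh3", "pi", "h", "h2o",
                       "co2", "for", "ac", "etoh", "lac__D", "cas")
TOY_CYTOSOLIC <- c("glc__D", "gal", "lcts", "malt", "xyl__D", "rib__D",
                   "cit", "arg__L", "orn", "glu__L", "leu__L", "cys__L",
                   "met__L", "so4", "nh4", "nh3", "pi", "h", "h2o", "co2",
                   "for", "ac", "etoh", "lac__D", "g6p", "fdp", "dhap",
                   "g3p", "pep", "pyr", "accoa", "coa", "nad", "nadh",
                   "atp", "adp", "actp", "gal6p", "lac6p", "malt6p",
                   "xylu__D", "xu5p__D", "r5p", "h2s", "glyc1", "glyc2")

#' Pathway-profile flags of the toy universe
#' @return character vector of the profile booleans accepted by
#'   [deriveStrain()].
#' @export
toyPathwayFlags <- function() {
  c("tag6p", "leloir", "lactose_pts", "lactose_permease", "maltose_pts",
    "maltose_abc", "xylulokinase", "phosphoketolase", "sulfate_assimilation",
    "leucine_synthesis", "arginine_deiminase", "citrate_lyase")
}

## id, equation, gpr, group ("core" or a pathway flag), rev implied by eq
toyReactionDefs <- function() {
  r <- function(id, eq, gpr = "", group = "core", name = id) {
    list(id = id, eq = eq, gpr = gpr, group = group, name = name)
  }
  list(
    ## -- transport, core
    r("GLCpts", "glc__D_e + pep_c -> g6p_c + pyr_c", "gPTS1 and gPTS2",
      name = "Glucose PTS"),
    r("XYLt", "xyl__D_e + h_e -> xyl__D_c + h_c", "gXYLT", "xylulokinase"),
    r("RIBt", "rib__D_e + h_e -> rib__D_c + h_c", "gRIBT"),
    r("CITt", "cit_e + h_e -> cit_c + h_c", "gCITP"),
    r("GLUt", "glu__L_e <-> glu__L_c", "gGLUP"),
    r("LEUt", "leu__L_e <-> leu__L_c", "gLEUP"),
    r("CYSt", "cys__L_e -> cys__L_c", "gCYSP"),
    r("METt", "met__L_e <-> met__L_c", "gMETP"),
    r("NH4t", "nh4_e <-> nh4_c", "gNH4T"),
    r("NH3t", "nh3_e <-> nh3_c"),
    r("SO4t", "so4_e <-> so4_c", "gSO4T"),
    r("PIt", "pi_e <-> pi_c", "gPIT"),
    r("H2Ot", "h2o_e <-> h2o_c"),
    r("CO2t", "co2_e <-> co2_c"),
    r("ETOHt", "etoh_e <-> etoh_c"),
    r("FORt", "for_c + h_c <-> for_e + h_e", "gFORT"),
    r("ACt", "ac_c + h_c <-> ac_e + h_e", "gACT"),
    r("LACt", "lac__D_c + h_c <-> lac__D_e + h_e", "gLACT"),
    r("ATPS4r", "adp_c + pi_c + 4 h_e <-> atp_c + 3 h_c + h2o_c",
      "gATP1 and gATP2", name = "F1F0 ATP synthase"),
    ## -- transport, pathway-gated
    r("GALt", "gal_e + h_e -> gal_c + h_c", "gGALP", "leloir"),
    r("GALpts", "gal_e + pep_c -> gal6p_c + pyr_c", "gGALPTS", "tag6p"),
    r("LCTSt", "lcts_e + h_e -> lcts_c + h_c", "gLACP", "lactose_permease"),
    r("LCTSpts", "lcts_e + pep_c -> lac6p_c + pyr_c",
      "gLACPTS1 and gLACPTS2", "lactose_pts"),
    r("MALTpts", "malt_e + pep_c -> malt6p_c + pyr_c", "gMALPTS",
      "maltose_pts", name = "Maltose PTS"),
    r("MALTabc", "malt_e + atp_c + h2o_c -> malt_c + adp_c + pi_c + h_c",
      "gMALE and gMALF and gMALG", "maltose_abc"),
    r("ARGORNt", "arg__L_e + orn_c -> arg__L_c + orn_e", "gARCD",
      "arginine_deiminase"),
    ## -- metabolism, core (glycolysis lumps and fermentation branches)
    r("PFK", "g6p_c + atp_c -> fdp_c + adp_c + h_c", "gPFK",
      name = "Phosphofructokinase (PGI lumped)"),
    r("FBA", "fdp_c <-> dhap_c + g3p_c", "gFBA"),
    r("TPI", "dhap_c <-> g3p_c", "gTPI"),
    r("GAPD_L",
      "g3p_c + pi_c + nad_c + adp_c -> pep_c + atp_c + nadh_c + h2o_c + h_c",
      "gGAPD", name = "Lower glycolysis lump (GAPD..ENO)"),
    r("PYK", "pep_c + adp_c + h_c -> pyr_c + atp_c", "gPYK"),
    r("LDH_D", "pyr_c + nadh_c + h_c -> lac__D_c + nad_c",
      "gLDH1 or gLDH2", name = "D-Lactate dehydrogenase"),
    r("PFL", "pyr_c + coa_c -> accoa_c + for_c", "gPFL and gPFLA",
      name = "Pyruvate formate lyase"),
    r("PDH", "pyr_c + coa_c + nad_c -> accoa_c + co2_c + nadh_c",
      "gPDHA and gPDHB and gPDHC", name = "Pyruvate dehydrogenase"),
    r("PTAACK", "accoa_c + adp_c + pi_c -> ac_c + atp_c + coa_c",
      "gPTA and gACK", name = "Phosphotransacetylase/acetate kinase lump"),
    r("ALCD_L", "accoa_c + 2 nadh_c + 2 h_c -> etoh_c + 2 nad_c + coa_c",
      "gADHE", name = "Ethanol branch lump"),
    r("ATPM", "atp_c + h2o_c -> adp_c + pi_c + h_c",
      name = "ATP maintenance"),
    r("GLK", "glc__D_c + atp_c -> g6p_c + adp_c + h_c", "gGLK"),
    r("XYLI", "xyl__D_c <-> xylu__D_c", "gXYLA", "xylulokinase"),
    r("RBK", "rib__D_c + atp_c -> r5p_c + adp_c + h_c", "gRBK"),
    r("RIBBYP_L", "r5p_c -> g3p_c + ac_c + h_c",
      "gNUC1 and gNUC2 and gNUC3",
      name = "Nucleotide-loop ribose bypass lump"),
    r("CYSS_L", "pyr_c + nh4_c + h2s_c -> cys__L_c + h2o_c", "gCYSK",
      name = "Cysteine-from-serine route lump"),
    r("GLY1", "g6p_c -> glyc1_c", "gGLY1",
      name = "Storage pathway step 1 (dead end, synthetic)"),
    r("GLY2", "glyc1_c + h2o_c -> glyc2_c + pi_c", "gGLY2",
      name = "Storage pathway step 2 (dead end, synthetic)"),
    ## -- metabolism, pathway-gated
    r("GALK_L", "gal_c + 2 atp_c + h2o_c -> g6p_c + 2 adp_c + pi_c + 2 h_c",
      "gGALK and gGALT", "leloir", name = "Leloir route lump (costed)"),
    r("TAG6P_L", "gal6p_c + atp_c -> fdp_c + adp_c + h_c",
      "gLACC and gLACD", "tag6p", name = "Tagatose-6P route lump"),
    r("LAC6PH", "lac6p_c + h2o_c -> glc__D_c + gal6p_c", "gPBGAL",
      "lactose_pts", name = "Phospho-beta-galactosidase"),
    r("LACZ", "lcts_c + h2o_c -> glc__D_c + gal_c", "gBGAL",
      "lactose_permease", name = "Beta-galactosidase"),
    r("MALT6PH", "malt6p_c + h2o_c -> glc__D_c + g6p_c", "gMAPH",
      "maltose_pts"),
    r("MALTH", "malt_c + h2o_c -> 2 glc__D_c", "gMALH", "maltose_abc"),
    r("XYLK", "xylu__D_c + atp_c -> xu5p__D_c + adp_c + h_c", "gXYLB",
      "xylulokinase", name = "Xylulokinase"),
    r("PKETX", "xu5p__D_c + pi_c -> g3p_c + actp_c + h2o_c", "gXPK",
      "phosphoketolase", name = "Phosphoketolase"),
    r("RPE_L", "r5p_c <-> xu5p__D_c", "gRPI and gRPE", "phosphoketolase",
      name = "Pentose isomerase/epimerase lump"),
    r("ACKr", "actp_c + adp_c -> ac_c + atp_c", "gACK2", "phosphoketolase",
      name = "Acetate kinase (acetyl-P)"),
    r("SULFAS_L",
      "so4_c + atp_c + 4 nadh_c + 5 h_c -> h2s_c + 3 h2o_c + 4 nad_c + adp_c + pi_c",
      "gCYSDN and gCYSH", "sulfate_assimilation",
      name = "Sulfate assimilation lump"),
    r("LEUS_L",
      "2 pyr_c + accoa_c + nadh_c + nh4_c + 2 h_c -> leu__L_c + 2 co2_c + coa_c + nad_c + h2o_c",
      "gLEUA and gLEUB and gLEUCD", "leucine_synthesis",
      name = "Leucine biosynthesis lump"),
    r("ADI_L",
      "arg__L_c + h2o_c + h_c + adp_c + pi_c -> orn_c + 2 nh3_c + co2_c + atp_c",
      "gARCA and gARCB and gARCC", "arginine_deiminase",
      name = "Arginine deiminase pathway lump"),
    r("CITL_L", "cit_c + h_c -> ac_c + pyr_c + co2_c", "gCITDEF",
      "citrate_lyase",
      name = "Citrate lyase + oxaloacetate decarboxylase lump")
  )
}

TOY_BIOMASS_AA <- c(glu__L = 0.5, leu__L = 0.3, met__L = 0.15, cys__L = 0.05)
TOY_GAM <- 60  # growth-associated ATP hydrolysis, mmol/gDW

#' The strain-specific (Lactococcus-style) biomass specification
#'
#' Four amino acids in experimentally-motivated proportions (cysteine 5% of
#' the amino-acid composition) plus growth-associated ATP hydrolysis.
#'
#' @return list with `id` and `stoich` for [installBiomass()].
#' @export
toyBiomassSpec <- function() {
  st <- c(-TOY_BIOMASS_AA, atp = -TOY_GAM, h2o = -TOY_GAM,
          adp = TOY_GAM, pi = TOY_GAM, h = TOY_GAM)
  names(st) <- paste0(names(c(TOY_BIOMASS_AA,
                              atp = 1, h2o = 1, adp = 1, pi = 1, h = 1)), "_c")
  list(id = "BIOMASS_LACTO", stoich = st)
}

## generic database biomass carried by the universal model: same backbone
## plus a sulfate precursor that the species-specific spec omits
toyUniversalBiomass <- function() {
  spec <- toyBiomassSpec()
  spec$id <- "BIOMASS_UNIV"
  spec$stoich <- c(spec$stoich, so4_c = -0.01)
  spec
}

## Add protons to close a pure protonation/charge gap; error on any other
## elemental imbalance (the fixture must be constructed balanced).
balanceProtons <- function(model, rid) {
  be <- checkReactionBalance(model, rid)
  if (be$classification %in% c("balanced", "exempt", "unknown_formula")) {
    return(model)
  }
  if (be$classification == "proton_imbalanced") {
    S <- model@stoichiometry
    S["h_c", rid] <- S["h_c", rid] - be$element_delta[["H"]]
    model@stoichiometry <- methods::as(Matrix::drop0(S), "CsparseMatrix")
    return(model)
  }
  stop("toy reaction '", rid, "' is not balanceable: ",
       be$classification, " (",
       paste(sprintf("%s:%+g", names(be$element_delta), be$element_delta),
             collapse = ", "), ", charge ", be$charge_delta, ")")
}

#' Build the toy universal reaction-database model
#'
#' A balanced anaerobic core network (all non-exempt reactions pass
#' [auditBalance()]) with PTS glucose uptake, lumped glycolysis, the
#' LDH/PFL/PDH pyruvate branches, acetate and ethanol branches, both
#' galactose routes, both lactose and maltose routes, xylose/ribose
#' pentose routes with a deliberately low-yield nucleotide-loop bypass,
#' sulfate assimilation, a two-step synthetic dead-end storage pathway and
#' a generic biomass. Optional injections provide known curation targets.
#'
#' @param injectDuplicates inject three duplicate reactions and two
#'   duplicate metabolites (with carrier reactions), recorded in the
#'   manifest.
#' @param seed recorded in the manifest (generation itself is
#'   deterministic).
#' @return list with `model` (a [GEM]) and `manifest`.
#' @export
buildToyUniversal <- function(injectDuplicates = FALSE, seed = 0L) {
  defs <- toyMetaboliteDefs()
  bases <- vapply(defs, `[[`, character(1), "base")
  mkRows <- function(whichBases, comp) {
    idx <- match(whichBases, bases)
    df <- data.frame(
      id = paste0(whichBases, "_", comp),
      name = vapply(defs[idx], `[[`, character(1), "name"),
      compartment = comp,
      formula = vapply(defs[idx], `[[`, character(1), "formula"),
      charge = vapply(defs[idx], function(d) as.integer(d$charge),
                      integer(1)),
      stringsAsFactors = FALSE)
    df$annotations <- lapply(defs[idx], function(d) {
      if (is.na(d$chebi)) list() else list(chebi = d$chebi)
    })
    df
  }
  met <- rbind(mkRows(TOY_EXTRACELLULAR, "e"), mkRows(TOY_CYTOSOLIC, "c"))

  rxn <- emptyReactionFrame()
  model <- newGEM("toy_universal", met, rxn,
                  matrix(0, nrow(met), 0), objective = "")

  groups <- character()
  for (ex in TOY_EXTRACELLULAR) {
    rid <- paste0("EX_", ex, "_e")
    st <- stats::setNames(-1, paste0(ex, "_e"))
    model <- addReaction(model, rid, st, name = paste0(ex, " exchange"),
                         lb = 0, ub = 1000, flags = "exempt_from_balance")
    groups[rid] <- "exchange"
  }
  for (d in toyReactionDefs()) {
    pr <- parseReactionString(d$eq)
    model <- addReaction(model, d$id, pr$stoich, name = d$name,
                         lb = if (pr$reversible) -1000 else 0, ub = 1000,
                         gpr = d$gpr)
    model <- balanceProtons(model, d$id)
    groups[d$id] <- d$group
  }
  bm <- toyUniversalBiomass()
  model <- installBiomass(model, bm)
  groups[bm$id] <- "biomass"

  manifest <- list(
    seed = seed,
    groups = groups,
    pathway_flags = toyPathwayFlags(),
    biomass = bm$id,
    injected = list(duplicate_reactions = character(),
                    duplicate_metabolites = character(),
                    duplicate_carriers = character())
  )

  if (injectDuplicates) {
    dupMet <- data.frame(
      id = c("glcdup_c", "lacdup_c"),
      name = c("D-Glucose", "D-Lactate"),
      compartment = "c",
      formula = c("C6H12O6", "C3H5O3"),
      charge = c(0L, -1L), stringsAsFactors = FALSE)
    dupMet$annotations <- list(list(chebi = "CHEBI:17634"),
                               list(chebi = "CHEBI:16004"))
    model <- addMetabolites(model, dupMet)
    model <- addReaction(model, "LDH_D_dup",
      reactionStoich(model, "LDH_D"), gpr = "gLDH3",
      name = "D-Lactate dehydrogenase (duplicate entry)")
    model <- addReaction(model, "TPI_rev",
      -reactionStoich(model, "TPI"), lb = -1000, gpr = "gTPI2",
      name = "Triose isomerase (sign-flipped duplicate)")
    model <- addReaction(model, "ACKr_dup",
      reactionStoich(model, "ACKr"), gpr = "gACK3",
      name = "Acetate kinase (duplicate entry)")
    model <- addReaction(model, "GLK_alt",
      c(glcdup_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
      gpr = "gGLK2", name = "Glucokinase (duplicate-metabolite carrier)")
    model <- addReaction(model, "LDH_alt",
      c(pyr_c = -1, nadh_c = -1, h_c = -1, lacdup_c = 1, nad_c = 1),
      gpr = "gLDH4",
      name = "Lactate dehydrogenase (duplicate-metabolite carrier)")
    manifest$injected$duplicate_reactions <-
      c("LDH_D_dup", "TPI_rev", "ACKr_dup")
    manifest$injected$duplicate_metabolites <- c("glcdup_c", "lacdup_c")
    manifest$injected$duplicate_carriers <- c("GLK_alt", "LDH_alt")
  }
  list(model = model, manifest = manifest)
}

#' Default pathway profile (everything present)
#' @return named logical vector over [toyPathwayFlags()].
#' @export
fullProfile <- function() {
  stats::setNames(rep(TRUE, length(toyPathwayFlags())), toyPathwayFlags())
}

injectedGapfillDefs <- function() {
  list(
    list(id = "FBP_gf", eq = "fdp_c + h2o_c -> g6p_c + pi_c",
         kind = "metabolic",
         mets = NULL),
    list(id = "XYLUR_gf", eq = "xylu__D_c + nadh_c + h_c -> xylt_c + nad_c",
         kind = "metabolic",
         mets = data.frame(id = "xylt_c", name = "Xylitol", compartment = "c",
                           formula = "C5H12O5", charge = 0L,
                           stringsAsFactors = FALSE)),
    list(id = "ACTPH_gf", eq = "actp_c + h2o_c -> ac_c + pi_c + h_c",
         kind = "metabolic", mets = NULL),
    list(id = "PYRt_gf", eq = "pyr_e + h_e -> pyr_c + h_c",
         kind = "transport_kept",
         mets = data.frame(id = "pyr_e", name = "Pyruvate",
                           compartment = "e", formula = "C3H3O3",
                           charge = -1L, stringsAsFactors = FALSE)),
    list(id = "EX_dxyl_e", eq = "dxyl_e ->", kind = "exchange",
         mets = data.frame(id = "dxyl_e", name = "Deoxypentose (synthetic)",
                           compartment = "e", formula = "C5H10O4",
                           charge = 0L, stringsAsFactors = FALSE))
  )
}

egcVariantDefs <- function() {
  list(
    list(id = "LACtv", eq = "lac__D_e <-> lac__D_c", gpr = "gLACT2",
         variant_of = "LACt"),
    list(id = "ACtv", eq = "ac_e <-> ac_c", gpr = "gACT2",
         variant_of = "ACt")
  )
}

#' Derive a draft strain model from the toy universal
#'
#' Stands in for a carving run: reactions whose pathway flag is off are
#' removed (with their genes), a configurable set of gene-evidenced
#' dead-end reactions is withheld (exercising restoration), gene-less
#' gap-filled reactions are injected (exercising pruning), and a carving
#' score table is emitted with positive scores exactly for the GPR-bearing
#' reactions whose genes the strain kept (including withheld ones).
#'
#' @param universal the clean toy universal [GEM].
#' @param profile named logical over [toyPathwayFlags()].
#' @param id strain id.
#' @param seed integer seed for the score values.
#' @param groups reaction -> group map from the universal manifest.
#' @param withhold reaction ids withheld from the draft despite gene
#'   evidence.
#' @param injectGapfill inject the standard gap-filled reaction set.
#' @param egcVariants inject proton-stoichiometry transport-variant pairs
#'   (energy-generating-cycle seeds).
#' @return list with `model`, `scores`, `manifest`.
#' @export
deriveStrain <- function(universal, profile, id, seed, groups,
                         withhold = c("GLY1", "GLY2"),
                         injectGapfill = TRUE, egcVariants = FALSE) {
  unknown <- setdiff(names(profile), toyPathwayFlags())
  if (length(unknown)) {
    stop("unknown profile key(s): ", paste(unknown, collapse = ", "))
  }
  off <- names(profile)[!profile]
  dropRxns <- names(groups)[groups %in% off]
  ## strains never inherit the casein exchange; attachCasein() adds milk
  ## machinery explicitly
  dropRxns <- c(dropRxns, "EX_cas_e", withhold)
  model <- removeReactions(universal, intersect(dropRxns,
                                                universal@reactions$id),
                           dropOrphans = TRUE)
  model@id <- id
  model@genes <- idSort(unique(unlist(lapply(model@reactions$gpr, gprGenes),
                                    use.names = FALSE)))

  if (injectGapfill) {
    for (g in injectedGapfillDefs()) {
      if (!is.null(g$mets)) {
        new <- g$mets[!(g$mets$id %in% model@metabolites$id), , drop = FALSE]
        if (nrow(new)) model <- addMetabolites(model, new)
      }
      pr <- parseReactionString(g$eq)
      ## pathway removal may have orphaned a participant; copy it back in
      fromUni <- setdiff(names(pr$stoich), model@metabolites$id)
      if (length(fromUni)) {
        ui <- match(fromUni, universal@metabolites$id)
        model <- addMetabolites(model,
                                universal@metabolites[ui, , drop = FALSE])
      }
      model <- addReaction(model, g$id, pr$stoich,
                           lb = if (pr$reversible) -1000 else 0, ub = 1000,
                           flags = c("gap_filled",
                                     if (g$kind == "exchange")
                                       "exempt_from_balance"))
    }
  }
  if (egcVariants) {
    for (v in egcVariantDefs()) {
      pr <- parseReactionString(v$eq)
      model <- addReaction(model, v$id, pr$stoich, lb = -1000, ub = 1000,
                           gpr = v$gpr,
                           name = paste0(v$variant_of, " variant"))
      model@genes <- idSort(union(model@genes, gprGenes(v$gpr)))
    }
  }

  withSeed(seed, {
    scored <- model@reactions$id[nzchar(model@reactions$gpr)]
    scored <- setdiff(scored, vapply(egcVariantDefs(), `[[`, character(1),
                                     "id"))
    scored <- idSort(unique(c(scored, withhold)))
    scores <- stats::setNames(round(stats::runif(length(scored), 0.5, 5), 3),
                              scored)
  })

  manifest <- list(
    id = id, seed = seed, profile = profile,
    withheld = withhold,
    injected_gapfill = if (injectGapfill) {
      vapply(injectedGapfillDefs(), `[[`, character(1), "id")
    } else character(),
    injected_gapfill_pruned = if (injectGapfill) {
      c("FBP_gf", "XYLUR_gf", "ACTPH_gf")
    } else character(),
    egc_variants = if (egcVariants) {
      vapply(egcVariantDefs(), `[[`, character(1), "id")
    } else character()
  )
  list(model = model, scores = scores, manifest = manifest)
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' Species-stratified pathway probabilities
#'
#' The generator's study conditions: probabilities chosen so the cohort
#' reproduces the hallmark fractions of a dairy Lactococcus panel —
#' xylose/ribose pentose capability confined to the "lactis-like" class,
#' maltose-PTS absence confined to a fraction of "cremoris-like" strains
#' (about 10% cohort-wide), sulfate assimilation in about 11% of strains
#' (cysteine auxotrophy in the rest), leucine biosynthesis in 5%, arginine
#' deiminase missing in about 4%, citrate lyase in 14%.
#'
#' @return list with one named probability vector per species class.
#' @export
defaultCohortProbabilities <- function() {
  ## The tagatose-6P/lactose-PTS system is plasmid-borne and associated
  ## with the dairy ("cremoris-like") class; Leloir/permease is the
  ## chromosomal default. Together with the pentose block this gives the
  ## two-cluster reaction-content structure of the cohort.
  lactis <- c(tag6p = 0.15, leloir = 0.95, lactose_pts = 0.95,
              lactose_permease = 0.95, maltose_pts = 1.0, maltose_abc = 1.0,
              xylulokinase = 1.0, phosphoketolase = 1.0,
              sulfate_assimilation = 0.07, leucine_synthesis = 0.05,
              arginine_deiminase = 0.987, citrate_lyase = 0.14)
  cremoris <- lactis
  cremoris["tag6p"] <- 0.92
  cremoris[c("xylulokinase", "phosphoketolase")] <- 0
  cremoris["maltose_pts"] <- 0.8
  cremoris["sulfate_assimilation"] <- 0.15
  cremoris["arginine_deiminase"] <- 0.935
  list(lactis = lactis, cremoris = cremoris)
}

#' Generate a seeded cohort of draft strain models
#'
#' Half the strains are "lactis-like", half "cremoris-like"; pathway flags
#' are sampled per strain from [defaultCohortProbabilities()] (lactose-PTS
#' is operon-linked to the tagatose-6P pathway and the lactose permease to
#' the Leloir route). Every strain grows on the glucose toy CDM by
#' construction (the medium supplies all four amino acids).
#'
#' @param n number of strains (>= 2).
#' @param seed integer seed; the cohort is reproducible and regeneration
#'   is byte-identical.
#' @param probabilities list as returned by [defaultCohortProbabilities()].
#' @param universalBuild result of [buildToyUniversal()]; defaults to a
#'   clean build.
#' @param egcVariants inject EGC variant pairs into every strain.
#' @param injectGapfill inject the standard gap-fill set into every strain.
#' @return list with `strains` (each a [deriveStrain()] result), `labels`
#'   (species class per strain) and `universal`.
#' @export
generateCohort <- function(n, seed, probabilities = defaultCohortProbabilities(),
                           universalBuild = NULL, egcVariants = FALSE,
                           injectGapfill = TRUE) {
  stopifnot(n >= 2)
  if (is.null(universalBuild)) universalBuild <- buildToyUniversal()
  uni <- universalBuild$model
  groups <- universalBuild$manifest$groups
  species <- rep(c("lactis", "cremoris"), c(ceiling(n / 2), floor(n / 2)))
  ids <- sprintf("%s_%03d", ifelse(species == "lactis", "LL", "LC"),
                 seq_len(n))
  strains <- vector("list", n)
  ## per-strain seeds are drawn from one master stream: consecutive integer
  ## seeds give correlated Mersenne streams, which would distort the
  ## low-probability pathway flags
  strainSeeds <- withSeed(seed, sample.int(2147483646L, n))
  for (i in seq_len(n)) {
    p <- probabilities[[species[i]]]
    strainSeed <- strainSeeds[i]
    prof <- withSeed(strainSeed, {
      draw <- stats::runif(length(p)) < p
      names(draw) <- names(p)
      ## operon linkage: the PTS/permease lactose routes require their
      ## galactose counterparts
      draw["lactose_pts"] <- draw["lactose_pts"] && draw["tag6p"]
      draw["lactose_permease"] <- draw["lactose_permease"] && draw["leloir"]
      draw
    })
    strains[[i]] <- deriveStrain(uni, prof, ids[i], strainSeed, groups,
                                 injectGapfill = injectGapfill,
                                 egcVariants = egcVariants)
  }
  names(strains) <- ids
  list(strains = strains, labels = stats::setNames(species, ids),
       universal = uni)
}

#' The variant-removal curation patch for the injected EGC pairs
#' @return a patch (list of edits) deleting the redundant transport
#'   variants, applicable to every strain.
#' @export
egcVariantPatch <- function() {
  lapply(egcVariantDefs(), function(v) {
    list(op = "delete_reaction", target = v$id, arg1 = "", arg2 = "",
         arg3 = "")
  })
}
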