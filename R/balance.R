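## Formula parsing and mass/charge balance auditing.
##
## Roughly one in five reactions in pooled reaction-database models is mass
## or charge imbalanced (mixed protonation conventions, inconsistent R-group
## usage); the audit below classifies every reaction so patch files can fix
## them.

#' Parse a chemical formula into an element count map
#'
#' Grammar: a sequence of `Element[Count]` tokens, where an element is a
#' capital letter plus optional lowercase letter and count is a positive
#' integer (default 1). The pseudo-elements `R` and `X` (generic acyl /
#' unspecified groups, common in fatty-acid and polymer entries) are
#' ordinary single-letter elements under this grammar. Parenthesized or
#' polymeric formulas are deliberately not supported: they signal
#' `unknown_formula` rather than aborting an audit.
#'
#' @param text formula string, e.g. `"C6H12O6"` or `"C2H3OR"`.
#' @return named integer vector of element counts, or `NULL` when the
#'   formula is empty/unparsable (the unknown-formula signal).
#' @examples
#' parseFormula("H2O")      # H=2, O=1
#' parseFormula("C2H3OR")   # includes pseudo-element R
#' @export
parseFormula <- function(text) {
  if (is.null(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    return(NULL)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) return(NULL) # stray chars
  out <- integer()
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    cnt <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (n < 1L) return(NULL)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  if (!length(out)) NULL else out
}

sumElementMaps <- function(maps, weights) {
  els <- unique(unlist(lapply(maps, names), use.names = FALSE))
  out <- stats::setNames(numeric(length(els)), els)
  for (i in seq_along(maps)) {
    out[names(maps[[i]])] <- out[names(maps[[i]])] + weights[i] * maps[[i]]
  }
  out
}

#' Mass/charge balance of one reaction
#'
#' Sums `coefficient x (formula, charge)` over all participants.
#' Classification: `exempt` for reactions flagged `exempt_from_balance`
#' (exchanges, sinks, biomass); `unknown_formula` if any participant lacks
#' a parsable formula; `balanced` when all deltas are zero;
#' `proton_imbalanced` when only hydrogen and charge are off by the same
#' amount (a protonation-state mismatch); `charge_imbalanced` when only the
#' charge is off; otherwise `mass_imbalanced`.
#'
#' @param model a [GEM].
#' @param rid reaction id.
#' @return list with `reaction`, `element_delta` (named numeric),
#'   `charge_delta`, `classification`.
#' @export
checkReactionBalance <- function(model, rid) {
  entry <- function(cls, ed = numeric(), cd = NA_real_) {
    list(reaction = rid, element_delta = ed, charge_delta = cd,
         classification = cls)
  }
  if (hasFlag(model, rid, "exempt_from_balance")) return(entry("exempt"))
  st <- reactionStoich(model, rid)
  idx <- match(names(st), model@metabolites$id)
  maps <- lapply(model@metabolites$formula[idx], parseFormula)
  if (any(vapply(maps, is.null, logical(1)))) return(entry("unknown_formula"))
  ed <- sumElementMaps(maps, unname(st))
  ed <- ed[abs(ed) > 1e-9]
  cd <- sum(unname(st) * model@metabolites$charge[idx])
  if (!length(ed) && abs(cd) < 1e-9) return(entry("balanced", ed, cd))
  onlyH <- length(ed) == 1L && names(ed) == "H"
  if (onlyH && abs(cd - ed[["H"]]) < 1e-9) {
    return(entry("proton_imbalanced", ed, cd))
  }
  if (!length(ed)) return(entry("charge_imbalanced", ed, cd))
  entry("mass_imbalanced", ed, cd)
}

#' Audit the balance of every reaction in a model
#'
#' @param model a [GEM].
#' @return list with `entries` (data.frame: reaction, classification,
#'   element_deltas, charge_delta) and `summary` (fractions; the imbalanced
#'   fraction is computed over non-exempt, known-formula reactions).
#' @export
auditBalance <- function(model) {
  ids <- model@reactions$id
  ents <- lapply(ids, function(r) checkReactionBalance(model, r))
  cls <- vapply(ents, `[[`, character(1), "classification")
  fmtDelta <- function(e) {
    d <- e$element_delta
    if (!length(d)) return("")
    paste(sprintf("%s:%+g", names(d), d), collapse = ";")
  }
  df <- data.frame(
    reaction = ids,
    classification = cls,
    element_deltas = vapply(ents, fmtDelta, character(1)),
    charge_delta = vapply(ents, function(e) {
      if (is.na(e$charge_delta)) NA_real_ else e$charge_delta
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  assessed <- !(cls %in% c("exempt", "unknown_formula"))
  imbalanced <- assessed & cls != "balanced"
  list(
    entries = df,
    summary = list(
      n_reactions = length(ids),
      n_assessed = sum(assessed),
      n_imbalanced = sum(imbalanced),
      imbalanced_fraction = if (sum(assessed)) {
        sum(imbalanced) / sum(assessed)
      } else 0,
      by_class = as.list(table(cls))
    )
  )
}

#' Classify one reaction as exchange / transport / biomass / metabolic
#'
#' An exchange is a boundary pseudo-reaction with exactly one metabolite; a
#' transport spans two or more compartments; a biomass reaction carries the
#' `biomass` flag; everything else is metabolic.
#'
#' @param model a [GEM].
#' @param rid reaction id.
#' @return one of `"exchange"`, `"transport"`, `"biomass"`, `"metabolic"`.
#' @export
classifyReaction <- function(model, rid) {
  if (hasFlag(model, rid, "biomass")) return("biomass")
  st <- reactionStoich(model, rid)
  if (length(st) == 1L) return("exchange")
  comps <- unique(compartmentOf(names(st)))
  if (length(comps) >= 2L) return("transport")
  "metabolic"
}

#' Vectorized reaction classification
#' @param model a [GEM].
#' @return character vector (named by reaction id) of classes.
#' @export
classifyReactions <- function(model) {
  ids <- model@reactions$id
  stats::setNames(vapply(ids, function(r) classifyReaction(model, r),
                         character(1)), ids)
}

isExchange <- function(model) classifyReactions(model) == "exchange"

#' Model statistics in the style of model-comparison tables
#'
#' Unique metabolites are counted at the species level (compartment suffix
#' stripped); a disconnected metabolite participates in at most one
#' reaction; "genes in multiple reactions" counts genes whose id occurs in
#' the GPR of two or more reactions.
#'
#' @param model a [GEM].
#' @return named list of counts and percentages.
#' @export
modelStats <- function(model) {
  met <- model@metabolites
  rxn <- model@reactions
  cls <- classifyReactions(model)
  nR <- nrow(rxn)
  degree <- Matrix::rowSums(model@stoichiometry != 0)
  geneLists <- lapply(rxn$gpr, gprGenes)
  geneTab <- table(unlist(lapply(geneLists, unique), use.names = FALSE))
  pct <- function(x, d) if (d > 0) 100 * x / d else 0
  nGenes <- length(model@genes)
  list(
    metabolites = nrow(met),
    unique_metabolites = length(unique(baseMetaboliteId(met$id))),
    unique_metabolites_pct = pct(length(unique(baseMetaboliteId(met$id))),
                                 nrow(met)),
    disconnected_metabolites = sum(degree <= 1L),
    disconnected_metabolites_pct = pct(sum(degree <= 1L), nrow(met)),
    reactions = nR,
    metabolic_reactions = sum(cls == "metabolic"),
    metabolic_reactions_pct = pct(sum(cls == "metabolic"), nR),
    transport_reactions = sum(cls == "transport"),
    transport_reactions_pct = pct(sum(cls == "transport"), nR),
    exchange_reactions = sum(cls == "exchange"),
    exchange_reactions_pct = pct(sum(cls == "exchange"), nR),
    biomass_reactions = sum(cls == "biomass"),
    reactions_with_genes = sum(nzchar(rxn$gpr)),
    reactions_with_genes_pct = pct(sum(nzchar(rxn$gpr)), nR),
    genes = nGenes,
    genes_multiple_reactions = sum(geneTab >= 2L),
    genes_multiple_reactions_pct = pct(sum(geneTab >= 2L), nGenes)
  )
}
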