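#' @importFrom Matrix sparseMatrix Matrix
NULL

## locale-independent (C collation) id sorting: kept-id tie-breaks and
## serialization order must not depend on LC_COLLATE
idSort <- function(x) {
  if (is.null(x) || !length(x)) return(character(0))
  sort(x, method = "radix")
}

## ---- construction -----------------------------------------------------

emptyMetaboliteFrame <- function() {
  df <- data.frame(id = character(), name = character(),
                   compartment = character(), formula = character(),
                   charge = integer(), stringsAsFactors = FALSE)
  df$annotations <- list()
  df
}

emptyReactionFrame <- function() {
  df <- data.frame(id = character(), name = character(),
                   lb = numeric(), ub = numeric(), gpr = character(),
                   subsystem = character(), stringsAsFactors = FALSE)
  df$flags <- list()
  df$annotations <- list()
  df
}

#' Construct a GEM from component tables
#'
#' Low-level constructor. Most users obtain models from [readSBML()] or
#' [buildToyUniversal()].
#'
#' @param id model id.
#' @param metabolites metabolite `data.frame` (see [GEM-class]); missing
#'   optional columns are filled with defaults.
#' @param reactions reaction `data.frame`.
#' @param stoichiometry a matrix coercible to sparse, metabolites x
#'   reactions, dimnames matching the id columns.
#' @param genes character vector of gene ids; defaults to all genes
#'   mentioned in GPRs.
#' @param objective objective reaction id (`""` for none, e.g. a universal
#'   database model before biomass installation).
#' @return a validated [GEM].
#' @export
newGEM <- function(id, metabolites, reactions, stoichiometry,
                   genes = NULL, objective = "") {
  metabolites <- fillMetDefaults(metabolites)
  reactions <- fillRxnDefaults(reactions)
  S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (is.null(genes)) {
    genes <- idSort(unique(unlist(lapply(reactions$gpr, gprGenes),
                                use.names = FALSE)))
  }
  methods::new("GEM", id = id, metabolites = metabolites,
               reactions = reactions, stoichiometry = S,
               genes = as.character(genes), objective = objective,
               compartments = idSort(unique(metabolites$compartment)))
}

fillMetDefaults <- function(df) {
  n <- nrow(df)
  if (is.null(df$name)) df$name <- df$id
  if (is.null(df$compartment)) df$compartment <- compartmentOf(df$id)
  if (is.null(df$formula)) df$formula <- rep(NA_character_, n)
  if (is.null(df$charge)) df$charge <- rep(0L, n)
  df$charge <- as.integer(df$charge)
  if (is.null(df$annotations)) df$annotations <- replicate(n, list(), FALSE)
  rownames(df) <- NULL
  df
}

fillRxnDefaults <- function(df) {
  n <- nrow(df)
  if (is.null(df$name)) df$name <- df$id
  if (is.null(df$lb)) df$lb <- rep(0, n)
  if (is.null(df$ub)) df$ub <- rep(1000, n)
  if (is.null(df$gpr)) df$gpr <- rep("", n)
  df$gpr[is.na(df$gpr)] <- ""
  if (is.null(df$subsystem)) df$subsystem <- rep("", n)
  if (is.null(df$flags)) df$flags <- replicate(n, character(), FALSE)
  if (is.null(df$annotations)) df$annotations <- replicate(n, list(), FALSE)
  rownames(df) <- NULL
  df
}

#' Compartment code implied by a metabolite id suffix
#'
#' Ids follow the BiGG convention `<base>_<compartment>`; the suffix after
#' the last underscore is the compartment code.
#'
#' @param ids character vector of metabolite ids.
#' @return character vector of compartment codes.
#' @export
compartmentOf <- function(ids) sub("^.*_([a-z]+)$", "\\1", ids)

#' Base metabolite id with the compartment suffix stripped
#' @param ids character vector of metabolite ids.
#' @return character vector of species-level ids.
#' @export
baseMetaboliteId <- function(ids) sub("_[a-z]+$", "", ids)

## ---- accessors --------------------------------------------------------

#' @rdname strainforge-generics
#' @export
setMethod("metabolites", "GEM", function(object) object@metabolites)

#' @rdname strainforge-generics
#' @export
setMethod("reactions", "GEM", function(object) object@reactions)

#' @rdname strainforge-generics
#' @export
setMethod("stoichMatrix", "GEM", function(object) object@stoichiometry)

#' @rdname strainforge-generics
#' @export
setMethod("genes", "GEM", function(object) object@genes)

#' @rdname strainforge-generics
#' @export
setMethod("objectiveReaction", "GEM", function(object) object@objective)

#' @rdname strainforge-generics
#' @export
setMethod("objectiveReaction<-", "GEM", function(object, value) {
  object@objective <- value
  methods::validObject(object)
  object
})

#' @rdname strainforge-generics
#' @export
setMethod("reactionIds", "GEM", function(object) object@reactions$id)

#' @rdname strainforge-generics
#' @export
setMethod("metaboliteIds", "GEM", function(object) object@metabolites$id)

#' @rdname strainforge-generics
#' @export
setMethod("modelId", "GEM", function(object) object@id)

#' @rdname strainforge-generics
#' @export
setMethod("panUnion", "PanModel", function(object) object@union)

setMethod("show", "GEM", function(object) {
  cls <- table(classifyReactions(object))
  n <- function(k) if (k %in% names(cls)) cls[[k]] else 0L
  cat(sprintf("GEM '%s': %d metabolites, %d reactions, %d genes\n",
              object@id, nrow(object@metabolites), nrow(object@reactions),
              length(object@genes)))
  cat(sprintf("  metabolic %d | transport %d | exchange %d | biomass %d\n",
              n("metabolic"), n("transport"), n("exchange"), n("biomass")))
  cat(sprintf("  compartments: %s; objective: %s\n",
              paste(object@compartments, collapse = ", "),
              if (nzchar(object@objective)) object@objective else "<none>"))
})

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution: status %s, objective %s (%d fluxes)\n",
              object@status,
              if (length(object@objectiveValue)) {
                format(object@objectiveValue, digits = 6)
              } else "NA",
              length(object@fluxes)))
})

setMethod("show", "PanModel", function(object) {
  cat(sprintf("PanModel: %d strains x %d reactions (union of %d metabolites)\n",
              nrow(object@presence), ncol(object@presence),
              nrow(object@union@metabolites)))
})

setMethod("show", "SimulationCondition", function(object) {
  cat(sprintf(
    "SimulationCondition: %d medium components, %d unconstrained, %d overrides\n",
    length(object@medium), length(object@unconstrained),
    length(object@overrides)))
})


## ---- reaction / metabolite manipulation -------------------------------

#' Named stoichiometry of one reaction
#' @param model a [GEM].
#' @param rid reaction id.
#' @return named numeric of nonzero coefficients (negative = consumed).
#' @export
reactionStoich <- function(model, rid) {
  col <- model@stoichiometry[, rid]
  col[col != 0]
}

rxnFlags <- function(model, rid) {
  model@reactions$flags[[match(rid, model@reactions$id)]]
}

hasFlag <- function(model, rid, flag) {
  vapply(rid, function(r) flag %in% rxnFlags(model, r), logical(1),
         USE.NAMES = FALSE)
}

setFlag <- function(model, rid, flag) {
  i <- match(rid, model@reactions$id)
  model@reactions$flags[i] <- lapply(model@reactions$flags[i],
                                     function(f) union(f, flag))
  model
}

#' Add metabolites to a model
#' @param model a [GEM].
#' @param df metabolite data.frame rows to append (ids must be new).
#' @return the extended model.
#' @export
addMetabolites <- function(model, df) {
  df <- fillMetDefaults(df)
  dup <- intersect(df$id, model@metabolites$id)
  if (length(dup)) stop("metabolites already present: ",
                        paste(dup, collapse = ", "))
  model@metabolites <- rbind(model@metabolites, df)
  S <- model@stoichiometry
  pad <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(df), ncol(S)))
  model@stoichiometry <- methods::as(rbind(S, pad), "CsparseMatrix")
  dimnames(model@stoichiometry) <- list(model@metabolites$id,
                                        model@reactions$id)
  model@compartments <- idSort(unique(model@metabolites$compartment))
  model
}

#' Add one reaction to a model
#'
#' @param model a [GEM].
#' @param id new reaction id.
#' @param stoich named numeric, metabolite id -> coefficient; all
#'   metabolites must already exist (see [addMetabolites()]).
#' @param name,lb,ub,gpr,subsystem,flags,annotations reaction fields.
#' @return the extended model.
#' @export
addReaction <- function(model, id, stoich, name = id, lb = 0, ub = 1000,
                        gpr = "", subsystem = "", flags = character(),
                        annotations = list()) {
  if (id %in% model@reactions$id) stop("reaction already present: ", id)
  missing <- setdiff(names(stoich), model@metabolites$id)
  if (length(missing)) stop("unknown metabolites in '", id, "': ",
                            paste(missing, collapse = ", "))
  row <- data.frame(id = id, name = name, lb = lb, ub = ub, gpr = gpr,
                    subsystem = subsystem, stringsAsFactors = FALSE)
  row$flags <- list(flags)
  row$annotations <- list(annotations)
  model@reactions <- rbind(model@reactions, row)
  i <- match(names(stoich), model@metabolites$id)
  newcol <- Matrix::sparseMatrix(i = i, j = rep(1L, length(i)),
                                 x = unname(stoich),
                                 dims = c(nrow(model@metabolites), 1L))
  model@stoichiometry <- methods::as(cbind(model@stoichiometry, newcol),
                                     "CsparseMatrix")
  dimnames(model@stoichiometry) <- list(model@metabolites$id,
                                        model@reactions$id)
  g <- gprGenes(gpr)
  model@genes <- idSort(union(model@genes, g))
  model
}

#' Remove reactions (and optionally newly orphaned metabolites)
#'
#' @param model a [GEM].
#' @param ids reaction ids to drop.
#' @param dropOrphans also drop metabolites left with no reaction.
#' @return the reduced model.
#' @export
removeReactions <- function(model, ids, dropOrphans = FALSE) {
  keep <- !(model@reactions$id %in% ids)
  model@reactions <- model@reactions[keep, , drop = FALSE]
  rownames(model@reactions) <- NULL
  model@stoichiometry <- model@stoichiometry[, keep, drop = FALSE]
  if (nzchar(model@objective) && !(model@objective %in% model@reactions$id)) {
    model@objective <- ""
  }
  if (dropOrphans) {
    used <- Matrix::rowSums(model@stoichiometry != 0) > 0
    model@metabolites <- model@metabolites[used, , drop = FALSE]
    rownames(model@metabolites) <- NULL
    model@stoichiometry <- model@stoichiometry[used, , drop = FALSE]
  }
  model
}

#' Set flux bounds on a reaction
#' @param model a [GEM].
#' @param rid reaction id.
#' @param lb,ub new bounds.
#' @return the model.
#' @export
setBounds <- function(model, rid, lb, ub) {
  i <- match(rid, model@reactions$id)
  if (anyNA(i)) stop("unknown reaction: ",
                     paste(rid[is.na(i)], collapse = ", "))
  model@reactions$lb[i] <- lb
  model@reactions$ub[i] <- ub
  model
}

## ---- GPR expression trees ---------------------------------------------

#' Parse a GPR boolean expression
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := gene | '(' expr ')'`. Returns a nested list with elements
#' `op` (`"and"`/`"or"`) and `args`, or a character scalar for a single
#' gene; `NULL` for an empty association.
#'
#' @param text GPR string, e.g. `"g1 and (g2 or g3)"`.
#' @return expression tree, or `NULL`.
#' @export
gprParse <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()\\s]+", text, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parseExpr <- function() {
    args <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parseTerm()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parseFactor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR: ", text)
    if (t == "(") {
      e <- parseExpr()
      if (!identical(take(), ")")) stop("malformed GPR (missing ')'): ", text)
      return(e)
    }
    if (t %in% c(")", "and", "or")) stop("malformed GPR: ", text)
    t
  }
  out <- parseExpr()
  if (pos <= length(toks)) stop("malformed GPR (trailing tokens): ", text)
  out
}

#' Genes referenced by a GPR expression
#' @param gpr GPR string or parsed tree.
#' @return character vector of gene ids (empty for no association).
#' @export
gprGenes <- function(gpr) {
  tree <- if (is.character(gpr) && length(gpr) == 1L) gprParse(gpr) else gpr
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gprGenes), use.names = FALSE))
}

#' Combine GPRs with OR, deduplicating
#' @param gprs character vector of GPR strings.
#' @return a single GPR string.
#' @export
gprUnion <- function(gprs) {
  gprs <- unique(gprs[nzchar(gprs)])
  if (!length(gprs)) return("")
  if (length(gprs) == 1L) return(gprs)
  wrap <- function(g) if (grepl("\\bor\\b", g)) g else if (grepl("\\band\\b", g)) paste0("(", g, ")") else g
  paste(vapply(gprs, wrap, character(1)), collapse = " or ")
}

## ---- reaction equation strings ----------------------------------------

#' Parse a reaction equation string
#'
#' Accepts `"a + 2 b -> c"` (irreversible) or `"a + b <-> c"` (reversible);
#' coefficients default to 1. Used by currency-dissipation tables and
#' patch files.
#'
#' @param eq equation string over metabolite ids.
#' @return list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parseReactionString <- function(eq) {
  rev <- grepl("<->|<=>", eq)
  sides <- strsplit(eq, "<->|<=>|-->|->|=>", perl = TRUE)[[1]]
  if (length(sides) == 1L && grepl("<->|<=>|-->|->|=>", eq)) {
    sides <- c(sides, "")  # boundary reaction with an empty product side
  }
  if (length(sides) != 2L) stop("malformed reaction equation: ", eq)
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.]+)\\s+(\\S+)$", tm))[[1]]
      if (length(m)) {
        out[m[3]] <- (out[m[3]] %||0% 0) + sign * as.numeric(m[2])
      } else {
        out[tm] <- (out[tm] %||0% 0) + sign
      }
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  st <- c(lhs, numeric(0))
  for (nm in names(rhs)) st[nm] <- (st[nm] %||0% 0) + rhs[nm]
  st <- st[st != 0]
  list(stoich = st, reversible = rev)
}

`%||0%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Format a stoichiometry as an equation string
#' @param stoich named numeric coefficient map.
#' @param reversible use a reversible arrow.
#' @return equation string.
#' @export
formatReactionString <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    vapply(seq_along(v), function(i) {
      cf <- abs(v[i])
      if (cf == 1) names(v)[i] else paste(format(cf), names(v)[i])
    }, character(1))
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(paste(fmt(lhs), collapse = " + "),
        if (reversible) "<->" else "->",
        paste(fmt(rhs), collapse = " + "))
}
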