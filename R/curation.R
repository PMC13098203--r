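## Universal-model curation: duplicate detection/merging and patch
## application. Pooled reaction-database models accumulate duplicate
## entries from their source reconstructions; duplicates skew reaction
## presence/absence comparisons and inflate network size, so they are
## merged while keeping GPRs and database annotations.

canonicalName <- function(x) gsub("[^a-z0-9]", "", tolower(x))

## orient a stoichiometry to the lexicographically smaller of (s, -s),
## with metabolite ids sorted; returns list(key, flipped)
normalizeStoich <- function(st) {
  st <- st[order(names(st), method = "radix")]
  keyOf <- function(s) paste(names(s), formatC(s, digits = 12, format = "g"),
                             collapse = "|")
  k1 <- keyOf(st)
  k2 <- keyOf(-st)
  if (k2 < k1) list(key = k2, flipped = TRUE) else list(key = k1, flipped = FALSE)
}

#' Find duplicate metabolites and reactions
#'
#' Metabolites are grouped when they share compartment, formula and charge
#' and either share an annotation identifier in any database or have equal
#' canonicalized names (lowercase, non-alphanumerics stripped). Reactions
#' are grouped when their normalized stoichiometries are identical, where
#' normalization orients each reaction to the lexicographically smaller of
#' (stoich, -stoich); groups are connected components of the pair relation.
#'
#' @param model a [GEM].
#' @return list with `metabolite_groups`, `reaction_groups` (lists of id
#'   vectors, each of size >= 2) and per-group `evidence` tags.
#' @export
findDuplicates <- function(model) {
  met <- model@metabolites
  mgroups <- list(); mev <- character()
  if (nrow(met) > 1L) {
    key <- paste(met$compartment, ifelse(is.na(met$formula), "?", met$formula),
                 met$charge, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      ids <- met$id[key == k]
      if (length(ids) < 2L) next
      ## within the candidate set, link by shared annotation or equal name
      idx <- match(ids, met$id)
      n <- length(ids)
      adj <- matrix(FALSE, n, n)
      for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
        annA <- unlist(met$annotations[[idx[a]]], use.names = FALSE)
        annB <- unlist(met$annotations[[idx[b]]], use.names = FALSE)
        shared <- length(intersect(annA, annB)) > 0
        sameName <- canonicalName(met$name[idx[a]]) ==
          canonicalName(met$name[idx[b]])
        adj[a, b] <- adj[b, a] <- shared || sameName
      }
      comp <- connectedComponents(adj)
      for (cc in comp) {
        if (length(cc) < 2L) next
        idxA <- idx[cc[1]]; idxB <- idx[cc[2]]
        shared <- length(intersect(
          unlist(met$annotations[[idxA]], use.names = FALSE),
          unlist(met$annotations[[idxB]], use.names = FALSE))) > 0
        mgroups <- c(mgroups, list(idSort(ids[cc])))
        mev <- c(mev, if (shared) "shared_annotation" else
                        "identical_formula_charge_name")
      }
    }
  }
  rxnIds <- model@reactions$id
  norm <- lapply(rxnIds, function(r) normalizeStoich(reactionStoich(model, r)))
  keys <- vapply(norm, `[[`, character(1), "key")
  flips <- vapply(norm, `[[`, logical(1), "flipped")
  rgroups <- list(); rev <- character()
  for (k in unique(keys[duplicated(keys)])) {
    ids <- rxnIds[keys == k]
    rgroups <- c(rgroups, list(idSort(ids)))
    f <- flips[keys == k]
    rev <- c(rev, if (length(unique(f)) > 1L) "sign_flipped_stoichiometry"
                  else "identical_stoichiometry")
  }
  list(metabolite_groups = mgroups, metabolite_evidence = mev,
       reaction_groups = rgroups, reaction_evidence = rev)
}

connectedComponents <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; comp <- integer()
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    comps <- c(comps, list(sort(comp)))
  }
  comps
}

mergeMetaboliteGroup <- function(model, ids) {
  keep <- idSort(ids)[1]
  drop <- setdiff(ids, keep)
  met <- model@metabolites
  ki <- match(keep, met$id)
  for (d in drop) {
    di <- match(d, met$id)
    for (db in names(met$annotations[[di]])) {
      met$annotations[[ki]][[db]] <-
        idSort(union(met$annotations[[ki]][[db]], met$annotations[[di]][[db]]))
    }
  }
  model@metabolites <- met
  S <- as.matrix(model@stoichiometry)
  for (d in drop) {
    S[keep, ] <- S[keep, ] + S[d, ]
  }
  S <- S[!(rownames(S) %in% drop), , drop = FALSE]
  model@metabolites <- model@metabolites[!(met$id %in% drop), , drop = FALSE]
  rownames(model@metabolites) <- NULL
  model@stoichiometry <- methods::as(Matrix::Matrix(S, sparse = TRUE),
                                     "CsparseMatrix")
  dimnames(model@stoichiometry) <- list(model@metabolites$id,
                                        model@reactions$id)
  model
}

mergeReactionGroup <- function(model, ids) {
  keep <- idSort(ids)[1]
  drop <- setdiff(ids, keep)
  rxn <- model@reactions
  ki <- match(keep, rxn$id)
  keepNorm <- normalizeStoich(reactionStoich(model, keep))
  lbs <- rxn$lb[ki]; ubs <- rxn$ub[ki]
  gprs <- rxn$gpr[ki]
  for (d in drop) {
    di <- match(d, rxn$id)
    dNorm <- normalizeStoich(reactionStoich(model, d))
    sameOrientation <- dNorm$flipped == keepNorm$flipped
    if (sameOrientation) {
      lbs <- min(lbs, rxn$lb[di]); ubs <- max(ubs, rxn$ub[di])
    } else {  # orient the member to the kept reaction's direction
      lbs <- min(lbs, -rxn$ub[di]); ubs <- max(ubs, -rxn$lb[di])
    }
    gprs <- c(gprs, rxn$gpr[di])
    for (db in names(rxn$annotations[[di]])) {
      rxn$annotations[[ki]][[db]] <-
        idSort(union(rxn$annotations[[ki]][[db]], rxn$annotations[[di]][[db]]))
    }
    rxn$flags[[ki]] <- union(rxn$flags[[ki]], rxn$flags[[di]])
  }
  rxn$lb[ki] <- lbs; rxn$ub[ki] <- ubs
  rxn$gpr[ki] <- gprUnion(gprs)
  model@reactions <- rxn
  model <- removeReactions(model, drop)
  model
}

#' Merge duplicate groups, iterating to a fixpoint
#'
#' Per metabolite group the lexicographically smallest id is kept, all
#' stoichiometries rewritten and annotations unioned; per reaction group
#' the smallest id is kept with the OR of member GPRs, unioned annotations,
#' and bounds widened to the union of feasible directions after orienting
#' members to the kept reaction. Because metabolite merges can surface new
#' reaction duplicates, scanning and merging repeat until
#' [findDuplicates()] comes back empty.
#'
#' @param model a [GEM].
#' @param groups result of [findDuplicates()]; defaults to scanning.
#' @return list with `model` and `log` (data.frame: kind, kept, removed).
#' @export
mergeDuplicates <- function(model, groups = NULL) {
  if (is.null(groups)) groups <- findDuplicates(model)
  allG <- c(groups$metabolite_groups, groups$reaction_groups)
  if (length(allG) > 1L) {
    flat <- unlist(allG)
    if (anyDuplicated(flat)) stop("overlapping duplicate groups")
  }
  log <- data.frame(kind = character(), kept = character(),
                    removed = character(), stringsAsFactors = FALSE)
  repeat {
    for (g in groups$metabolite_groups) {
      model <- mergeMetaboliteGroup(model, g)
      log <- rbind(log, data.frame(
        kind = "metabolite", kept = idSort(g)[1],
        removed = paste(setdiff(g, idSort(g)[1]), collapse = ","),
        stringsAsFactors = FALSE))
    }
    for (g in groups$reaction_groups) {
      model <- mergeReactionGroup(model, g)
      log <- rbind(log, data.frame(
        kind = "reaction", kept = idSort(g)[1],
        removed = paste(setdiff(g, idSort(g)[1]), collapse = ","),
        stringsAsFactors = FALSE))
    }
    groups <- findDuplicates(model)
    if (!length(groups$metabolite_groups) && !length(groups$reaction_groups)) {
      break
    }
  }
  list(model = model, log = log)
}

## ---- patches ----------------------------------------------------------

#' Read a curation patch (TSV)
#'
#' Columns `op`, `target`, `arg1`, `arg2`, `arg3`. Supported ops:
#' \describe{
#'   \item{set_stoichiometry}{target = reaction, arg1 = metabolite,
#'     arg2 = coefficient (0 removes the participant).}
#'   \item{set_charge}{target = metabolite, arg1 = charge.}
#'   \item{set_formula}{target = metabolite, arg1 = formula.}
#'   \item{set_bounds}{target = reaction, arg1 = lb, arg2 = ub.}
#'   \item{delete_reaction}{target = reaction (already-absent = no-op, so
#'     patches are idempotent).}
#'   \item{add_reaction}{target = new id, arg1 = equation string
#'     (see [parseReactionString()]), arg2 = "lb,ub" (optional),
#'     arg3 = GPR (optional). Already-present = no-op.}
#' }
#'
#' @param path TSV file path.
#' @return a patch: list of edit lists.
#' @export
readPatchTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("op", "target") %in% names(df))) {
    stop("patch TSV must have columns op, target (plus arg1..arg3)")
  }
  for (col in c("arg1", "arg2", "arg3")) if (is.null(df[[col]])) df[[col]] <- ""
  lapply(seq_len(nrow(df)), function(i) {
    list(op = df$op[i], target = df$target[i], arg1 = df$arg1[i],
         arg2 = df$arg2[i], arg3 = df$arg3[i])
  })
}

#' Apply a curation patch to a model
#'
#' Edits are applied in order; applying the same patch twice yields the
#' same model (idempotent edit semantics). An edit referencing an entity
#' that cannot be resolved (other than the deliberate no-op cases of
#' `delete_reaction` / `add_reaction`) raises an error naming the edit
#' index.
#'
#' @param model a [GEM].
#' @param patch result of [readPatchTSV()] or a list of edits.
#' @return the patched model.
#' @export
applyPatch <- function(model, patch) {
  for (k in seq_along(patch)) {
    e <- patch[[k]]
    bad <- function(msg) stop("patch edit ", k, " (", e$op, " ", e$target,
                              "): ", msg)
    model <- switch(e$op,
      set_stoichiometry = {
        if (!(e$target %in% model@reactions$id)) bad("unknown reaction")
        if (!(e$arg1 %in% model@metabolites$id)) bad("unknown metabolite")
        S <- model@stoichiometry
        S[e$arg1, e$target] <- as.numeric(e$arg2)
        model@stoichiometry <- methods::as(Matrix::drop0(S), "CsparseMatrix")
        model
      },
      set_charge = {
        i <- match(e$target, model@metabolites$id)
        if (is.na(i)) bad("unknown metabolite")
        model@metabolites$charge[i] <- as.integer(e$arg1)
        model
      },
      set_formula = {
        i <- match(e$target, model@metabolites$id)
        if (is.na(i)) bad("unknown metabolite")
        model@metabolites$formula[i] <- e$arg1
        model
      },
      set_bounds = {
        if (!(e$target %in% model@reactions$id)) bad("unknown reaction")
        setBounds(model, e$target, as.numeric(e$arg1), as.numeric(e$arg2))
      },
      delete_reaction = {
        if (e$target %in% model@reactions$id) {
          removeReactions(model, e$target)
        } else model
      },
      add_reaction = {
        if (e$target %in% model@reactions$id) model else {
          pr <- parseReactionString(e$arg1)
          bnds <- if (nzchar(e$arg2)) {
            as.numeric(strsplit(e$arg2, ",", fixed = TRUE)[[1]])
          } else c(if (pr$reversible) -1000 else 0, 1000)
          missing <- setdiff(names(pr$stoich), model@metabolites$id)
          if (length(missing)) bad(paste("unknown metabolites:",
                                         paste(missing, collapse = ", ")))
          addReaction(model, e$target, pr$stoich, lb = bnds[1], ub = bnds[2],
                      gpr = e$arg3)
        }
      },
      bad("unknown op"))
  }
  model
}
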