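# independent character-walk formula parser used as an oracle: no regex,
# one character at a time
charWalkFormula <- function(text) {
  if (!nzchar(text)) return(NULL)
  chars <- strsplit(text, "")[[1]]
  out <- integer(); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (!grepl("^[A-Z]$", ch)) return(NULL)
    el <- ch; i <- i + 1L
    if (i <= n && grepl("^[a-z]$", chars[i])) {
      el <- paste0(el, chars[i]); i <- i + 1L
    }
    digits <- ""
    while (i <= n && grepl("^[0-9]$", chars[i])) {
      digits <- paste0(digits, chars[i]); i <- i + 1L
    }
    cnt <- if (nzchar(digits)) as.integer(digits) else 1L
    if (cnt < 1L) return(NULL)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + cnt
  }
  out
}

test_that("formula parsing handles elements, counts and pseudo-elements", {
  expect_equal(parseFormula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parseFormula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parseFormula("C2H3OR"), c(C = 2L, H = 3L, O = 1L, R = 1L))
  expect_null(parseFormula(""))
  expect_null(parseFormula(NA_character_))
  expect_null(parseFormula("C6(H2O)6"))   # polymer grammar unsupported
  expect_null(parseFormula("c6h12"))      # lowercase start
})

test_that("formula parser agrees with a character-walk oracle on 1000 random strings", {
  set.seed(421)
  els <- c("C", "H", "O", "N", "P", "S", "Fe", "Mg", "Na", "Cl", "R", "X")
  for (k in 1:1000) {
    n <- sample(1:6, 1)
    toks <- vapply(seq_len(n), function(i) {
      el <- sample(els, 1)
      cnt <- sample(0:30, 1)
      paste0(el, if (cnt > 0) cnt else "")
    }, character(1))
    s <- paste(toks, collapse = "")
    got <- parseFormula(s)
    want <- charWalkFormula(s)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got[sort(names(got))], want[sort(names(want))])
    }
  }
})

test_that("reaction balance classification distinguishes proton, charge and mass errors", {
  m <- fxUniversal()$model
  # ATP maintenance hydrolysis is balanced with consistent formulas
  expect_identical(checkReactionBalance(m, "ATPM")$classification, "balanced")
  # deleting the proton product forces a protonation-state mismatch
  S <- stoichMatrix(m)
  m2 <- m
  m2@stoichiometry["h_c", "ATPM"] <- 0
  expect_identical(checkReactionBalance(m2, "ATPM")$classification,
                   "proton_imbalanced")
  # exchanges are exempt by flag
  expect_identical(checkReactionBalance(m, "EX_glc__D_e")$classification,
                   "exempt")
  # charge-only error: wrong charge on a metabolite
  m3 <- m
  m3@metabolites$charge[match("pi_c", metaboliteIds(m3))] <- -3L
  cls3 <- checkReactionBalance(m3, "ATPM")$classification
  expect_identical(cls3, "charge_imbalanced")
  # mass error: corrupt a coefficient
  m4 <- m
  m4@stoichiometry["adp_c", "ATPM"] <- 2
  expect_identical(checkReactionBalance(m4, "ATPM")$classification,
                   "mass_imbalanced")
  # unknown formula propagates
  m5 <- m
  m5@metabolites$formula[match("atp_c", metaboliteIds(m5))] <- NA_character_
  expect_identical(checkReactionBalance(m5, "ATPM")$classification,
                   "unknown_formula")
})

test_that("R-group accounting balances only when pseudo-element counts match", {
  met <- data.frame(
    id = c("acylr_c", "h2o_c", "rcooh_c", "roh_c"),
    compartment = "c",
    formula = c("C2H3OR", "H2O", "C2H5O2R", "C2H5O2R2"),
    charge = 0L, stringsAsFactors = FALSE)
  rxn <- data.frame(id = c("HYD_OK", "HYD_BAD"), lb = 0, ub = 1000,
                    stringsAsFactors = FALSE)
  S <- matrix(0, 4, 2, dimnames = list(met$id, rxn$id))
  S[, "HYD_OK"] <- c(-1, -1, 1, 0)    # acyl-R + h2o -> R-acid: R conserved
  S[, "HYD_BAD"] <- c(-1, -1, 0, 1)   # product carries two R groups
  m <- newGEM("rgroup", met, rxn, S)
  m@objective <- ""
  expect_identical(checkReactionBalance(m, "HYD_OK")$classification,
                   "balanced")
  bad <- checkReactionBalance(m, "HYD_BAD")
  expect_identical(bad$classification, "mass_imbalanced")
  expect_equal(bad$element_delta[["R"]], 1)
})

test_that("reaction classes partition the model and match hand rules", {
  m <- fxReference()
  cls <- classifyReactions(m)
  expect_identical(unname(cls[["EX_lac__D_e"]]), "exchange")
  expect_identical(unname(cls[["GLCpts"]]), "transport")  # spans e and c
  expect_identical(unname(cls[["LDH_D"]]), "metabolic")   # all cytosolic
  expect_identical(unname(cls[["BIOMASS_LACTO"]]), "biomass")
  expect_equal(sum(table(cls)), length(reactionIds(m)))
})

test_that("model statistics count unique and disconnected metabolites as documented", {
  m <- fxUniversal()$model
  st <- modelStats(m)
  expect_equal(st$reactions, length(reactionIds(m)))
  expect_equal(st$metabolic_reactions + st$transport_reactions +
                 st$exchange_reactions + st$biomass_reactions, st$reactions)
  # unique metabolites strip the compartment suffix
  expect_equal(st$unique_metabolites,
               length(unique(baseMetaboliteId(metaboliteIds(m)))))
  # the synthetic storage dead-end participates in exactly one reaction
  degree <- Matrix::rowSums(stoichMatrix(m) != 0)
  expect_true(degree[["glyc2_c"]] == 1)
  expect_equal(st$disconnected_metabolites, sum(degree <= 1))
  # single-reaction toy model stays consistent
  one <- newGEM("one",
                data.frame(id = "x_e", compartment = "e",
                           stringsAsFactors = FALSE),
                data.frame(id = "EX_x_e", lb = -1, ub = 1,
                           stringsAsFactors = FALSE),
                matrix(-1, 1, 1, dimnames = list("x_e", "EX_x_e")))
  s1 <- modelStats(one)
  expect_equal(s1$reactions, 1)
  expect_equal(s1$exchange_reactions, 1)
})
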