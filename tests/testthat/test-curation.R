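test_that("duplicate detection follows the grouping rules", {
  u <- buildToyUniversal(injectDuplicates = TRUE)
  fd <- findDuplicates(u$model)
  # exactly the injected groups (carriers surface only after merging)
  expect_setequal(vapply(fd$metabolite_groups, paste, character(1),
                         collapse = "+"),
                  c("glc__D_c+glcdup_c", "lac__D_c+lacdup_c"))
  expect_setequal(vapply(fd$reaction_groups, paste, character(1),
                         collapse = "+"),
                  c("LDH_D+LDH_D_dup", "TPI+TPI_rev", "ACKr+ACKr_dup"))
  flip <- fd$reaction_evidence[vapply(fd$reaction_groups, function(g)
    "TPI_rev" %in% g, logical(1))]
  expect_identical(flip, "sign_flipped_stoichiometry")
  # same formula/charge but disjoint annotations and different names: no group
  m <- addMetabolites(fxUniversal()$model, data.frame(
    id = "isoglc_c", name = "Unrelated hexose", compartment = "c",
    formula = "C6H12O6", charge = 0L, stringsAsFactors = FALSE))
  m <- addReaction(m, "ISO", c(isoglc_c = -1, glc__D_c = 1))
  fd2 <- findDuplicates(m)
  expect_false(any(vapply(fd2$metabolite_groups, function(g)
    "isoglc_c" %in% g, logical(1))))
})

test_that("merging eliminates duplicates idempotently and preserves behavior", {
  clean <- fxUniversal()$model
  u <- buildToyUniversal(injectDuplicates = TRUE)
  mg <- mergeDuplicates(u$model)
  # re-scan finds nothing; model size returns to the clean build
  fd <- findDuplicates(mg$model)
  expect_length(fd$metabolite_groups, 0)
  expect_length(fd$reaction_groups, 0)
  expect_equal(length(reactionIds(mg$model)), length(reactionIds(clean)))
  # merging again is a no-op
  mg2 <- mergeDuplicates(mg$model)
  expect_identical(reactionIds(mg2$model), reactionIds(mg$model))
  expect_equal(nrow(mg2$log), 0)
  # GPRs were kept as OR of members; bounds unioned to the widest direction
  i <- match("LDH_D", reactionIds(mg$model))
  expect_identical(reactions(mg$model)$gpr[i],
                   "gLDH1 or gLDH2 or gLDH3 or gLDH4")
  j <- match("TPI", reactionIds(mg$model))
  expect_equal(unlist(reactions(mg$model)[j, c("lb", "ub")],
                      use.names = FALSE), c(-1000, 1000))
  # growth under the packaged CDM is untouched (duplicates are redundant)
  cdm <- fxCDM()
  f1 <- solveFBA(clean, cdm)@objectiveValue
  f2 <- solveFBA(mg$model, cdm)@objectiveValue
  expect_equal(f1, f2, tolerance = 1e-6)
  # no groups -> unchanged, empty log
  noop <- mergeDuplicates(clean, findDuplicates(clean))
  expect_identical(reactionIds(noop$model), reactionIds(clean))
  expect_equal(nrow(noop$log), 0)
})

test_that("balance audit flags exactly the corrupted reactions (100 seeded trials)", {
  m <- fxUniversal()$model
  aud0 <- auditBalance(m)
  expect_equal(aud0$summary$imbalanced_fraction, 0)
  assessable <- aud0$entries$reaction[aud0$entries$classification == "balanced"]
  set.seed(909)
  for (trial in 1:100) {
    nCorrupt <- sample(1:3, 1)
    victims <- sample(assessable, nCorrupt)
    m2 <- m
    for (v in victims) {
      st <- reactionStoich(m2, v)
      pick <- sample(names(st), 1)
      m2@stoichiometry[pick, v] <- st[[pick]] + sample(c(1, 2), 1)
    }
    aud <- auditBalance(m2)
    flagged <- aud$entries$reaction[
      !(aud$entries$classification %in% c("balanced", "exempt",
                                          "unknown_formula"))]
    expect_setequal(flagged, victims)
  }
})

test_that("patches apply in order, idempotently, with resolvable references", {
  m <- fxReference()
  expect_identical(reactionIds(applyPatch(m, list())), reactionIds(m))
  # reopening an export-only transporter makes import feasible
  m1 <- setBounds(m, "LACt", 0, 1000)   # export-only lactate symport
  patch <- list(list(op = "set_bounds", target = "LACt",
                     arg1 = "-1000", arg2 = "1000"))
  m2 <- applyPatch(m1, patch)
  i <- match("LACt", reactionIds(m2))
  expect_equal(reactions(m2)$lb[i], -1000)
  # add_reaction + delete_reaction are no-ops the second time
  patch2 <- list(
    list(op = "add_reaction", target = "DM_pyr",
         arg1 = "pyr_c ->", arg2 = "0,10", arg3 = ""),
    list(op = "delete_reaction", target = "GLY1"),
    list(op = "set_formula", target = "glyc2_c", arg1 = "C6H12O6"),
    list(op = "set_charge", target = "glyc2_c", arg1 = "0"),
    list(op = "set_stoichiometry", target = "ATPM", arg1 = "h_c",
         arg2 = "1"))
  a <- applyPatch(m, patch2)
  b <- applyPatch(a, patch2)
  expect_identical(reactionIds(a), reactionIds(b))
  expect_true(all(abs(stoichMatrix(a) - stoichMatrix(b)) < 1e-12))
  expect_true("DM_pyr" %in% reactionIds(a))
  expect_false("GLY1" %in% reactionIds(a))
  # unresolvable references name the edit index
  bad <- list(list(op = "set_charge", target = "nope_c", arg1 = "1"))
  expect_error(applyPatch(m, bad), "edit 1")
})

test_that("patch TSV files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("op\ttarget\targ1\targ2\targ3",
               "set_bounds\tLACt\t-1000\t1000\t",
               "delete_reaction\tGLY2\t\t\t"), f)
  p <- readPatchTSV(f)
  expect_length(p, 2)
  m <- applyPatch(fxReference(), p)
  expect_false("GLY2" %in% reactionIds(m))
})
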