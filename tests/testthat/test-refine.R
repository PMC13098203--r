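test_that("reaction-score tables are validated on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction\tscore", "PFK\t2.5", "LDH_D\t0.7"), f)
  sc <- readReactionScores(f)
  expect_equal(sc, c(PFK = 2.5, LDH_D = 0.7))
  writeLines(c("reaction\tscore", "PFK\t2.5", "PFK\t1.0"), f)
  expect_error(readReactionScores(f), "duplicated")
  writeLines(c("reaction\tscore", "PFK\thigh"), f)
  expect_error(readReactionScores(f), "non-numeric")
  writeLines(c("rxn\tvalue", "PFK\t1"), f)
  expect_error(readReactionScores(f), "reaction, score")
})

test_that("gap-fill pruning removes exactly the unused gene-less reactions", {
  u <- fxUniversal()
  cdm <- fxCDM()
  d <- deriveStrain(u$model, fullProfile(), "pr1", 3, u$manifest$groups)
  m <- installBiomass(d$model, toyBiomassSpec())
  pre <- solveFBA(m, cdm)@objectiveValue
  pg <- pruneGapfill(m, list(cdm))
  expect_setequal(pg$log$pruned_metabolic,
                  c("FBP_gf", "XYLUR_gf", "ACTPH_gf"))
  expect_identical(pg$log$pruned_exchanges, "EX_dxyl_e")
  # gene-less transporter kept: pyruvate is made by GPR-bearing reactions
  expect_length(pg$log$pruned_transport, 0)
  expect_true("PYRt_gf" %in% reactionIds(pg$model))
  # growth is preserved and no GPR-bearing reaction was touched
  expect_equal(solveFBA(pg$model, cdm)@objectiveValue, pre,
               tolerance = 1e-6)
  gone <- setdiff(reactionIds(m), reactionIds(pg$model))
  expect_true(all(!nzchar(
    reactions(m)$gpr[match(gone, reactionIds(m))])))
  # a model without gap_filled flags passes through unchanged
  clean <- fxReference()
  pg2 <- pruneGapfill(clean, list(cdm))
  expect_identical(reactionIds(pg2$model), reactionIds(clean))
  # an infeasible condition violates the gap-fill guarantee
  noMedium <- simulationCondition()
  expect_error(pruneGapfill(m, list(noMedium)), "infeasible")
})

test_that("scored-but-absent reactions are restored with flags and metabolites", {
  u <- fxUniversal()
  d <- deriveStrain(u$model, fullProfile(), "rs1", 5, u$manifest$groups,
                    injectGapfill = FALSE)
  m <- installBiomass(d$model, toyBiomassSpec())
  expect_false(any(c("GLY1", "GLY2") %in% reactionIds(m)))
  rs <- restoreScoredReactions(m, u$model, d$scores)
  expect_setequal(rs$log$restored, c("GLY1", "GLY2"))
  expect_true(all(hasFlag(rs$model, c("GLY1", "GLY2"),
                          "restored_disconnected")))
  expect_true(all(c("glyc1_c", "glyc2_c") %in% metaboliteIds(rs$model)))
  # all positives already present -> unchanged
  rs2 <- restoreScoredReactions(rs$model, u$model, d$scores)
  expect_length(rs2$log$restored, 0)
  # a scored id missing from the universal is an input error
  expect_error(restoreScoredReactions(m, u$model, c(NOPE = 1)),
               "absent from the universal")
})

test_that("biomass installation swaps the objective and its precursor demands", {
  u <- fxUniversal()
  d <- deriveStrain(u$model, fullProfile(), "bm1", 9, u$manifest$groups,
                    injectGapfill = FALSE)
  m <- installBiomass(d$model, toyBiomassSpec())
  expect_identical(objectiveReaction(m), "BIOMASS_LACTO")
  expect_false("BIOMASS_UNIV" %in% reactionIds(m))
  # idempotent
  m2 <- installBiomass(m, toyBiomassSpec())
  expect_identical(reactionIds(m2), reactionIds(m))
  # the generic biomass demands sulfate; the species-specific one does not,
  # so a sulfate-free medium supports growth only after the swap
  cdmNoSO4 <- fxCDM()
  cdmNoSO4@medium <- cdmNoSO4@medium[names(cdmNoSO4@medium) != "EX_so4_e"]
  cdmNoSO4@overrides[["EX_so4_e"]] <- c(0, 0)
  generic <- d$model
  gGen <- solveFBA(generic, cdmNoSO4)@objectiveValue
  gSpec <- solveFBA(m, cdmNoSO4)@objectiveValue
  expect_lt(gGen, 1e-6)
  expect_gt(gSpec, 0.1)
  # unknown precursor errors with its name
  bad <- toyBiomassSpec()
  bad$stoich <- c(bad$stoich, missing_c = -1)
  expect_error(installBiomass(d$model, bad), "missing_c")
})

test_that("full refinement improves gene coverage and is deterministic", {
  u <- fxUniversal()
  cdm <- fxCDM()
  co <- fxCohort()
  for (k in c(1, 20, 40)) {
    draft <- co$raw$strains[[k]]$model
    refined <- co$refined[[k]]
    nGf <- function(m) sum(vapply(reactions(m)$flags, function(f)
      "gap_filled" %in% f, logical(1)))
    nGpr <- function(m) sum(nzchar(reactions(m)$gpr))
    expect_lt(nGf(refined), nGf(draft))
    expect_gte(nGpr(refined), nGpr(draft))
    # refined strains share at least as many reactions with the reference
    ref <- fxReference()
    shared <- function(m) length(intersect(reactionIds(m), reactionIds(ref)))
    expect_gte(shared(refined), shared(draft))
  }
  # byte-identical SBML across two independent refinement runs
  s <- co$raw$strains[[1]]
  r1 <- refineStrain(s$model, u$model, s$scores, list(cdm),
                     toyBiomassSpec())$model
  r2 <- refineStrain(s$model, u$model, s$scores, list(cdm),
                     toyBiomassSpec())$model
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeSBML(r1, f1); writeSBML(r2, f2)
  expect_identical(readBin(f1, "raw", 5e6), readBin(f2, "raw", 5e6))
})
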