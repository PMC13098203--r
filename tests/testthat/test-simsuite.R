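test_that("CDM carbon bounds follow the C-mol equivalent rule", {
  expect_equal(buildCDM("EX_glc__D_e", 6)@medium[["EX_glc__D_e"]], 20)
  expect_equal(buildCDM("EX_lcts_e", 12)@medium[["EX_lcts_e"]], 10)
  expect_equal(buildCDM("EX_rib__D_e", 5)@medium[["EX_rib__D_e"]], 24)
  expect_error(buildCDM("EX_glc__D_e", 0), "carbons")
  cdm <- buildCDM("EX_glc__D_e", 6)
  expect_true(all(cdm@medium[names(cdm@medium) != "EX_glc__D_e"] == 1))
  expect_setequal(cdm@unconstrained, c("EX_h2o_e", "EX_h_e"))
})

test_that("fermentation profiles shift from mixed-acid to homolactate with the PFL cap", {
  m <- fxReference()
  fp <- fermentationProfile(m, fxCDM())
  expect_true(all(c("for", "ac", "etoh") %in% fp$main_products))
  expect_gt(fp$secretion[["EX_for_e"]],
            10 * max(fp$secretion[["EX_lac__D_e"]], 1e-9))
  homo <- buildCDM("EX_glc__D_e", 6, overrides = homolactateOverrides())
  fph <- fermentationProfile(m, homo)
  expect_gt(fph$secretion[["EX_lac__D_e"]],
            sum(fph$secretion) - fph$secretion[["EX_lac__D_e"]])
  expect_lt(fph$growth_rate, fp$growth_rate)
  # a cysteine auxotroph on free amino acids secretes no byproducts
  aux <- fxStrainWithProfile(c(sulfate_assimilation = FALSE,
                               leucine_synthesis = FALSE,
                               arginine_deiminase = FALSE))
  expect_length(fermentationProfile(aux, fxCDM())$byproducts, 0)
})

test_that("PFL scans are monotone and saturate at the unconstrained profile", {
  m <- fxReference()
  cdm <- fxCDM()
  ps <- pflScan(m, cdm, grid = c(0.1, 1, 5, 20, 40, 60))
  expect_true(all(diff(ps$growth_rate) >= -1e-9))
  free <- solvePFBA(m, cdm)
  expect_equal(ps$growth_rate[nrow(ps)], free@objectiveValue,
               tolerance = 1e-6)
  expect_equal(ps$EX_for_e[nrow(ps)], free@fluxes[["EX_for_e"]],
               tolerance = 1e-5)
  # lactate dominates at the 0.1 cap
  expect_gt(ps$EX_lac__D_e[1], 30)
  expect_error(pflScan(m, cdm, pfl = "NOPE"), "absent")
})

test_that("leave-one-out essentiality applies the 10% rule and the sulfate linkage", {
  cdm <- fxCDM()
  proto <- fxReference()
  es <- essentialityScan(proto, cdm)
  pick <- function(df, comp) df[df$component == comp, ]
  expect_true(pick(es, "EX_glu__L_e")$essential)   # no glutamate synthesis
  expect_true(pick(es, "EX_met__L_e")$essential)
  expect_false(pick(es, "EX_cys__L_e")$essential)  # sulfate assimilation
  expect_false(pick(es, "EX_so4_e")$essential)     # free cysteine suffices
  # knocking out the sulfate-assimilation lump flips cysteine essentiality
  ko <- setBounds(proto, "SULFAS_L", 0, 0)
  expect_true(pick(essentialityScan(ko, cdm, "EX_cys__L_e"),
                   "EX_cys__L_e")$essential)
  aux <- fxStrainWithProfile(c(sulfate_assimilation = FALSE))
  expect_true(pick(essentialityScan(aux, cdm, "EX_cys__L_e"),
                   "EX_cys__L_e")$essential)
  # a component without an exchange reaction cannot be phantom-essential
  es2 <- essentialityScan(proto, cdm, "EX_unobtainium_e")
  expect_equal(es2$relative_growth, 1)
  expect_false(es2$essential)
})

test_that("casein growth is cysteine-limited and restored by free cysteine", {
  aux <- fxStrainWithProfile(c(sulfate_assimilation = FALSE))
  spec <- caseinSpec()
  m <- attachCasein(aux, spec)
  cdmL <- buildCDM("EX_lcts_e", 12)
  milk <- buildMilkCDM("EX_lcts_e", 12)
  gref <- solvePFBA(aux, cdmL)@objectiveValue
  gmilk <- solvePFBA(m, milk)@objectiveValue
  expect_lt(gmilk, 0.5 * gref)
  # hand-written cysteine balance: growth x (cys biomass fraction) equals
  # the peptide cysteine supply (uptake bound x casein cys fraction)
  cysSupply <- spec$uptake_bound * spec$fractions[["cys__L"]]
  expect_equal(gmilk * 0.05, cysSupply, tolerance = 1e-6)
  # supplementing free cysteine at the CDM level restores growth exactly
  milkCys <- buildMilkCDM("EX_lcts_e", 12, extra = c(EX_cys__L_e = 1))
  gcys <- solvePFBA(m, milkCys)@objectiveValue
  expect_equal(gcys, gref, tolerance = 1e-6)
  # a prototroph keeps near-reference growth on plain casein
  proto <- attachCasein(fxReference(), spec)
  gproto <- solvePFBA(proto, milk)@objectiveValue
  grefp <- solvePFBA(fxReference(), cdmL)@objectiveValue
  expect_gt(gproto, 0.9 * grefp)
  # attach/detach restores the original model
  back <- detachCasein(m)
  expect_identical(reactionIds(back), reactionIds(aux))
  expect_identical(metaboliteIds(back), metaboliteIds(aux))
  # a missing amino acid is reported by name
  bad <- caseinSpec(data.frame(amino_acid = c("glu__L", "trp__L"),
                               fraction = c(0.9, 0.1)))
  expect_error(attachCasein(aux, bad), "trp__L")
})

test_that("catabolic capacity requires both ATP gain and nutrient uptake", {
  m <- fxReference()
  arg <- catabolicCapacity(m, "EX_arg__L_e")
  expect_true(arg$capable)
  expect_equal(arg$atp_flux, 1, tolerance = 1e-6)  # 1 ATP per arginine
  noADI <- fxStrainWithProfile(c(arginine_deiminase = FALSE))
  expect_false(catabolicCapacity(noADI, "EX_arg__L_e")$capable)
  expect_false(catabolicCapacity(m, "EX_h2o_e")$capable)
  expect_false(catabolicCapacity(m, "EX_absent_e")$capable)
  # citrate requires the lyase
  expect_true(catabolicCapacity(m, "EX_cit_e")$capable)
  noLyase <- fxStrainWithProfile(c(citrate_lyase = FALSE))
  expect_false(catabolicCapacity(noLyase, "EX_cit_e")$capable)
})

test_that("restricting transport to the maltose PTS reproduces maltose incapacity", {
  m <- fxReference()
  cdmM <- buildCDM("EX_malt_e", 12)
  g0 <- solvePFBA(m, cdmM)@objectiveValue
  only_pts <- restrictTransport(m, "malt_e", keep = "MALTpts")
  g1 <- solvePFBA(only_pts, cdmM)@objectiveValue
  expect_equal(g1, g0, tolerance = 1e-6)  # PTS route is the optimal one
  noPTS <- fxStrainWithProfile(c(maltose_pts = FALSE))
  gn <- solvePFBA(noPTS, cdmM)@objectiveValue
  expect_gt(gn, 0.1)                       # ABC route still works
  only_abc_closed <- restrictTransport(noPTS, "malt_e", keep = "MALTabc")
  expect_gt(solvePFBA(only_abc_closed, cdmM)@objectiveValue, 0.1)
  expect_error(restrictTransport(noPTS, "malt_e", keep = "MALTpts"),
               "not a transport reaction")
  # closing the ABC route on a PTS-less strain abolishes maltose growth
  closed <- setBounds(noPTS, "MALTabc", 0, 0)
  gno <- solveFBA(closed, cdmM)
  expect_true(gno@status != "optimal" || gno@objectiveValue < 1e-6)
  # restricting an unrelated transporter leaves glucose growth unchanged
  rg <- restrictTransport(m, "lac__D_e", keep = "LACt")
  expect_equal(solvePFBA(rg, fxCDM())@objectiveValue,
               solvePFBA(m, fxCDM())@objectiveValue, tolerance = 1e-6)
})

test_that("cross-feeding calls require uptake plus a growth gain", {
  co <- fxCohort()
  sub <- co$refined[1:6]
  cdm <- fxCDM()
  mains <- c("EX_lac__D_e", "EX_for_e", "EX_ac_e", "EX_etoh_e")
  xf <- crossfeedScreen(sub, cdm, c(mains, "EX_cit_e"))
  # fermentation end products are never consumed anaerobically
  expect_false(any(xf$consumed[xf$product %in% mains]))
  # citrate is consumed exactly by lyase carriers
  hasLyase <- vapply(sub, function(m) "CITL_L" %in% reactionIds(m),
                     logical(1))
  cit <- xf[xf$product == "EX_cit_e", ]
  expect_identical(cit$consumed, unname(hasLyase[cit$strain]))
  # a leucine auxotroph under scarce leucine takes up the supplement
  aux <- fxStrainWithProfile(c(leucine_synthesis = FALSE))
  scarce <- cdm
  scarce@medium["EX_leu__L_e"] <- 0.1
  xl <- crossfeedScreen(list(aux = aux), scarce, "EX_leu__L_e")
  expect_true(xl$consumed)
  expect_gt(xl$uptake_flux, 0.1)
})
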