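test_that("applying a condition sets exchange bounds as specified", {
  m <- fxReference()
  # empty medium: all exchanges closed to uptake, no growth
  closed <- applyCondition(m, simulationCondition())
  ex <- names(which(classifyReactions(closed) == "exchange"))
  expect_true(all(reactions(closed)$lb[match(ex, reactionIds(closed))] == 0))
  s <- solveFBA(closed)
  expect_true(s@status != "optimal" || s@objectiveValue <= 1e-6)
  # glucose-only medium caps uptake at the stated bound
  cond <- simulationCondition(medium = c(EX_glc__D_e = 20),
                              unconstrained = c("EX_h_e", "EX_h2o_e"))
  mm <- applyCondition(m, cond)
  i <- match("EX_glc__D_e", reactionIds(mm))
  expect_equal(reactions(mm)$lb[i], -20)
  sol <- solveFBA(mm)
  expect_lte(-sol@fluxes[["EX_glc__D_e"]], 20 + 1e-9)
  # missing medium ids are reported, absent override reactions are errors
  cond2 <- simulationCondition(medium = c(EX_nothere_e = 1))
  expect_identical(attr(applyCondition(m, cond2), "missing"), "EX_nothere_e")
  cond3 <- simulationCondition(overrides = list(NOPE = c(0, 1)))
  expect_error(applyCondition(m, cond3), "absent reaction")
  # a PFL cap constrains the flux in the solution
  capped <- fxCDM()
  capped@overrides[["PFL"]] <- c(0, 0.1)
  sc <- solvePFBA(m, capped)
  expect_lte(sc@fluxes[["PFL"]], 0.1 + 1e-9)
})

test_that("toy ATP anchors hold exactly: 3 per glucose mixed-acid, 2 homolactate", {
  m <- fxReference()
  simp <- buildSimplifiedMedium("EX_glc__D_e")
  expect_equal(maxATPYield(m, simp, "EX_glc__D_e", 6), 0.5, tolerance = 1e-6)
  homo <- simp
  homo@overrides <- list(PFL = c(0, 0), PDH = c(0, 0))
  expect_equal(maxATPYield(m, homo, "EX_glc__D_e", 6), 1 / 3,
               tolerance = 1e-5)
  # a strain without xylulokinase extracts nothing from xylose
  crem <- fxStrainWithProfile(c(xylulokinase = FALSE, phosphoketolase = FALSE))
  expect_equal(maxATPYield(crem, buildSimplifiedMedium("EX_xyl__D_e"),
                           "EX_xyl__D_e", 5), 0)
  # galactose: the tagatose-6P route beats the (costed) Leloir route
  tagY <- maxATPYield(m, buildSimplifiedMedium("EX_gal_e"), "EX_gal_e", 6)
  lel <- fxStrainWithProfile(c(tag6p = FALSE, lactose_pts = FALSE))
  lelY <- maxATPYield(lel, buildSimplifiedMedium("EX_gal_e"), "EX_gal_e", 6)
  expect_gt(tagY, lelY + 0.05)
})

test_that("pFBA fixes the FBA optimum and minimizes total flux", {
  m <- fxReference()
  cdm <- fxCDM()
  fba <- solveFBA(m, cdm)
  pfba <- solvePFBA(m, cdm)
  expect_equal(pfba@objectiveValue, fba@objectiveValue, tolerance = 1e-6)
  expect_lte(sum(abs(pfba@fluxes)), sum(abs(fba@fluxes)) + 1e-6)
  # steady-state residuals of returned solutions
  resid <- as.numeric(stoichMatrix(m) %*% pfba@fluxes[reactionIds(m)])
  expect_lt(max(abs(resid)), 1e-6)
  resid2 <- as.numeric(stoichMatrix(m) %*% fba@fluxes[reactionIds(m)])
  expect_lt(max(abs(resid2)), 1e-6)
})

test_that("widening any bound never decreases the FBA optimum", {
  m <- applyCondition(fxReference(), fxCDM())
  base <- solveFBA(m)@objectiveValue
  set.seed(5)
  picks <- sample(length(reactionIds(m)), 25)
  for (i in picks) {
    m2 <- m
    m2@reactions$ub[i] <- m2@reactions$ub[i] + 50
    m2@reactions$lb[i] <- m2@reactions$lb[i] -
      if (m2@reactions$lb[i] <= -1000) 0 else 50
    relaxed <- solveFBA(m2)@objectiveValue
    expect_gte(relaxed, base - 1e-6)
  }
})

test_that("FBA and pFBA agree with an independently formulated LP (HiGHS)", {
  u <- fxUniversal()
  cdm <- fxCDM()
  models <- c(list(fxReference()), unname(fxCohort()$refined[1:10]))
  cases <- lapply(models, function(mm) {
    m <- applyCondition(mm, cdm)
    tr <- Matrix::summary(stoichMatrix(m))
    list(i = as.integer(tr$i), j = as.integer(tr$j), x = as.numeric(tr$x),
         nm = nrow(stoichMatrix(m)), nr = ncol(stoichMatrix(m)),
         lb = reactions(m)$lb, ub = reactions(m)$ub,
         obj = match(objectiveReaction(m), reactionIds(m)))
  })
  inp <- withr::local_tempfile(fileext = ".json")
  outp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cases, inp, auto_unbox = TRUE, digits = NA)
  py <- paste0("
import json, numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix, identity, hstack, vstack
cases = json.load(open('", inp, "'))
res = []
for c in cases:
    nm, nr = c['nm'], c['nr']
    S = coo_matrix((c['x'], (np.array(c['i'])-1, np.array(c['j'])-1)), shape=(nm, nr)).tocsc()
    lb, ub = np.array(c['lb'], dtype=float), np.array(c['ub'], dtype=float)
    obj = np.zeros(nr); obj[c['obj']-1] = -1.0
    r1 = linprog(obj, A_eq=S, b_eq=np.zeros(nm), bounds=list(zip(lb, ub)), method='highs')
    opt = -r1.fun
    # explicit flux-split pFBA: v = vf - vr, minimize sum(vf + vr)
    lb2 = lb.copy(); lb2[c['obj']-1] = max(lb[c['obj']-1], opt*(1-1e-6))
    A = hstack([S, -S]).tocsc()
    nb = [(max(l,0), u if u>0 else 0) for l,u in zip(lb2, ub)]
    rb = [(max(-u,0), -l if l<0 else 0) for l,u in zip(lb2, ub)]
    r2 = linprog(np.ones(2*nr), A_eq=A, b_eq=np.zeros(nm), bounds=nb+rb, method='highs')
    res.append({'fba': opt, 'pfba_total': r2.fun})
json.dump(res, open('", outp, "', 'w'))
")
  system2("python", "-", input = py)
  oracle <- jsonlite::fromJSON(outp)
  for (k in seq_along(models)) {
    fba <- solveFBA(models[[k]], cdm)
    pfba <- solvePFBA(models[[k]], cdm)
    expect_equal(fba@objectiveValue, oracle$fba[k], tolerance = 1e-6)
    expect_equal(sum(abs(pfba@fluxes)), oracle$pfba_total[k],
                 tolerance = 1e-5)
  }
})
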