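# Shared fixtures, built once per test run. Everything is generated in
# code from the toy universe; seeds are fixed so failures reproduce.

.fx <- new.env(parent = emptyenv())

fxUniversal <- function() {
  if (is.null(.fx$uni)) .fx$uni <- buildToyUniversal()
  .fx$uni
}

fxCDM <- function() buildCDM("EX_glc__D_e", 6)

# fully-refined reference strain (all pathways, no injections)
fxReference <- function() {
  if (is.null(.fx$ref)) {
    u <- fxUniversal()
    d <- deriveStrain(u$model, fullProfile(), "toy_ref", 11,
                      u$manifest$groups, withhold = character(),
                      injectGapfill = FALSE)
    .fx$ref <- installBiomass(d$model, toyBiomassSpec())
  }
  .fx$ref
}

# seeded 40-strain cohort, refined; reused across refinement/simulation/
# comparison checks
fxCohort <- function() {
  if (is.null(.fx$cohort)) {
    u <- fxUniversal()
    co <- generateCohort(40, 107, universalBuild = u)
    cdm <- fxCDM()
    refined <- lapply(co$strains, function(s) {
      refineStrain(s$model, u$model, s$scores, list(cdm),
                   toyBiomassSpec())
    })
    .fx$cohort <- list(raw = co,
                       refined = lapply(refined, `[[`, "model"),
                       logs = lapply(refined, `[[`, "log"),
                       labels = co$labels)
  }
  .fx$cohort
}

# derive one strain with a given profile tweak, refined
fxStrainWithProfile <- function(tweaks, seed = 23) {
  u <- fxUniversal()
  p <- fullProfile()
  p[names(tweaks)] <- tweaks
  d <- deriveStrain(u$model, p, paste0("toy_", seed), seed,
                    u$manifest$groups, withhold = character(),
                    injectGapfill = FALSE)
  installBiomass(d$model, toyBiomassSpec())
}

expect_samePartition <- function(a, b) {
  # cluster labels equal up to renaming; b may be unnamed but in a's order
  expect_equal(length(a), length(b))
  if (!is.null(names(b))) b <- b[names(a)]
  tab <- table(a, b)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
}

pythonAvailable <- function() {
  nzchar(Sys.which("python"))
}
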