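## Constraint-based simulation core: FBA / parsimonious FBA on GLPK.
##
## All solves share one deterministic, single-threaded simplex path; flux
## values below FLUX_TOL are treated as zero throughout the package
## (pruning, secretion calls, energy-cycle detection).

FLUX_TOL <- 1e-6
PFBA_RELAX <- 1e-6   # relative slack when fixing the objective for pFBA
UNCONSTRAINED_BOUND <- 1000

glpkStatus <- c(`1` = "undefined", `2` = "feasible", `3` = "infeasible",
                `4` = "nofeasible", `5` = "optimal", `6` = "unbounded")

## rows: equality/steady-state plus any extra inequality rows
solveLP <- function(Si, Sj, Sv, rlb, rub, clb, cub, obj, maximize = TRUE) {
  res <- .Call(sf_glpk_solve, as.integer(Si), as.integer(Sj), as.double(Sv),
               as.double(rlb), as.double(rub), as.double(clb),
               as.double(cub), as.double(obj), as.logical(maximize))
  st <- glpkStatus[as.character(res$status)]
  if (res$ret != 0 && !(st %in% c("optimal", "unbounded", "infeasible",
                                  "nofeasible"))) {
    stop("LP solver failure (glp_simplex code ", res$ret, ", status ", st, ")")
  }
  res$statusName <- switch(st,
    optimal = "optimal",
    unbounded = "unbounded",
    infeasible = ,
    nofeasible = "infeasible",
    "infeasible")
  res
}

lpData <- function(model) {
  S <- model@stoichiometry
  tr <- Matrix::summary(S)  # i, j, x triplets
  list(m = nrow(S), n = ncol(S), i = tr$i, j = tr$j, x = tr$x,
       lb = model@reactions$lb, ub = model@reactions$ub)
}

#' Build a simulation condition
#'
#' @param medium named numeric of maximum uptake magnitudes keyed by
#'   exchange reaction id (mmol/gDW/h).
#' @param unconstrained exchange ids left unbounded (water, protons).
#' @param overrides named list of `c(lb, ub)` bound overrides applied after
#'   the medium.
#' @param objective optional objective reaction id override.
#' @return a [SimulationCondition].
#' @export
simulationCondition <- function(medium = numeric(), unconstrained = character(),
                                overrides = list(), objective = character()) {
  methods::new("SimulationCondition", medium = medium,
               unconstrained = unconstrained, overrides = overrides,
               objectiveOverride = objective)
}

#' Read a medium table (TSV)
#'
#' Columns `exchange_id` and `max_uptake`; rows whose `max_uptake` is `*`
#' join the unconstrained set (water, protons).
#'
#' @param path file path.
#' @return a [SimulationCondition].
#' @export
readMediumTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("exchange_id", "max_uptake")
  if (!all(need %in% names(df))) {
    stop("medium TSV must have columns: ", paste(need, collapse = ", "))
  }
  free <- df$max_uptake == "*"
  simulationCondition(
    medium = stats::setNames(as.numeric(df$max_uptake[!free]),
                             df$exchange_id[!free]),
    unconstrained = df$exchange_id[free]
  )
}

#' Apply a condition to a model
#'
#' Exchanges named in the medium get lower bound `-uptake` (upper bound
#' unchanged); exchanges in the unconstrained set get lower bound -1000;
#' every other exchange is closed to uptake (lower bound 0). Reaction
#' overrides are applied last. Medium ids absent from the model are
#' collected in the `"missing"` attribute of the result (a strain may
#' simply lack a transporter); an override naming an absent reaction is an
#' error, since overrides are deliberate.
#'
#' @param model a [GEM].
#' @param cond a [SimulationCondition].
#' @return constrained copy of `model`, with attribute `missing`.
#' @export
applyCondition <- function(model, cond) {
  ex <- names(which(isExchange(model)))
  model@reactions$lb[model@reactions$id %in% ex] <- 0
  medIds <- names(cond@medium)
  missing <- setdiff(c(medIds, cond@unconstrained), model@reactions$id)
  hit <- intersect(medIds, model@reactions$id)
  i <- match(hit, model@reactions$id)
  model@reactions$lb[i] <- -abs(cond@medium[hit])
  j <- match(intersect(cond@unconstrained, model@reactions$id),
             model@reactions$id)
  model@reactions$lb[j] <- -UNCONSTRAINED_BOUND
  if (length(cond@overrides)) {
    absent <- setdiff(names(cond@overrides), model@reactions$id)
    if (length(absent)) {
      stop("override references absent reaction(s): ",
           paste(absent, collapse = ", "))
    }
    for (rid in names(cond@overrides)) {
      b <- cond@overrides[[rid]]
      model <- setBounds(model, rid, b[1], b[2])
    }
  }
  if (length(cond@objectiveOverride) == 1L &&
      nzchar(cond@objectiveOverride)) {
    if (!(cond@objectiveOverride %in% model@reactions$id)) {
      stop("objective override references absent reaction: ",
           cond@objectiveOverride)
    }
    model@objective <- cond@objectiveOverride
  }
  attr(model, "missing") <- missing
  model
}

newSolution <- function(status, obj = NA_real_, fluxes = numeric()) {
  methods::new("FluxSolution", status = status,
               objectiveValue = obj, fluxes = fluxes)
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction flux subject to steady state
#' (`S v = 0`) and flux bounds.
#'
#' @param model a [GEM] (with an objective, or `cond` must override one).
#' @param cond optional [SimulationCondition] applied first.
#' @return a [FluxSolution].
#' @export
solveFBA <- function(model, cond = NULL) {
  if (!is.null(cond)) model <- applyCondition(model, cond)
  obj <- model@objective
  if (!nzchar(obj)) stop("model has no objective reaction")
  d <- lpData(model)
  cvec <- numeric(d$n)
  cvec[match(obj, model@reactions$id)] <- 1
  res <- solveLP(d$i, d$j, d$x, rlb = numeric(d$m), rub = numeric(d$m),
                 clb = d$lb, cub = d$ub, obj = cvec, maximize = TRUE)
  if (res$statusName != "optimal") return(newSolution(res$statusName))
  newSolution("optimal", res$objval,
              stats::setNames(res$x, model@reactions$id))
}

#' Parsimonious FBA
#'
#' Two-stage solve: the FBA optimum is computed, the objective flux is
#' fixed at `(1 - 1e-6)` of it, and total absolute flux is minimized with
#' split forward/reverse variables. The reported `objectiveValue` is the
#' FBA optimum.
#'
#' @inheritParams solveFBA
#' @return a [FluxSolution] with the flux-minimal distribution.
#' @export
solvePFBA <- function(model, cond = NULL) {
  if (!is.null(cond)) model <- applyCondition(model, cond)
  fba <- solveFBA(model)
  if (fba@status != "optimal") return(fba)
  opt <- fba@objectiveValue
  d <- lpData(model)
  oi <- match(model@objective, model@reactions$id)
  lb <- d$lb
  ub <- d$ub
  floorv <- if (opt >= 0) opt * (1 - PFBA_RELAX) else opt * (1 + PFBA_RELAX)
  lb[oi] <- max(lb[oi], floorv)
  ## columns: v (n) then t (n) with t_j >= |v_j|;
  ## rows: m steady-state equalities, then t - v >= 0 and t + v >= 0
  n <- d$n; m <- d$m
  i2 <- c(d$i, m + seq_len(n), m + seq_len(n),
          m + n + seq_len(n), m + n + seq_len(n))
  j2 <- c(d$j, seq_len(n), n + seq_len(n), seq_len(n), n + seq_len(n))
  x2 <- c(d$x, rep(-1, n), rep(1, n), rep(1, n), rep(1, n))
  rlb <- c(numeric(m), numeric(2 * n))
  rub <- c(numeric(m), rep(Inf, 2 * n))
  clb <- c(lb, numeric(n))
  cub <- c(ub, rep(Inf, n))
  cvec <- c(numeric(n), rep(1, n))
  res <- solveLP(i2, j2, x2, rlb, rub, clb, cub, cvec, maximize = FALSE)
  if (res$statusName != "optimal") {
    stop("pFBA stage-2 solve not optimal (status ", res$statusName, ")")
  }
  newSolution("optimal", opt,
              stats::setNames(res$x[seq_len(n)], model@reactions$id))
}

#' Growth call under the 10% rule
#'
#' A simulation is called non-growing when its growth rate falls below 10%
#' of the reference (standard-condition) rate; residual catabolism of
#' single amino acids can otherwise masquerade as growth.
#'
#' @param growth_rate observed rate (h^-1).
#' @param reference_rate rate under the standard condition (h^-1, > 0).
#' @return list with `growth_rate`, `reference_rate`, `growing`.
#' @export
growthCall <- function(growth_rate, reference_rate) {
  stopifnot(reference_rate > 0)
  list(growth_rate = growth_rate, reference_rate = reference_rate,
       growing = growth_rate >= 0.10 * reference_rate)
}

#' Maximum ATP yield on a substrate (mol ATP per C-mol)
#'
#' Swaps the objective to an ATP-maintenance hydrolysis reaction
#' (atp + h2o -> adp + pi + h; added when absent), maximizes its flux
#' under `cond`, and normalizes by carbon uptake:
#' `yield = v_ATPM / (carbons x substrate uptake)`.
#' The condition is expected to be a simplified medium (no amino acids /
#' vitamins) so that all ATP derives from the substrate.
#'
#' @param model a [GEM].
#' @param cond a [SimulationCondition] whose medium contains
#'   `substrate_exchange`.
#' @param substrate_exchange exchange reaction id of the carbon source.
#' @param carbons carbon atoms per substrate molecule (>= 1).
#' @param atpm id of the maintenance reaction.
#' @return ATP yield (0 when there is no uptake or no ATP optimum).
#' @export
maxATPYield <- function(model, cond, substrate_exchange, carbons,
                        atpm = "ATPM") {
  stopifnot(carbons >= 1)
  if (!(substrate_exchange %in% model@reactions$id)) {
    stop("substrate exchange absent from model: ", substrate_exchange)
  }
  if (!(atpm %in% model@reactions$id)) {
    model <- addReaction(model, atpm,
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      name = "ATP maintenance", lb = 0, ub = UNCONSTRAINED_BOUND)
  }
  cond@objectiveOverride <- atpm
  sol <- solvePFBA(model, cond)
  if (sol@status != "optimal" || sol@objectiveValue <= FLUX_TOL) return(0)
  uptake <- -sol@fluxes[[substrate_exchange]]
  if (uptake <= FLUX_TOL) return(0)
  sol@objectiveValue / (carbons * uptake)
}
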