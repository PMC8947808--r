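# Brute-force isotopomer reference model. Enumerates every isotopomer of
# every tracked metabolite and builds the full isotopomer balances directly
# from the reaction atom maps, with no cumomer/EMU machinery. Used as an
# independent cross-check of the cascade and collocation pipelines on small
# networks (<= ~12 total carbons).

# Precompute, per reaction and product occurrence, the reactant-side
# pattern-extraction tables used to evaluate production rates.
isotopomerModel <- function(net) {
  if (!net@split) net <- splitReversible(net)
  mets <- stateMets(net)
  metNames <- mets$name
  nC <- setNames(mets$n_carbons, metNames)
  roles <- setNames(net@metabolites$role, net@metabolites$name)
  terms <- list()
  for (r in net@reactions) {
    for (pi in seq_along(r$products)) {
      pmet <- r$products[[pi]]$met
      if (!pmet %in% metNames) next
      np <- nC[[pmet]]
      groups <- preimageGroups(r, pi, seq_len(np))
      gInfo <- lapply(groups, function(g) {
        # for each product pattern 0..2^np-1, the required label pattern on
        # the group's reactant atoms (as a reactant-local mask)
        prodPos <- vapply(g$atoms, function(a) {
          letter <- r$reactants[[g$occ]]$atoms[a]
          match(letter, r$products[[pi]]$atoms)
        }, integer(1))
        Sp <- 0:(2^np - 1L)
        req <- integer(length(Sp))
        for (bi in seq_along(g$atoms)) {
          has <- bitwAnd(Sp, bitwShiftL(1L, prodPos[bi] - 1L)) != 0L
          req[has] <- bitwOr(req[has], bitwShiftL(1L, g$atoms[bi] - 1L))
        }
        list(met = g$met, mask = atomsToMask(g$atoms), req = req)
      })
      terms[[length(terms) + 1L]] <- list(
        rxn = r$id, met = pmet, coeff = r$products[[pi]]$coeff, groups = gInfo)
    }
  }
  cons <- list()
  for (r in net@reactions) {
    for (term in r$reactants) {
      if (!term$met %in% metNames || roles[[term$met]] != "balanced") next
      cons[[length(cons) + 1L]] <- list(rxn = r$id, met = term$met,
                                        coeff = term$coeff)
    }
  }
  list(net = net, mets = metNames, nC = nC, roles = roles,
       terms = terms, cons = cons)
}

# production rates of every metabolite's isotopomers given current
# distributions (list of per-metabolite vectors) and fluxes
oracleProduction <- function(model, isoList, v) {
  prod <- lapply(model$mets, function(m) numeric(2^model$nC[[m]]))
  names(prod) <- model$mets
  for (tm in model$terms) {
    rate <- v[[tm$rxn]] * tm$coeff
    if (rate == 0) next
    np <- model$nC[[tm$met]]
    contrib <- rep(rate, 2^np)
    for (g in tm$groups) {
      isoR <- isoList[[g$met]]
      idx <- bitwAnd(seq_along(isoR) - 1L, g$mask)
      marg <- rowsum(isoR, idx)              # sums by masked pattern
      lookup <- setNames(as.numeric(marg), rownames(marg))
      contrib <- contrib * lookup[as.character(g$req)]
    }
    prod[[tm$met]] <- prod[[tm$met]] + contrib
  }
  prod
}

oracleConsumptionRate <- function(model, v) {
  out <- setNames(numeric(length(model$mets)), model$mets)
  for (cn in model$cons) out[[cn$met]] <- out[[cn$met]] + v[[cn$rxn]] * cn$coeff
  out
}

# initial isotopomer distributions from the tracer specification
oracleInitial <- function(model, tracers = model$net@tracers,
                          natAbundance = model$net@natAbundance) {
  bySub <- split(tracers, vapply(tracers, `[[`, character(1), "substrate"))
  out <- list()
  for (m in model$mets) {
    n <- model$nC[[m]]
    comps <- bySub[[m]]
    if (is.null(comps))
      comps <- list(list(fraction = 1, positions = integer(0), enrichment = 0))
    iso <- numeric(2^n)
    for (comp in comps) {
      f <- comp$fraction %||% 1
      e <- componentEnrichment(comp, n, natAbundance)
      iso <- iso + f * isoFromEnrichment(e)
    }
    out[[m]] <- iso / sum(iso)
  }
  out
}

isoFromEnrichment <- function(e) {
  n <- length(e)
  iso <- numeric(2^n)
  for (S in 0:(2^n - 1L)) {
    p <- 1
    for (a in seq_len(n))
      p <- p * if (bitwAnd(S, bitwShiftL(1L, a - 1L)) != 0L) e[a] else 1 - e[a]
    iso[S + 1L] <- p
  }
  iso
}

#' Brute-force isotopomer steady state
#'
#' Solves the full isotopomer balances by fixed-point iteration
#' `x <- production(x) / consumption`, independent of the cumomer/EMU
#' cascade. Only practical for small networks.
#'
#' @param net an [MFANetwork-class].
#' @param v named flux vector.
#' @param tol convergence tolerance on the max absolute update.
#' @param maxit iteration limit.
#' @return named list of per-metabolite isotopomer vectors (bitmask order).
#' @export
oracleSteadyState <- function(net, v, tol = 1e-13, maxit = 20000L) {
  model <- isotopomerModel(net)
  iso <- oracleInitial(model)
  consRate <- oracleConsumptionRate(model, v)
  balanced <- model$mets[model$roles[model$mets] == "balanced"]
  if (any(consRate[balanced] <= 0))
    stopf("balanced metabolite with zero consumption flux")
  for (it in seq_len(maxit)) {
    prod <- oracleProduction(model, iso, v)
    delta <- 0
    for (m in balanced) {
      newIso <- prod[[m]] / consRate[[m]]
      delta <- max(delta, max(abs(newIso - iso[[m]])))
      iso[[m]] <- newIso
    }
    if (delta < tol) return(iso)
  }
  stopf("isotopomer fixed point did not converge (last update %g)", delta)
}

#' Brute-force isotopomer trajectory
#'
#' Integrates the full isotopomer ODEs with the adaptive stiff integrator,
#' independent of the cumomer/EMU machinery.
#'
#' @param net an [MFANetwork-class].
#' @param v named flux vector.
#' @param pmet named metabolite pool sizes.
#' @param times output time points.
#' @return list with `times` and `iso`: a list (per time) of per-metabolite
#'   isotopomer vectors.
#' @export
oracleTrajectory <- function(net, v, pmet, times) {
  model <- isotopomerModel(net)
  iso0 <- oracleInitial(model)
  balanced <- model$mets[model$roles[model$mets] == "balanced"]
  consRate <- oracleConsumptionRate(model, v)
  sizes <- vapply(model$mets, function(m) 2^model$nC[[m]], numeric(1))
  offs <- cumsum(c(0, sizes))
  pack <- function(isoList) unlist(isoList[model$mets], use.names = FALSE)
  unpack <- function(y) {
    out <- list()
    for (i in seq_along(model$mets))
      out[[model$mets[i]]] <- y[(offs[i] + 1L):offs[i + 1L]]
    out
  }
  dfun <- function(t, y, parms) {
    isoList <- unpack(y)
    prod <- oracleProduction(model, isoList, v)
    dy <- numeric(length(y))
    for (i in seq_along(model$mets)) {
      m <- model$mets[i]
      if (!m %in% balanced) next
      rng <- (offs[i] + 1L):offs[i + 1L]
      dy[rng] <- (prod[[m]] - consRate[[m]] * isoList[[m]]) / pmet[[m]]
    }
    list(dy)
  }
  sol <- deSolve::lsoda(y = pack(iso0), times = times, func = dfun,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  list(times = times,
       iso = lapply(seq_along(times), function(i)
         unpack(as.numeric(sol[i, -1]))))
}

#' Fragment MIDs from an isotopomer distribution
#'
#' @param iso isotopomer vector of one metabolite (bitmask order).
#' @param atoms fragment atom positions.
#' @return numeric MID of length `length(atoms) + 1`.
#' @export
isotopomerMid <- function(iso, atoms) {
  rowSums(tandemMid(iso, atoms))
}
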