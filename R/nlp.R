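# Assembly of the steady-state and isotopically nonstationary estimation
# problems. The equality constraints of the weighted least-squares fit
# (balances or transcribed dynamics, S v = 0, pool mapping, scaling ties,
# measurement mapping, zero-order pins, initial conditions) are eliminated
# exactly when the objective is evaluated: fluxes move inside the affine
# space {v : S v = 0, fixed fluxes}, the labeling states are solved from the
# balances level by level, and scaling factors are profiled analytically.
# The remaining reduced problem is a box-bounded nonlinear least squares in
# (free-flux coordinates, log pool sizes).

nullSpaceParam <- function(net) {
  S <- as.matrix(stoichMatrix(net))
  bd <- fluxBounds(net)
  fixed <- which(is.finite(bd$lb) & bd$lb == bd$ub)
  Aeq <- S; rhs <- rep(0, nrow(S))
  if (length(fixed)) {
    E <- matrix(0, length(fixed), ncol(S))
    E[cbind(seq_along(fixed), fixed)] <- 1
    Aeq <- rbind(S, E); rhs <- c(rhs, bd$lb[fixed])
  }
  sv <- svd(Aeq, nu = nrow(Aeq), nv = ncol(Aeq))   # full SVD: V spans R^n
  tol <- 1e-10 * max(sv$d)
  r <- sum(sv$d > tol)
  # minimum-norm particular solution
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  coef <- dinv * crossprod(sv$u[, seq_along(sv$d), drop = FALSE], rhs)
  v0 <- sv$v[, seq_along(sv$d), drop = FALSE] %*% coef
  N <- sv$v[, seq_len(ncol(sv$v)) > r, drop = FALSE]
  list(v0 = as.numeric(v0), N = N, ids = bd$ids, lb = bd$lb, ub = bd$ub,
       nFreeFlux = ncol(N))
}

#' Assemble the steady-state MFA estimation problem
#'
#' Encodes the steady-state fit: flux residuals and labeling-measurement
#' residuals weighted by their standard deviations, subject to the balance
#' equalities, stoichiometric constraints, flux bounds and inequality rows,
#' scaling-factor ties and the measurement mapping.
#'
#' @param net a split [MFANetwork-class].
#' @param arrays a [ModelArrays-class].
#' @param mm a [MeasurementModel-class] with measured values (steady state:
#'   `time` all `NA`).
#' @param options list: `scalingsFree` (default FALSE: complete normalized
#'   MIDs, all scaling factors fixed to 1), `penalty` (weight of the
#'   inequality penalty residuals, default 1e4).
#' @return an [NLPProblem-class].
#' @export
assembleSteadyNLP <- function(net, arrays, mm, options = list()) {
  if (arrays@framework != mm@framework)
    stopf("arrays and measurement model use different frameworks")
  if (nrow(mm@meas) == 0) stopf("no measured values attached")
  if (any(!is.na(mm@meas$time)))
    stopf("steady-state problem but measurements carry times; use assembleInstNLP")
  states <- arrays@states
  pools <- buildPoolModel(net, states)
  input <- buildInputVector(net, states)
  reduced <- c(nullSpaceParam(net),
               list(options = mergeOptions(options),
                    Rineq = net@Rineq, bineq = net@bineq))
  new("NLPProblem", kind = "steady", net = net, arrays = arrays, mm = mm,
      input = input, pools = pools, grid = NULL, scheme = NULL,
      reduced = reduced)
}

#' Assemble the isotopically nonstationary MFA estimation problem
#'
#' Encodes the nonstationary fit: labeling residuals at the measurement
#' times plus optional flux and pool-size residuals, subject to the
#' collocation-transcribed labeling dynamics, the pool mapping
#' `p_k = D p_met`, stoichiometric constraints, scaling ties, interpolation
#' and measurement mapping rows, zero-order pins, initial conditions and all
#' bounds.
#'
#' @param net a split [MFANetwork-class].
#' @param arrays a [ModelArrays-class].
#' @param pools a [PoolModel-class].
#' @param mm a [MeasurementModel-class] with timed measured values.
#' @param grid a [TimeGrid-class] spanning all measurement times.
#' @param scheme a [CollocationScheme-class] (see [radauIIA()]).
#' @param options as in [assembleSteadyNLP()]; for nonstationary data free
#'   scalings are per fragment and time.
#' @return an [NLPProblem-class].
#' @export
assembleInstNLP <- function(net, arrays, pools, mm, grid,
                            scheme = radauIIA(3), options = list()) {
  if (arrays@framework != mm@framework)
    stopf("arrays and measurement model use different frameworks")
  if (nrow(mm@meas) == 0) stopf("no measured values attached")
  if (any(is.na(mm@meas$time)))
    stopf("nonstationary problem but some measurements carry no time")
  tmu <- mm@times
  if (any(tmu <= grid@nodes[1]) || any(tmu > grid@nodes[length(grid@nodes)] + 1e-9))
    stopf("measurement time outside the transcription grid (%g, %g]",
          grid@nodes[1], grid@nodes[length(grid@nodes)])
  states <- arrays@states
  input <- buildInputVector(net, states)
  reduced <- c(nullSpaceParam(net),
               list(options = mergeOptions(options),
                    Rineq = net@Rineq, bineq = net@bineq))
  new("NLPProblem", kind = "inst", net = net, arrays = arrays, mm = mm,
      input = input, pools = pools, grid = grid, scheme = scheme,
      reduced = reduced)
}

mergeOptions <- function(options) {
  utils::modifyList(list(scalingsFree = FALSE, penalty = 1e4,
                         feasTol = 1e-7), options)
}

# profiled optimal scaling factor per group: residual (h * value - sim)/sd
profileScalings <- function(value, sim, sd, group, free) {
  if (!free) return(rep(1, length(value)))
  num <- tapply(value * sim / sd^2, group, sum)
  den <- tapply(value^2 / sd^2, group, sum)
  h <- ifelse(den > 0, num / den, 1)
  h <- pmax(as.numeric(h), 1e-12)
  as.numeric(h[match(group, names(num))])
}

# parameter vector layout: [u (free flux coords), log pools (inst only)]
thetaLayout <- function(problem) {
  nu <- problem@reduced$nFreeFlux
  if (problem@kind == "inst") {
    mets <- problem@pools@mets
    list(nu = nu, poolMets = mets, n = nu + length(mets))
  } else list(nu = nu, poolMets = character(0), n = nu)
}

thetaFromStart <- function(problem, start) {
  red <- problem@reduced
  lay <- thetaLayout(problem)
  v <- start$v[red$ids]
  if (anyNA(v)) stopf("start flux vector missing reactions")
  u <- as.numeric(crossprod(red$N, v - red$v0))
  if (length(lay$poolMets)) {
    p <- start$pools[lay$poolMets]
    if (anyNA(p)) stopf("start pool vector missing metabolites")
    c(u, log(as.numeric(p)))
  } else u
}

# inverse of thetaFromStart: reduced parameter vector -> start list
startFromTheta <- function(problem, theta) {
  red <- problem@reduced
  lay <- thetaLayout(problem)
  v <- as.numeric(red$v0 + red$N %*% theta[seq_len(lay$nu)])
  names(v) <- red$ids
  out <- list(v = v)
  if (length(lay$poolMets))
    out$pools <- setNames(exp(theta[lay$nu + seq_along(lay$poolMets)]),
                          lay$poolMets)
  out
}

thetaBounds <- function(problem) {
  lay <- thetaLayout(problem)
  lower <- rep(-Inf, lay$n); upper <- rep(Inf, lay$n)
  if (length(lay$poolMets)) {
    b <- problem@pools@bounds
    i <- match(lay$poolMets, b$metabolite)
    lower[lay$nu + seq_along(i)] <- log(b$lb[i])
    upper[lay$nu + seq_along(i)] <- log(b$ub[i])
  }
  list(lower = lower, upper = upper)
}

# core model evaluation at a parameter vector: returns fluxes, pools,
# simulated measurements, profiled scalings, objective residuals and
# penalty residuals
evaluateProblem <- function(problem, theta) {
  red <- problem@reduced
  lay <- thetaLayout(problem)
  u <- theta[seq_len(lay$nu)]
  v <- as.numeric(red$v0 + red$N %*% u)
  names(v) <- red$ids
  pmet <- NULL
  meas <- problem@mm@meas
  if (problem@kind == "steady") {
    x <- solveSteadyState(problem@arrays, v, problem@input)
    sims <- as.numeric(problem@mm@M %*% x)[meas$channel]
    group <- problem@mm@channels$fragment[meas$channel]
    extra <- NULL
  } else {
    pmet <- setNames(exp(theta[lay$nu + seq_along(lay$poolMets)]), lay$poolMets)
    ts <- transcribe(problem@arrays, problem@grid, problem@scheme)
    pstate <- as.numeric(problem@pools@D %*% pmet[problem@pools@mets])
    sol <- solveTranscribed(ts, v, pstate, problem@input)
    xmu <- interpolateAt(sol, ts, problem@mm@times)
    simsAll <- problem@mm@M %*% Matrix::t(xmu)  # channels x times
    ti <- match(meas$time, problem@mm@times)
    sims <- as.numeric(simsAll[cbind(meas$channel, ti)])
    group <- paste(problem@mm@channels$fragment[meas$channel], meas$time)
    extra <- list(sol = sol, ts = ts, xmu = xmu)
  }
  h <- profileScalings(meas$value, sims, meas$sd, group,
                       red$options$scalingsFree)
  rMeas <- (h * meas$value - sims) / meas$sd
  # flux measurement residuals
  fm <- problem@net@fluxMeas
  rFlux <- if (nrow(fm)) (fm$value - v[fm$reaction]) / fm$sd else numeric(0)
  # pool measurement residuals
  pm <- problem@pools@meas
  rPool <- if (!is.null(pmet) && nrow(pm))
    (pm$value - pmet[pm$metabolite]) / pm$sd else numeric(0)
  # inequality and bound penalties, scaled to dominate the measurement
  # weights so bound violations are never traded for fit quality
  pen <- (sqrt(red$options$penalty) / min(meas$sd)) * c(
    pmax(0, red$lb[is.finite(red$lb)] - v[is.finite(red$lb)]),
    pmax(0, v[is.finite(red$ub)] - red$ub[is.finite(red$ub)]),
    if (!is.null(red$Rineq)) pmax(0, as.numeric(red$Rineq %*% v) - red$bineq))
  list(v = v, pools = pmet, sims = sims, h = h, group = group,
       rMeas = rMeas, rFlux = rFlux, rPool = rPool, pen = pen,
       z = sum(rMeas^2) + sum(rFlux^2) + sum(rPool^2), extra = extra)
}

#' Dimensions of the full (unreduced) estimation problem
#'
#' Counts the variables and equality constraints of the fit as posed before
#' elimination. Steady state: variables are fluxes, states, simulated
#' measurements and (if free) fragment and measurement scaling factors;
#' equality constraints are the balances of unpinned states, the
#' stoichiometric rows, scaling ties, measurement mapping rows and pins of
#' the pinned states. Nonstationary: additionally the metabolite pools,
#' node/stage/stage-derivative variables and interpolated states, with the
#' three transcription families, the pool mapping, interpolation rows,
#' per-time scaling ties and initial conditions.
#'
#' @param problem an [NLPProblem-class].
#' @return list with `nVariables` and `nEqualities`.
#' @export
problemDimensions <- function(problem) {
  st <- problem@arrays@states@states
  n <- nrow(st); nFree <- sum(!st$pinned); nPin <- n - nFree
  nrx <- length(problem@reduced$ids)
  S <- stoichMatrix(problem@net)
  nMeas <- nrow(problem@mm@meas)
  nFrag <- nrow(problem@mm@fragments)
  free <- problem@reduced$options$scalingsFree
  if (problem@kind == "steady") {
    nVars <- nrx + n + nMeas + if (free) nFrag + nMeas else 0
    nEq <- nFree + nrow(S) + nMeas + nPin +
      (if (free) nMeas else 0)            # U ties
    list(nVariables = as.integer(nVars), nEqualities = as.integer(nEq))
  } else {
    G <- length(problem@grid@h); s <- problem@scheme@s
    nT <- length(problem@mm@times)
    nPool <- length(problem@pools@mets)
    nVars <- nrx + nPool + nFree +                   # v, p_met, p_k
      n * (1 + G * (2 * s + 1)) +                    # x nodes, K, k
      nT * n + nMeas +                               # x_mu, m_nmu
      if (free) nFrag * nT + nMeas else 0
    nEq <- G * s * n * 2 + G * n +                   # three families
      nFree +                                        # p_k = D p_met
      nrow(S) + nT * n + nMeas +                     # S v, interpolation, M
      (G + 1) * nPin + n +                           # pins, x_0 = x_inp
      (if (free) nMeas else 0)
    list(nVariables = as.integer(nVars), nEqualities = as.integer(nEq))
  }
}
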