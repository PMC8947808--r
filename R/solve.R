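# Reduced solve of the estimation problem: Levenberg-Marquardt on the
# box-bounded nonlinear least squares remaining after exact elimination of
# the equality constraints.

#' Solve an assembled estimation problem
#'
#' Minimizes the variance-weighted sum of squared residuals over the reduced
#' parameters (free-flux coordinates and, for nonstationary problems, log
#' pool sizes) with the Levenberg-Marquardt algorithm. Every candidate point
#' satisfies the model equality constraints exactly by construction (the
#' balances/transcribed dynamics are solved level by level, scaling ties and
#' measurement mappings are substituted, and fluxes stay in the affine space
#' of the stoichiometric constraints); flux bounds and inequality rows enter
#' as penalty residuals and are verified a posteriori against the
#' feasibility tolerance.
#'
#' @param problem an [NLPProblem-class].
#' @param start list with named `v` (fluxes, on the affine constraint space)
#'   and, for nonstationary problems, `pools`; e.g. one draw from
#'   [sampleFeasibleFluxesPools()].
#' @param tol feasibility tolerance for the returned point (default 1e-7).
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @param sdStages homotopy schedule: the fit is solved repeatedly with the
#'   measurement standard deviations inflated by these factors, each stage
#'   warm-starting the next. The default widens the basin of attraction from
#'   poor random starts; `1` alone disables the homotopy.
#' @return an [MFAFit-class].
#' @export
solveNLP <- function(problem, start, tol = 1e-7,
                     control = list(maxiter = 200), sdStages = c(25, 1)) {
  theta0 <- thetaFromStart(problem, start)
  bounds <- thetaBounds(problem)
  theta0 <- pmin(pmax(theta0, bounds$lower), bounds$upper)
  ctrl <- do.call(minpack.lm::nls.lm.control, control)
  niter <- 0L
  runStages <- function(theta0) {
    res <- NULL
    for (f in sdStages) {
      pf <- problem
      if (f != 1) pf@mm@meas$sd <- problem@mm@meas$sd * f
      residFun <- function(theta) {
        ev <- evaluateProblem(pf, theta)
        c(ev$rMeas, ev$rFlux, ev$rPool, ev$pen)
      }
      res <- minpack.lm::nls.lm(par = theta0, lower = bounds$lower,
                                upper = bounds$upper, fn = residFun,
                                control = ctrl)
      theta0 <- res$par
      niter <<- niter + as.integer(res$niter)
    }
    res
  }
  res <- runStages(theta0)
  # repair pass: a poor random start can strand pool sizes at their bounds,
  # where the labeling transient is insensitive to them; re-centre stuck
  # pools (keeping the fitted fluxes) and re-solve once, keeping the better
  # of the two solutions
  lay <- thetaLayout(problem)
  if (length(lay$poolMets)) {
    pIdx <- lay$nu + seq_along(lay$poolMets)
    stuck <- res$par[pIdx] <= bounds$lower[pIdx] + 1e-6 |
             res$par[pIdx] >= bounds$upper[pIdx] - 1e-6
    if (any(stuck)) {
      theta1 <- res$par
      theta1[pIdx][stuck] <- (bounds$lower[pIdx][stuck] +
                              bounds$upper[pIdx][stuck]) / 2
      res1 <- runStages(theta1)
      if (res1$deviance < res$deviance) res <- res1
    }
  }
  buildFit(problem, res$par, tol,
           iterations = niter,
           solverInfo = list(info = res$info, message = res$message))
}

# assemble an MFAFit from a parameter vector
buildFit <- function(problem, theta, tol = 1e-7, iterations = NA_integer_,
                     solverInfo = list()) {
  ev <- evaluateProblem(problem, theta)
  feas <- feasibilityResidual(problem, ev)
  status <- if (!is.null(solverInfo$info) && solverInfo$info %in% 1:4) {
    if (feas$ineq > tol) "locally-optimal-infeasible" else "locally-optimal"
  } else if (!is.null(solverInfo$info) && solverInfo$info %in% c(5, -1))
    "iteration-limit"
  else if (length(solverInfo) == 0) "evaluated"
  else "failed"
  scal <- unique(data.frame(group = ev$group, h = ev$h,
                            stringsAsFactors = FALSE))
  traj <- NULL
  if (problem@kind == "inst") {
    meas <- problem@mm@meas
    ch <- problem@mm@channels[meas$channel, ]
    traj <- data.frame(fragment = ch$fragment, mass = ch$mass,
                       dmass = ch$dmass, time = meas$time,
                       measured = meas$value, fitted = ev$sims,
                       sd = meas$sd,
                       residual = (ev$h * meas$value - ev$sims) / meas$sd)
    rownames(traj) <- NULL
  }
  new("MFAFit", v = ev$v,
      pools = if (is.null(ev$pools)) numeric(0) else ev$pools,
      scalings = scal, z = ev$z, status = status,
      feasResid = max(feas$eq, feas$ineq), iterations = iterations,
      trajectory = traj, theta = as.numeric(theta),
      info = c(solverInfo,
               list(kind = problem@kind,
                    order = if (!is.null(problem@scheme)) problem@scheme@order)))
}

# max equality-constraint and inequality violations at an evaluated point
feasibilityResidual <- function(problem, ev) {
  red <- problem@reduced
  S <- stoichMatrix(problem@net)
  eq <- if (nrow(S)) max(abs(as.numeric(S %*% ev$v))) else 0
  if (problem@kind == "steady") {
    ops <- balanceOperators(problem@arrays, ev$v, problem@input)
    x <- solveSteadyState(problem@arrays, ev$v, problem@input)
    free <- !problem@arrays@states@states$pinned
    eq <- max(eq, max(abs(balanceRate(ops, x)[free])))
  } else if (!is.null(ev$extra)) {
    pstate <- as.numeric(problem@pools@D %*% ev$pools[problem@pools@mets])
    tr <- transcriptionResiduals(ev$extra$ts, ev$extra$sol, ev$v, pstate,
                                 problem@input)
    eq <- max(eq, max(tr))
  }
  ineq <- max(0,
              red$lb[is.finite(red$lb)] - ev$v[is.finite(red$lb)],
              ev$v[is.finite(red$ub)] - red$ub[is.finite(red$ub)],
              if (!is.null(red$Rineq)) as.numeric(red$Rineq %*% ev$v) - red$bineq)
  list(eq = eq, ineq = ineq)
}

#' Audit a fit: recompute objective and constraint residuals
#'
#' Recomputes the objective and the equality/inequality residuals from the
#' stored parameter vector of a fit and compares with the reported values.
#'
#' @param problem the [NLPProblem-class] the fit came from.
#' @param fit an [MFAFit-class].
#' @return list with `z` (recomputed), `dz` (absolute difference to the
#'   reported value), `eqResid`, `ineqResid`.
#' @export
auditFit <- function(problem, fit) {
  ev <- evaluateProblem(problem, fit@theta)
  feas <- feasibilityResidual(problem, ev)
  list(z = ev$z, dz = abs(ev$z - fit@z), eqResid = feas$eq,
       ineqResid = feas$ineq)
}
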