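# Multistart estimation, high-order refinement and goodness of fit.

#' Multistart estimation from random feasible starting points
#'
#' Restarts the optimization from independent random feasible flux and pool
#' size distributions (drawn by [sampleFeasibleFluxesPools()]) and returns
#' all fits sorted by objective value. Restart i uses a seed derived from
#' the master seed by a counter, so any single restart is reproducible in
#' isolation. The recommended workflow is a low-order (3rd) multistart
#' followed by [refineFit()] at 9th order.
#'
#' @param problem an [NLPProblem-class].
#' @param nRestarts number of restarts.
#' @param seed master seed.
#' @param control solver control, see [solveNLP()].
#' @param nScreen candidate starting points screened per restart: each
#'   restart samples `nScreen` feasible points, evaluates the objective at
#'   each (cheap, since the states are solved directly), and runs the full
#'   solve from the two best-screened candidates, keeping the better fit.
#'   Set to 1 to optimize from the raw sampled point.
#' @return list of [MFAFit-class] objects sorted by ascending SSR; the
#'   attribute `"restartLog"` carries a per-restart data.frame (seed, z,
#'   status, iterations).
#' @export
multistart <- function(problem, nRestarts = 10, seed = 1L,
                       control = list(maxiter = 200), nScreen = 20) {
  if (nRestarts < 1) stopf("nRestarts must be >= 1")
  fits <- vector("list", nRestarts)
  errors <- character(0)
  for (i in seq_len(nRestarts)) {
    si <- childSeed(seed, i)
    fit <- try({
      cand <- sampleFeasibleFluxesPools(problem@net,
                                        poolBounds = problem@pools@bounds,
                                        seed = si, n = max(1L, nScreen))
      if (nScreen <= 1) {
        solveNLP(problem, cand, control = control)
      } else {
        zscr <- vapply(cand, function(st)
          evaluateProblem(problem, thetaFromStart(problem, st))$z, numeric(1))
        pick <- order(zscr)[1:min(2L, length(cand))]
        arms <- lapply(cand[pick], function(st)
          solveNLP(problem, st, control = control))
        arms[[which.min(vapply(arms, ssr, numeric(1)))]]
      }
    }, silent = TRUE)
    if (inherits(fit, "try-error")) {
      errors <- c(errors, sprintf("restart %d: %s", i, conditionMessage(attr(fit, "condition"))))
      fits[i] <- list(NULL)
    } else {
      fit@info$restart <- i
      fit@info$seed <- si
      fits[[i]] <- fit
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stopf("all %d restarts failed:\n%s", nRestarts,
          paste(errors, collapse = "\n"))
  fits <- fits[ok]
  ord <- order(vapply(fits, ssr, numeric(1)))
  fits <- fits[ord]
  log <- data.frame(
    restart = vapply(fits, function(f) f@info$restart, integer(1)),
    seed = vapply(fits, function(f) as.numeric(f@info$seed), numeric(1)),
    z = vapply(fits, ssr, numeric(1)),
    status = vapply(fits, function(f) f@status, character(1)),
    iterations = vapply(fits, function(f) f@iterations, integer(1)))
  attr(fits, "restartLog") <- log
  fits
}

#' Refine a fit with a higher-order collocation scheme
#'
#' Re-transcribes the dynamics at a higher Radau IIA order (the states are
#' re-solved exactly from the new transcription, which warm-starts them
#' consistently with the low-order solution's parameters) and re-solves from
#' the low-order optimum.
#'
#' @param fit the best low-order [MFAFit-class].
#' @param problem the [NLPProblem-class] the fit came from (nonstationary).
#' @param order target Radau IIA order (default 9).
#' @param control solver control.
#' @return list with `fit` (the refined [MFAFit-class]) and `problem` (the
#'   re-transcribed high-order problem, for auditing).
#' @export
refineFit <- function(fit, problem, order = 9, control = list(maxiter = 200)) {
  if (problem@kind != "inst")
    stopf("refinement applies to nonstationary problems")
  hi <- assembleInstNLP(problem@net, problem@arrays, problem@pools,
                        problem@mm, problem@grid, radauIIA(order),
                        options = problem@reduced$options)
  start <- list(v = fit@v, pools = fit@pools)
  out <- solveNLP(hi, start, control = control, sdStages = 1)
  out@info$refinedFrom <- fit@z
  list(fit = out, problem = hi)
}

#' Chi-square acceptance threshold for the SSR
#'
#' Upper quantile of the chi-square distribution with
#' `nMeas - nParams` degrees of freedom: a fit is statistically acceptable
#' at the given level if its SSR does not exceed this threshold.
#'
#' @param nMeas number of fitted measurements.
#' @param nParams number of free parameters (independent fluxes + free pool
#'   sizes + free scaling factors).
#' @param level confidence level (default 0.95).
#' @return the SSR threshold.
#' @examples
#' chi2Acceptance(110, 9)
#' @export
chi2Acceptance <- function(nMeas, nParams, level = 0.95) {
  dof <- nMeas - nParams
  if (dof <= 0) stopf("degrees of freedom must be positive (nMeas > nParams)")
  stats::qchisq(level, df = dof)
}
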