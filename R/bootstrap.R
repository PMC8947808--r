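# Parametric bootstrap confidence intervals for fluxes and pool sizes.

#' Bootstrap Monte-Carlo confidence intervals
#'
#' Parametric bootstrap from the fitted model: measurement values are
#' resampled as `N(fitted value, sd)`, the model is refit from the point
#' estimate, and the resample estimates are collected. Reports mean, sd and
#' percentile intervals per parameter. Deterministic given `seed`.
#'
#' @param problem the [NLPProblem-class] of the original fit.
#' @param fit the converged [MFAFit-class].
#' @param nBoot number of resamples.
#' @param seed master seed (per-resample seeds derived by counter).
#' @param level confidence level for the percentile intervals.
#' @param control solver control for the refits.
#' @param sdStages homotopy schedule for the refits (see [solveNLP()]).
#' @param jitter standard deviation of the random perturbation applied to
#'   each refit's starting point (free-flux coordinates and log pool
#'   sizes). Weakly identified problems have ridge-shaped objectives on
#'   which refits started exactly at the point estimate stay at the nearest
#'   ridge point and underestimate the resampling spread; jittered starts
#'   let each refit explore the ridge, while well-identified refits still
#'   converge to their optimum regardless of the start.
#' @return a [BootstrapResult-class].
#' @export
bootstrapCI <- function(problem, fit, nBoot = 100, seed = 1L, level = 0.95,
                        control = list(maxiter = 150), sdStages = c(25, 1),
                        jitter = 0.3) {
  ev <- evaluateProblem(problem, fit@theta)
  meas <- problem@mm@meas
  fitted <- ev$sims / ev$h          # measurement-scale fitted values
  start <- list(v = fit@v, pools = fit@pools)
  paramNames <- c(names(fit@v), names(fit@pools))
  samples <- matrix(NA_real_, nBoot, length(paramNames),
                    dimnames = list(NULL, paramNames))
  nFail <- 0L
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  theta0 <- thetaFromStart(problem, start)
  for (bIdx in seq_len(nBoot)) {
    set.seed(as.integer(childSeed(seed, bIdx)))
    pb <- problem
    newMeas <- meas
    newMeas$value <- fitted + stats::rnorm(nrow(meas), 0, meas$sd)
    pb@mm@meas <- newMeas
    startB <- if (jitter > 0)
      startFromTheta(problem,
                     theta0 + stats::rnorm(length(theta0), 0, jitter))
    else start
    res <- try(solveNLP(pb, startB, control = control, sdStages = sdStages),
               silent = TRUE)
    if (inherits(res, "try-error") ||
        res@status %in% c("failed", "locally-optimal-infeasible")) {
      nFail <- nFail + 1L
      next
    }
    samples[bIdx, ] <- c(res@v, res@pools)
  }
  if (nFail > 0.1 * nBoot)
    warnf("%d of %d bootstrap refits failed and were excluded", nFail, nBoot)
  ok <- stats::complete.cases(samples)
  sm <- samples[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  summary <- data.frame(
    parameter = paramNames,
    estimate = c(fit@v, fit@pools),
    mean = colMeans(sm),
    sd = apply(sm, 2, stats::sd),
    lower = apply(sm, 2, stats::quantile, probs = alpha),
    upper = apply(sm, 2, stats::quantile, probs = 1 - alpha),
    row.names = NULL)
  new("BootstrapResult", samples = sm, summary = summary,
      level = level, nFail = nFail)
}
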