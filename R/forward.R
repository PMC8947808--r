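# Forward simulation: steady-state cascade solver, dense ODE integration of
# the labeling dynamics, synthetic measurement generation.

#' Solve the labeling steady state by the weight cascade
#'
#' Exploits the cascade structure of the balances: the balance of a weight-w
#' cumomer (or size-w EMU) is linear in the weight-w states given all lower
#' weights, so the steady state is obtained by one sparse linear solve per
#' weight level.
#'
#' @param arrays a [ModelArrays-class].
#' @param v named flux vector covering all reactions.
#' @param xinp input/initial state vector from [buildInputVector()] (pinned
#'   entries are used as the fixed input values).
#' @param tol residual tolerance for the final balance check.
#' @return named numeric vector x with all balances satisfied to `tol`.
#' @export
solveSteadyState <- function(arrays, v, xinp, tol = 1e-10) {
  st <- arrays@states@states
  ops <- balanceOperators(arrays, v, xinp)
  x <- numeric(nrow(st))
  x[st$pinned] <- xinp[st$pinned]
  for (w in sort(unique(st$weight[!st$pinned]))) {
    idxL <- which(!st$pinned & st$weight == w)
    xm <- x; xm[idxL] <- 0
    r0 <- balanceRate(ops, xm)[idxL]
    A <- ops$Pv[idxL, idxL, drop = FALSE]
    dead <- which(Matrix::rowSums(abs(A)) == 0)
    if (length(dead))
      stopf("singular balance at weight %d: unreachable states %s (zero-flux dead end?)",
            w, paste(st$key[idxL[dead]], collapse = ", "))
    sol <- try(Matrix::solve(A, -r0), silent = TRUE)
    if (inherits(sol, "try-error"))
      stopf("singular balance system at weight %d (states %s)",
            w, paste(st$key[idxL], collapse = ", "))
    x[idxL] <- as.numeric(sol)
  }
  resid <- max(abs(balanceRate(ops, x)[!st$pinned]))
  scale <- max(1, max(abs(v)))
  if (resid > tol * scale)
    warnf("steady-state balance residual %.3e exceeds tolerance", resid)
  names(x) <- st$key
  x
}

labelingRHS <- function(ops, pinned, pstate) {
  force(ops); force(pinned); force(pstate)
  function(x) {
    dx <- numeric(length(x))
    rate <- balanceRate(ops, x)
    dx[!pinned] <- rate[!pinned] / pstate
    dx
  }
}

#' Integrate the labeling dynamics
#'
#' Integrates `p_k dx_k/dt = net production rate of x_k` from a given initial
#' state. The default integrator is classical fixed-step RK4; `"lsoda"`
#' selects the adaptive stiff integrator from deSolve.
#'
#' @param arrays a [ModelArrays-class].
#' @param v named flux vector.
#' @param pools a [PoolModel-class].
#' @param pmet named metabolite pool sizes (all > 0).
#' @param x0 initial composite state vector (e.g. from [buildInputVector()]).
#' @param times output time points; the first is the initial time.
#' @param method `"rk4"` or `"lsoda"`.
#' @param dt RK4 step size.
#' @return a [Trajectory-class].
#' @export
integrateLabeling <- function(arrays, v, pools, pmet, x0,
                              times, method = c("rk4", "lsoda"), dt = 0.02) {
  method <- match.arg(method)
  st <- arrays@states@states
  pstate <- as.numeric(pools@D %*% pmet[pools@mets])
  if (any(!is.finite(pstate)) || any(pstate <= 0))
    stopf("all pool sizes must be positive")
  ops <- balanceOperators(arrays, v, x0)
  rhs <- labelingRHS(ops, st$pinned, pstate)
  x0v <- as.numeric(x0)

  if (method == "rk4") {
    out <- matrix(NA_real_, length(times), length(x0v))
    out[1, ] <- x0v
    x <- x0v
    for (seg in seq_len(length(times) - 1L)) {
      t0 <- times[seg]; t1 <- times[seg + 1L]
      nstep <- max(1L, ceiling((t1 - t0) / dt - 1e-9))
      h <- (t1 - t0) / nstep
      for (s in seq_len(nstep)) {
        k1 <- rhs(x)
        k2 <- rhs(x + h / 2 * k1)
        k3 <- rhs(x + h / 2 * k2)
        k4 <- rhs(x + h * k3)
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (min(x) < -0.01 || max(x) > 1.01)
          stopf("integration unstable at t = %g (state outside [-0.01, 1.01]); reduce dt or use method = 'lsoda'",
                t0 + s * h)
      }
      out[seg + 1L, ] <- x
    }
  } else {
    dfun <- function(t, y, parms) list(rhs(y))
    sol <- deSolve::lsoda(y = x0v, times = times, func = dfun, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    out <- unname(as.matrix(sol[, -1, drop = FALSE]))
  }
  colnames(out) <- st$key
  out[out < 0 & out > -1e-9] <- 0
  new("Trajectory", times = times, x = out, method = method,
      dt = if (method == "rk4") dt else NA_real_)
}

# state vector at a stored trajectory time
trajectoryState <- function(traj, t) {
  i <- which(abs(traj@times - t) <= 1e-9)
  if (!length(i)) stopf("time %g not stored in the trajectory", t)
  traj@x[i[1], ]
}

#' Generate synthetic noisy measurements from a trajectory
#'
#' Evaluates the measurement model along a trajectory and perturbs the
#' simulated values with independent Gaussian noise, emulating measured
#' MIDs: `value = (M x(t))_n + N(0, noiseSd)`. Deterministic given `seed`.
#'
#' @param traj a [Trajectory-class] whose stored times include `times`.
#' @param mm a [MeasurementModel-class] (its channels define the rows).
#' @param times measurement times.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param sdFloor recorded standard deviation floor (keeps weights finite
#'   when `noiseSd = 0`).
#' @return data.frame in the measurement-table format (`fragment`, `time`,
#'   `mass`, `dmass`, `value`, `sd`).
#' @export
generateSyntheticMeasurements <- function(traj, mm, times, noiseSd = 0.01,
                                          seed = 1L, sdFloor = 1e-4) {
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(as.integer(seed))
  ch <- mm@channels
  rows <- list()
  for (t in times) {
    x <- trajectoryState(traj, t)
    sim <- as.numeric(mm@M %*% x)
    rows[[length(rows) + 1L]] <- data.frame(
      fragment = ch$fragment, time = t, mass = ch$mass, dmass = ch$dmass,
      value = sim + stats::rnorm(length(sim), 0, noiseSd),
      sd = max(noiseSd, sdFloor))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
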