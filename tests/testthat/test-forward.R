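# Steady-state cascade, ODE integration and synthetic measurement
# generation, cross-checked against the brute-force isotopomer oracle.

test_that("fully labeled feed drives all states to 1 at steady state", {
  net <- toyNetwork()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  x <- solveSteadyState(arr, toyTruth()$v, buildInputVector(net, st))
  expect_equal(unname(x), rep(1, length(x)), tolerance = 1e-10)
})

test_that("cascade steady state matches the brute-force isotopomer oracle", {
  for (fix in list(chainNetwork(), cleaveNetwork(), selfCondenseNetwork())) {
    v <- fixtureFluxes(fix, seed = 3)
    st <- enumerateCumomers(fix)
    arr <- buildModelArrays(fix, st)
    x <- solveSteadyState(arr, v, buildInputVector(fix, st))
    iso <- oracleSteadyState(fix, v)
    frs <- allFragments(fix)
    mids <- pipelineMids(st, frs, x)
    ref <- oracleMids(iso, frs)
    for (id in frs$id)
      expect_equal(mids[[id]], unname(ref[[id]]), tolerance = 1e-8,
                   label = paste("cumomer steady MID", id))
    # EMU pipeline agrees too
    stE <- emuDecompose(fix, lapply(seq_len(nrow(frs)), function(i)
      list(met = frs$met[i],
           atoms = as.integer(strsplit(frs$atoms[i], ",")[[1]]))))
    arrE <- buildModelArrays(fix, stE)
    xE <- solveSteadyState(arrE, v, buildInputVector(fix, stE))
    midsE <- pipelineMids(stE, frs, xE)
    for (id in frs$id)
      expect_equal(midsE[[id]], unname(ref[[id]]), tolerance = 1e-8,
                   label = paste("EMU steady MID", id))
  }
})

test_that("single-pool labeling follows the closed-form exponential", {
  net <- splitReversible(parseNetwork(
    "vin: X (a) -> A (a)\nvout: A (a) -> Y (a)",
    list(fixed = list(vin = 0.7),
         tracers = list(list(substrate = "X", fraction = 1,
                             positions = "U", enrichment = 1)),
         nat_abundance = 0)))
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  pools <- buildPoolModel(net, st)
  pmet <- c(A = 1.3)
  times <- seq(0, 6, by = 0.5)
  traj <- integrateLabeling(arr, c(vin = 0.7, vout = 0.7), pools, pmet,
                            buildInputVector(net, st), times, dt = 0.02)
  xa <- traj@x[, fluxnlp:::stateKey("A", 1L)]
  expect_equal(xa, 1 - exp(-0.7 * times / 1.3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("MIDs stay normalized along trajectories", {
  study <- toyStudy(noiseSd = 0, seed = 1)
  mm <- study$mm
  for (i in seq_along(study$traj@times)) {
    sims <- as.numeric(mm@M %*% study$traj@x[i, ])
    sums <- tapply(sims, mm@channels$fragment, sum)
    expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("steady state is the long-time limit of the dynamics", {
  fix <- chainNetwork()
  v <- fixtureFluxes(fix, seed = 5)
  st <- enumerateCumomers(fix)
  arr <- buildModelArrays(fix, st)
  pools <- buildPoolModel(fix, st)
  pmet <- randomPools(fix, seed = 5)
  x0 <- buildInputVector(fix, st)
  xss <- solveSteadyState(arr, v, x0)
  traj <- integrateLabeling(arr, v, pools, pmet, x0, c(0, 300), method = "lsoda")
  expect_lt(max(abs(traj@x[2, ] - xss)), 1e-6)
})

test_that("trajectories match the isotopomer oracle over time", {
  for (fix in list(chainNetwork(), selfCondenseNetwork())) {
    v <- fixtureFluxes(fix, seed = 4)
    st <- enumerateCumomers(fix)
    arr <- buildModelArrays(fix, st)
    pools <- buildPoolModel(fix, st)
    pmet <- randomPools(fix, seed = 4)
    x0 <- buildInputVector(fix, st)
    times <- c(0, 0.5, 1, 2, 5)
    traj <- integrateLabeling(arr, v, pools, pmet, x0, times, dt = 0.01)
    otraj <- oracleTrajectory(fix, v, pmet, times)
    frs <- allFragments(fix)
    for (i in seq_along(times)) {
      mids <- pipelineMids(st, frs, traj@x[i, ])
      ref <- oracleMids(otraj$iso[[i]], frs)
      for (id in frs$id)
        expect_equal(mids[[id]], unname(ref[[id]]), tolerance = 1e-7,
                     label = paste("MID", id, "t =", times[i]))
    }
  }
})

test_that("synthetic measurements are exact at zero noise and seed-stable", {
  study <- toyStudy(noiseSd = 0, seed = 9)
  mm0 <- buildMeasurementModel(study$states, toyFragments(), natAbundance = 0)
  exact <- generateSyntheticMeasurements(study$traj, mm0, c(2, 10),
                                         noiseSd = 0, seed = 1)
  for (k in seq_len(nrow(exact))) {
    x <- fluxnlp:::trajectoryState(study$traj, exact$time[k])
    chan <- which(mm0@channels$fragment == exact$fragment[k] &
                  mm0@channels$mass == exact$mass[k])
    expect_equal(exact$value[k], as.numeric(mm0@M %*% x)[chan],
                 tolerance = 1e-12)
  }
  expect_equal(exact$sd, rep(1e-4, nrow(exact)))  # sd floor at zero noise
  a <- generateSyntheticMeasurements(study$traj, mm0, c(2, 10), 0.01, seed = 5)
  b <- generateSyntheticMeasurements(study$traj, mm0, c(2, 10), 0.01, seed = 5)
  expect_identical(a, b)
})

test_that("empirical noise sd matches the requested level", {
  study <- toyStudy(noiseSd = 0, seed = 9)
  mm0 <- buildMeasurementModel(study$states, toyFragments(), natAbundance = 0)
  exact <- generateSyntheticMeasurements(study$traj, mm0, c(4, 8, 16),
                                         noiseSd = 0, seed = 1)
  devs <- unlist(lapply(1:400, function(i) {
    m <- generateSyntheticMeasurements(study$traj, mm0, c(4, 8, 16),
                                       noiseSd = 0.02, seed = 1000 + i)
    m$value - exact$value
  }))
  expect_equal(sd(devs), 0.02, tolerance = 0.02)
})
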