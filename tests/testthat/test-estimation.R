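# Estimation problem assembly, reduced solve, multistart, refinement,
# goodness of fit and bootstrap.

steadyFixture <- function(noise = 0, seed = 1) {
  # mixed tracer makes the steady-state labeling flux-dependent
  net <- splitReversible(parseNetwork(toyNetworkText(), modifyList(toyConfig(),
    list(tracers = list(
      list(substrate = "A.ext", fraction = 0.5, positions = "U", enrichment = 1),
      list(substrate = "A.ext", fraction = 0.5, positions = integer(0),
           enrichment = 0))))), exchangeUb = 5)
  truth <- toyTruth()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  x <- solveSteadyState(arr, truth$v, buildInputVector(net, st))
  mm0 <- buildMeasurementModel(st, toyFragments(), natAbundance = 0)
  sims <- as.numeric(mm0@M %*% x)
  set.seed(seed)
  meas <- data.frame(fragment = mm0@channels$fragment,
                     time = NA_real_, mass = mm0@channels$mass,
                     dmass = NA_integer_,
                     value = sims + rnorm(length(sims), 0, max(noise, 0)),
                     sd = max(noise, 1e-4))
  mm <- buildMeasurementModel(st, toyFragments(), meas, natAbundance = 0)
  list(net = net, st = st, arr = arr, mm = mm, truth = truth)
}

test_that("noise-free steady-state data is fit to machine accuracy", {
  fx <- steadyFixture(noise = 0)
  prob <- assembleSteadyNLP(fx$net, fx$arr, fx$mm)
  fit <- solveNLP(prob, list(v = fx$truth$v), sdStages = 1)
  expect_lt(fit@z, 1e-6)
  expect_lt(max(abs(fit@v - fx$truth$v) / pmax(fx$truth$v, 1)), 1e-4)
  expect_lt(fit@feasResid, 1e-7)
  expect_identical(fit@status, "locally-optimal")
  # all scaling factors fixed at 1 for complete normalized MIDs
  expect_true(all(fit@scalings$h == 1))
})

test_that("noise-free nonstationary data recovers fluxes and pools", {
  net <- toyNetwork(); truth <- toyTruth()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  pools <- buildPoolModel(net, st)
  x0 <- buildInputVector(net, st)
  times <- seq(2, 20, by = 2)
  traj <- integrateLabeling(arr, truth$v, pools, truth$pools, x0,
                            sort(unique(c(0, times))), method = "lsoda")
  mm0 <- buildMeasurementModel(st, toyFragments(), natAbundance = 0)
  meas <- generateSyntheticMeasurements(traj, mm0, times, noiseSd = 0, seed = 1)
  mm <- buildMeasurementModel(st, toyFragments(), meas, natAbundance = 0)
  grid <- makeTimeGrid(c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12,
                         14, 16, 18, 20))
  prob <- assembleInstNLP(net, arr, pools, mm, grid, radauIIA(9))
  fit <- solveNLP(prob, list(v = truth$v, pools = truth$pools), sdStages = 1)
  expect_lt(fit@z, 1e-6)
  expect_lt(max(abs(fit@v - truth$v) / pmax(truth$v, 1e-9)), 1e-4)
  expect_lt(max(abs(fit@pools - truth$pools[names(fit@pools)]) /
                truth$pools[names(fit@pools)]), 1e-3)
  expect_lt(fit@feasResid, 1e-7)
})

test_that("problem dimensions match hand counts on a two-reaction fixture", {
  net <- splitReversible(parseNetwork(
    "vin: X (a) -> A (a)\nvout: A (a) -> Y (a)",
    list(fixed = list(vin = 1),
         tracers = list(list(substrate = "X", fraction = 1, positions = "U",
                             enrichment = 1)), nat_abundance = 0)))
  st <- enumerateCumomers(net)   # X: 2 states, A: 2 states; A{1} unpinned
  arr <- buildModelArrays(net, st)
  frag <- data.frame(id = "A1", met = "A", atoms = "1", daughter = "",
                     formula = "", stringsAsFactors = FALSE)
  # steady state: 2 fluxes + 4 states + 2 measurement rows; equalities:
  # 1 balance + 1 stoichiometric row + 2 mapping rows + 3 pins
  measS <- data.frame(fragment = "A1", time = NA_real_, mass = 0:1,
                      dmass = NA_integer_, value = c(0, 1), sd = 0.01)
  mmS <- buildMeasurementModel(st, frag, measS, natAbundance = 0)
  dims <- problemDimensions(assembleSteadyNLP(net, arr, mmS))
  expect_identical(dims$nVariables, 2L + 4L + 2L)
  expect_identical(dims$nEqualities, 1L + 1L + 2L + 3L)
  # nonstationary, 2 intervals, 2 stages, 1 measured time:
  measI <- measS; measI$time <- 1
  mmI <- buildMeasurementModel(st, frag, measI, natAbundance = 0)
  pools <- buildPoolModel(net, st)
  prob <- assembleInstNLP(net, arr, pools, mmI, makeTimeGrid(c(0, 1, 2)),
                          radauIIA(3))
  dims <- problemDimensions(prob)
  n <- 4; G <- 2; s <- 2
  expect_identical(dims$nVariables,
                   as.integer(2 + 1 + 1 + n * (1 + G * (2 * s + 1)) + n + 2))
  expect_identical(dims$nEqualities,
                   as.integer(2 * G * s * n + G * n + 1 + 1 + n + 2 +
                              (G + 1) * 3 + n))
})

test_that("solver restarts are deterministic and converge from the truth", {
  study <- toyStudy(noiseSd = 0.01, seed = 2)
  prob <- assembleInstNLP(study$net, study$arrays, study$pools, study$mm,
                          toyGrid(), radauIIA(3))
  fitT <- solveNLP(prob, list(v = study$truth$v, pools = study$truth$pools))
  expect_lt(fitT@feasResid, 1e-7)
  # statistical acceptability is judged after high-order refinement (the
  # low-order transcription inflates the SSR by its discretization error)
  ref <- refineFit(fitT, prob, order = 9)
  # a correctly specified model passes the chi-square test (0.995 level so
  # that a single unlucky noise draw does not trip the check)
  expect_lt(ref$fit@z, chi2Acceptance(nrow(study$mm@meas), 9, level = 0.995))
  fits1 <- multistart(prob, nRestarts = 2, seed = 7, nScreen = 5)
  fits2 <- multistart(prob, nRestarts = 2, seed = 7, nScreen = 5)
  expect_identical(lapply(fits1, ssr), lapply(fits2, ssr))
  expect_identical(fits1[[1]]@theta, fits2[[1]]@theta)
})

test_that("fit audit reproduces the reported objective and feasibility", {
  study <- toyStudy(noiseSd = 0.01, seed = 3)
  prob <- assembleInstNLP(study$net, study$arrays, study$pools, study$mm,
                          toyGrid(), radauIIA(3))
  fit <- solveNLP(prob, list(v = study$truth$v, pools = study$truth$pools))
  audit <- auditFit(prob, fit)
  expect_lt(audit$dz, 1e-8)
  expect_lt(audit$eqResid, 1e-7)
  expect_lt(audit$ineqResid, 1e-7)
})

test_that("9th-order refinement preserves an already-resolved optimum", {
  study <- toyStudy(noiseSd = 0.01, seed = 4)
  prob <- assembleInstNLP(study$net, study$arrays, study$pools, study$mm,
                          toyGrid(), radauIIA(3))
  fit <- solveNLP(prob, list(v = study$truth$v, pools = study$truth$pools))
  ref <- refineFit(fit, prob, order = 9)
  # the low-order discretization error is below the noise level here, so
  # refinement must stay at the same optimum (small relative change)
  expect_lt(abs(ref$fit@z - fit@z) / fit@z, 0.05)
  expect_identical(ref$fit@info$order, 9L)
  expect_lt(ref$fit@feasResid, 1e-7)
})

test_that("chi-square acceptance thresholds are standard quantiles", {
  expect_equal(chi2Acceptance(19, 9), 18.307, tolerance = 1e-3)
  expect_equal(chi2Acceptance(110, 10), qchisq(0.95, 100), tolerance = 1e-12)
  th <- vapply(c(0.9, 0.95, 0.99), function(l) chi2Acceptance(2, 1, l),
               numeric(1))
  expect_true(all(diff(th) > 0))
  expect_error(chi2Acceptance(5, 5), "positive")
})

test_that("pools are unidentifiable from equilibrated labeling, fluxes are not", {
  # measurements taken long after label equilibration: the nonstationary fit
  # reproduces the steady-state flux estimates while the objective is flat
  # in the pool sizes
  fx <- steadyFixture(noise = 0)
  probS <- assembleSteadyNLP(fx$net, fx$arr, fx$mm)
  fitS <- solveNLP(probS, list(v = fx$truth$v), sdStages = 1)
  # same measured values presented as late time points
  measLate <- fx$mm@meas
  measLate <- do.call(rbind, lapply(c(200, 220), function(t) {
    m <- measLate; m$time <- t; m
  }))
  measLate$fragment <- fx$mm@channels$fragment[measLate$channel]
  measLate$mass <- fx$mm@channels$mass[measLate$channel]
  measLate$dmass <- NA_integer_
  measLate$sd <- 1e-3   # realistic weight: the transcription error at late
                        # times must stay well below one standard deviation
  mmI <- buildMeasurementModel(fx$st, toyFragments(), measLate,
                               natAbundance = 0)
  pools <- buildPoolModel(fx$net, fx$st)
  # pin the pool sizes: with only equilibrated data they carry no
  # information (their flatness is asserted below), and leaving them free
  # makes the two-time-point fit overparametrized
  pools@bounds$lb <- pools@bounds$ub <- unname(toyTruth()$pools[pools@mets])
  grid <- makeTimeGrid(c(0, 2, 5, 10, 20, 40, 80, 120, 160, 200, 220))
  probI <- assembleInstNLP(fx$net, fx$arr, pools, mmI, grid, radauIIA(9))
  fitI <- solveNLP(probI, list(v = fitS@v, pools = toyTruth()$pools),
                   sdStages = 1)
  # pathway fluxes agree; the exchange flux (v1.f/v1.b split) is a known
  # steady-state-unidentifiable direction and is excluded
  idf <- c("v0", "v2", "v3", "v4", "v5", "v6", "v7")
  expect_lt(max(abs(fitI@v[idf] - fitS@v[idf])), 1e-3)
  # flat objective in pools at the optimum
  th <- fitI@theta
  lay <- fluxnlp:::thetaLayout(probI)
  th2 <- th; th2[lay$nu + seq_along(lay$poolMets)] <-
    th2[lay$nu + seq_along(lay$poolMets)] + log(1.5)
  z2 <- fluxnlp:::evaluateProblem(probI, th2)$z
  expect_lt(abs(z2 - fitI@z), 1e-4)
})

test_that("bootstrap resamples collapse to the point estimate as sd -> 0", {
  study <- toyStudy(noiseSd = 0.01, seed = 5)
  prob <- assembleInstNLP(study$net, study$arrays, study$pools, study$mm,
                          toyGrid(), radauIIA(3))
  fit <- solveNLP(prob, list(v = study$truth$v, pools = study$truth$pools))
  tiny <- prob
  tiny@mm@meas$sd <- 1e-7
  # re-evaluate the fit under the tiny-sd problem so fitted values are kept
  fit2 <- fluxnlp:::buildFit(tiny, fit@theta)
  bs <- bootstrapCI(tiny, fit2, nBoot = 5, seed = 11)
  expect_equal(bs@nFail, 0L)
  for (b in seq_len(nrow(bs@samples)))
    expect_lt(max(abs(bs@samples[b, ] - c(fit2@v, fit2@pools))), 1e-4)
})
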