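# Radau IIA schemes, transcription, exact per-interval solution and
# interpolation.

test_that("Radau IIA schemes satisfy their defining identities to 1e-12", {
  for (ord in c(3, 5, 9)) {
    sc <- radauIIA(ord)
    s <- sc@s
    expect_equal(sc@c[s], 1, tolerance = 1e-12)
    expect_equal(sum(sc@b), 1, tolerance = 1e-12)
    expect_lt(max(abs(sc@a[s, ] - sc@b)), 1e-12)
    Bt1 <- vapply(seq_len(s), function(al)
      fluxnlp:::polyEvalAsc(sc@Bcoef[al, ], 1), numeric(1))
    expect_lt(max(abs(Bt1 - sc@b)), 1e-12)
    Bt0 <- vapply(seq_len(s), function(al)
      fluxnlp:::polyEvalAsc(sc@Bcoef[al, ], 0), numeric(1))
    expect_lt(max(abs(Bt0)), 1e-12)
    # row-sum identity a 1 = c
    expect_lt(max(abs(rowSums(sc@a) - sc@c)), 1e-12)
  }
  expect_error(radauIIA(7), "unsupported")
})

test_that("2-stage nodes are (1/3, 1) and 3-stage matches the classical tableau", {
  sc <- radauIIA(3)
  expect_equal(sc@c, c(1 / 3, 1), tolerance = 1e-14)
  expect_equal(sc@a, rbind(c(5 / 12, -1 / 12), c(3 / 4, 1 / 4)),
               tolerance = 1e-13, ignore_attr = TRUE)
  # classical 3-stage Radau IIA tableau (independent closed forms)
  sc5 <- radauIIA(5)
  sq6 <- sqrt(6)
  expect_equal(sc5@c, c((4 - sq6) / 10, (4 + sq6) / 10, 1), tolerance = 1e-13)
  aRef <- rbind(
    c((88 - 7 * sq6) / 360, (296 - 169 * sq6) / 1800, (-2 + 3 * sq6) / 225),
    c((296 + 169 * sq6) / 1800, (88 + 7 * sq6) / 360, (-2 - 3 * sq6) / 225),
    c((16 - sq6) / 36, (16 + sq6) / 36, 1 / 9))
  expect_equal(sc5@a, aRef, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sc5@b, c((16 - sq6) / 36, (16 + sq6) / 36, 1 / 9),
               tolerance = 1e-13)
})

# one-pool decay fixture: impulse-labeled A relaxing to the unlabeled feed,
# dx/dt = -(v/p) x
decayFixture <- function() {
  net <- splitReversible(parseNetwork(
    "vin: X (a) -> A (a)\nvout: A (a) -> Y (a)",
    list(fixed = list(vin = 1),
         tracers = list(list(substrate = "A", fraction = 1,
                             positions = "U", enrichment = 1)),
         nat_abundance = 0)))
  st <- enumerateCumomers(net)
  list(net = net, st = st, arr = buildModelArrays(net, st),
       pools = buildPoolModel(net, st),
       x0 = buildInputVector(net, st))
}

test_that("one interval of 2-stage Radau IIA reproduces its stability function", {
  fx <- decayFixture()
  h <- 1.7
  ts <- transcribe(fx$arr, makeTimeGrid(c(0, h)), radauIIA(3))
  sol <- solveTranscribed(ts, c(vin = 1, vout = 1), pstate = 1, fx$x0)
  zh <- -h
  Rz <- (1 + zh / 3) / (1 - 2 * zh / 3 + zh^2 / 6)
  xa <- sol$xNodes[2, fluxnlp:::stateKey("A", 1L)]
  expect_equal(unname(xa), Rz, tolerance = 1e-12)
})

test_that("transcription variable and constraint counts follow the formulas", {
  net <- toyNetwork()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  ts <- transcribe(arr, toyGrid(), radauIIA(5))
  n <- nrow(statesTable(st)); G <- 8; s <- 3
  expect_identical(variableCount(ts), as.integer(n * (1 + G * (2 * s + 1))))
  expect_identical(constraintCount(ts), as.integer(2 * G * s * n + G * n))
  expect_error(transcribe(arr, makeTimeGrid(c(0)), radauIIA(3)))
})

test_that("endpoint error scales as h^(2s-1) on a nonlinear fixture", {
  fix <- selfCondenseNetwork()   # bimolecular, genuinely nonlinear dynamics
  v <- c(vin = 1, v1 = 0.5, vout = 0.5)
  st <- enumerateCumomers(fix)
  arr <- buildModelArrays(fix, st)
  pools <- buildPoolModel(fix, st)
  pmet <- c(A = 0.9, B = 1.4)
  x0 <- buildInputVector(fix, st)
  pstate <- as.numeric(pools@D %*% pmet[pools@mets])
  Tend <- 2
  ref <- integrateLabeling(arr, v, pools, pmet, x0, c(0, Tend),
                           method = "lsoda")@x[2, ]
  for (s in c(2, 3)) {
    ord <- 2 * s - 1
    errs <- vapply(c(2, 4, 8, 16), function(G) {
      ts <- transcribe(arr, makeTimeGrid(seq(0, Tend, length.out = G + 1)),
                       radauIIA(ord))
      sol <- solveTranscribed(ts, v, pstate, x0)
      max(abs(sol$xNodes[G + 1, ] - ref))
    }, numeric(1))
    slope <- -coef(lm(log(errs) ~ log(c(2, 4, 8, 16))))[2]
    expect_lt(abs(slope - ord) / ord, 0.15)
  }
})

test_that("interpolation reproduces node and stage values exactly", {
  net <- toyNetwork(); truth <- toyTruth()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  pools <- buildPoolModel(net, st)
  x0 <- buildInputVector(net, st)
  pstate <- as.numeric(pools@D %*% truth$pools[pools@mets])
  sc <- radauIIA(5)
  ts <- transcribe(arr, toyGrid(), sc)
  sol <- solveTranscribed(ts, truth$v, pstate, x0)
  nodes <- toyGrid()@nodes
  # tau = 1: the interval-end node state
  xi <- interpolateAt(sol, ts, nodes[4])
  expect_equal(as.numeric(xi), unname(sol$xNodes[4, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # tau = c_alpha: the stage state K_alpha
  g <- 3; h <- ts@grid@h[g]
  for (al in 1:2) {
    tmu <- nodes[g] + sc@c[al] * h
    xi <- interpolateAt(sol, ts, tmu)
    K <- sol$xNodes[g, ] + h * as.numeric(sc@a[al, ] %*% sol$k[[g]])
    expect_equal(as.numeric(xi), unname(K), tolerance = 1e-12)
  }
  expect_error(interpolateAt(sol, ts, 25), "outside")
  # audit: the exact solution satisfies all three constraint families
  res <- transcriptionResiduals(ts, sol, truth$v, pstate, x0)
  expect_lt(max(res), 1e-10)
})

test_that("stiff stability: an over-wide first interval does not corrupt later ones", {
  net <- toyNetwork(); truth <- toyTruth()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  pools <- buildPoolModel(net, st)
  x0 <- buildInputVector(net, st)
  pstate <- as.numeric(pools@D %*% truth$pools[pools@mets])
  ts <- transcribe(arr, makeTimeGrid(c(0, 10, 20)), radauIIA(5))
  sol <- solveTranscribed(ts, truth$v, pstate, x0)
  ref <- function(tt) integrateLabeling(arr, truth$v, pools, truth$pools, x0,
                                        c(0, tt), dt = 0.005)@x[-1, , drop = FALSE]
  err1 <- max(abs(interpolateAt(sol, ts, c(1, 2, 3)) - ref(c(1, 2, 3))))
  err2 <- max(abs(interpolateAt(sol, ts, c(12, 15, 18)) - ref(c(12, 15, 18))))
  expect_gt(err1, 0.05)    # the stiff region is poorly approximated
  expect_lt(err2, 0.02)    # the next interval recovers
  # final node approaches the true steady state (full enrichment)
  free <- !statesTable(st)$pinned
  expect_lt(max(abs(sol$xNodes[3, free] - 1)), 0.1)
})
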