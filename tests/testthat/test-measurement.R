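# Cumomer/isotopomer transforms, tandem mass matrices, natural-abundance
# operator and the M/U mapping matrices.

test_that("cumomer-isotopomer inversion matches hand-worked cases", {
  # all cumomers 0 except the zero-order one: everything unlabeled
  x <- c(1, rep(0, 7))
  iso <- cumomersToIsotopomers(x)
  expect_equal(iso, c(1, rep(0, 7)))
  # 2-carbon with independent half-labeled atoms: all four isotopomers 1/4
  x2 <- c(1, 0.5, 0.5, 0.25)
  expect_equal(cumomersToIsotopomers(x2), rep(0.25, 4))
})

test_that("isotopomer->cumomer->isotopomer round-trips on random distributions", {
  set.seed(42)
  for (n in c(2, 3, 4)) {
    for (rep in 1:5) {
      iso <- rexp(2^n); iso <- iso / sum(iso)
      cum <- isotopomersToCumomers(iso)
      expect_equal(cum[1], 1, tolerance = 1e-12)
      expect_equal(cumomersToIsotopomers(cum), iso, tolerance = 1e-12)
    }
  }
})

test_that("large negativity errors, tiny negativity clamps with warning", {
  x <- c(1, 0.6, 0.6, 0.1)   # inconsistent: iso{} = 1-0.6-0.6+0.1 < 0
  expect_error(cumomersToIsotopomers(x), "inconsistent")
  x2 <- c(1, 0.9, 0.9, 0.8 - 5e-10)
  expect_warning(iso2 <- cumomersToIsotopomers(x2), "clamp")
  expect_true(all(iso2 >= 0))
  expect_equal(sum(iso2), 1, tolerance = 1e-9)
})

test_that("tandem mass matrix matches direct enumeration", {
  # unlabeled 2-carbon parent: all mass at (0,0)
  iso0 <- c(1, 0, 0, 0)
  tm <- tandemMid(iso0, c(1, 2), 1)
  expect_equal(tm["M+0", "m+0"], 1)
  expect_equal(sum(tm), 1)
  # fully labeled: all mass at (2,1)
  isoF <- c(0, 0, 0, 1)
  expect_equal(tandemMid(isoF, c(1, 2), 1)["M+2", "m+1"], 1)
  # uniform isotopomers: entries (0,0), (1,0), (1,1), (2,1) each 1/4
  isoU <- rep(0.25, 4)
  tmU <- tandemMid(isoU, c(1, 2), 1)
  expect_equal(unname(tmU),
               rbind(c(0.25, 0), c(0.25, 0.25), c(0, 0.25)))
  expect_error(tandemMid(isoU, 1, c(1, 2)), "subset")
})

test_that("tandem daughter marginal equals the parent MID", {
  set.seed(7)
  iso <- rexp(8); iso <- iso / sum(iso)
  tm <- tandemMid(iso, c(1, 2, 3), c(2, 3))
  expect_equal(rowSums(tm), isotopomerMid(iso, 1:3), tolerance = 1e-12)
  tm2 <- tandemMid(iso, c(1, 3), 3)
  expect_equal(rowSums(tm2), isotopomerMid(iso, c(1, 3)), tolerance = 1e-12)
})

test_that("natural-abundance operator is column-stochastic convolution", {
  expect_equal(naturalAbundanceOperator("", 2), diag(3),
               ignore_attr = TRUE)
  p <- 0.0107
  op <- naturalAbundanceOperator("C", 0,
                                 isotopes = list(C = c(1 - p, p)))
  expect_equal(unname(op[, 1]), c(1 - p, p))
  op2 <- naturalAbundanceOperator("C2H3NOSi", 3)
  expect_equal(unname(colSums(op2)), rep(1, 4), tolerance = 1e-12)
  expect_error(naturalAbundanceOperator("Zz2", 2), "isotope data")
})

test_that("measurement mapping is linear and complete MIDs sum to 1", {
  net <- toyNetwork()
  truth <- toyTruth()
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  x <- solveSteadyState(arr, truth$v, buildInputVector(net, st))
  mm <- buildMeasurementModel(st, toyFragments(), natAbundance = 0)
  sims <- as.numeric(mm@M %*% x)
  sums <- tapply(sims, mm@channels$fragment, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
  # U: one 1 per channel row, fragment column sums = channel counts
  expect_true(all(Matrix::rowSums(mm@U) == 1))
  expect_equal(unname(Matrix::colSums(mm@U)), c(3, 3, 4))  # B12, B23, B123
})

test_that("tandem M rows reproduce brute-force enumeration on a 3-carbon fragment", {
  net <- cleaveNetwork()
  v <- fixtureFluxes(net, seed = 3)
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  x <- solveSteadyState(arr, v, buildInputVector(net, st))
  frag <- data.frame(id = "D123", met = "D", atoms = "1,2,3", daughter = "2,3",
                     formula = "", stringsAsFactors = FALSE)
  mm <- buildMeasurementModel(st, frag, natAbundance = 0)
  sims <- as.numeric(mm@M %*% x)
  iso <- oracleSteadyState(net, v)
  ref <- tandemMid(iso[["D"]], 1:3, c(2, 3))
  for (i in seq_len(nrow(mm@channels))) {
    ch <- mm@channels[i, ]
    expect_equal(sims[i], ref[ch$mass + 1, ch$dmass + 1], tolerance = 1e-8)
  }
  # tandem fragments require the cumomer framework
  emuSt <- emuDecompose(net, list(list(met = "D", atoms = 1:3)))
  expect_error(buildMeasurementModel(emuSt, frag), "cumomer")
})

test_that("formula-bearing fragments fold the convolution into M", {
  net <- chainNetwork()
  v <- fixtureFluxes(net, seed = 2)
  st <- enumerateCumomers(net)
  arr <- buildModelArrays(net, st)
  x <- solveSteadyState(arr, v, buildInputVector(net, st))
  fragPlain <- data.frame(id = "C123", met = "C", atoms = "1,2,3",
                          daughter = "", formula = "", stringsAsFactors = FALSE)
  fragForm <- data.frame(id = "C123d", met = "C", atoms = "1,2,3",
                         daughter = "", formula = "C2Si",
                         stringsAsFactors = FALSE)
  na <- 0.0107
  simPlain <- as.numeric(buildMeasurementModel(st, fragPlain,
                                               natAbundance = na)@M %*% x)
  simForm <- as.numeric(buildMeasurementModel(st, fragForm,
                                              natAbundance = na)@M %*% x)
  iso <- isotopeTable(); iso$C <- c(1 - na, na)
  op <- naturalAbundanceOperator("C2Si", 3, isotopes = iso)
  expect_equal(simForm, as.numeric(op %*% simPlain), tolerance = 1e-10)
})

test_that("measurement tables round-trip through the TSV dialect", {
  study <- toyStudy(noiseSd = 0.01, seed = 1)
  path <- tempfile(fileext = ".tsv")
  writeMeasurementTable(toyFragments(), study$meas, path)
  back <- readMeasurementTable(path)
  expect_equal(back$fragments$id, toyFragments()$id)
  expect_equal(back$meas$value, study$meas$value, tolerance = 1e-12)
})
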