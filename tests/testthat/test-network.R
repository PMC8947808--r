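# Network parsing, reversible splitting, flux degrees of freedom and
# feasible sampling.

test_that("reaction lines parse into atom-mapped reactions", {
  net <- parseNetwork("v1: A (abc) -> B (abc)")
  r <- reactions(net)[[1]]
  expect_length(reactions(net), 1)
  expect_identical(r$reactants[[1]]$atoms, c("a", "b", "c"))
  expect_identical(r$products[[1]]$atoms, c("a", "b", "c"))
  expect_false(r$reversible)

  net2 <- parseNetwork("v3: C (ab) + D (c) -> E (abc)")
  r2 <- reactions(net2)[[1]]
  expect_length(r2$reactants, 2)
  # E carbons 1,2 trace to C, carbon 3 to D
  g <- fluxnlp:::preimageGroups(r2, 1, 1:3)
  expect_setequal(vapply(g, `[[`, character(1), "met"), c("C", "D"))
  gc <- g[[which(vapply(g, `[[`, character(1), "met") == "C")]]
  expect_identical(gc$atoms, 1:2)

  net3 <- parseNetwork("v2: B (ab) <-> C (ba)")
  expect_true(reactions(net3)[[1]]$reversible)
  expect_identical(reactions(net3)[[1]]$products[[1]]$atoms, c("b", "a"))
})

test_that("parse errors name the offending reaction", {
  expect_error(parseNetwork("vbad: A (abc) -> B (ab)"),
               "vbad.*unbalanced carbon")
  expect_error(parseNetwork("v1: A (a) -> B (a)\nv1: B (a) -> C (a)"),
               "duplicate reaction id")
  expect_error(parseNetwork("v1: A (a) -> B (a)",
                            list(pools = list(Zz = list(lb = 1, ub = 2)))),
               "unknown metabolite 'Zz'")
})

test_that("splitReversible produces nonnegative bounds and inverse maps", {
  net <- parseNetwork("v1: A (ab) <-> B (ba)",
                      list(bounds = list(v1 = list(lb = 0.2, ub = 2))))
  sp <- splitReversible(net)
  ids <- vapply(reactions(sp), `[[`, character(1), "id")
  expect_identical(ids, c("v1.f", "v1.b"))
  lb <- vapply(reactions(sp), `[[`, numeric(1), "lb")
  expect_true(all(lb >= 0))
  # reverse map is the inverse of the forward map
  fwd <- reactions(sp)[[1]]; rev <- reactions(sp)[[2]]
  expect_identical(rev$reactants, fwd$products)
  expect_identical(rev$products, fwd$reactants)
  # net-flux bounds become inequality rows enforcing lb <= vf - vb <= ub
  expect_equal(nrow(sp@Rineq), 2)
  expect_equal(unname(sp@Rineq %*% c(1, 0.5))[, 1] <= sp@bineq,
               c(TRUE, TRUE))
  v_violate <- c(0.1, 0)   # net flux 0.1 < lb 0.2
  expect_false(all(sp@Rineq %*% v_violate <= sp@bineq))
  # fully irreversible network is unchanged
  net2 <- parseNetwork("v1: A (a) -> B (a)")
  expect_identical(reactions(splitReversible(net2))[[1]]$id, "v1")
})

test_that("independent flux count equals reactions minus rank minus fixed", {
  chain <- splitReversible(parseNetwork(
    "vin: X (a) -> A (a)\nv1: A (a) -> B (a)\nvout: B (a) -> Y (a)",
    list(fixed = list(vin = 1))))
  expect_identical(countIndependentFluxes(chain, subtractFixed = FALSE), 1L)
  expect_identical(countIndependentFluxes(toyNetwork()), 3L)
  # cross-check against an explicit dense null-space dimension
  S <- as.matrix(stoichMatrix(toyNetwork()))
  expect_identical(ncol(S) - qr(S)$rank - 1L, 3L)   # v0 is fixed
})

test_that("feasible sampling respects all constraints and is deterministic", {
  net <- toyNetwork()
  S <- stoichMatrix(net)
  draws <- sampleFeasibleFluxesPools(net, seed = 5, n = 100)
  for (d in draws) {
    expect_lt(max(abs(as.numeric(S %*% d$v))), 1e-9)
    lb <- vapply(reactions(net), `[[`, numeric(1), "lb")
    ub <- vapply(reactions(net), `[[`, numeric(1), "ub")
    expect_true(all(d$v >= lb - 1e-9 & d$v <= ub + 1e-9))
    expect_true(all(as.numeric(net@Rineq %*% d$v) <= net@bineq + 1e-9))
    expect_true(all(d$pools >= 0.05 - 1e-12 & d$pools <= 20 + 1e-12))
  }
  again <- sampleFeasibleFluxesPools(net, seed = 5, n = 100)
  expect_identical(draws, again)
})

test_that("linear chain with fixed input has the unique unit solution", {
  chain <- splitReversible(parseNetwork(
    "vin: X (a) -> A (a)\nv1: A (a) -> B (a)\nvout: B (a) -> Y (a)",
    list(fixed = list(vin = 1))))
  d <- sampleFeasibleFluxesPools(chain, seed = 2)
  expect_equal(unname(d$v), c(1, 1, 1), tolerance = 1e-9)
})
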