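# Bundled synthetic toy model: metabolite A is converted to B through three
# pathways with distinct carbon rearrangements -- intact transfer via C
# (reversible first step), cleavage after carbon 1 via the one-carbon pool D
# and the two-carbon unit E, and cleavage after carbon 2 via the two-carbon
# unit F and the shared one-carbon pool D. The substrate is 100% U-13C with
# no natural abundance, so the steady state is fully enriched and all flux
# and pool information sits in the labeling transient: the three pathways
# leave distinct mass signatures on the B[1,2], B[2,3] and B[1,2,3]
# fragments (intact triple vs. recombination products of independently
# labeled one- and two-carbon units at different positions). The uptake v0
# is known exactly, leaving three independent fluxes and six intracellular
# pool sizes. The generating parameter values are this package's own choice
# of realistic magnitudes.

toyNetworkText <- function() {
  paste(
    "# three pathways from A to B, one reversible",
    "v0: A.ext (abc) -> A (abc)",
    "v1: A (abc) <-> C (abc)",
    "v2: C (abc) -> B (abc)",
    "v3: A (abc) -> D (a) + E (bc)",
    "v4: D (a) + E (bc) -> B (abc)",
    "v5: A (abc) -> F (ab) + D (c)",
    "v6: F (ab) + D (c) -> B (abc)",
    "v7: B (abc) -> B.ext (abc)",
    sep = "\n")
}

toyConfig <- function() {
  list(
    fixed = list(v0 = 1),
    bounds = list(v1 = list(lb = -5, ub = 5),
                  v2 = list(ub = 5), v3 = list(ub = 5), v4 = list(ub = 5),
                  v5 = list(ub = 5), v6 = list(ub = 5), v7 = list(ub = 5)),
    pools = lapply(setNames(nm = c("A", "B", "C", "D", "E", "F")),
                   function(m) list(lb = 0.05, ub = 20)),
    tracers = list(list(substrate = "A.ext", fraction = 1,
                        positions = "U", enrichment = 1)),
    nat_abundance = 0
  )
}

#' Bundled toy network
#'
#' A small synthetic nonstationary MFA model: substrate A is taken up at a
#' known rate and converted to product B by three pathways with distinct
#' carbon atom rearrangements (one reversible, one passing through a
#' cleavage into two- and one-carbon intermediates that recombine). Six
#' intracellular pools, three independent fluxes. The fed substrate is 100%
#' uniformly 13C-labeled and natural abundance is zero, so all flux and pool
#' information is in the labeling transient.
#'
#' @param split split reversible reactions (default TRUE).
#' @return an [MFANetwork-class].
#' @export
toyNetwork <- function(split = TRUE) {
  net <- parseNetwork(toyNetworkText(), toyConfig())
  if (split) net <- splitReversible(net, exchangeUb = 5)
  net
}

#' Generating parameters of the toy model
#'
#' The flux distribution satisfies the stoichiometric balances with the
#' uptake fixed at 1; the reversible step carries an exchange flux.
#'
#' @return list with named vectors `v` (fluxes of the split network) and
#'   `pools` (metabolite pool sizes).
#' @export
toyTruth <- function() {
  v <- c(v0 = 1, v1.f = 0.55, v1.b = 0.3, v2 = 0.25,
         v3 = 0.3, v4 = 0.3, v5 = 0.45, v6 = 0.45, v7 = 1)
  pools <- c(A = 1.5, B = 4, C = 2, D = 0.5, E = 0.8, F = 0.6)
  list(v = v, pools = pools)
}

#' Measured fragments of the toy model
#'
#' Fragments B[1,2], B[2,3] and B[1,2,3] of the product metabolite.
#'
#' @return fragment definition data.frame for [buildMeasurementModel()].
#' @export
toyFragments <- function() {
  data.frame(id = c("B12", "B23", "B123"), met = "B",
             atoms = c("1,2", "2,3", "1,2,3"),
             daughter = "", formula = "", stringsAsFactors = FALSE)
}

#' Simulate the toy study: trajectory and noisy measurement table
#'
#' Forward-simulates the labeling dynamics at the generating parameters with
#' fixed-step RK4 (dt = 0.02) and draws Gaussian measurement noise on the
#' fragment MIDs at times 2, 4, ..., 20.
#'
#' @param noiseSd measurement noise standard deviation (default 0.01).
#' @param seed integer seed for the noise draw.
#' @param times measurement times.
#' @return list: `net`, `states`, `arrays`, `mm` (with measured values
#'   attached), `truth`, `traj`, `meas`.
#' @export
toyStudy <- function(noiseSd = 0.01, seed = 1L, times = seq(2, 20, by = 2)) {
  net <- toyNetwork()
  truth <- toyTruth()
  states <- enumerateCumomers(net)
  arrays <- buildModelArrays(net, states)
  pools <- buildPoolModel(net, states)
  x0 <- buildInputVector(net, states)
  traj <- integrateLabeling(arrays, truth$v, pools, truth$pools, x0,
                            times = sort(unique(c(0, times))), dt = 0.02)
  mm0 <- buildMeasurementModel(states, toyFragments(), natAbundance = 0)
  meas <- generateSyntheticMeasurements(traj, mm0, times, noiseSd = noiseSd,
                                        seed = seed)
  mm <- buildMeasurementModel(states, toyFragments(), meas, natAbundance = 0)
  list(net = net, states = states, arrays = arrays, pools = pools, x0 = x0,
       mm = mm, truth = truth, traj = traj, meas = meas)
}

#' Default collocation grid for the toy study
#'
#' Eight intervals on [0, 20], short at early times so the fast initial
#' labeling transient (the fastest pool turns over in about one time unit)
#' is resolved, widening toward the slowly varying tail.
#'
#' @return a [TimeGrid-class].
#' @export
toyGrid <- function() makeTimeGrid(c(0, 1, 2, 4, 6, 9, 12, 16, 20))
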