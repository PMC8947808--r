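# Shared fixtures: small networks exercising permutation, reversibility,
# cleavage/condensation, self-condensation and tracer mixtures. All are
# small enough for the brute-force isotopomer oracle.

chainNetwork <- function() {
  splitReversible(parseNetwork(paste(
    "vin: X.ext (abc) -> A (abc)",
    "v1: A (abc) <-> B (cab)",
    "v2: B (abc) -> C (bca)",
    "vout: C (abc) -> C.ext (abc)",
    sep = "\n"),
    list(fixed = list(vin = 1),
         bounds = list(v1 = list(lb = -4, ub = 4), v2 = list(ub = 6),
                       vout = list(ub = 6)),
         tracers = list(list(substrate = "X.ext", fraction = 0.7,
                             positions = c(1, 3), enrichment = 0.95),
                        list(substrate = "X.ext", fraction = 0.3,
                             positions = "U", enrichment = 0.99)),
         nat_abundance = 0.011)), exchangeUb = 4)
}

cleaveNetwork <- function() {
  splitReversible(parseNetwork(paste(
    "vin: X.ext (abcd) -> A (abcd)",
    "v1: A (abcd) -> B (ab) + C (cd)",
    "v2: B (ab) + C (cd) -> D (cadb)",
    "v3: B (ab) -> E (ba)",
    "v4: A (abcd) -> D (badc)",
    "vC: C (ab) -> C.ext (ab)",
    "vD: D (abcd) -> D.ext (abcd)",
    "vE: E (ab) -> E.ext (ab)",
    sep = "\n"),
    list(fixed = list(vin = 1),
         bounds = list(v1 = list(ub = 6), v2 = list(ub = 6),
                       v3 = list(ub = 6), v4 = list(ub = 6),
                       vC = list(ub = 6), vD = list(ub = 6),
                       vE = list(ub = 6)),
         tracers = list(list(substrate = "X.ext", fraction = 1,
                             positions = c(1, 2), enrichment = 0.99)),
         nat_abundance = 0.0107)))
}

selfCondenseNetwork <- function() {
  splitReversible(parseNetwork(paste(
    "vin: X.ext (a) -> A (a)",
    "v1: A (a) + A (b) -> B (ab)",
    "vout: B (ab) -> B.ext (ab)",
    sep = "\n"),
    list(fixed = list(vin = 1),
         bounds = list(v1 = list(ub = 6), vout = list(ub = 6)),
         tracers = list(list(substrate = "X.ext", fraction = 1,
                             positions = "U", enrichment = 0.8)),
         nat_abundance = 0)))
}

# fragments covering every balanced metabolite of a fixture network
allFragments <- function(net) {
  mets <- metabolites(net)
  mets <- mets[mets$role == "balanced" & mets$n_carbons > 0, ]
  data.frame(id = paste0(mets$name, "_full"), met = mets$name,
             atoms = vapply(mets$n_carbons, function(n)
               paste(seq_len(n), collapse = ","), character(1)),
             daughter = "", formula = "", stringsAsFactors = FALSE)
}

# oracle fragment MIDs (list per fragment) at steady state / a time index
oracleMids <- function(isoList, fragments) {
  out <- list()
  for (i in seq_len(nrow(fragments))) {
    atoms <- as.integer(strsplit(fragments$atoms[i], ",")[[1]])
    out[[fragments$id[i]]] <- isotopomerMid(isoList[[fragments$met[i]]], atoms)
  }
  out
}

# cumomer- or EMU-pipeline fragment MIDs from a composite state vector
pipelineMids <- function(states, fragments, x) {
  mm <- buildMeasurementModel(states, fragments, natAbundance = 0)
  sims <- as.numeric(mm@M %*% x)
  split(sims, mm@channels$fragment)[fragments$id]
}

# a strictly interior feasible flux draw (vertex draws can zero out a
# pathway and leave dead-end states): average several polytope samples
fixtureFluxes <- function(net, seed = 1) {
  draws <- sampleFeasibleFluxesPools(net, seed = seed, n = 4)
  v <- rowMeans(vapply(draws, `[[`, draws[[1]]$v, "v"))
  v
}

randomPools <- function(net, seed = 1, lo = 0.3, hi = 3) {
  mets <- metabolites(net)
  mets <- mets$name[mets$role == "balanced"]
  set.seed(seed)
  setNames(exp(runif(length(mets), log(lo), log(hi))), mets)
}
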