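# Input/initial labeling state vector from the tracer specification.

# per-atom enrichment vector for one tracer mixture component
componentEnrichment <- function(comp, nCarbons, natAbundance) {
  e <- rep(natAbundance, nCarbons)
  pos <- comp$positions %||% "U"
  enr <- comp$enrichment %||% 1
  if (enr < 0 || enr > 1) stopf("tracer enrichment must lie in [0, 1]")
  if (identical(pos, "U")) e[] <- enr
  else e[as.integer(unlist(pos))] <- enr
  e
}

# mass distribution of the number of labeled atoms among `atoms`
# (independent per-atom labeling probabilities e): iterated convolution
labelCountDist <- function(e, atoms) {
  d <- 1
  for (a in atoms) d <- convolve1(d, c(1 - e[a], e[a]))
  d
}

convolve1 <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Build the input/initial labeling state vector
#'
#' Computes the value of every labeling state at time zero (and, for input
#' metabolites, for all times): cumomer values are mixture-weighted products
#' of per-atom enrichments, EMU states carry the corresponding mass
#' distributions. Atoms not named by a tracer component get the natural 13C
#' abundance, as do all metabolites without a tracer entry. Tracer entries
#' for balanced metabolites set their initial labeling (impulse-input
#' experiments); balanced metabolites without an entry start at natural
#' abundance.
#'
#' @param net an [MFANetwork-class] (its `tracers` and `natAbundance` are the
#'   defaults).
#' @param states a [LabelingStates-class].
#' @param tracers list of mixture components (`substrate`, `fraction`,
#'   `positions` = integer vector or `"U"`, `enrichment`); fractions must sum
#'   to 1 per substrate.
#' @param natAbundance natural 13C abundance.
#' @return named numeric vector over the composite state order; weight-0
#'   cumomer states are 1.
#' @export
buildInputVector <- function(net, states, tracers = net@tracers,
                             natAbundance = net@natAbundance) {
  st <- states@states
  mets <- net@metabolites
  bySub <- split(tracers, vapply(tracers, `[[`, character(1), "substrate"))
  for (sub in names(bySub)) {
    fr <- vapply(bySub[[sub]], function(tr) tr$fraction %||% 1, numeric(1))
    if (abs(sum(fr) - 1) > 1e-8)
      stopf("tracer mixture fractions for '%s' must sum to 1 (got %g)", sub, sum(fr))
  }
  x <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    met <- st$met[i]
    nc <- mets$n_carbons[match(met, mets$name)]
    atoms <- maskToAtoms(st$mask[i])
    comps <- bySub[[met]]
    if (is.null(comps))
      comps <- list(list(fraction = 1, positions = integer(0), enrichment = 0))
    val <- 0
    for (comp in comps) {
      f <- comp$fraction %||% 1
      e <- componentEnrichment(comp, nc, natAbundance)
      if (is.na(st$mass[i])) { # cumomer: P(all atoms labeled)
        val <- val + f * prod(e[atoms])
      } else {                 # EMU mass fraction
        d <- labelCountDist(e, atoms)
        val <- val + f * d[st$mass[i] + 1L]
      }
    }
    x[i] <- val
  }
  names(x) <- st$key
  x
}
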