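#' Accessors for fluxnlp model objects
#'
#' Small generic accessor family used instead of direct slot access.
#'
#' @param object a fluxnlp model object.
#' @return `metabolites()` and `reactions()` return the metabolite table and
#'   reaction list of an [MFANetwork-class]; `statesTable()` the state table
#'   of a [LabelingStates-class] or [ModelArrays-class]; `framework()` the
#'   framework tag; `fluxes()`, `poolSizes()` and `ssr()` the estimates and
#'   objective of an [MFAFit-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("statesTable", function(object) standardGeneric("statesTable"))
#' @rdname accessors
#' @export
setGeneric("framework", function(object) standardGeneric("framework"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("poolSizes", function(object) standardGeneric("poolSizes"))
#' @rdname accessors
#' @export
setGeneric("ssr", function(object) standardGeneric("ssr"))

#' @rdname accessors
setMethod("metabolites", "MFANetwork", function(object) object@metabolites)
#' @rdname accessors
setMethod("reactions", "MFANetwork", function(object) object@reactions)
#' @rdname accessors
setMethod("statesTable", "LabelingStates", function(object) object@states)
#' @rdname accessors
setMethod("statesTable", "ModelArrays", function(object) object@states@states)
#' @rdname accessors
setMethod("framework", "LabelingStates", function(object) object@framework)
#' @rdname accessors
setMethod("framework", "ModelArrays", function(object) object@framework)
#' @rdname accessors
setMethod("framework", "MeasurementModel", function(object) object@framework)
#' @rdname accessors
setMethod("fluxes", "MFAFit", function(object) object@v)
#' @rdname accessors
setMethod("poolSizes", "MFAFit", function(object) object@pools)
#' @rdname accessors
setMethod("ssr", "MFAFit", function(object) object@z)

setMethod("show", "MFANetwork", function(object) {
  met <- object@metabolites
  cat(sprintf("MFANetwork: %d metabolites (%d balanced, %d input, %d output), %d reactions%s\n",
              nrow(met), sum(met$role == "balanced"), sum(met$role == "input"),
              sum(met$role == "output"), length(object@reactions),
              if (object@split) " (reversible split)" else ""))
  if (!is.null(object@Rineq) && nrow(object@Rineq) > 0)
    cat(sprintf("  %d flux inequality constraints\n", nrow(object@Rineq)))
  if (nrow(object@fluxMeas) > 0)
    cat(sprintf("  %d measured fluxes\n", nrow(object@fluxMeas)))
})

setMethod("show", "LabelingStates", function(object) {
  st <- object@states
  cat(sprintf("LabelingStates (%s): %d states (%d pinned), weights %d..%d\n",
              object@framework, nrow(st), sum(st$pinned),
              min(st$weight), max(st$weight)))
})

setMethod("show", "ModelArrays", function(object) {
  cat(sprintf("ModelArrays (%s): %d states; Q %d, P %d, Pinp %d nonzeros over %d reactions\n",
              object@framework, nrow(object@states@states),
              nrow(object@Q), nrow(object@P), nrow(object@Pinp),
              length(object@rxnIds)))
})

setMethod("show", "MeasurementModel", function(object) {
  cat(sprintf("MeasurementModel (%s): %d fragments, %d channels, %d measured values%s\n",
              object@framework, nrow(object@fragments), nrow(object@channels),
              nrow(object@meas),
              if (length(object@times)) sprintf(", %d time points", length(object@times)) else ""))
})

setMethod("show", "CollocationScheme", function(object) {
  cat(sprintf("Radau IIA collocation: s = %d stages, order %d\n  nodes: %s\n",
              object@s, object@order, paste(signif(object@c, 6), collapse = ", ")))
})

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid: %d intervals on [%g, %g]\n",
              length(object@h), object@nodes[1], object@nodes[length(object@nodes)]))
})

setMethod("show", "MFAFit", function(object) {
  cat(sprintf("MFAFit: SSR = %.6g, status = %s, feasibility residual = %.2e\n",
              object@z, object@status, object@feasResid))
  cat("  fluxes:\n")
  print(round(object@v, 5))
  if (length(object@pools)) {
    cat("  pool sizes:\n")
    print(round(object@pools, 5))
  }
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d resamples (%d failed), %.0f%% percentile intervals\n",
              nrow(object@samples), object@nFail, 100 * object@level))
  print(object@summary, digits = 5)
})
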