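# Natural isotope abundance handling for atoms outside the carbon backbone.

#' Natural isotope mass-shift distributions
#'
#' Per-atom probability of mass shifts +0, +1, ... for the elements commonly
#' found in derivatized metabolite fragments. Values are IUPAC representative
#' isotopic compositions.
#'
#' @return named list of numeric vectors (ascending mass shift).
#' @export
isotopeTable <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    Si = c(0.92223, 0.04685, 0.03092)
  )
}

parseFormula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != gsub("\\s", "", formula))
    stopf("cannot parse elemental formula '%s'", formula)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  if (any(ct < 0)) stopf("negative element count in formula '%s'", formula)
  out <- tapply(ct, el, sum)
  setNames(as.integer(out), names(out))
}

#' Natural-abundance convolution operator
#'
#' Builds the column-stochastic matrix that maps a carbon-backbone MID to the
#' observed MID when the measured ion carries additional atoms (derivatization
#' groups, heteroatoms) at natural isotope abundance. Row `m+1`, column `j+1`
#' holds the probability that the extra atoms contribute mass shift `m - j`.
#'
#' @param formula elemental formula of the atoms outside the carbon backbone
#'   (e.g. `"C4H9NO2Si"`), or `""`/`NULL` for none.
#' @param nBackbone number of backbone carbons (columns span masses 0..n).
#' @param isotopes isotope table, see [isotopeTable()].
#' @return matrix with `nBackbone + 1` columns; rows cover all reachable
#'   observed masses. Columns each sum to 1.
#' @export
naturalAbundanceOperator <- function(formula, nBackbone,
                                     isotopes = isotopeTable()) {
  counts <- parseFormula(formula)
  extra <- 1
  for (el in names(counts)) {
    d <- isotopes[[el]]
    if (is.null(d)) stopf("no isotope data for element '%s'", el)
    for (i in seq_len(counts[[el]])) extra <- convolve1(extra, d)
  }
  nr <- nBackbone + length(extra)
  op <- matrix(0, nr, nBackbone + 1L)
  for (j in 0:nBackbone)
    op[j + seq_along(extra), j + 1L] <- extra
  rownames(op) <- paste0("M+", 0:(nr - 1L))
  colnames(op) <- paste0("M+", 0:nBackbone)
  op
}
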