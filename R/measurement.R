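# Measurement modeling: cumomer/isotopomer transforms, tandem-MS mass
# matrices, and construction of the mapping matrices M and U.

#' Convert cumomer values of one metabolite to isotopomer fractions
#'
#' Inverse of the subset-sum (zeta) transform: for atom subsets S of an
#' n-carbon metabolite, `iso[S] = sum_{T >= S} (-1)^{|T|-|S|} cum[T]`
#' (Moebius inversion). The input is ordered by atom bitmask 0..2^n-1 with
#' the weight-0 entry equal to 1; the output sums to 1.
#'
#' @param x numeric vector of 2^n cumomer values in bitmask order.
#' @param clampTol negative results larger than `-clampTol` are clamped to 0
#'   and the distribution renormalized; larger negativity is an error.
#' @return numeric vector of 2^n isotopomer fractions in bitmask order.
#' @seealso [isotopomersToCumomers()]
#' @export
cumomersToIsotopomers <- function(x, clampTol = 1e-9) {
  n <- as.integer(round(log2(length(x))))
  if (2^n != length(x)) stopf("length must be a power of 2")
  if (abs(x[1] - 1) > 1e-6)
    stopf("zero-order cumomer must be 1 (got %g)", x[1])
  iso <- as.numeric(x)
  # superset Moebius transform, one bit at a time
  for (b in seq_len(n) - 1L) {
    hasBit <- bitwAnd(seq_along(iso) - 1L, bitwShiftL(1L, b)) != 0L
    iso[!hasBit] <- iso[!hasBit] - iso[hasBit]
  }
  if (any(iso < -clampTol))
    stopf("cumomer values are numerically inconsistent (isotopomer %g < 0)",
          min(iso))
  if (any(iso < 0)) {
    warnf("clamping %d slightly negative isotopomer fractions", sum(iso < 0))
    iso[iso < 0] <- 0
    iso <- iso / sum(iso)
  }
  iso
}

#' Convert isotopomer fractions to cumomer values
#'
#' Superset-sum (zeta) transform: `cum[T] = sum_{S >= T} iso[S]`.
#'
#' @param iso numeric vector of 2^n isotopomer fractions in bitmask order.
#' @return numeric vector of 2^n cumomer values in bitmask order.
#' @export
isotopomersToCumomers <- function(iso) {
  n <- as.integer(round(log2(length(iso))))
  if (2^n != length(iso)) stopf("length must be a power of 2")
  cum <- as.numeric(iso)
  for (b in seq_len(n) - 1L) {
    hasBit <- bitwAnd(seq_along(cum) - 1L, bitwShiftL(1L, b)) != 0L
    cum[!hasBit] <- cum[!hasBit] + cum[hasBit]
  }
  cum
}

#' Tandem mass-isotopomer matrix of a fragment
#'
#' Joint parent/daughter mass distribution: entry (M+1, m+1) is the summed
#' fraction of isotopomers with M labeled carbons among the parent atoms and
#' m labeled carbons among the daughter atoms.
#'
#' @param iso isotopomer fractions of the whole metabolite (bitmask order,
#'   length 2^n).
#' @param parentAtoms integer positions of the parent fragment's carbons.
#' @param daughterAtoms integer positions of the daughter's carbons (subset
#'   of `parentAtoms`).
#' @return matrix of dimension `(|parent|+1) x (|daughter|+1)`; its row sums
#'   are the parent MID.
#' @export
tandemMid <- function(iso, parentAtoms, daughterAtoms = integer(0)) {
  if (!all(daughterAtoms %in% parentAtoms))
    stopf("daughter atoms must be a subset of the parent atoms")
  n <- as.integer(round(log2(length(iso))))
  pm <- atomsToMask(parentAtoms); dm <- atomsToMask(daughterAtoms)
  S <- seq_along(iso) - 1L
  Ms <- maskWeight(bitwAnd(S, pm))
  ms <- maskWeight(bitwAnd(S, dm))
  out <- matrix(0, length(parentAtoms) + 1L, length(daughterAtoms) + 1L,
                dimnames = list(paste0("M+", 0:length(parentAtoms)),
                                paste0("m+", 0:length(daughterAtoms))))
  for (idx in seq_along(iso))
    out[Ms[idx] + 1L, ms[idx] + 1L] <- out[Ms[idx] + 1L, ms[idx] + 1L] + iso[idx]
  out
}

# Linear coefficients of the (parent mass, daughter mass) channels of a
# fragment over the cumomers of subsets of its parent atoms. Returns a list
# of data.frames keyed by channel: subset mask (within the metabolite) and
# coefficient. Derivation: iso[S] = sum_{T >= S} (-1)^{|T|-|S|} cum[T] over
# subsets of the parent atom set, so channel (M, m) = sum over S with
# |S| = M, |S n D| = m of iso[S].
cumomerChannelCoefs <- function(parentAtoms, daughterAtoms = integer(0)) {
  np <- length(parentAtoms)
  subsets <- 0:(2^np - 1L)
  # local bit positions -> metabolite atom positions
  toMet <- function(localMask) {
    atomsToMask(parentAtoms[maskToAtoms(localMask)])
  }
  dLocal <- atomsToMask(which(parentAtoms %in% daughterAtoms))
  coefEnv <- new.env(parent = emptyenv())
  add <- function(chKey, metMask, coef) {
    cur <- coefEnv[[chKey]]
    if (is.null(cur)) cur <- list(mask = integer(0), coef = numeric(0))
    hit <- match(metMask, cur$mask)
    if (is.na(hit)) {
      cur$mask <- c(cur$mask, metMask); cur$coef <- c(cur$coef, coef)
    } else cur$coef[hit] <- cur$coef[hit] + coef
    assign(chKey, cur, envir = coefEnv)
  }
  for (S in subsets) {
    Ms <- maskWeight(S)
    ms <- maskWeight(bitwAnd(S, dLocal))
    chKey <- paste0(Ms, ":", ms)
    # enumerate supersets T of S within the parent set
    comp <- bitwAnd(bitwNot(S), 2^np - 1L)
    compBits <- maskToAtoms(comp)
    for (addMask in 0:(2^length(compBits) - 1L)) {
      Tmask <- bitwOr(S, atomsToMask(compBits[maskToAtoms(addMask)]))
      add(chKey, toMet(Tmask), (-1)^(maskWeight(Tmask) - Ms))
    }
  }
  coefEnv
}

defaultFragments <- function() {
  data.frame(id = character(0), met = character(0), atoms = character(0),
             daughter = character(0), formula = character(0),
             stringsAsFactors = FALSE)
}

#' Build the measurement model (mapping matrix M and scaling matrix U)
#'
#' Assembles one row of the sparse mapping matrix M per measurement channel
#' (fragment x parent mass [x daughter mass]); `m = M %*% x` gives the
#' simulated measurements for a composite state vector x. Single-MS
#' fragments map, in the EMU framework, directly to the EMU mass states of
#' their atom set; in the cumomer framework the linear inclusion-exclusion
#' over sub-cumomers is stored. Tandem fragments (nonempty daughter set)
#' require the cumomer framework. A nonempty elemental `formula` folds the
#' natural-abundance convolution of non-backbone atoms into the fragment's M
#' rows (single MS only). U ties every channel to its fragment.
#'
#' @param states a [LabelingStates-class].
#' @param fragments data.frame with columns `id`, `met`, `atoms` (e.g.
#'   `"1,2,3"`), `daughter` (`""` for single MS), `formula` (`""` for none).
#' @param meas optional data.frame of measured values with columns
#'   `fragment`, `time` (`NA` for steady state), `mass`, `dmass`, `value`,
#'   `sd`; matched to channels by (fragment, mass, dmass).
#' @param natAbundance natural 13C abundance for backbone-external carbon in
#'   `formula`s (passed to [naturalAbundanceOperator()] via the isotope
#'   table; the table's carbon entry is replaced by
#'   `c(1 - natAbundance, natAbundance)`).
#' @return a [MeasurementModel-class].
#' @export
buildMeasurementModel <- function(states, fragments, meas = NULL,
                                  natAbundance = 0.0107) {
  st <- states@states
  emu <- states@framework == "emu"
  idxEnv <- new.env(parent = emptyenv(), size = nrow(st))
  for (i in seq_len(nrow(st))) assign(st$key[i], i, envir = idxEnv)
  lookup <- function(met, mask, mass = NA_integer_) {
    k <- idxEnv[[stateKey(met, mask, mass)]]
    if (is.null(k)) NA_integer_ else k
  }
  iso <- isotopeTable()
  iso$C <- c(1 - natAbundance, natAbundance)

  chFragment <- character(0); chMass <- integer(0); chDmass <- integer(0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  addRow <- function(frag, mass, dmass, jIdx, coefs) {
    chFragment <<- c(chFragment, frag)
    chMass <<- c(chMass, mass); chDmass <<- c(chDmass, dmass)
    n <- length(chFragment)
    ii <<- c(ii, rep(n, length(jIdx))); jj <<- c(jj, jIdx); xx <<- c(xx, coefs)
  }

  for (f in seq_len(nrow(fragments))) {
    frag <- fragments$id[f]
    met <- fragments$met[f]
    atoms <- parseAtomList(fragments$atoms[f])
    datoms <- parseAtomList(fragments$daughter[f])
    formula <- fragments$formula[f] %||% ""
    if (is.na(formula)) formula <- ""
    tandem <- length(datoms) > 0
    if (length(setdiff(datoms, atoms)))
      stopf("fragment '%s': daughter atoms must be a subset of the backbone", frag)
    if (tandem && emu)
      stopf("fragment '%s' is a tandem fragment; tandem MS requires the cumomer framework",
            frag)
    if (tandem && nzchar(formula))
      stopf("fragment '%s': natural-abundance formulas are supported for single-MS fragments only",
            frag)
    w <- length(atoms)
    if (emu) {
      rows <- lapply(0:w, function(m) {
        j <- lookup(met, atomsToMask(atoms), m)
        if (is.na(j))
          stopf("fragment '%s': EMU %s missing from the decomposition (add it to the targets)",
                frag, stateKey(met, atomsToMask(atoms), m))
        list(j = j, coef = 1)
      })
      baseRows <- lapply(seq_along(rows), function(m)
        list(mass = m - 1L, dmass = NA_integer_,
             j = rows[[m]]$j, coef = rows[[m]]$coef))
    } else {
      coefEnv <- cumomerChannelCoefs(atoms, datoms)
      keys <- ls(coefEnv)
      ord <- order(as.integer(sub(":.*", "", keys)),
                   as.integer(sub(".*:", "", keys)))
      baseRows <- lapply(keys[ord], function(k) {
        cc <- coefEnv[[k]]
        jIdx <- vapply(cc$mask, function(m) lookup(met, m), integer(1))
        if (anyNA(jIdx))
          stopf("fragment '%s': cumomer states of '%s' missing", frag, met)
        keep <- cc$coef != 0
        list(mass = as.integer(sub(":.*", "", k)),
             dmass = if (tandem) as.integer(sub(".*:", "", k)) else NA_integer_,
             j = jIdx[keep], coef = cc$coef[keep])
      })
      if (!tandem) {
        # collapse duplicate (mass) channels: with empty daughter set each
        # parent mass appears once already
        baseRows <- baseRows[!duplicated(vapply(baseRows, `[[`, integer(1), "mass"))]
      }
    }
    if (nzchar(formula)) {
      op <- naturalAbundanceOperator(formula, w, isotopes = iso)
      # observed mass rows as linear combinations of backbone rows
      for (mObs in seq_len(nrow(op)) - 1L) {
        jAll <- integer(0); cAll <- numeric(0)
        for (mB in 0:w) {
          wgt <- op[mObs + 1L, mB + 1L]
          if (wgt == 0) next
          br <- baseRows[[mB + 1L]]
          jAll <- c(jAll, br$j); cAll <- c(cAll, wgt * br$coef)
        }
        if (length(jAll))
          addRow(frag, mObs, NA_integer_, jAll, cAll)
      }
    } else {
      for (br in baseRows)
        addRow(frag, br$mass, br$dmass, br$j, br$coef)
    }
  }

  nCh <- length(chFragment)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nCh, nrow(st)))
  channels <- data.frame(fragment = chFragment, mass = chMass, dmass = chDmass,
                         stringsAsFactors = FALSE)
  U <- Matrix::sparseMatrix(i = seq_len(nCh),
                            j = match(chFragment, fragments$id),
                            x = 1, dims = c(nCh, nrow(fragments)))
  times <- numeric(0)
  measDf <- data.frame(channel = integer(0), time = numeric(0),
                       value = numeric(0), sd = numeric(0))
  if (!is.null(meas) && nrow(meas)) {
    if (!"dmass" %in% names(meas)) meas$dmass <- NA_integer_
    if (!"time" %in% names(meas)) meas$time <- NA_real_
    chKey <- paste(channels$fragment, channels$mass, channels$dmass, sep = "/")
    mKey <- paste(meas$fragment, meas$mass, meas$dmass, sep = "/")
    ch <- match(mKey, chKey)
    if (anyNA(ch))
      stopf("measurement references unknown channel '%s'", mKey[which(is.na(ch))[1]])
    measDf <- data.frame(channel = ch, time = meas$time,
                         value = meas$value, sd = meas$sd)
    ord <- order(measDf$channel, measDf$time, na.last = TRUE)
    measDf <- measDf[ord, , drop = FALSE]
    rownames(measDf) <- NULL
    times <- sort(unique(measDf$time[!is.na(measDf$time)]))
  }
  new("MeasurementModel", fragments = fragments, channels = channels,
      M = M, U = U, meas = measDf, times = times,
      framework = states@framework)
}

#' Read / write the flat measurement table dialect
#'
#' Tab-separated with columns `fragment_id`, `metabolite`, `atoms`,
#' `daughter_atoms`, `formula`, `time`, `mass`, `daughter_mass`, `value`,
#' `sd`. Fragment definitions are repeated on every row of the fragment;
#' empty `daughter_atoms` means single MS, empty `time` means steady state.
#'
#' @param path file path.
#' @return `readMeasurementTable`: list with `fragments` (unique definitions)
#'   and `meas` (values table as used by [buildMeasurementModel()]).
#' @export
readMeasurementTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(fragment_id = "character"))
  need <- c("fragment_id", "metabolite", "atoms", "daughter_atoms", "formula",
            "time", "mass", "daughter_mass", "value", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("measurement table missing columns: %s",
                          paste(miss, collapse = ", "))
  fr <- unique(df[c("fragment_id", "metabolite", "atoms", "daughter_atoms", "formula")])
  fragments <- data.frame(id = fr$fragment_id, met = fr$metabolite,
                          atoms = as.character(fr$atoms),
                          daughter = ifelse(is.na(fr$daughter_atoms), "",
                                            as.character(fr$daughter_atoms)),
                          formula = ifelse(is.na(fr$formula), "",
                                           as.character(fr$formula)),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(fragments$id))
    stopf("fragment '%s' has inconsistent definitions across rows",
          fragments$id[duplicated(fragments$id)][1])
  meas <- data.frame(fragment = df$fragment_id, time = df$time,
                     mass = df$mass, dmass = df$daughter_mass,
                     value = df$value, sd = df$sd)
  list(fragments = fragments, meas = meas)
}

#' @rdname readMeasurementTable
#' @param fragments,meas tables as returned by `readMeasurementTable`.
#' @export
writeMeasurementTable <- function(fragments, meas, path) {
  fi <- match(meas$fragment, fragments$id)
  out <- data.frame(fragment_id = meas$fragment,
                    metabolite = fragments$met[fi],
                    atoms = fragments$atoms[fi],
                    daughter_atoms = fragments$daughter[fi],
                    formula = fragments$formula[fi],
                    time = meas$time, mass = meas$mass,
                    daughter_mass = meas$dmass,
                    value = meas$value, sd = meas$sd)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
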