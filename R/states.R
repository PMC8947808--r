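# Enumeration of labeling states: full cumomer sets and measurement-driven
# EMU decompositions.

stateMets <- function(net) {
  m <- net@metabolites
  m[m$role != "output" & m$n_carbons > 0, , drop = FALSE]
}

# For product occurrence `pi` of reaction `r` and an atom subset of that
# product, return the pre-image grouped by reactant occurrence:
# list of list(met, occ, atoms). Letters tie product carbons to reactant
# carbons.
preimageGroups <- function(r, pi, atoms) {
  letters_ <- r$products[[pi]]$atoms[atoms]
  groups <- list()
  for (ri in seq_along(r$reactants)) {
    hit <- which(r$reactants[[ri]]$atoms %in% letters_)
    if (length(hit))
      groups[[length(groups) + 1L]] <- list(met = r$reactants[[ri]]$met,
                                            occ = ri, atoms = hit)
  }
  nfound <- sum(vapply(groups, function(g) length(g$atoms), integer(1)))
  if (nfound != length(atoms))
    stopf("reaction '%s': product carbons of %s not fully mapped",
          r$id, r$products[[pi]]$met)
  groups
}

orderStates <- function(df) {
  ord <- order(df$weight, df$met, df$mask, df$mass, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Enumerate all cumomer states of a network
#'
#' For every metabolite carrying tracked carbon (balanced or input; output
#' sinks are not simulated) all 2^n cumomer states are created, ordered by
#' ascending weight, then metabolite name, then atom bitmask. Weight-0 states
#' are pinned to 1; all states of input metabolites are pinned to their
#' tracer-determined values.
#'
#' @param net a split [MFANetwork-class].
#' @return a [LabelingStates-class] with framework `"cumomer"`.
#' @export
enumerateCumomers <- function(net) {
  mets <- stateMets(net)
  rows <- list()
  for (i in seq_len(nrow(mets))) {
    nc <- mets$n_carbons[i]
    masks <- 0:(2^nc - 1L)
    rows[[i]] <- data.frame(met = mets$name[i], mask = masks,
                            weight = maskWeight(masks), mass = NA_integer_,
                            pinned = mets$role[i] == "input",
                            stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, rows)
  st$pinned <- st$pinned | st$weight == 0L
  st <- orderStates(st)
  st$key <- stateKey(st$met, st$mask)
  new("LabelingStates", states = st, framework = "cumomer")
}

#' Number of isotopomers in a network
#'
#' Sum of 2^n over all metabolites with tracked carbon (the states a full
#' isotopomer model would carry).
#'
#' @param net an [MFANetwork-class].
#' @return integer isotopomer count.
#' @export
countIsotopomers <- function(net) {
  sum(2^stateMets(net)$n_carbons)
}

#' EMU decomposition from measured fragments
#'
#' Computes the minimal closed set of elementary metabolite units reachable
#' backward from the target fragments through the atom maps, then expands
#' each EMU of size w into its w+1 mass-shift states. States are ordered by
#' ascending EMU size, then metabolite, then atom bitmask, then mass.
#'
#' @param net a split [MFANetwork-class].
#' @param targets list of fragment targets, each `list(met =, atoms =)` with
#'   `atoms` an integer vector of carbon positions.
#' @return a [LabelingStates-class] with framework `"emu"`.
#' @export
emuDecompose <- function(net, targets) {
  mets <- net@metabolites
  seen <- new.env(parent = emptyenv())
  queue <- list()
  pushEmu <- function(met, mask) {
    key <- paste0(met, "#", mask)
    if (is.null(seen[[key]])) {
      assign(key, list(met = met, mask = mask), envir = seen)
      queue[[length(queue) + 1L]] <<- list(met = met, mask = mask)
    }
  }
  for (tg in targets) {
    i <- match(tg$met, mets$name)
    if (is.na(i)) stopf("EMU target references unknown metabolite '%s'", tg$met)
    if (any(tg$atoms > mets$n_carbons[i]) || any(tg$atoms < 1))
      stopf("EMU target atoms exceed carbon count of '%s'", tg$met)
    pushEmu(tg$met, atomsToMask(tg$atoms))
  }
  while (length(queue)) {
    e <- queue[[1]]; queue[[1]] <- NULL
    role <- mets$role[match(e$met, mets$name)]
    if (role != "balanced") next # input EMUs are terminal (values known)
    atoms <- maskToAtoms(e$mask)
    for (r in net@reactions) {
      for (pi in seq_along(r$products)) {
        if (r$products[[pi]]$met != e$met) next
        for (g in preimageGroups(r, pi, atoms))
          pushEmu(g$met, atomsToMask(g$atoms))
      }
    }
  }
  emus <- eapply(seen, identity)
  rows <- lapply(emus, function(e) {
    w <- length(maskToAtoms(e$mask))
    data.frame(met = e$met, mask = e$mask, weight = w, mass = 0:w,
               pinned = mets$role[match(e$met, mets$name)] == "input",
               stringsAsFactors = FALSE)
  })
  st <- orderStates(do.call(rbind, rows))
  st$key <- stateKey(st$met, st$mask, st$mass)
  new("LabelingStates", states = st, framework = "emu")
}

#' Pool-size mapping for labeling states
#'
#' Builds the 0/1 matrix D tying each (unpinned) labeling state to the pool
#' size of its metabolite: `p_state = D %*% p_met`. Bounds and measured pool
#' sizes are taken from the network's pool configuration.
#'
#' @param net an [MFANetwork-class].
#' @param states a [LabelingStates-class].
#' @return a [PoolModel-class].
#' @export
buildPoolModel <- function(net, states) {
  st <- states@states
  free <- st[!st$pinned, , drop = FALSE]
  mets <- sort(unique(free$met))
  D <- Matrix::sparseMatrix(i = seq_len(nrow(free)),
                            j = match(free$met, mets),
                            x = 1, dims = c(nrow(free), length(mets)),
                            dimnames = list(free$key, mets))
  pinf <- net@poolInfo
  idx <- match(mets, pinf$metabolite)
  bounds <- data.frame(metabolite = mets,
                       lb = ifelse(is.na(idx), 1e-3, pinf$lb[idx]),
                       ub = ifelse(is.na(idx), 1e3, pinf$ub[idx]),
                       stringsAsFactors = FALSE)
  meas <- pinf[!is.na(pinf$value) & pinf$metabolite %in% mets,
               c("metabolite", "value", "sd"), drop = FALSE]
  new("PoolModel", D = D, mets = mets, bounds = bounds, meas = meas)
}
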