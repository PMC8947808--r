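# Construction of the sparse balance arrays Q, P and P_inp, and evaluation
# of the flux-weighted balance operators used by the steady-state cascade,
# the ODE integrator and the collocation transcription.

#' Build the sparse balance arrays for a network
#'
#' Walks every reaction's atom map and deposits the production and
#' consumption entries of the cumomer or EMU balances: for every state k the
#' net production rate is
#' `sum_r v_r (1/2 sum_ij Q[r,k,i,j] x_i x_j + sum_j P[r,k,j] x_j +
#' sum_j Pinp[r,k,j] xinp_j)`.
#' Unimolecular production terms (pre-image within one reactant) go into P,
#' or into Pinp when the pre-image lies in an input metabolite; bimolecular
#' terms (pre-image spanning two reactants) go into Q, stored symmetrically
#' with diagonal entries doubled so the 1/2 factor reproduces `s x_i x_j`.
#' Consumption contributes `-s` on the diagonal of P for every state of each
#' balanced reactant. Balances are only imposed for unpinned states.
#'
#' @param net a split [MFANetwork-class].
#' @param states a [LabelingStates-class] from [enumerateCumomers()] or
#'   [emuDecompose()].
#' @param framework `"cumomer"` or `"emu"`; must match `states`.
#' @return a [ModelArrays-class].
#' @export
buildModelArrays <- function(net, states, framework = states@framework) {
  if (framework != states@framework)
    stopf("framework '%s' does not match the states object ('%s')",
          framework, states@framework)
  st <- states@states
  idxEnv <- new.env(parent = emptyenv(), size = nrow(st))
  for (i in seq_len(nrow(st))) assign(st$key[i], i, envir = idxEnv)
  lookup <- function(met, mask, mass = NA_integer_) {
    k <- idxEnv[[stateKey(met, mask, mass)]]
    if (is.null(k)) NA_integer_ else k
  }
  roles <- setNames(net@metabolites$role, net@metabolites$name)
  emu <- framework == "emu"

  Qr <- list(); Pr <- list(); Ir <- list()
  addQ <- function(r, k, i, j, s) {
    # symmetric deposit reproducing s*x_i*x_j under the 1/2 factor
    if (i == j) Qr[[length(Qr) + 1L]] <<- c(r, k, i, j, 2 * s)
    else {
      Qr[[length(Qr) + 1L]] <<- c(r, k, i, j, s)
      Qr[[length(Qr) + 1L]] <<- c(r, k, j, i, s)
    }
  }
  addP <- function(r, k, j, s) Pr[[length(Pr) + 1L]] <<- c(r, k, j, s)
  addI <- function(r, k, j, s) Ir[[length(Ir) + 1L]] <<- c(r, k, j, s)

  # which (met, mask[, mass]) states exist, per metabolite
  metMasks <- split(st$mask, st$met)

  rxns <- net@reactions
  for (ri in seq_along(rxns)) {
    r <- rxns[[ri]]
    # production: for every product occurrence and every state of it
    for (pi in seq_along(r$products)) {
      pmet <- r$products[[pi]]$met
      masks <- unique(metMasks[[pmet]])
      if (is.null(masks)) next
      s <- r$products[[pi]]$coeff
      for (mask in masks[masks != 0L]) {
        atoms <- maskToAtoms(mask)
        w <- length(atoms)
        groups <- preimageGroups(r, pi, atoms)
        if (length(groups) > 2)
          stopf("reaction '%s': state of %s derives from more than two reactant molecules",
                r$id, pmet)
        if (emu) {
          targetKnown <- !is.na(lookup(pmet, mask, 0L))
          if (!targetKnown) next
        }
        kIdx <- function(m) lookup(pmet, mask, if (emu) m else NA_integer_)
        if (length(groups) == 1) {
          g <- groups[[1]]
          jmask <- atomsToMask(g$atoms)
          inp <- roles[[g$met]] == "input"
          if (emu) {
            for (m in 0:w) {
              k <- kIdx(m); j <- lookup(g$met, jmask, m)
              if (is.na(j)) stopf("reaction '%s': missing EMU %s for product of %s",
                                  r$id, stateKey(g$met, jmask, m), pmet)
              if (inp) addI(ri, k, j, s) else addP(ri, k, j, s)
            }
          } else {
            j <- lookup(g$met, jmask)
            if (is.na(j)) stopf("reaction '%s': state referencing unknown metabolite '%s'",
                                r$id, g$met)
            if (inp) addI(ri, kIdx(NA_integer_), j, s)
            else addP(ri, kIdx(NA_integer_), j, s)
          }
        } else {
          g1 <- groups[[1]]; g2 <- groups[[2]]
          m1k <- atomsToMask(g1$atoms); m2k <- atomsToMask(g2$atoms)
          if (emu) {
            w1 <- length(g1$atoms); w2 <- length(g2$atoms)
            for (m in 0:w) {
              k <- kIdx(m)
              for (mm1 in max(0, m - w2):min(w1, m)) {
                i <- lookup(g1$met, m1k, mm1)
                j <- lookup(g2$met, m2k, m - mm1)
                if (is.na(i) || is.na(j))
                  stopf("reaction '%s': missing condensation EMUs for %s", r$id, pmet)
                addQ(ri, k, i, j, s)
              }
            }
          } else {
            i <- lookup(g1$met, m1k); j <- lookup(g2$met, m2k)
            if (is.na(i) || is.na(j))
              stopf("reaction '%s': state referencing unknown metabolite", r$id)
            addQ(ri, kIdx(NA_integer_), i, j, s)
          }
        }
      }
    }
    # consumption: -s on the diagonal for every state of each balanced reactant
    for (qi in seq_along(r$reactants)) {
      rmet <- r$reactants[[qi]]$met
      if (is.null(metMasks[[rmet]]) || roles[[rmet]] != "balanced") next
      s <- r$reactants[[qi]]$coeff
      masks <- unique(metMasks[[rmet]])
      for (mask in masks[masks != 0L]) {
        if (emu) {
          w <- length(maskToAtoms(mask))
          for (m in 0:w) {
            k <- lookup(rmet, mask, m)
            if (!is.na(k)) addP(ri, k, k, -s)
          }
        } else {
          k <- lookup(rmet, mask)
          addP(ri, k, k, -s)
        }
      }
    }
  }

  toDf <- function(lst, cols) {
    if (!length(lst)) {
      df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
      names(df) <- cols
      return(df)
    }
    df <- as.data.frame(do.call(rbind, lst))
    names(df) <- cols
    df
  }
  Q <- toDf(Qr, c("r", "k", "i", "j", "val"))
  P <- toDf(Pr, c("r", "k", "j", "val"))
  Pinp <- toDf(Ir, c("r", "k", "j", "val"))
  # aggregate duplicate entries
  agg <- function(df, by) {
    if (!nrow(df)) return(df)
    key <- do.call(paste, c(df[by], sep = ":"))
    out <- df[!duplicated(key), , drop = FALSE]
    out$val <- as.numeric(tapply(df$val, factor(key, levels = unique(key)), sum))
    rownames(out) <- NULL
    out
  }
  Q <- agg(Q, c("r", "k", "i", "j"))
  P <- agg(P, c("r", "k", "j"))
  Pinp <- agg(Pinp, c("r", "k", "j"))

  arr <- new("ModelArrays", framework = framework, states = states,
             Q = Q, P = P, Pinp = Pinp,
             rxnIds = vapply(rxns, `[[`, character(1), "id"))
  # weight cascade sanity: P couples states of equal weight only,
  # Q couples a state only to strictly lower weights
  wt <- st$weight
  if (nrow(P) && any(wt[P$k] != wt[P$j]))
    stopf("internal error: P entry couples different weights")
  if (nrow(Q) && any(wt[Q$i] + wt[Q$j] != wt[Q$k]))
    stopf("internal error: Q entry violates weight additivity")
  arr
}

# Flux-weighted operators: Pv (sparse matrix), Qw (triplets with w = v*val),
# cv (constant vector from Pinp and the input values).
balanceOperators <- function(arrays, v, xfix) {
  st <- arrays@states@states
  n <- nrow(st)
  vv <- v[arrays@rxnIds]
  if (anyNA(vv)) stopf("flux vector missing entries for some reactions")
  P <- arrays@P; Q <- arrays@Q; I <- arrays@Pinp
  Pv <- Matrix::sparseMatrix(i = P$k, j = P$j, x = P$val * vv[P$r],
                             dims = c(n, n))
  Qw <- NULL
  if (nrow(Q)) Qw <- list(k = Q$k, i = Q$i, j = Q$j, w = Q$val * vv[Q$r])
  cv <- numeric(n)
  if (nrow(I)) {
    contrib <- I$val * vv[I$r] * xfix[I$j]
    agg <- rowsum(contrib, I$k, reorder = FALSE)
    cv[as.integer(rownames(agg))] <- as.numeric(agg)
  }
  list(Pv = Pv, Qw = Qw, cv = cv, n = n)
}

# net production rate of every state at state vector x
balanceRate <- function(ops, x) {
  rate <- as.numeric(ops$Pv %*% x) + ops$cv
  if (!is.null(ops$Qw)) {
    q <- 0.5 * ops$Qw$w * x[ops$Qw$i] * x[ops$Qw$j]
    qs <- rowsum(q, ops$Qw$k, reorder = FALSE)
    rate[as.integer(rownames(qs))] <- rate[as.integer(rownames(qs))] + as.numeric(qs)
  }
  rate
}
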