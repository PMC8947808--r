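# Network-level operations: reversible splitting, stoichiometry, flux rank,
# feasible-point sampling.

#' Split reversible reactions into forward and reverse reactions
#'
#' Every flux must be nonnegative, so each reversible reaction is replaced by
#' an irreversible forward reaction (`<id>.f`) and a reverse reaction
#' (`<id>.b`) whose atom map is the inverse of the forward map. Finite
#' net-flux bounds given for the reversible reaction are preserved as linear
#' inequality rows on `v_f - v_b`.
#'
#' @param net an [MFANetwork-class] from [parseNetwork()].
#' @param exchangeUb upper bound applied to each direction of a split
#'   reaction (keeps the flux polytope bounded; default 1000).
#' @return the network with only irreversible reactions and `split = TRUE`.
#' @export
splitReversible <- function(net, exchangeUb = 1000) {
  if (net@split) return(net)
  out <- list()
  ineqRows <- list(); ineqRhs <- numeric(0)
  for (r in net@reactions) {
    if (!r$reversible) {
      out[[length(out) + 1L]] <- r
      next
    }
    fwd <- r; fwd$id <- paste0(r$id, ".f"); fwd$reversible <- FALSE
    rev <- r; rev$id <- paste0(r$id, ".b"); rev$reversible <- FALSE
    rev$reactants <- r$products; rev$products <- r$reactants
    fwd$lb <- 0; fwd$ub <- exchangeUb
    rev$lb <- 0; rev$ub <- exchangeUb
    # net-flux bounds become inequality rows  lb <= v_f - v_b <= ub
    if (is.finite(r$lb)) {
      ineqRows[[length(ineqRows) + 1L]] <- c(setNames(-1, fwd$id), setNames(1, rev$id))
      ineqRhs <- c(ineqRhs, -r$lb)
    }
    if (is.finite(r$ub)) {
      ineqRows[[length(ineqRows) + 1L]] <- c(setNames(1, fwd$id), setNames(-1, rev$id))
      ineqRhs <- c(ineqRhs, r$ub)
    }
    out[[length(out) + 1L]] <- fwd
    out[[length(out) + 1L]] <- rev
  }
  ids <- vapply(out, `[[`, character(1), "id")
  Rm <- NULL
  if (length(ineqRows)) {
    Rm <- matrix(0, length(ineqRows), length(ids), dimnames = list(NULL, ids))
    for (i in seq_along(ineqRows))
      Rm[i, names(ineqRows[[i]])] <- ineqRows[[i]]
  }
  net@reactions <- out
  net@Rineq <- Rm
  net@bineq <- ineqRhs
  net@split <- TRUE
  validObject(net)
  net
}

#' Stoichiometric matrix of the balanced metabolites
#'
#' @param net an [MFANetwork-class].
#' @param balancedOnly if TRUE (default) only rows for balanced metabolites.
#' @return a sparse matrix S with one row per (balanced) metabolite and one
#'   column per reaction; `S v = 0` expresses metabolic steady state.
#' @export
stoichMatrix <- function(net, balancedOnly = TRUE) {
  mets <- net@metabolites
  rows <- if (balancedOnly) mets$name[mets$role == "balanced"] else mets$name
  ids <- vapply(net@reactions, `[[`, character(1), "id")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(net@reactions)) {
    r <- net@reactions[[j]]
    for (term in r$reactants) {
      i <- match(term$met, rows)
      if (!is.na(i)) { ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, -term$coeff) }
    }
    for (term in r$products) {
      i <- match(term$met, rows)
      if (!is.na(i)) { ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, term$coeff) }
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(rows), length(ids)),
                            dimnames = list(rows, ids))
  S
}

numericalRank <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (length(A) == 0) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv))
}

#' Number of independent fluxes
#'
#' Degrees of freedom of the flux polytope: number of reactions minus the
#' rank of the stoichiometric matrix, optionally reduced by the number of
#' fluxes fixed exactly (`lb == ub`).
#'
#' @param net a split [MFANetwork-class].
#' @param subtractFixed subtract exactly-fixed fluxes (default TRUE).
#' @return integer count of independent fluxes.
#' @export
countIndependentFluxes <- function(net, subtractFixed = TRUE) {
  if (length(net@reactions) == 0) stopf("empty network")
  if (!net@split) net <- splitReversible(net)
  S <- stoichMatrix(net)
  nfix <- 0L
  if (subtractFixed) {
    lb <- vapply(net@reactions, `[[`, numeric(1), "lb")
    ub <- vapply(net@reactions, `[[`, numeric(1), "ub")
    nfix <- sum(is.finite(lb) & lb == ub)
  }
  as.integer(length(net@reactions) - numericalRank(S) - nfix)
}

fluxBounds <- function(net) {
  ids <- vapply(net@reactions, `[[`, character(1), "id")
  list(ids = ids,
       lb = setNames(vapply(net@reactions, `[[`, numeric(1), "lb"), ids),
       ub = setNames(vapply(net@reactions, `[[`, numeric(1), "ub"), ids))
}

# solve one LP  max c'v  s.t. S v = 0, R v <= b, lb <= v <= ub
# via boot::simplex on the shifted variable w = v - lb >= 0.
lpVertex <- function(net, obj, boxUb = 1e3) {
  S <- as.matrix(stoichMatrix(net))
  bd <- fluxBounds(net)
  lb <- bd$lb
  ub <- pmin(bd$ub, lb + boxUb) # keep the polytope bounded for the simplex
  n <- length(lb)
  # drop linearly dependent stoichiometric rows (the simplex cannot handle
  # redundant equalities)
  qrS <- qr(t(S))
  keep <- sort(qrS$pivot[seq_len(qrS$rank)])
  S <- S[keep, , drop = FALSE]
  A3 <- S; b3 <- as.numeric(-S %*% lb)
  A1 <- diag(n); b1 <- ub - lb
  if (!is.null(net@Rineq)) {
    A1 <- rbind(A1, net@Rineq)
    b1 <- c(b1, net@bineq - as.numeric(net@Rineq %*% lb))
  }
  # boot::simplex requires nonnegative right-hand sides
  neg3 <- b3 < 0; A3[neg3, ] <- -A3[neg3, , drop = FALSE]; b3[neg3] <- -b3[neg3]
  A2 <- NULL; b2 <- NULL
  neg1 <- b1 < 0
  if (any(neg1)) {
    A2 <- -A1[neg1, , drop = FALSE]; b2 <- -b1[neg1]
    A1 <- A1[!neg1, , drop = FALSE]; b1 <- b1[!neg1]
  }
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = TRUE, n.iter = 200 + 40 * n)
  if (res$solved != 1)
    stopf("flux polytope is infeasible or the LP failed (simplex status %d)", res$solved)
  v <- res$soln + lb
  names(v) <- bd$ids
  v
}

#' Sample random feasible fluxes and pool sizes
#'
#' Draws flux vectors from the flux polytope `{v : S v = 0, R v <= b,
#' lb <= v <= ub}` by solving linear programs with random-cosine objectives
#' and blending pairs of vertex solutions with a random convex weight; pool
#' sizes are drawn log-uniformly within their bounds. Deterministic given
#' `seed`.
#'
#' @param net a split [MFANetwork-class].
#' @param poolBounds optional data.frame `metabolite`, `lb`, `ub` overriding
#'   the network's pool bounds.
#' @param seed integer seed.
#' @param n number of samples.
#' @return for `n = 1` a list with `v` (named flux vector) and `pools`
#'   (named pool-size vector); for `n > 1` a list of such lists.
#' @export
sampleFeasibleFluxesPools <- function(net, poolBounds = NULL, seed = 1L, n = 1L) {
  if (!net@split) net <- splitReversible(net)
  pb <- poolBounds
  if (is.null(pb)) {
    mets <- net@metabolites$name[net@metabolites$role == "balanced"]
    pinf <- net@poolInfo
    pb <- data.frame(metabolite = mets,
                     lb = ifelse(mets %in% pinf$metabolite,
                                 pinf$lb[match(mets, pinf$metabolite)], 1e-2),
                     ub = ifelse(mets %in% pinf$metabolite,
                                 pinf$ub[match(mets, pinf$metabolite)], 1e2))
  }
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(as.integer(seed))
  nr <- length(net@reactions)
  draws <- vector("list", n)
  for (k in seq_len(n)) {
    v1 <- lpVertex(net, cos(2 * pi * stats::runif(nr)))
    v2 <- lpVertex(net, cos(2 * pi * stats::runif(nr)))
    lam <- stats::runif(1)
    v <- lam * v1 + (1 - lam) * v2
    pools <- setNames(exp(stats::runif(nrow(pb), log(pb$lb), log(pb$ub))),
                      pb$metabolite)
    draws[[k]] <- list(v = v, pools = pools)
  }
  if (n == 1L) draws[[1]] else draws
}
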