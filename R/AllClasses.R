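#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rankMatrix t crossprod solve
#' @importClassesFrom Matrix Matrix
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Metabolic network with carbon atom transitions
#'
#' Central container for a parsed metabolic network: metabolites with carbon
#' counts and roles (balanced, input or output), reactions with stoichiometry
#' and per-carbon atom maps, flux bounds, linear inequality constraints on
#' fluxes and optional flux measurements. Reversible reactions are flagged at
#' parse time and materialized into separate forward/reverse reactions by
#' [splitReversible()].
#'
#' @slot metabolites data.frame with columns `name`, `n_carbons`, `role`.
#' @slot reactions list of reaction records (id, reversible flag, bounds,
#'   reactant/product lists with atom maps).
#' @slot Rineq,bineq linear inequality system `R v <= b` on the flux vector.
#' @slot fluxMeas data.frame of measured fluxes (`reaction`, `value`, `sd`).
#' @slot poolInfo data.frame of pool-size bounds and measurements per
#'   metabolite (`metabolite`, `lb`, `ub`, `value`, `sd`).
#' @slot tracers list describing the fed label (see [buildInputVector()]).
#' @slot natAbundance natural 13C abundance used for unspecified atoms.
#' @slot split logical; TRUE once reversible reactions have been split.
#'
#' @seealso [parseNetwork()], [splitReversible()], [stoichMatrix()]
#' @export
setClass("MFANetwork",
  representation(
    metabolites = "data.frame",
    reactions = "list",
    Rineq = "matrixOrNULL",
    bineq = "numeric",
    fluxMeas = "data.frame",
    poolInfo = "data.frame",
    tracers = "list",
    natAbundance = "numeric",
    split = "logical"
  ),
  prototype(
    Rineq = NULL, bineq = numeric(0),
    fluxMeas = data.frame(reaction = character(0), value = numeric(0), sd = numeric(0)),
    poolInfo = data.frame(metabolite = character(0), lb = numeric(0), ub = numeric(0),
                          value = numeric(0), sd = numeric(0)),
    tracers = list(), natAbundance = 0.0107, split = FALSE
  )
)

setValidity("MFANetwork", function(object) {
  msg <- character(0)
  met <- object@metabolites
  if (!all(c("name", "n_carbons", "role") %in% names(met)))
    msg <- c(msg, "metabolites must have columns name, n_carbons, role")
  else {
    if (any(met$n_carbons < 0)) msg <- c(msg, "n_carbons must be nonnegative")
    if (!all(met$role %in% c("balanced", "input", "output")))
      msg <- c(msg, "role must be balanced, input or output")
    if (anyDuplicated(met$name)) msg <- c(msg, "duplicate metabolite names")
  }
  ids <- vapply(object@reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate reaction ids")
  if (object@split) {
    lb <- vapply(object@reactions, `[[`, numeric(1), "lb")
    if (any(lb < 0)) msg <- c(msg, "after splitting all flux lower bounds must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Enumerated labeling states (cumomers or EMUs)
#'
#' Ordered table of the labeling state variables forming the composite state
#' vector x. In the cumomer framework one state per (metabolite, atom subset),
#' including the weight-0 states pinned to 1; in the EMU framework one state
#' per (EMU, mass shift), restricted to the EMUs reachable backward from the
#' measured fragments. States of input metabolites are flagged `pinned`: their
#' values are fixed by the tracer specification.
#'
#' @slot states data.frame with columns `met`, `mask` (atom-position bitmask),
#'   `weight`, `mass` (`NA` in the cumomer framework), `pinned`, `key`.
#'   Row order is the composite-vector order: ascending weight, then
#'   metabolite name, then bitmask, then mass.
#' @slot framework `"cumomer"` or `"emu"`.
#' @export
setClass("LabelingStates",
  representation(states = "data.frame", framework = "character")
)

setValidity("LabelingStates", function(object) {
  st <- object@states
  msg <- character(0)
  if (!object@framework %in% c("cumomer", "emu"))
    msg <- c(msg, "framework must be 'cumomer' or 'emu'")
  need <- c("met", "mask", "weight", "mass", "pinned", "key")
  if (!all(need %in% names(st)))
    msg <- c(msg, "states table missing required columns")
  else {
    if (is.unsorted(st$weight)) msg <- c(msg, "states must be ordered by ascending weight")
    if (anyDuplicated(st$key)) msg <- c(msg, "duplicate state keys")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse balance arrays Q, P and P_inp
#'
#' Sparse representations of the arrays defining the cumomer or EMU balances:
#' for every state k the net production rate is
#' `sum_r v_r (1/2 sum_ij Q[r,k,i,j] x_i x_j + sum_j P[r,k,j] x_j +
#' sum_j Pinp[r,k,j] xinp_j)`. Q is stored symmetrically (both (i,j) and
#' (j,i)); self-condensation entries on the diagonal carry `2s` so that the
#' 1/2 factor in the balance reproduces `s x_i x_j` exactly.
#'
#' @slot framework `"cumomer"` or `"emu"`.
#' @slot states the [LabelingStates-class] the indices refer to.
#' @slot Q data.frame (`r`, `k`, `i`, `j`, `val`) of bimolecular entries.
#' @slot P data.frame (`r`, `k`, `j`, `val`) of unimolecular production and
#'   diagonal consumption entries.
#' @slot Pinp data.frame (`r`, `k`, `j`, `val`): entry of fed compounds; `j`
#'   indexes pinned input states of the composite vector.
#' @slot rxnIds character vector mapping flux index r to reaction id.
#' @export
setClass("ModelArrays",
  representation(
    framework = "character",
    states = "LabelingStates",
    Q = "data.frame",
    P = "data.frame",
    Pinp = "data.frame",
    rxnIds = "character"
  )
)

#' Pool-size model
#'
#' Maps metabolite pool sizes to per-state pool sizes through the 0/1 matrix
#' D (one 1 per row): `p_k = sum_m D[k,m] p_met[m]`. Every state of the same
#' metabolite shares that metabolite's pool size.
#'
#' @slot D sparse 0/1 matrix, rows = unpinned states, cols = metabolites.
#' @slot mets metabolite names (column order of D).
#' @slot bounds data.frame `metabolite`, `lb`, `ub`.
#' @slot meas data.frame `metabolite`, `value`, `sd` (may be empty).
#' @export
setClass("PoolModel",
  representation(D = "Matrix", mets = "character",
                 bounds = "data.frame", meas = "data.frame")
)

setValidity("PoolModel", function(object) {
  rs <- Matrix::rowSums(object@D)
  if (any(rs != 1)) "each row of D must contain exactly one 1" else TRUE
})

#' Measurement model: fragments, mapping matrix M and scaling matrix U
#'
#' Couples the labeling state vector to the measured quantities. Each row n of
#' the sparse matrix M gives one simulated measurement `m_n = sum_j M[n,j] x_j`
#' (single-MS mass fraction or tandem parent/daughter mass pair, with any
#' natural-abundance convolution of non-backbone atoms folded in). U ties each
#' measurement row to its fragment's scaling factor.
#'
#' @slot fragments data.frame: `id`, `met`, `atoms`, `daughter`, `formula`.
#' @slot channels data.frame, one row per M row: `fragment`, `mass`, `dmass`
#'   (`NA` for single MS). A channel is one simulated measurement quantity;
#'   in nonstationary fits the same channel is evaluated at every
#'   measurement time.
#' @slot M sparse mapping matrix (rows = channels, cols = states).
#' @slot U sparse 0/1 matrix (rows = channels, cols = fragments) tying each
#'   measurement to its fragment's scaling factor.
#' @slot meas data.frame of measured values: `channel` (row of M), `time`
#'   (`NA` for steady state), `value`, `sd`.
#' @slot times sorted unique measurement times (length 0 for steady state).
#' @slot framework framework the M matrix was built for.
#' @export
setClass("MeasurementModel",
  representation(
    fragments = "data.frame",
    channels = "data.frame",
    M = "Matrix",
    U = "Matrix",
    meas = "data.frame",
    times = "numeric",
    framework = "character"
  )
)

setValidity("MeasurementModel", function(object) {
  msg <- character(0)
  if (nrow(object@channels) != nrow(object@M))
    msg <- c(msg, "channels table and M must have matching rows")
  if (nrow(object@U) != nrow(object@M))
    msg <- c(msg, "U and M must have matching rows")
  if (nrow(object@U) > 0 && any(Matrix::rowSums(object@U) != 1))
    msg <- c(msg, "each row of U must contain exactly one 1")
  if (any(object@meas$sd <= 0, na.rm = TRUE))
    msg <- c(msg, "measurement standard deviations must be positive")
  if (nrow(object@meas) &&
      (any(object@meas$channel < 1) || any(object@meas$channel > nrow(object@M))))
    msg <- c(msg, "meas$channel out of range")
  if (length(msg)) msg else TRUE
})

#' Labeling trajectory
#'
#' Time course of the composite labeling state vector from numerical
#' integration of the labeling dynamics.
#'
#' @slot times stored time points (first entry is the initial condition).
#' @slot x matrix, rows = time points, cols = states (named by state key).
#' @slot method integrator used (`"rk4"` or `"lsoda"`).
#' @slot dt step size (RK4) or `NA` for adaptive integration.
#' @export
setClass("Trajectory",
  representation(times = "numeric", x = "matrix", method = "character",
                 dt = "numeric")
)

setValidity("Trajectory", function(object) {
  msg <- character(0)
  if (nrow(object@x) != length(object@times))
    msg <- c(msg, "x must have one row per time point")
  if (length(object@x) && (min(object@x) < -1e-6 || max(object@x) > 1 + 1e-6))
    msg <- c(msg, "states must lie within [-1e-6, 1 + 1e-6]")
  if (length(msg)) msg else TRUE
})

#' Radau IIA collocation scheme
#'
#' Nodes, Runge-Kutta matrix, weights and integrated-Lagrange basis functions
#' of an s-stage Radau IIA method (order 2s-1). The scheme is stiffly
#' accurate: the last node is 1 and the last row of `a` equals `b`.
#'
#' @slot s stage count.
#' @slot order classical order 2s-1.
#' @slot c collocation nodes in (0, 1].
#' @slot a s x s Runge-Kutta matrix, `a[i,j] = B_j(c_i)`.
#' @slot b weights, `b[j] = B_j(1)`.
#' @slot Bcoef s x (s+1) matrix of polynomial coefficients (ascending powers)
#'   of the basis functions `B_alpha(tau)`.
#' @export
setClass("CollocationScheme",
  representation(s = "integer", order = "integer", c = "numeric",
                 a = "matrix", b = "numeric", Bcoef = "matrix")
)

setValidity("CollocationScheme", function(object) {
  msg <- character(0)
  if (abs(object@c[object@s] - 1) > 1e-10) msg <- c(msg, "last node must be 1")
  if (abs(sum(object@b) - 1) > 1e-10) msg <- c(msg, "weights must sum to 1")
  if (max(abs(object@a[object@s, ] - object@b)) > 1e-10)
    msg <- c(msg, "scheme must be stiffly accurate (last row of a equals b)")
  if (length(msg)) msg else TRUE
})

#' Time grid for collocation transcription
#'
#' @slot nodes strictly increasing time nodes t_0 < ... < t_Gamma.
#' @slot h interval widths, `h[g] = nodes[g+1] - nodes[g]`.
#' @export
setClass("TimeGrid", representation(nodes = "numeric", h = "numeric"))

setValidity("TimeGrid", function(object) {
  if (length(object@nodes) < 2) return("grid needs at least two nodes")
  if (any(diff(object@nodes) <= 0)) return("nodes must be strictly increasing")
  if (!isTRUE(all.equal(object@h, diff(object@nodes)))) return("h inconsistent with nodes")
  TRUE
})

#' Transcribed labeling ODE system
#'
#' The collocation transcription of the labeling dynamics: stage-state
#' relations, stage balances and node update equations over a time grid. The
#' object carries the dimensions of the three constraint families and
#' evaluates their residuals at given variable values; the constraint system
#' is solved exactly, level by level, by [solveTranscribed()].
#'
#' @slot arrays the [ModelArrays-class] being transcribed.
#' @slot grid the [TimeGrid-class].
#' @slot scheme the [CollocationScheme-class].
#' @slot nStates number of state variables (composite vector length).
#' @slot nFree number of unpinned states.
#' @export
setClass("TranscribedSystem",
  representation(arrays = "ModelArrays", grid = "TimeGrid",
                 scheme = "CollocationScheme",
                 nStates = "integer", nFree = "integer")
)

#' Assembled MFA estimation problem
#'
#' Bundles all model structure needed to evaluate the weighted least-squares
#' objective of a steady-state or isotopically nonstationary MFA fit: the
#' network with its flux polytope, the balance arrays, the measurement model,
#' the pool model, the input/initial-condition vector and (for the
#' nonstationary case) the collocation transcription. The equality
#' constraints (balances or transcribed dynamics, S v = 0, scaling ties,
#' measurement mapping, zero-order pins, initial conditions) are eliminated
#' exactly when the objective is evaluated, so every candidate point is
#' feasible by construction.
#'
#' @slot kind `"steady"` or `"inst"`.
#' @slot net,arrays,mm,input,pools,grid,scheme model components.
#' @slot reduced internal list: null-space parametrization of `S v = 0`,
#'   variable maps, options.
#' @export
setClass("NLPProblem",
  representation(kind = "character", net = "MFANetwork", arrays = "ModelArrays",
                 mm = "MeasurementModel", input = "numeric", pools = "PoolModel",
                 grid = "ANY", scheme = "ANY", reduced = "list")
)

#' Result of an MFA fit
#'
#' @slot v named flux estimates.
#' @slot pools named metabolite pool-size estimates (empty for steady-state).
#' @slot scalings data.frame of fitted scaling factors per fragment (and time).
#' @slot z variance-weighted sum of squared residuals at the solution.
#' @slot status solver status string.
#' @slot feasResid maximum absolute equality-constraint residual at the
#'   returned point.
#' @slot iterations solver iteration count.
#' @slot trajectory data.frame of interpolated states/measurements (inst).
#' @slot theta internal reduced-parameter vector at the solution.
#' @slot info list of metadata (seed, scheme order, per-restart records, ...).
#' @export
setClass("MFAFit",
  representation(v = "numeric", pools = "numeric", scalings = "data.frame",
                 z = "numeric", status = "character", feasResid = "numeric",
                 iterations = "integer", trajectory = "dfOrNULL",
                 theta = "numeric", info = "list")
)

#' Parametric bootstrap result
#'
#' @slot samples matrix of resample estimates (rows = resamples).
#' @slot summary data.frame: parameter, mean, sd, percentile interval.
#' @slot level confidence level of the percentile intervals.
#' @slot nFail number of failed resample refits (excluded).
#' @export
setClass("BootstrapResult",
  representation(samples = "matrix", summary = "data.frame",
                 level = "numeric", nFail = "integer")
)
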