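#' @import methods
NULL

#' MolecularSystem: a topology plus one coordinate set
#'
#' The common currency of all structure operations: an ordered atom table
#' (serial, name, element, residue name/number, chain) with one set of
#' Cartesian coordinates in Angstrom, an optional orthorhombic box, and a
#' free-text label.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resid}, \code{chain},
#'   \code{x}, \code{y}, \code{z}. Coordinates in Angstrom; \code{resid}
#'   is the author residue number.
#' @slot box numeric(3) box lengths in Angstrom, or \code{NA} when unset.
#' @slot label character(1) free-text label.
#' @exportClass MolecularSystem
setClass("MolecularSystem",
  representation(atoms = "data.frame", box = "numeric", label = "character"),
  prototype(atoms = data.frame(), box = c(NA_real_, NA_real_, NA_real_),
            label = ""))

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must contain columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      return("atom positions must be finite")
    if (any(!nzchar(a$name)))
      return("atom names must be non-empty")
  }
  if (length(object@box) != 3) return("box must be numeric(3)")
  TRUE
})

#' AtomSelection: resolved atom indices for a selection expression
#'
#' @slot indices integer vector of atom indices (1-based), unique and
#'   ordered as in the topology.
#' @slot spec character(1) the selection expression the indices resolve.
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(indices = "integer", spec = "character"),
  prototype(indices = integer(0), spec = ""))

setValidity("AtomSelection", function(object) {
  idx <- object@indices
  if (anyDuplicated(idx)) return("selection indices must be unique")
  if (length(idx) && (is.unsorted(idx) || any(idx < 1)))
    return("selection indices must be positive and ordered")
  TRUE
})

#' FrameEnsemble: ordered coordinate frames for one replica
#'
#' @slot topology \code{MolecularSystem}; its coordinates are ignored,
#'   only the atom table matters.
#' @slot coords numeric array \code{n_atoms x 3 x n_frames}, Angstrom.
#' @slot times numeric vector of frame times in ps, strictly increasing.
#' @slot replicaId integer(1) replica identifier.
#' @exportClass FrameEnsemble
setClass("FrameEnsemble",
  representation(topology = "MolecularSystem", coords = "array",
                 times = "numeric", replicaId = "integer"),
  prototype(times = numeric(0), replicaId = 1L))

setValidity("FrameEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return(sprintf("coords has %d atoms but topology has %d",
                   d[1], nrow(object@topology@atoms)))
  if (length(object@times) != d[3])
    return("times must have one entry per frame")
  if (d[3] > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3) return("translation must be length 3")
  TRUE
})

#' HydrationProfile: across-replica axial water probability profile
#'
#' @slot sliceCenters numeric, slice centres along z, Angstrom.
#' @slot meanProbability numeric in [0, 1], across-replica mean of the
#'   per-replica normalized profiles.
#' @slot sem numeric >= 0, standard error of the mean across replicas.
#' @slot nReplicas integer(1).
#' @slot perReplica matrix (replica x slice) of normalized profiles.
#' @exportClass HydrationProfile
setClass("HydrationProfile",
  representation(sliceCenters = "numeric", meanProbability = "numeric",
                 sem = "numeric", nReplicas = "integer",
                 perReplica = "matrix"))

setValidity("HydrationProfile", function(object) {
  n <- length(object@sliceCenters)
  if (length(object@meanProbability) != n || length(object@sem) != n)
    return("sliceCenters, meanProbability and sem must have equal length")
  if (any(object@sem < -1e-12)) return("sem must be non-negative")
  if (nrow(object@perReplica) > 0 &&
      any(abs(apply(object@perReplica, 1, max) - 1) > 1e-9))
    return("each replica profile must peak at exactly 1 (solvent slice)")
  TRUE
})

#' NwaterDistribution: gate water-count probability distribution
#'
#' @slot counts integer vector of water counts 0..max.
#' @slot meanProbability numeric, across-replica mean probability per count.
#' @slot sem numeric, SEM across replicas per count.
#' @slot perReplicaMeanN numeric, mean gate water count per replica.
#' @slot perReplica matrix (replica x count) of per-replica probabilities.
#' @exportClass NwaterDistribution
setClass("NwaterDistribution",
  representation(counts = "integer", meanProbability = "numeric",
                 sem = "numeric", perReplicaMeanN = "numeric",
                 perReplica = "matrix"))

setValidity("NwaterDistribution", function(object) {
  n <- length(object@counts)
  if (length(object@meanProbability) != n || length(object@sem) != n)
    return("counts, meanProbability and sem must have equal length")
  if (nrow(object@perReplica) > 0 &&
      any(abs(rowSums(object@perReplica) - 1) > 1e-9))
    return("each replica's probabilities must sum to 1")
  TRUE
})

#' GateDistanceSeries: per-frame opposing S6-tail distances
#'
#' @slot d1 numeric, DI-DIII projected CoM distance per frame, Angstrom.
#' @slot d2 numeric, DII-DIV projected CoM distance per frame, Angstrom.
#' @slot frameIndices integer.
#' @slot replicaId integer(1).
#' @exportClass GateDistanceSeries
setClass("GateDistanceSeries",
  representation(d1 = "numeric", d2 = "numeric", frameIndices = "integer",
                 replicaId = "integer"),
  prototype(replicaId = 1L))

setValidity("GateDistanceSeries", function(object) {
  if (length(object@d1) != length(object@d2))
    return("d1 and d2 must have equal length")
  if (any(object@d1 <= 0) || any(object@d2 <= 0))
    return("gate distances must be positive")
  TRUE
})

#' FreeEnergySurface: Boltzmann-inverted 2D histogram of (d1, d2)
#'
#' @slot d1Edges,d2Edges numeric bin edges, Angstrom.
#' @slot freeEnergy matrix (d1 bin x d2 bin) of free energies in kcal/mol;
#'   occupied minimum is 0 and empty bins are \code{NA} (masked).
#' @slot temperature numeric(1), Kelvin.
#' @slot kB numeric(1), Boltzmann constant in kcal/mol/K.
#' @exportClass FreeEnergySurface
setClass("FreeEnergySurface",
  representation(d1Edges = "numeric", d2Edges = "numeric",
                 freeEnergy = "matrix", temperature = "numeric",
                 kB = "numeric"),
  prototype(temperature = 303.15, kB = 0.0019872041))

setValidity("FreeEnergySurface", function(object) {
  F <- object@freeEnergy
  if (nrow(F) != length(object@d1Edges) - 1 ||
      ncol(F) != length(object@d2Edges) - 1)
    return("freeEnergy dimensions must match bin edges")
  occ <- F[!is.na(F)]
  if (length(occ) && abs(min(occ)) > 1e-9)
    return("minimum over occupied bins must be 0")
  TRUE
})

#' FitResult: nonlinear least-squares fit summary
#'
#' @slot model character(1), e.g. "hill", "exponential_association".
#' @slot parameters named numeric of point estimates.
#' @slot se named numeric of standard errors (0 for fixed parameters).
#' @slot fixed character, names of parameters held fixed.
#' @slot rss numeric(1) residual sum of squares.
#' @slot nPoints integer(1).
#' @slot converged logical(1).
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "character", parameters = "numeric",
                 se = "numeric", fixed = "character", rss = "numeric",
                 nPoints = "integer", converged = "logical"),
  prototype(fixed = character(0), converged = FALSE))

setValidity("FitResult", function(object) {
  if (length(object@se) && any(object@se < 0))
    return("standard errors must be non-negative")
  TRUE
})
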