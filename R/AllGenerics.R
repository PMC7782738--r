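#' Accessors for poregate containers
#'
#' Small accessor generics: \code{atoms} returns the atom table of a
#' \code{MolecularSystem}; \code{coords} returns the coordinates (an
#' \code{n x 3} matrix for a system, an \code{n x 3 x n_frames} array for
#' an ensemble); \code{nAtoms} and \code{nFrames} count atoms and frames;
#' \code{frameTimes} returns frame times in ps; \code{replicaId} the
#' replica identifier; \code{systemLabel} the free-text label.
#'
#' @param x a \code{MolecularSystem} or \code{FrameEnsemble}.
#' @return See description; counts are integers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("replicaId", function(x) standardGeneric("replicaId"))
#' @rdname accessors
#' @export
setGeneric("systemLabel", function(x) standardGeneric("systemLabel"))

#' @rdname accessors
setMethod("atoms", "MolecularSystem", function(x) x@atoms)
#' @rdname accessors
setMethod("coords", "MolecularSystem", function(x) .coordMatrix(x))
#' @rdname accessors
setMethod("coords", "FrameEnsemble", function(x) x@coords)
#' @rdname accessors
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nAtoms", "FrameEnsemble", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nFrames", "FrameEnsemble", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("frameTimes", "FrameEnsemble", function(x) x@times)
#' @rdname accessors
setMethod("replicaId", "FrameEnsemble", function(x) x@replicaId)
#' @rdname accessors
setMethod("systemLabel", "MolecularSystem", function(x) x@label)

#' Extract one frame of an ensemble as a MolecularSystem
#'
#' @param ensemble a \code{FrameEnsemble}.
#' @param i frame index (1-based).
#' @return \code{MolecularSystem} with the topology's atom table and the
#'   coordinates of frame \code{i}.
#' @export
getFrame <- function(ensemble, i) {
  stopifnot(is(ensemble, "FrameEnsemble"))
  if (i < 1 || i > nFrames(ensemble)) stop("frame index out of range")
  .setCoords(ensemble@topology, ensemble@coords[, , i, drop = TRUE])
}

setMethod("show", "MolecularSystem", function(object) {
  a <- object@atoms
  cat(sprintf("MolecularSystem '%s': %d atoms, %d residues, %d chain(s)\n",
              object@label, nrow(a),
              length(unique(paste(a$chain, a$resid))),
              length(unique(a$chain))))
  if (!all(is.na(object@box)))
    cat(sprintf("  box: %.1f x %.1f x %.1f A\n",
                object@box[1], object@box[2], object@box[3]))
})

setMethod("show", "FrameEnsemble", function(object) {
  cat(sprintf("FrameEnsemble (replica %d): %d atoms x %d frames, t = %g..%g ps\n",
              object@replicaId, dim(object@coords)[1], dim(object@coords)[3],
              min(object@times), max(object@times)))
})

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection '%s': %d atoms\n",
              object@spec, length(object@indices)))
})

setMethod("show", "HydrationProfile", function(object) {
  cat(sprintf("HydrationProfile: %d slices (z %.1f..%.1f A), %d replica(s)\n",
              length(object@sliceCenters), min(object@sliceCenters),
              max(object@sliceCenters), object@nReplicas))
})

setMethod("show", "NwaterDistribution", function(object) {
  cat(sprintf("NwaterDistribution: N = 0..%d, %d replica(s), mean N = %.2f\n",
              max(object@counts), nrow(object@perReplica),
              mean(object@perReplicaMeanN)))
})

setMethod("show", "GateDistanceSeries", function(object) {
  cat(sprintf("GateDistanceSeries (replica %d): %d frames, d1 = %.2f A, d2 = %.2f A (means)\n",
              object@replicaId, length(object@d1),
              mean(object@d1), mean(object@d2)))
})

setMethod("show", "FreeEnergySurface", function(object) {
  occ <- sum(!is.na(object@freeEnergy))
  cat(sprintf("FreeEnergySurface: %d x %d bins (%d occupied), T = %.2f K\n",
              nrow(object@freeEnergy), ncol(object@freeEnergy), occ,
              object@temperature))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]%s: n = %d, RSS = %.4g\n", object@model,
              if (object@converged) "" else " (NOT converged)",
              object@nPoints, object@rss))
  for (p in names(object@parameters)) {
    tag <- if (p %in% object@fixed) " (fixed)" else
      sprintf(" +/- %.4g", object@se[p])
    cat(sprintf("  %s = %.6g%s\n", p, object@parameters[p], tag))
  }
})
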