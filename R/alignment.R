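# frame_alignment: rigid-body superposition and canonical pore-frame
# transformation. The canonical frame places the pore axis on z with the
# selectivity-filter DEKA Calpha centre of mass at z = 0 and the pore
# transmembrane helices' centre of mass on the z axis (x = y = 0).

#' Canonical pore-frame specification
#'
#' Bundles the three selections defining the canonical frame: the
#' Calpha set used for least-squares alignment to the reference (pore
#' transmembrane helices, S5 and S6 from all domains), the set whose
#' centre of mass fixes x = y = 0 (same pore helices), and the set whose
#' centre of mass fixes z = 0 (the DEKA-motif Calpha atoms of the
#' selectivity filter).
#'
#' @param align,xyCenter,zCenter selection expression strings (or
#'   \code{AtomSelection}s).
#' @return A list of class \code{"CanonicalFrameSpec"}.
#' @export
canonicalFrameSpec <- function(align, xyCenter = align, zCenter) {
  structure(list(align = align, xyCenter = xyCenter, zCenter = zCenter),
            class = "CanonicalFrameSpec")
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets (SVD-based). At least three non-collinear points are
#' required.
#'
#' @param mobile,reference \code{n x 3} coordinate matrices with
#'   row-by-row correspondence.
#' @return list with \code{transform} (a \code{RigidTransform} mapping
#'   mobile onto reference as \code{x' = R x + t}) and \code{rmsd}
#'   (Angstrom, after transformation).
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be n x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate geometry: need at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm)
  Rf <- sweep(reference, 2, cr)
  sv <- svd(M)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: points are collinear")
  H <- crossprod(M, Rf)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- as.numeric(cr - R %*% cm)
  fitted <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Rf)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = tvec),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param x an \code{n x 3} matrix, a \code{MolecularSystem}, or a
#'   \code{FrameEnsemble} (applied to every frame).
#' @param transform a \code{RigidTransform}.
#' @return Object of the same type with transformed coordinates.
#' @export
applyTransform <- function(x, transform) {
  stopifnot(is(transform, "RigidTransform"))
  R <- transform@rotation
  tv <- transform@translation
  if (is(x, "MolecularSystem"))
    return(.setCoords(x, sweep(.coordMatrix(x) %*% t(R), 2, -tv)))
  if (is(x, "FrameEnsemble")) {
    for (i in seq_len(nFrames(x)))
      x@coords[, , i] <- sweep(x@coords[, , i] %*% t(R), 2, -tv)
    return(x)
  }
  sweep(as.matrix(x) %*% t(R), 2, -tv)
}

#' Invert a rigid transform
#'
#' @param transform a \code{RigidTransform}.
#' @return The inverse \code{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  R <- t(transform@rotation)
  new("RigidTransform", rotation = R,
      translation = as.numeric(-R %*% transform@translation))
}

# Mass-weighted CoM over a selection of a coordinate matrix.
.selectionCoM <- function(coordMat, atoms, idx) {
  .centreOfMass(coordMat[idx, , drop = FALSE], elementMasses(atoms$element[idx]))
}

# Resolve the align selection on mobile and reference topologies and
# match atoms by (chain, residue number, atom name).
.matchedAlignIndices <- function(mobileSys, referenceSys, spec) {
  im <- selectAtoms(mobileSys, spec)@indices
  ir <- selectAtoms(referenceSys, spec)@indices
  if (!length(im) || !length(ir))
    stop("alignment selection resolves to no atoms in mobile and/or reference")
  km <- .atomKeys(mobileSys@atoms, im)
  kr <- .atomKeys(referenceSys@atoms, ir)
  common <- intersect(km, kr)
  if (length(common) < 3)
    stop("alignment selection mismatch between mobile and reference: ",
         "fewer than 3 atoms pair by (chain, residue, atom name)")
  list(mobile = im[match(common, km)], reference = ir[match(common, kr)])
}

# Centering translation for a coordinate matrix: CoM(xy sel) -> x=y=0,
# CoM(z sel) -> z=0.
.canonicalTranslation <- function(coordMat, atoms, xyIdx, zIdx) {
  comXY <- .selectionCoM(coordMat, atoms, xyIdx)
  comZ <- .selectionCoM(coordMat, atoms, zIdx)
  c(-comXY[1], -comXY[2], -comZ[3])
}

#' Canonicalize trajectory frames into the pore frame
#'
#' Every frame receives one rigid transform: a Kabsch superposition of
#' the alignment selection onto the reference structure, followed by a
#' translation putting the centre of mass of \code{xyCenter} at
#' x = y = 0 and the centre of mass of \code{zCenter} at z = 0 (centres
#' of mass are mass-weighted). The reference's own orientation therefore
#' defines the pore axis; see \code{\link{canonicalizeStructure}} for
#' orienting a standalone structure.
#'
#' @param ensemble \code{FrameEnsemble}.
#' @param reference \code{MolecularSystem}; the selections must resolve
#'   in both the ensemble topology and the reference.
#' @param spec a \code{\link{canonicalFrameSpec}}.
#' @return A canonicalized \code{FrameEnsemble}.
#' @export
canonicalizeFrames <- function(ensemble, reference, spec) {
  stopifnot(is(ensemble, "FrameEnsemble"), is(reference, "MolecularSystem"),
            inherits(spec, "CanonicalFrameSpec"))
  topo <- ensemble@topology
  al <- .matchedAlignIndices(topo, reference, spec$align)
  xyIdx <- selectAtoms(topo, spec$xyCenter)@indices
  zIdx <- selectAtoms(topo, spec$zCenter)@indices
  if (!length(xyIdx) || !length(zIdx))
    stop("centering selections must be non-empty")
  refCoords <- .coordMatrix(reference)[al$reference, , drop = FALSE]
  out <- ensemble
  for (i in seq_len(nFrames(ensemble))) {
    fr <- ensemble@coords[, , i]
    fit <- kabschSuperpose(fr[al$mobile, , drop = FALSE], refCoords)
    moved <- applyTransform(fr, fit$transform)
    shift <- .canonicalTranslation(moved, topo@atoms, xyIdx, zIdx)
    out@coords[, , i] <- sweep(moved, 2, -shift)
  }
  out
}

#' Canonicalize a static structure
#'
#' Treats the structure as a one-frame ensemble. With a \code{reference},
#' this is exactly \code{\link{canonicalizeFrames}}. Without one, the
#' structure is canonicalized against itself: optionally (default) the
#' pore axis -- the direction from the xy-centering selection's centre of
#' mass to the z-centering selection's centre of mass -- is first rotated
#' onto +z, then the centering translation is applied.
#'
#' @param system \code{MolecularSystem}.
#' @param spec a \code{\link{canonicalFrameSpec}}.
#' @param reference optional \code{MolecularSystem} defining the target
#'   orientation.
#' @param orient logical; when no reference is given, rotate the pore
#'   axis onto +z before centering.
#' @return A canonicalized \code{MolecularSystem}.
#' @export
canonicalizeStructure <- function(system, spec, reference = NULL,
                                  orient = TRUE) {
  stopifnot(is(system, "MolecularSystem"))
  if (!is.null(reference)) {
    ens <- newFrameEnsemble(system, list(.coordMatrix(system)))
    return(getFrame(canonicalizeFrames(ens, reference, spec), 1))
  }
  xyIdx <- selectAtoms(system, spec$xyCenter)@indices
  zIdx <- selectAtoms(system, spec$zCenter)@indices
  if (!length(xyIdx) || !length(zIdx))
    stop("centering selections must be non-empty")
  cm <- .coordMatrix(system)
  if (orient) {
    axis <- .selectionCoM(cm, system@atoms, zIdx) -
      .selectionCoM(cm, system@atoms, xyIdx)
    if (sqrt(sum(axis^2)) > 1e-8) {
      R <- .rotationBetween(axis, c(0, 0, 1))
      cm <- cm %*% t(R)
    }
  }
  shift <- .canonicalTranslation(cm, system@atoms, xyIdx, zIdx)
  .setCoords(system, sweep(cm, 2, -shift))
}
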