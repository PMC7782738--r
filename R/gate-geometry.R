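# gate_geometry: opposing S6-tail gate distances (d1, d2), their
# Boltzmann-inverted free-energy surface, and the static van der Waals
# pore-diameter profile along the canonical z axis.

#' S6-tail gate selections
#'
#' One Calpha selection per domain tail. Defaults are the rNav1.5
#' activation-gate residues: DI 410-413, DII 939-942, DIII 1469-1472,
#' DIV 1771-1774 (author numbering); chain is deliberately left out of
#' the default expressions so they resolve whether the four domains live
#' on one chain or several.
#'
#' @param di,dii,diii,div selection expressions for the four tails.
#' @return list of class \code{"GateSelections"}.
#' @export
gateSelections <- function(di = "name CA and resid 410-413",
                           dii = "name CA and resid 939-942",
                           diii = "name CA and resid 1469-1472",
                           div = "name CA and resid 1771-1774") {
  structure(list(di = di, dii = dii, diii = diii, div = div),
            class = "GateSelections")
}

# Projected-CoM distance between two tail selections for one frame.
.tailCoMxy <- function(coordMat, atoms, idx) {
  .selectionCoM(coordMat, atoms, idx)[1:2]
}

#' Gate distances d1 and d2
#'
#' The mass-weighted centre of mass of each tail's Calpha selection is
#' projected onto the xy-plane (the structure must be canonicalized so
#' that the pore axis is z) and the distances between opposing tails are
#' measured: \code{d1} = DI-DIII, \code{d2} = DII-DIV.
#'
#' @param x a canonicalized \code{MolecularSystem} (one frame) or
#'   \code{FrameEnsemble} (per-frame series).
#' @param sels a \code{\link{gateSelections}}.
#' @return A \code{GateDistanceSeries}.
#' @export
gateDistances <- function(x, sels = gateSelections()) {
  stopifnot(inherits(sels, "GateSelections"))
  topo <- if (is(x, "FrameEnsemble")) x@topology else x
  idx <- lapply(sels, function(s) selectAtoms(topo, s)@indices)
  bad <- names(idx)[vapply(idx, length, integer(1)) == 0]
  if (length(bad))
    stop("gate selection(s) resolve to no atoms: ",
         paste(bad, "=", unlist(sels[bad]), collapse = "; "))
  oneFrame <- function(cm) {
    p <- lapply(idx, function(ii) .tailCoMxy(cm, topo@atoms, ii))
    c(sqrt(sum((p$di - p$diii)^2)), sqrt(sum((p$dii - p$div)^2)))
  }
  if (is(x, "MolecularSystem")) {
    d <- oneFrame(.coordMatrix(x))
    return(new("GateDistanceSeries", d1 = d[1], d2 = d[2],
               frameIndices = 1L, replicaId = 1L))
  }
  nf <- nFrames(x)
  d <- vapply(seq_len(nf), function(i) oneFrame(x@coords[, , i]),
              numeric(2))
  new("GateDistanceSeries", d1 = d[1, ], d2 = d[2, ],
      frameIndices = seq_len(nf), replicaId = replicaId(x))
}

#' Free-energy surface over (d1, d2)
#'
#' Pools all series into one 2D histogram with square bins and converts
#' the normalized probability to free energy by Boltzmann inversion,
#' \eqn{F = -k_B T \ln(P / P_{max})}, so the most occupied bin sits at
#' 0 kcal/mol; empty bins are masked (\code{NA}). Contour levels every
#' 0.5 kcal/mol from 0 to 4 are attached as attribute
#' \code{"contourLevels"} of the returned surface's \code{freeEnergy}.
#'
#' @param series a \code{GateDistanceSeries} or list of them.
#' @param binWidth bin width in Angstrom (default 0.25).
#' @param temperature temperature in Kelvin (default 303.15).
#' @return A \code{FreeEnergySurface}.
#' @export
freeEnergySurface <- function(series, binWidth = 0.25,
                              temperature = 303.15) {
  if (is(series, "GateDistanceSeries")) series <- list(series)
  if (!length(series)) stop("need at least one distance series")
  if (binWidth <= 0) stop("binWidth must be positive")
  d1 <- unlist(lapply(series, function(s) s@d1))
  d2 <- unlist(lapply(series, function(s) s@d2))
  kB <- 0.0019872041
  e1 <- seq(floor(min(d1) / binWidth) * binWidth,
            ceiling(max(d1) / binWidth + 1e-9) * binWidth + binWidth,
            by = binWidth)
  e2 <- seq(floor(min(d2) / binWidth) * binWidth,
            ceiling(max(d2) / binWidth + 1e-9) * binWidth + binWidth,
            by = binWidth)
  i1 <- findInterval(d1, e1, rightmost.closed = TRUE)
  i2 <- findInterval(d2, e2, rightmost.closed = TRUE)
  counts <- matrix(0, length(e1) - 1, length(e2) - 1)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  if (sum(counts > 0) == 1)
    warning("all samples fall in a single bin; surface is one zero bin")
  P <- counts / sum(counts)
  F <- -kB * temperature * log(P / max(P))
  F[counts == 0] <- NA_real_
  attr(F, "contourLevels") <- seq(0, 4, by = 0.5)
  new("FreeEnergySurface", d1Edges = e1, d2Edges = e2, freeEnergy = F,
      temperature = temperature, kB = kB)
}

#' Free energy at a point of the surface
#'
#' @param fes a \code{FreeEnergySurface}.
#' @param d1,d2 coordinates in Angstrom.
#' @return Free energy in kcal/mol (\code{NA} for masked/out-of-range
#'   bins).
#' @export
fesValue <- function(fes, d1, d2) {
  i <- findInterval(d1, fes@d1Edges, rightmost.closed = TRUE)
  j <- findInterval(d2, fes@d2Edges, rightmost.closed = TRUE)
  if (i < 1 || j < 1 || i > nrow(fes@freeEnergy) || j > ncol(fes@freeEnergy))
    return(NA_real_)
  fes@freeEnergy[i, j]
}

#' Van der Waals pore-diameter profile
#'
#' At each z-grid point p on the canonical pore axis the accessible
#' radius is \code{r(z) = min over atoms (|p - atom| - vdW(atom))} and
#' the diameter is \code{2 r(z)} floored at 0. Protein heavy atoms only
#' by default (waters, ions and hydrogens excluded); radii are Bondi by
#' default.
#'
#' @param system canonicalized \code{MolecularSystem}.
#' @param zRange numeric(2) axial range to scan, Angstrom.
#' @param dz grid spacing, Angstrom.
#' @param radii named vector overriding \code{\link{vdwRadii}} per
#'   element, or \code{NULL} for Bondi.
#' @param selection atoms considered (default \code{"protein and not
#'   element H"}).
#' @param searchRadius atoms farther than this from the axis are ignored
#'   (error if none remain).
#' @return data.frame with columns \code{z} and \code{diameter}
#'   (Angstrom).
#' @export
poreDiameterProfile <- function(system, zRange = c(-40, 5), dz = 0.2,
                                radii = NULL,
                                selection = "protein and not element H",
                                searchRadius = 20) {
  stopifnot(is(system, "MolecularSystem"))
  idx <- selectAtoms(system, selection)@indices
  cm <- .coordMatrix(system)[idx, , drop = FALSE]
  el <- system@atoms$element[idx]
  rxy2 <- cm[, 1]^2 + cm[, 2]^2
  near <- rxy2 <= searchRadius^2
  if (!any(near))
    stop("no atoms within ", searchRadius, " A of the pore axis")
  cm <- cm[near, , drop = FALSE]
  rv <- if (is.null(radii)) vdwRadii(el[near]) else
    .elementLookup(el[near], radii, 1.70)
  rxy2 <- rxy2[near]
  zs <- seq(zRange[1], zRange[2], by = dz)
  diam <- vapply(zs, function(z) {
    r <- sqrt(rxy2 + (cm[, 3] - z)^2) - rv
    max(2 * min(r), 0)
  }, numeric(1))
  data.frame(z = zs, diameter = diam)
}

#' Minimum gate diameter
#'
#' Minimum of the van der Waals pore-diameter profile over the gate
#' z-range, with the z at which it occurs.
#'
#' @param system canonicalized \code{MolecularSystem}.
#' @param gate a \code{\link{gateRegion}} giving the z-range.
#' @param ... passed to \code{\link{poreDiameterProfile}}.
#' @return list with \code{diameter} (Angstrom) and \code{z}.
#' @export
gateDiameter <- function(system, gate = gateRegion(), ...) {
  prof <- poreDiameterProfile(system, zRange = c(gate$zMin, gate$zMax), ...)
  k <- which.min(prof$diameter)
  list(diameter = prof$diameter[k], z = prof$z[k])
}
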