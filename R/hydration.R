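# hydration_permeation: cylindrical hydration profiles, gate water-count
# statistics and wetting classification on canonicalized ensembles.
# Units: Angstrom throughout; the gate region defaults to the
# intracellular activation gate, -28 A < z < -15 A within an 8.5 A
# cylinder around the pore axis.

#' Gate region specification
#'
#' The intracellular activation gate as a z-interval (open, as counted:
#' \code{zMin < z < zMax}) within a cylinder around the pore axis
#' (inclusive, \code{r <= radius}).
#'
#' @param zMin,zMax z bounds in Angstrom (defaults -28 and -15).
#' @param radius cylinder radius in Angstrom (default 8.5, the same
#'   radius used for axial hydration profiles).
#' @return list of class \code{"GateRegion"}.
#' @export
gateRegion <- function(zMin = -28, zMax = -15, radius = 8.5) {
  if (!(zMin < zMax)) stop("gate zMin must be below zMax")
  if (radius <= 0) stop("gate radius must be positive")
  structure(list(zMin = zMin, zMax = zMax, radius = radius),
            class = "GateRegion")
}

#' Cylinder slicing specification for axial profiles
#'
#' @param radius cylinder radius, Angstrom (default 8.5).
#' @param zMin,zMax axial extent, Angstrom (defaults -40, +40).
#' @param nSlices number of uniform slices (default 80, i.e. 1 A width).
#' @return list of class \code{"CylinderSpec"}.
#' @export
cylinderSpec <- function(radius = 8.5, zMin = -40, zMax = 40, nSlices = 80) {
  if (radius <= 0) stop("cylinder radius must be positive")
  if (!(zMin < zMax)) stop("zMin must be below zMax")
  if (nSlices < 1) stop("need at least one slice")
  structure(list(radius = radius, zMin = zMin, zMax = zMax,
                 nSlices = as.integer(nSlices)), class = "CylinderSpec")
}

# Water oxygen atom indices of a topology: O atoms of recognised water
# residues (HOH, TIP3, SOL, WAT, TIP; case-insensitive).
.waterOxygenIndices <- function(system) {
  a <- system@atoms
  which(.isWaterResname(a$resname) & toupper(a$element) == "O")
}

#' Axial water profile of one replica
#'
#' Counts water O-atoms within the cylinder in uniform z-slices
#' (half-open \code{[zLo, zHi)}), averages the per-slice counts over
#' frames, and normalizes by the maximum slice (the solvent slice), so
#' the profile peaks at exactly 1.
#'
#' @param ensemble canonicalized \code{FrameEnsemble}.
#' @param cyl a \code{\link{cylinderSpec}}.
#' @return list with \code{sliceCenters} and \code{probability} (both
#'   numeric, length \code{nSlices}).
#' @export
axialWaterProfile <- function(ensemble, cyl = cylinderSpec()) {
  stopifnot(is(ensemble, "FrameEnsemble"), inherits(cyl, "CylinderSpec"))
  wIdx <- .waterOxygenIndices(ensemble@topology)
  edges <- seq(cyl$zMin, cyl$zMax, length.out = cyl$nSlices + 1)
  counts <- numeric(cyl$nSlices)
  r2max <- cyl$radius^2
  nf <- nFrames(ensemble)
  for (i in seq_len(nf)) {
    fr <- matrix(ensemble@coords[wIdx, , i], ncol = 3)
    inside <- (fr[, 1]^2 + fr[, 2]^2) <= r2max
    z <- fr[inside, 3]
    bins <- findInterval(z, edges, rightmost.closed = FALSE,
                         left.open = FALSE)
    bins <- bins[bins >= 1 & bins <= cyl$nSlices & z < cyl$zMax]
    counts <- counts + tabulate(bins, nbins = cyl$nSlices)
  }
  if (sum(counts) == 0)
    stop("no solvent slice: no water found in the cylinder, ",
         "normalization undefined")
  meanCounts <- counts / nf
  list(sliceCenters = (edges[-1] + edges[-length(edges)]) / 2,
       probability = meanCounts / max(meanCounts))
}

#' Aggregate per-replica axial profiles
#'
#' Across-replica mean and standard error of the mean (sample SD divided
#' by the square root of the number of replicas; zero for one replica).
#'
#' @param profiles list of per-replica profiles from
#'   \code{\link{axialWaterProfile}} (identical slicing required).
#' @return A \code{HydrationProfile}.
#' @export
aggregateProfiles <- function(profiles) {
  if (!length(profiles)) stop("need at least one replica profile")
  centers <- profiles[[1]]$sliceCenters
  for (p in profiles)
    if (length(p$sliceCenters) != length(centers) ||
        max(abs(p$sliceCenters - centers)) > 1e-9)
      stop("replica profiles have mismatched slicing")
  mat <- do.call(rbind, lapply(profiles, `[[`, "probability"))
  n <- nrow(mat)
  sem <- if (n == 1) rep(0, ncol(mat)) else apply(mat, 2, stats::sd) / sqrt(n)
  new("HydrationProfile", sliceCenters = centers,
      meanProbability = colMeans(mat), sem = sem,
      nReplicas = as.integer(n), perReplica = mat)
}

# Count water O-atoms inside the gate for one coordinate frame.
.gateCountFrame <- function(frameCoords, wIdx, gate) {
  w <- frameCoords[wIdx, , drop = FALSE]
  sum(w[, 3] > gate$zMin & w[, 3] < gate$zMax &
        (w[, 1]^2 + w[, 2]^2) <= gate$radius^2)
}

#' Count water molecules in the activation gate
#'
#' Water O-atoms with \code{zMin < z < zMax} and xy-distance to the pore
#' axis at most \code{radius}. Zero is a valid count.
#'
#' @param x a canonicalized \code{MolecularSystem} (one count) or
#'   \code{FrameEnsemble} (one count per frame).
#' @param gate a \code{\link{gateRegion}}.
#' @return integer vector of counts.
#' @export
gateWaterCount <- function(x, gate = gateRegion()) {
  stopifnot(inherits(gate, "GateRegion"))
  if (is(x, "MolecularSystem"))
    return(.gateCountFrame(.coordMatrix(x), .waterOxygenIndices(x), gate))
  stopifnot(is(x, "FrameEnsemble"))
  wIdx <- .waterOxygenIndices(x@topology)
  vapply(seq_len(nFrames(x)),
         function(i) .gateCountFrame(x@coords[, , i, drop = TRUE], wIdx, gate),
         integer(1))
}

#' Gate water-count probability distribution across replicas
#'
#' Per replica, the histogram of the per-frame gate water count is
#' normalized by the number of frames (so each replica's probabilities
#' sum to 1); the mean and SEM are then computed across replicas, along
#' with each replica's mean count.
#'
#' @param ensembles list of canonicalized \code{FrameEnsemble}s (one per
#'   replica), or a single ensemble.
#' @param gate a \code{\link{gateRegion}}.
#' @return An \code{NwaterDistribution}.
#' @export
nwaterDistribution <- function(ensembles, gate = gateRegion()) {
  if (is(ensembles, "FrameEnsemble")) ensembles <- list(ensembles)
  if (!length(ensembles)) stop("need at least one replica ensemble")
  countsList <- lapply(ensembles, gateWaterCount, gate = gate)
  if (any(vapply(countsList, length, integer(1)) == 0))
    stop("empty ensemble: no frames to histogram")
  nMax <- max(unlist(countsList))
  probs <- t(vapply(countsList, function(cc)
    tabulate(cc + 1L, nbins = nMax + 1L) / length(cc), numeric(nMax + 1L)))
  probs <- matrix(probs, nrow = length(countsList))
  n <- nrow(probs)
  sem <- if (n == 1) rep(0, ncol(probs)) else
    apply(probs, 2, stats::sd) / sqrt(n)
  new("NwaterDistribution", counts = 0:nMax,
      meanProbability = colMeans(probs), sem = sem,
      perReplicaMeanN = vapply(countsList, mean, numeric(1)),
      perReplica = probs)
}

#' Classify gate wetting state
#'
#' A frame is wetted when the gate holds \code{threshold} or more water
#' molecules (boundary inclusive), the operational criterion for a
#' continuous water column through a hydrophobic gate.
#'
#' @param x a canonicalized \code{MolecularSystem}, a
#'   \code{FrameEnsemble}, or an integer vector of gate water counts.
#' @param gate a \code{\link{gateRegion}} (ignored for count input).
#' @param threshold integer >= 1, default 10.
#' @return factor with levels \code{dewetted}, \code{wetted}.
#' @export
classifyWetting <- function(x, gate = gateRegion(), threshold = 10L) {
  if (threshold < 1) stop("wetting threshold must be at least 1")
  n <- if (is.numeric(x)) x else gateWaterCount(x, gate)
  factor(ifelse(n >= threshold, "wetted", "dewetted"),
         levels = c("dewetted", "wetted"))
}

#' Connected-path wetting criterion (alternative, non-default)
#'
#' Classifies a frame as wetted when a connected chain of waters
#' (pairwise O-O distance at most \code{linkDistance}) spans the gate,
#' linking a water above \code{zMax} to one below \code{zMin} through
#' the gate cylinder. Stricter than the count criterion; provided for
#' sensitivity checks.
#'
#' @param system canonicalized \code{MolecularSystem}.
#' @param gate a \code{\link{gateRegion}}.
#' @param linkDistance maximum O-O link distance, Angstrom.
#' @param margin z-margin beyond the gate to anchor bulk waters.
#' @return factor with levels \code{dewetted}, \code{wetted}.
#' @export
classifyWettingPath <- function(system, gate = gateRegion(),
                                linkDistance = 3.5, margin = 3) {
  w <- .coordMatrix(system)[.waterOxygenIndices(system), , drop = FALSE]
  keep <- (w[, 1]^2 + w[, 2]^2) <= gate$radius^2 &
    w[, 3] > gate$zMin - margin & w[, 3] < gate$zMax + margin
  w <- w[keep, , drop = FALSE]
  lab <- factor("dewetted", levels = c("dewetted", "wetted"))
  if (nrow(w) < 2) return(lab)
  above <- which(w[, 3] >= gate$zMax)
  below <- which(w[, 3] <= gate$zMin)
  if (!length(above) || !length(below)) return(lab)
  # flood fill from the 'above' anchors
  d2 <- as.matrix(stats::dist(w))^2
  reach <- rep(FALSE, nrow(w))
  reach[above] <- TRUE
  repeat {
    new <- which(!reach & apply(d2[, reach, drop = FALSE] <=
                                  linkDistance^2, 1, any))
    if (!length(new)) break
    reach[new] <- TRUE
  }
  if (any(reach[below])) lab[1] <- "wetted"
  lab
}
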