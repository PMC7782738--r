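# synthetic_data: seeded generators producing desk-scale inputs with the
# statistical structure the analyses assume -- a four-fold pseudo-channel,
# two-state (wetted/dewetted) gate hydration, bulk water slabs, ions that
# cannot cross a dewetted gate -- plus dose-response and kinetics data.
# All generators are pure functions of (spec, seed).

#' Toy channel specification
#'
#' Defines the synthetic four-fold pseudo-channel: four S6-tail Calpha
#' clusters at chosen xy offsets (setting the true d1 and d2), a
#' pore-helix Calpha scaffold for alignment, selectivity-filter marker
#' atoms at \code{dekaZ}, and a ring of atoms forming the pore
#' constriction. Default tail offsets reproduce a gate with
#' (d1, d2) = (16.6, 16.8) Angstrom; the default carbon constriction
#' ring of radius 5.0 gives a van der Waals gate diameter of
#' 2 (5.0 - 1.70) = 6.6 Angstrom.
#'
#' @param tailXY 4 x 2 matrix of tail xy offsets (DI, DII, DIII, DIV),
#'   Angstrom.
#' @param nTailResidues Calpha atoms per tail.
#' @param nPoreResidues Calpha atoms per pore-helix strand.
#' @param dekaZ z of the selectivity-filter marker, Angstrom.
#' @param gate a \code{\link{gateRegion}}.
#' @param box numeric(3) box lengths, Angstrom.
#' @param constrictionRadius radius of the constriction ring, Angstrom.
#' @param constrictionZ z of the constriction ring, Angstrom.
#' @param constrictionN atoms in the ring.
#' @return list of class \code{"ToyChannelSpec"}.
#' @export
toyChannelSpec <- function(tailXY = rbind(c(8.3, 0), c(0, 8.4),
                                          c(-8.3, 0), c(0, -8.4)),
                           nTailResidues = 4L, nPoreResidues = 12L,
                           dekaZ = 0, gate = gateRegion(),
                           box = c(120, 120, 120),
                           constrictionRadius = 5.0, constrictionZ = -21,
                           constrictionN = 8L) {
  tailXY <- as.matrix(tailXY)
  stopifnot(all(dim(tailXY) == c(4, 2)))
  d1 <- sqrt(sum((tailXY[1, ] - tailXY[3, ])^2))
  d2 <- sqrt(sum((tailXY[2, ] - tailXY[4, ])^2))
  if (d1 <= 0 || d2 <= 0) stop("tail offsets imply non-positive d1/d2")
  structure(list(tailXY = tailXY, nTailResidues = as.integer(nTailResidues),
                 nPoreResidues = as.integer(nPoreResidues), dekaZ = dekaZ,
                 gate = gate, box = box,
                 constrictionRadius = constrictionRadius,
                 constrictionZ = constrictionZ,
                 constrictionN = as.integer(constrictionN),
                 trueD1 = d1, trueD2 = d2),
            class = "ToyChannelSpec")
}

# Residue numbering used by the toy channel (mirrors the field's
# activation-gate selections so the default gateSelections() resolve).
.TOY_TAIL_RESIDS <- list(A = 410:413, B = 939:942, C = 1469:1472,
                         D = 1771:1774)
.TOY_PORE_RESIDS <- list(A = 380:391, B = 909:920, C = 1439:1450,
                         D = 1741:1752)
.TOY_DEKA_RESIDS <- c(A = 371L, B = 898L, C = 1420L, D = 1712L)

#' Canonical-frame spec for toy-channel systems
#'
#' @return A \code{\link{canonicalFrameSpec}} whose selections resolve
#'   the toy channel's pore-helix scaffold and selectivity-filter
#'   markers.
#' @export
toyCanonicalSpec <- function() {
  canonicalFrameSpec(
    align = "name CA and resid 380-391,909-920,1439-1450,1741-1752",
    zCenter = "name CA and resid 371,898,1420,1712")
}

#' Build the toy four-fold pseudo-channel
#'
#' @param spec a \code{\link{toyChannelSpec}}.
#' @return A \code{MolecularSystem} (labelled synthetic). Chains A-D are
#'   the four domains; the constriction ring is chain R.
#' @export
makeToyChannel <- function(spec = toyChannelSpec()) {
  stopifnot(inherits(spec, "ToyChannelSpec"))
  chains <- c("A", "B", "C", "D")
  rows <- list()
  addAtom <- function(name, resname, resid, chain, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resname = resname, resid = resid, chain = chain,
      x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  # S6 tails: stacked CA at the exact xy offset, so CoM(xy) = offset
  tailZ <- seq(-24.5, by = 1.5, length.out = spec$nTailResidues)
  for (k in 1:4) {
    resids <- .TOY_TAIL_RESIDS[[chains[k]]]
    resids <- resids[seq_len(min(length(resids), spec$nTailResidues))]
    for (j in seq_along(resids))
      addAtom("CA", "LEU", resids[j], chains[k],
              spec$tailXY[k, 1], spec$tailXY[k, 2], tailZ[j])
  }
  # pore-helix scaffold: one helical strand per domain, radius 11
  for (k in 1:4) {
    resids <- .TOY_PORE_RESIDS[[chains[k]]][seq_len(spec$nPoreResidues)]
    for (j in seq_along(resids)) {
      ang <- (k - 1) * pi / 2 + 0.45 * (j - 1)
      addAtom("CA", "VAL", resids[j], chains[k],
              11 * cos(ang), 11 * sin(ang), -26 + 2.2 * (j - 1))
    }
  }
  # selectivity-filter (DEKA) markers at z = dekaZ
  dekaNames <- c("ASP", "GLU", "LYS", "ALA")
  for (k in 1:4) {
    ang <- pi / 4 + (k - 1) * pi / 2
    addAtom("CA", dekaNames[k], .TOY_DEKA_RESIDS[[chains[k]]], chains[k],
            3.5 * cos(ang), 3.5 * sin(ang), spec$dekaZ)
  }
  # constriction ring defining the vdW gate diameter
  for (j in seq_len(spec$constrictionN)) {
    ang <- 2 * pi * (j - 1) / spec$constrictionN
    addAtom("CB", "ALA", 3000L + j, "R",
            spec$constrictionRadius * cos(ang),
            spec$constrictionRadius * sin(ang), spec$constrictionZ)
  }
  atoms <- do.call(rbind, rows)
  d <- stats::dist(atoms[, c("x", "y", "z")])
  if (min(d) < 0.5)
    stop("toy channel has overlapping atoms (< 0.5 A apart); adjust spec")
  newMolecularSystem(atoms, box = spec$box,
                     label = "synthetic toy channel")
}

#' Two-state wetting model specification
#'
#' Per-frame Markov switching between a dewetted state (mean 4 gate
#' waters) and a wetted state (mean 12), the hydration statistics of a
#' hydrophobic gate that is predominantly dewetted with transient
#' wetting. Gate water counts are drawn Poisson around the state mean.
#'
#' @param kWet per-frame probability of switching dry -> wet.
#' @param kDry per-frame probability of switching wet -> dry.
#' @param meanNDewetted,meanNWetted expected gate waters per state.
#' @param bulkDensity bulk water density, molecules per 1000 Angstrom^3
#'   (default 33, liquid water).
#' @return list of class \code{"WettingModelSpec"}.
#' @export
wettingModelSpec <- function(kWet = 0.04, kDry = 0.16,
                             meanNDewetted = 4, meanNWetted = 12,
                             bulkDensity = 33) {
  if (kWet <= 0 || kWet >= 1 || kDry <= 0 || kDry >= 1)
    stop("switching probabilities must lie in (0, 1)")
  if (meanNDewetted < 0 || meanNWetted < 0) stop("state means must be >= 0")
  structure(list(kWet = kWet, kDry = kDry, meanNDewetted = meanNDewetted,
                 meanNWetted = meanNWetted, bulkDensity = bulkDensity,
                 wettedFraction = kWet / (kWet + kDry)),
            class = "WettingModelSpec")
}

#' Ion model specification
#'
#' Random-walking Na+ ions at a bulk concentration; with
#' \code{permeationMode = "reflecting"} moves into the gate region are
#' rejected, so ions can never cross a dewetted gate. \code{nScripted}
#' adds deterministic ions that traverse the gate axially (ground truth
#' for the permeation detector); they only move in \code{"permeant"}
#' mode.
#'
#' @param nIons number of free ions, or \code{NULL} to derive from
#'   \code{concentration} and the box volume.
#' @param concentration molar concentration used when \code{nIons} is
#'   \code{NULL} (default 0.150 M).
#' @param stepSd random-walk step SD per frame, Angstrom.
#' @param permeationMode \code{"reflecting"} or \code{"permeant"}.
#' @param nScripted scripted crossing ions (permeant mode).
#' @return list of class \code{"IonModelSpec"}.
#' @export
ionModelSpec <- function(nIons = NULL, concentration = 0.150, stepSd = 1.5,
                         permeationMode = c("reflecting", "permeant"),
                         nScripted = 0L) {
  permeationMode <- match.arg(permeationMode)
  if (!is.null(nIons) && nIons < 0) stop("nIons must be >= 0")
  structure(list(nIons = nIons, concentration = concentration,
                 stepSd = stepSd, permeationMode = permeationMode,
                 nScripted = as.integer(nScripted)),
            class = "IonModelSpec")
}

# Uniform points in a disk of radius R (polar inverse-CDF).
.runifDisk <- function(n, R) {
  r <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

#' Simulate two-state gating/hydration trajectories
#'
#' Generates \code{nReplicas} independent replicas of \code{nFrames}
#' frames each. Per frame: the hidden wetted/dewetted state follows the
#' two-state Markov chain; the gate water count is Poisson around the
#' state mean and those waters are placed uniformly in the gate
#' cylinder; bulk slabs above and below the gate are filled at
#' \code{bulkDensity}; the DII/DIV tails fluctuate radially (d2
#' excursions up to ~4 Angstrom by default); ions random-walk and are
#' reflected at the gate in \code{"reflecting"} mode. Unused gate-water
#' slots are parked far outside the analysis cylinder. The true state
#' sequences and scripted-crossing count are returned for ground-truth
#' testing.
#'
#' @param channel a \code{\link{toyChannelSpec}}.
#' @param wet a \code{\link{wettingModelSpec}}.
#' @param ions an \code{\link{ionModelSpec}}.
#' @param nFrames frames per replica.
#' @param nReplicas number of replicas (the study design uses 30).
#' @param seed integer seed; identical inputs give identical output.
#' @param dt frame spacing, ps.
#' @param d2FluctSd,d1FluctSd stationary SD of the radial tail
#'   fluctuation (AR(1), lag-1 correlation 0.9), Angstrom.
#' @return list of class \code{"GatingSimulation"} with elements
#'   \code{ensembles} (list of \code{FrameEnsemble}), \code{states}
#'   (list of 0/1 vectors, 1 = wetted), \code{trueWettedFraction},
#'   \code{nScriptedCrossings}, \code{ionSelection} (spec string) and
#'   the three input specs.
#' @export
simulateGatingTrajectory <- function(channel = toyChannelSpec(),
                                     wet = wettingModelSpec(),
                                     ions = ionModelSpec(),
                                     nFrames = 500L, nReplicas = 3L,
                                     seed = 1L, dt = 250,
                                     d2FluctSd = 0.9, d1FluctSd = 0.45) {
  stopifnot(nFrames >= 1, nReplicas >= 1)
  set.seed(seed)
  base <- makeToyChannel(channel)
  gate <- channel$gate
  nProt <- nAtoms(base)
  at <- base@atoms
  tailIdx <- lapply(c("A", "B", "C", "D"), function(ch)
    which(at$chain == ch &
            at$resid %in% .TOY_TAIL_RESIDS[[ch]] & at$name == "CA"))
  tailDir <- lapply(1:4, function(k) {
    v <- channel$tailXY[k, ]
    v / sqrt(sum(v^2))
  })
  # water bookkeeping: fixed gate slots + fixed bulk counts
  nGateSlots <- max(40L, ceiling(wet$meanNWetted * 3))
  zTop <- min(channel$dekaZ + 8, channel$box[3] / 2 - 2)
  upper <- c(gate$zMax + 0.5, zTop)
  lower <- c(-min(38, channel$box[3] / 2 - 2), gate$zMin - 0.5)
  areaCyl <- pi * gate$radius^2
  nUp <- max(1L, round(wet$bulkDensity / 1000 * areaCyl * diff(upper)))
  nLo <- max(1L, round(wet$bulkDensity / 1000 * areaCyl * diff(lower)))
  nWater <- nGateSlots + nUp + nLo
  # molarity -> count: N = c [mol/L] * N_A * V [A^3] * 1e-27 L/A^3
  nFree <- if (is.null(ions$nIons))
    round(ions$concentration * 6.02214076e-4 * prod(channel$box))
  else ions$nIons
  nScripted <- if (ions$permeationMode == "permeant") ions$nScripted else 0L
  nIonTot <- nFree + nScripted
  waterAtoms <- data.frame(
    name = "O", resname = "HOH", resid = seq_len(nWater),
    chain = "W", x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  ionAtoms <- if (nIonTot > 0) data.frame(
    name = "NA", resname = "SOD", resid = seq_len(nIonTot), chain = "I",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE) else NULL
  topo <- newMolecularSystem(
    rbind(at[, c("name", "resname", "resid", "chain", "x", "y", "z")],
          waterAtoms, if (!is.null(ionAtoms)) ionAtoms),
    box = channel$box, label = "synthetic gating trajectory topology")
  wIdxGate <- nProt + seq_len(nGateSlots)
  wIdxUp <- nProt + nGateSlots + seq_len(nUp)
  wIdxLo <- nProt + nGateSlots + nUp + seq_len(nLo)
  iIdx <- if (nIonTot > 0) nProt + nWater + seq_len(nIonTot) else integer(0)
  half <- channel$box / 2 - 1
  inGateRegion <- function(p)
    p[3] > gate$zMin & p[3] < gate$zMax &
      (p[1]^2 + p[2]^2) <= gate$radius^2
  phiAR <- 0.9
  innov2 <- d2FluctSd * sqrt(1 - phiAR^2)
  innov1 <- d1FluctSd * sqrt(1 - phiAR^2)
  ensembles <- vector("list", nReplicas)
  states <- vector("list", nReplicas)
  baseCoords <- .coordMatrix(base)
  for (rep in seq_len(nReplicas)) {
    coords <- array(0, dim = c(nAtoms(topo), 3, nFrames))
    st <- integer(nFrames)
    s <- as.integer(stats::runif(1) < wet$wettedFraction)
    del1 <- stats::rnorm(1, 0, d1FluctSd)
    del2 <- stats::rnorm(1, 0, d2FluctSd)
    ionPos <- cbind(stats::runif(nFree, -half[1], half[1]),
                    stats::runif(nFree, -half[2], half[2]),
                    stats::runif(nFree, -half[3], half[3]))
    if (nFree > 0) {
      bad <- apply(ionPos, 1, inGateRegion)
      ionPos[bad, 3] <- gate$zMax + 5   # start clear of the gate
    }
    # scripted ions traverse the gate axially, staggered in time
    scriptPaths <- if (nScripted > 0) lapply(seq_len(nScripted), function(k) {
      zStart <- gate$zMax + 4
      zEnd <- gate$zMin - 4
      steps <- max(5L, min(nFrames - 1L, 20L))
      off <- ((k - 1L) * max(1L, nFrames %/% (nScripted + 1L)))
      z <- rep(zEnd, nFrames)
      ramp <- seq(zStart, zEnd, length.out = steps)
      pre <- min(off, nFrames)
      z[seq_len(pre)] <- zStart
      take <- seq_len(min(steps, nFrames - pre))
      z[pre + take] <- ramp[take]
      z
    }) else list()
    for (t in seq_len(nFrames)) {
      s <- if (s == 1L) {
        if (stats::runif(1) < wet$kDry) 0L else 1L
      } else {
        if (stats::runif(1) < wet$kWet) 1L else 0L
      }
      st[t] <- s
      fr <- matrix(0, nAtoms(topo), 3)
      fr[seq_len(nProt), ] <- baseCoords
      # radial tail fluctuation (AR(1)): DII/DIV set d2, DI/DIII set d1
      del1 <- phiAR * del1 + stats::rnorm(1, 0, innov1)
      del2 <- phiAR * del2 + stats::rnorm(1, 0, innov2)
      for (k in c(1, 3))
        fr[tailIdx[[k]], 1:2] <- sweep(fr[tailIdx[[k]], 1:2, drop = FALSE],
                                       2, -del1 * tailDir[[k]])
      for (k in c(2, 4))
        fr[tailIdx[[k]], 1:2] <- sweep(fr[tailIdx[[k]], 1:2, drop = FALSE],
                                       2, -del2 * tailDir[[k]])
      # gate waters
      mu <- if (s == 1L) wet$meanNWetted else wet$meanNDewetted
      nGate <- min(stats::rpois(1, mu), nGateSlots)
      park <- cbind(60, 3 * seq_len(nGateSlots), 50)
      fr[wIdxGate, ] <- park
      if (nGate > 0) {
        xy <- .runifDisk(nGate, gate$radius)
        fr[wIdxGate[seq_len(nGate)], ] <-
          cbind(xy, stats::runif(nGate, gate$zMin, gate$zMax))
      }
      # bulk slabs, resampled each frame
      xyU <- .runifDisk(nUp, gate$radius)
      fr[wIdxUp, ] <- cbind(xyU, stats::runif(nUp, upper[1], upper[2]))
      xyL <- .runifDisk(nLo, gate$radius)
      fr[wIdxLo, ] <- cbind(xyL, stats::runif(nLo, lower[1], lower[2]))
      # ions
      if (nFree > 0) {
        prop <- ionPos + matrix(stats::rnorm(3 * nFree, 0, ions$stepSd),
                                ncol = 3)
        prop <- pmin(pmax(prop, rep(-half, each = nFree)),
                     rep(half, each = nFree))
        if (ions$permeationMode == "reflecting") {
          blocked <- apply(prop, 1, inGateRegion)
          prop[blocked, ] <- ionPos[blocked, ]
        }
        ionPos <- prop
        fr[iIdx[seq_len(nFree)], ] <- ionPos
      }
      if (nScripted > 0)
        for (k in seq_len(nScripted))
          fr[iIdx[nFree + k], ] <- c(0, 0, scriptPaths[[k]][t])
      coords[, , t] <- fr
    }
    ensembles[[rep]] <- newFrameEnsemble(topo, coords, replicaId = rep,
                                         dt = dt)
    states[[rep]] <- st
  }
  structure(list(ensembles = ensembles, states = states,
                 trueWettedFraction = wet$wettedFraction,
                 nScriptedCrossings = nScripted,
                 ionSelection = "resname SOD",
                 channel = channel, wet = wet, ions = ions),
            class = "GatingSimulation")
}

#' Simulate gate-distance samples from a two-basin free-energy model
#'
#' Draws (d1, d2) samples from a two-component Gaussian mixture whose
#' component weights encode an imposed free-energy difference
#' \code{deltaF} between a favoured asymmetric basin (d2 < d1 analogue)
#' and a metastable symmetric basin, for testing Boltzmann-inversion
#' recovery. Basin centres sit on 0.25-Angstrom bin centres so the
#' recovered bin difference is unbiased.
#'
#' @param n samples.
#' @param deltaF imposed free-energy difference, kcal/mol.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @param basin1,basin2 numeric(2) centres (d1, d2), Angstrom; basin1 is
#'   the favoured one.
#' @param spread per-axis Gaussian SD within a basin, Angstrom.
#' @param replicaId replica identifier.
#' @return A \code{GateDistanceSeries}.
#' @export
simulateGateDistanceSeries <- function(n, deltaF = 0.75,
                                       temperature = 303.15, seed = 1L,
                                       basin1 = c(15.125, 16.625),
                                       basin2 = c(16.625, 16.875),
                                       spread = 0.30, replicaId = 1L) {
  set.seed(seed)
  kB <- 0.0019872041
  w2 <- exp(-deltaF / (kB * temperature))
  p2 <- w2 / (1 + w2)
  pick <- stats::runif(n) < p2
  centre <- rbind(basin1, basin2)[pick + 1L, , drop = FALSE]
  d1 <- stats::rnorm(n, centre[, 1], spread)
  d2 <- stats::rnorm(n, centre[, 2], spread)
  ok <- d1 > 0 & d2 > 0
  new("GateDistanceSeries", d1 = d1[ok], d2 = d2[ok],
      frameIndices = seq_len(sum(ok)), replicaId = as.integer(replicaId))
}

#' Simulate concentration-response data
#'
#' Hill-model responses plus Gaussian noise, clipped to [0, 1].
#'
#' @param ec50 half-maximal concentration, nM.
#' @param hillN Hill coefficient.
#' @param concentrations nM (default the four-point design 1, 10, 100,
#'   1000 nM).
#' @param noiseSd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param top,bottom plateau values.
#' @return data.frame with \code{concentration} and \code{response}.
#' @export
simulateDoseResponse <- function(ec50 = 11.4, hillN = 1,
                                 concentrations = c(1, 10, 100, 1000),
                                 noiseSd = 0.03, seed = 1L,
                                 top = 1, bottom = 0) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  mu <- bottom + (top - bottom) / (1 + (ec50 / concentrations)^hillN)
  y <- mu + stats::rnorm(length(mu), 0, noiseSd)
  data.frame(concentration = concentrations,
             response = pmin(pmax(y, 0), 1))
}

#' Simulate single-exponential kinetics data
#'
#' @param tau time constant (same unit as \code{times}).
#' @param mode \code{"association"} or \code{"decay"}.
#' @param times sample times (default 0-28 min every 2 min).
#' @param amplitude,offset model parameters.
#' @param noiseSd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @return data.frame with \code{time} and \code{response}.
#' @export
simulateKinetics <- function(tau = 11.3, mode = c("association", "decay"),
                             times = seq(0, 28, by = 2), amplitude = 1,
                             offset = 0, noiseSd = 0.02, seed = 1L) {
  mode <- match.arg(mode)
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  mu <- if (mode == "association") amplitude * (1 - exp(-times / tau)) + offset
        else amplitude * exp(-times / tau) + offset
  data.frame(time = times, response = mu + stats::rnorm(length(mu), 0, noiseSd))
}
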