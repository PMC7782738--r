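# Shared fixtures and independent oracles, built in code at test time.

# Independent quaternion-method RMSD oracle (Horn 1987): the optimal
# superposition RMSD from the largest eigenvalue of the 4x4 key matrix,
# with no rotation matrix ever formed. Independent of the SVD route used
# by kabschSuperpose().
quaternionRmsd <- function(mobile, reference) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(sum(P^2) + sum(Q^2) - 2 * lambda, 0) / nrow(P))
}

# A minimal system from vectors (coordinates in Angstrom).
makeSystem <- function(name, resname, resid, chain, xyz) {
  newMolecularSystem(data.frame(
    name = name, resname = resname, resid = resid, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# A box of waters (O atoms) at the given coordinates, optionally merged
# with extra atoms.
makeWaterSystem <- function(xyz, resname = "HOH", extra = NULL) {
  at <- data.frame(name = "O", resname = resname,
                   resid = seq_len(nrow(xyz)), chain = "W",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) at <- rbind(extra, at)
  newMolecularSystem(at)
}

# Wrap a static system as a one-frame ensemble.
asEnsemble <- function(system, replicaId = 1L) {
  newFrameEnsemble(system, list(poregate::coords(system)),
                   replicaId = replicaId)
}

# Uniform random points inside a cylinder (seeded by caller).
cylinderPoints <- function(n, radius, zMin, zMax) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), runif(n, zMin, zMax))
}

# Standard-error of a Markov-chain occupancy estimate: binomial variance
# inflated by the chain's autocorrelation factor (1+rho)/(1-rho), where
# rho = 1 - kWet - kDry.
markovFractionSE <- function(p, n, kWet, kDry) {
  rho <- 1 - kWet - kDry
  sqrt(p * (1 - p) / n * (1 + rho) / (1 - rho))
}
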