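# Ideal-geometry backbone construction (internal coordinates -> Cartesian
# via the NeRF chain rule). Used by the synthetic generators and as an
# independent construction oracle for helix-type assignment.

# Place atom D given A-B-C, |C-D|, angle(B,C,D) and torsion(A,B,C,D).
.placeAtom <- function(A, B, C, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal polypeptide helix backbone
#'
#' Constructs N, CA, C, O backbone atoms for \code{n} residues at fixed
#' backbone dihedrals using standard bond lengths and angles (N-CA
#' 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom; trans peptide,
#' omega = 180). An ideal alpha-helix is phi = -57, psi = -47; an ideal
#' 3-10 helix is phi = -49, psi = -26.
#'
#' @param n number of residues.
#' @param phi,psi backbone dihedrals in degrees.
#' @param resname residue name(s), recycled.
#' @param chain chain identifier.
#' @param startResid first author residue number.
#' @return A \code{MolecularSystem} with 4 backbone atoms per residue.
#' @export
buildIdealHelix <- function(n, phi = -57, psi = -47, resname = "ALA",
                            chain = "A", startResid = 1L) {
  stopifnot(n >= 1)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.5
  Ns <- CAs <- Cs <- vector("list", n)
  Ns[[1]] <- c(0, 0, 0)
  CAs[[1]] <- c(bNCA, 0, 0)
  Cs[[1]] <- CAs[[1]] + bCAC *
    c(cos(pi - aNCAC * pi / 180), sin(pi - aNCAC * pi / 180), 0)
  for (i in seq_len(n - 1)) {
    Ns[[i + 1]] <- .placeAtom(Ns[[i]], CAs[[i]], Cs[[i]], bCN, aCACN, psi)
    CAs[[i + 1]] <- .placeAtom(CAs[[i]], Cs[[i]], Ns[[i + 1]], bNCA,
                               aCNCA, 180)
    Cs[[i + 1]] <- .placeAtom(Cs[[i]], Ns[[i + 1]], CAs[[i + 1]], bCAC,
                              aNCAC, phi)
  }
  # carbonyl O in the peptide plane, anti to the next residue's N
  Os <- lapply(seq_len(n), function(i)
    .placeAtom(Ns[[i]], CAs[[i]], Cs[[i]], bCO, aCACO, psi + 180))
  resname <- rep_len(resname, n)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- rbind(Ns[[i]], CAs[[i]], Cs[[i]], Os[[i]])
    data.frame(name = c("N", "CA", "C", "O"),
               resname = resname[i], resid = startResid + i - 1L,
               chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  newMolecularSystem(atoms, label = sprintf("ideal helix phi=%g psi=%g",
                                            phi, psi))
}

# Unit direction of a helix's axis estimated from its CA trace.
.helixAxis <- function(system) {
  ca <- .coordMatrix(system)[system@atoms$name == "CA", , drop = FALSE]
  centred <- sweep(ca, 2, colMeans(ca))
  v <- svd(centred)$v[, 1]
  if (sum(v * (ca[nrow(ca), ] - ca[1, ])) < 0) v <- -v
  v
}

#' Orient a helix along an axis through a point
#'
#' Rotates the system so its CA-trace principal axis (pointing from the
#' first to the last residue) lies along \code{axis}, then translates the
#' CA centroid to \code{origin}.
#'
#' @param system \code{MolecularSystem} (a helix).
#' @param axis target unit axis (default +z).
#' @param origin target centroid position.
#' @return The re-oriented \code{MolecularSystem}.
#' @export
orientHelix <- function(system, axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  R <- .rotationBetween(.helixAxis(system), axis)
  cm <- .coordMatrix(system) %*% t(R)
  ca <- cm[system@atoms$name == "CA", , drop = FALSE]
  .setCoords(system, sweep(cm, 2, colMeans(ca) - origin))
}
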