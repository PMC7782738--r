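# Element tables and small geometry helpers shared across modules.

# Standard atomic masses (amu) for common biomolecular elements.
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, NA. = 22.9898, CL = 35.45,
                   K = 39.098, MG = 24.305, FE = 55.845, ZN = 65.38,
                   F = 18.998, BR = 79.904, I = 126.904)

# Bondi van der Waals radii (Angstrom); used for pore diameters and SASA.
.VDW_BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                NA. = 2.27, K = 2.75, MG = 1.73, ZN = 1.39)

.WATER_RESNAMES <- c("HOH", "TIP3", "SOL", "WAT", "TIP")

.ION_RESNAMES <- c("NA", "CL", "K", "SOD", "CLA", "POT", "MG", "CAL",
                   "ZN", "NA+", "CL-", "K+")

.AA_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL", "MSE")

# Look up a per-element table, with a fallback for unknown elements.
# "NA" the element collides with NA the missing value, hence the "NA." key.
.elementLookup <- function(element, table, fallback) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  out <- unname(table[key])
  out[is.na(out)] <- fallback
  out
}

elementMasses <- function(element) .elementLookup(element, .ELEMENT_MASS, 12.011)

#' Bondi van der Waals radii
#'
#' Returns the Bondi van der Waals radius (Angstrom) for each element
#' symbol; unknown elements fall back to the carbon radius 1.70.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdwRadii <- function(element) .elementLookup(element, .VDW_BONDI, 1.70)

# Infer an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, then try the two-letter and one-letter stems.
.guessElement <- function(name) {
  stem <- toupper(gsub("[0-9'\\*\"]", "", name))
  two <- substr(stem, 1, 2)
  one <- substr(stem, 1, 1)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA"), two, one)
}

.isWaterResname <- function(resname) toupper(resname) %in% .WATER_RESNAMES

# Mass-weighted centre of mass of a coordinate block.
.centreOfMass <- function(coords, masses) {
  w <- masses / sum(masses)
  c(sum(coords[, 1] * w), sum(coords[, 2] * w), sum(coords[, 3] * w))
}

# Rotation matrix about an arbitrary unit axis (Rodrigues).
.rotationAboutAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation taking unit vector `from` onto unit vector `to`.
.rotationBetween <- function(from, to) {
  a <- from / sqrt(sum(from^2))
  b <- to / sqrt(sum(to^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ortho <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- ortho - sum(ortho * a) * a
    return(.rotationAboutAxis(axis, pi))
  }
  .rotationAboutAxis(v / s, atan2(s, cth))
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
.goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Coordinates of a system as an n x 3 matrix.
.coordMatrix <- function(system) {
  as.matrix(system@atoms[, c("x", "y", "z")])
}

# Replace the coordinates of a system (atom table order preserved).
.setCoords <- function(system, coords) {
  system@atoms$x <- coords[, 1]
  system@atoms$y <- coords[, 2]
  system@atoms$z <- coords[, 3]
  system
}

.atomKeys <- function(atoms, idx = seq_len(nrow(atoms))) {
  paste(atoms$chain[idx], atoms$resid[idx], atoms$name[idx], sep = "|")
}
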