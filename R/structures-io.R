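# structures_io: read/write structures and trajectories into the uniform
# data model. PDB/mmCIF/DCD parsing is delegated to bio3d; writing uses a
# small fixed-width PDB writer so that multi-model files and author
# numbering round-trip exactly.

#' Construct a MolecularSystem from an atom table
#'
#' @param atoms data.frame with at least \code{name}, \code{resname},
#'   \code{resid}, \code{chain}, \code{x}, \code{y}, \code{z}. Missing
#'   \code{serial} is filled with 1..n; missing \code{element} is guessed
#'   from the atom name.
#' @param box optional numeric(3) box lengths, Angstrom.
#' @param label free-text label.
#' @return A \code{MolecularSystem}.
#' @export
newMolecularSystem <- function(atoms, box = c(NA_real_, NA_real_, NA_real_),
                               label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element) || all(!nzchar(atoms$element)))
    atoms$element <- .guessElement(atoms$name)
  atoms$element[!nzchar(atoms$element)] <-
    .guessElement(atoms$name[!nzchar(atoms$element)])
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  rownames(atoms) <- NULL
  new("MolecularSystem",
      atoms = atoms[, c("serial", "name", "element", "resname", "resid",
                        "chain", "x", "y", "z")],
      box = as.numeric(box), label = label)
}

#' Construct a FrameEnsemble
#'
#' @param topology \code{MolecularSystem} (coordinates ignored).
#' @param coords \code{n_atoms x 3 x n_frames} array, or a list of
#'   \code{n_atoms x 3} matrices.
#' @param times frame times in ps; synthesized at \code{dt} spacing when
#'   omitted.
#' @param replicaId integer replica identifier.
#' @param dt time step in ps used when \code{times} is omitted.
#' @return A \code{FrameEnsemble}.
#' @export
newFrameEnsemble <- function(topology, coords, times = NULL,
                             replicaId = 1L, dt = 1) {
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (is.null(times)) times <- (seq_len(dim(coords)[3]) - 1) * dt
  new("FrameEnsemble", topology = topology, coords = coords,
      times = as.numeric(times), replicaId = as.integer(replicaId))
}

# Convert a bio3d pdb object (one model) into our atom table. Altloc
# conformers are resolved to the highest-occupancy one (ties -> first
# alphabetically), per the module's design decision.
.bio3dToAtoms <- function(pdb) {
  a <- pdb$atom
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(a))
  if (any(nzchar(alt))) {
    key <- paste(a$chain, a$resno, a$resid, a$elety, sep = "|")
    for (k in unique(key[nzchar(alt)])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        best <- idx[order(-occ[idx], alt[idx])][1]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem)) elem <- rep("", nrow(a))
  elem[is.na(elem) | !nzchar(elem)] <-
    .guessElement(a$elety[is.na(elem) | !nzchar(elem)])
  chain <- a$chain
  chain[is.na(chain)] <- ""
  data.frame(serial = as.integer(a$eleno), name = a$elety,
             element = toupper(elem), resname = a$resid,
             resid = as.integer(a$resno), chain = chain,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

#' Read a structure file (PDB or mmCIF)
#'
#' All ATOM/HETATM records are represented; author residue numbering is
#' preserved; alternate-location conformers are reduced to the
#' highest-occupancy one (ties broken alphabetically).
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @return A \code{MolecularSystem}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer structure format from extension '.",
                          ext, "'; pass format explicitly"))
  }
  pdb <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                       rm.alt = FALSE, verbose = FALSE))
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no ATOM/HETATM records found in '", path, "'")
  newMolecularSystem(.bio3dToAtoms(pdb), label = basename(path))
}

# One fixed-width PDB ATOM/HETATM line per atom.
.pdbRecordLines <- function(atoms) {
  name4 <- ifelse(nchar(atoms$name) >= 4, substr(atoms$name, 1, 4),
                  sprintf(" %-3s", atoms$name))
  rec <- ifelse(atoms$resname %in% c(.AA_RESNAMES, "DA", "DT", "DG", "DC"),
                "ATOM  ", "HETATM")
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000L, name4,
          substr(atoms$resname, 1, 3), substr(atoms$chain, 1, 1),
          atoms$resid %% 10000L, atoms$x, atoms$y, atoms$z, 1, 0,
          substr(atoms$element, 1, 2))
}

#' Write a structure to a PDB file
#'
#' @param system \code{MolecularSystem}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(system, path) {
  stopifnot(is(system, "MolecularSystem"))
  lines <- c(.pdbRecordLines(system@atoms), "END")
  if (!all(is.na(system@box)))
    lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       system@box[1], system@box[2], system@box[3]), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param ensemble \code{FrameEnsemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(ensemble, path) {
  stopifnot(is(ensemble, "FrameEnsemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nFrames(ensemble))) {
    sys <- getFrame(ensemble, i)
    writeLines(c(sprintf("MODEL     %4d", i),
                 .pdbRecordLines(sys@atoms), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory with its topology
#'
#' Multi-model PDB and DCD are supported (XTC is not; convert to DCD or
#' multi-model PDB upstream). Frames are kept in file order; when MODEL
#' numbers in a multi-model PDB are out of order a warning is issued and
#' times are re-synthesized at fixed stride.
#'
#' @param topologyPath structure file naming the atoms.
#' @param trajectoryPath trajectory file.
#' @param format \code{"auto"}, \code{"multipdb"}, \code{"dcd"} or
#'   \code{"xtc"}.
#' @param dt time stride in ps used to synthesize frame times.
#' @param replicaId integer replica identifier.
#' @return A \code{FrameEnsemble}.
#' @export
readTrajectory <- function(topologyPath, trajectoryPath,
                           format = c("auto", "multipdb", "dcd", "xtc"),
                           dt = 1, replicaId = 1L) {
  format <- match.arg(format)
  topo <- readStructure(topologyPath)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(trajectoryPath))
    format <- switch(ext, pdb = "multipdb", ent = "multipdb", dcd = "dcd",
                     xtc = "xtc",
                     stop("cannot infer trajectory format from extension '.",
                          ext, "'"))
  }
  if (format == "xtc")
    stop("XTC trajectories are not supported; convert to DCD or ",
         "multi-model PDB")
  if (format == "multipdb") {
    modelNos <- suppressWarnings(as.integer(substr(
      grep("^MODEL", readLines(trajectoryPath), value = TRUE), 11, 14)))
    pdb <- tryCatch(
      bio3d::read.pdb(trajectoryPath, multi = TRUE, verbose = FALSE),
      error = function(e) stop("failed to parse multi-model PDB '",
                               trajectoryPath, "': ",
                               conditionMessage(e), call. = FALSE))
    xyz <- pdb$xyz
    if (length(modelNos) > 1 && any(diff(modelNos) <= 0, na.rm = TRUE))
      warning("MODEL records out of order in '", trajectoryPath,
              "'; keeping file order and re-synthesizing times")
  } else {
    xyz <- bio3d::read.dcd(trajectoryPath, verbose = FALSE)
  }
  xyz <- matrix(xyz, nrow = if (is.matrix(xyz)) nrow(xyz) else 1,
                ncol = if (is.matrix(xyz)) ncol(xyz) else length(xyz))
  nTraj <- ncol(xyz) / 3
  if (nTraj != nAtoms(topo))
    stop(sprintf("atom-count mismatch: topology has %d atoms but trajectory frames have %d",
                 nAtoms(topo), nTraj))
  nfr <- nrow(xyz)
  coords <- array(0, dim = c(nAtoms(topo), 3, nfr))
  for (i in seq_len(nfr))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  newFrameEnsemble(topo, coords, replicaId = replicaId, dt = dt)
}
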