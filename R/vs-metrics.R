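# vs_trapping_metrics: static-structure comparisons -- selection RMSD,
# per-residue displacement, gating-charge ion-pair census and
# alpha/3-10 helix discrimination.

# Side-chain atoms participating in salt bridges, by residue type.
.BASIC_N_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                       HIS = c("ND1", "NE2"), HSD = c("ND1", "NE2"),
                       HSE = c("ND1", "NE2"), HSP = c("ND1", "NE2"))
.ACIDIC_O_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Pair atoms of two systems by (chain, residue number, atom name) within
# a selection; returns matched index vectors plus the unpaired counts.
.pairAtoms <- function(a, b, spec) {
  ia <- selectAtoms(a, spec)@indices
  ib <- selectAtoms(b, spec)@indices
  ka <- .atomKeys(a@atoms, ia)
  kb <- .atomKeys(b@atoms, ib)
  common <- intersect(ka, kb)
  list(a = ia[match(common, ka)], b = ib[match(common, kb)],
       nUnpaired = (length(ia) - length(common)) +
         (length(ib) - length(common)))
}

#' RMSD over a selection of two structures
#'
#' Atoms are paired by (chain, author residue number, atom name);
#' unpaired atoms are dropped and their count reported. With
#' \code{superpose = TRUE} (the "minimum RMSD" convention) a Kabsch
#' superposition over the paired set precedes the measurement.
#'
#' @param a,b \code{MolecularSystem}s.
#' @param spec selection expression (default all Calpha atoms).
#' @param superpose logical, default \code{TRUE}.
#' @return list with \code{rmsd} (Angstrom), \code{nResidues} (distinct
#'   paired residues), \code{nAtoms} (paired atoms) and \code{nUnpaired}.
#' @export
rmsdOverSelection <- function(a, b, spec = "name CA", superpose = TRUE) {
  p <- .pairAtoms(a, b, spec)
  if (!length(p$a)) stop("zero atoms pair between the two structures")
  ca <- .coordMatrix(a)[p$a, , drop = FALSE]
  cb <- .coordMatrix(b)[p$b, , drop = FALSE]
  rmsd <- if (superpose && nrow(ca) >= 3) {
    kabschSuperpose(cb, ca)$rmsd
  } else {
    sqrt(mean(rowSums((ca - cb)^2)))
  }
  list(rmsd = rmsd,
       nResidues = length(unique(paste(a@atoms$chain[p$a],
                                       a@atoms$resid[p$a]))),
       nAtoms = length(p$a), nUnpaired = p$nUnpaired)
}

#' Per-residue Calpha displacement between two structures
#'
#' Structure \code{b} is first superposed onto \code{a} over the
#' \code{referenceSpec} pairing (e.g. the pore module), then the Calpha
#' displacement of every paired residue in \code{selectionSpec} is
#' measured. Unpaired residues are omitted and listed in the
#' \code{"unpaired"} attribute.
#'
#' @param a,b \code{MolecularSystem}s.
#' @param selectionSpec selection whose displacements are measured
#'   (Calpha atoms are used).
#' @param referenceSpec selection defining the superposition frame.
#' @return data.frame with columns \code{chain}, \code{resid},
#'   \code{displacement} (Angstrom).
#' @export
residueDisplacement <- function(a, b, selectionSpec, referenceSpec) {
  ref <- .pairAtoms(a, b, referenceSpec)
  if (length(ref$a) < 3)
    stop("reference selection pairs fewer than 3 atoms")
  fit <- kabschSuperpose(.coordMatrix(b)[ref$b, , drop = FALSE],
                         .coordMatrix(a)[ref$a, , drop = FALSE])
  bMoved <- applyTransform(b, fit$transform)
  caSpec <- paste0("(", selectionSpec, ") and name CA")
  p <- .pairAtoms(a, bMoved, caSpec)
  if (!length(p$a)) stop("no paired Calpha atoms in the selection")
  da <- .coordMatrix(a)[p$a, , drop = FALSE]
  db <- .coordMatrix(bMoved)[p$b, , drop = FALSE]
  out <- data.frame(chain = a@atoms$chain[p$a], resid = a@atoms$resid[p$a],
                    displacement = sqrt(rowSums((da - db)^2)),
                    stringsAsFactors = FALSE)
  attr(out, "unpaired") <- p$nUnpaired
  out
}

#' Gating-charge ion-pair census
#'
#' Reports one pair per (basic residue, acidic residue) combination whose
#' minimum side-chain N-O distance is at most \code{cutoff} (default
#' 4.0 Angstrom, the salt-bridge criterion). Basic side-chain N atoms are
#' Arg NE/NH1/NH2, Lys NZ, His ND1/NE2; acidic O atoms are Asp OD1/OD2,
#' Glu OE1/OE2 (both configurable). When \code{hcsZ} is supplied, each
#' pair is classified by the acidic residue's mean z relative to the
#' hydrophobic constriction site: above = \code{ENC} (extracellular
#' negative cluster), below = \code{INC}; otherwise \code{other}.
#'
#' @param structure \code{MolecularSystem} (canonicalized if \code{hcsZ}
#'   is used).
#' @param basicSpec,acidicSpec selection expressions (non-empty).
#' @param cutoff distance cutoff, Angstrom.
#' @param hcsZ z-coordinate of the HCS, or \code{NA}.
#' @param basicAtoms,acidicAtoms named lists residue -> atom names.
#' @return data.frame with one row per residue pair: \code{basicChain},
#'   \code{basicResid}, \code{basicResname}, \code{acidicChain},
#'   \code{acidicResid}, \code{acidicResname}, \code{minDistance},
#'   \code{side}.
#' @export
ionPairCensus <- function(structure, basicSpec, acidicSpec, cutoff = 4.0,
                          hcsZ = NA_real_, basicAtoms = .BASIC_N_ATOMS,
                          acidicAtoms = .ACIDIC_O_ATOMS) {
  stopifnot(is(structure, "MolecularSystem"))
  at <- structure@atoms
  pick <- function(spec, table) {
    idx <- selectAtoms(structure, spec)@indices
    if (!length(idx)) stop("selection resolves to no atoms: ", spec)
    keep <- vapply(idx, function(i) {
      nm <- table[[toupper(at$resname[i])]]
      !is.null(nm) && at$name[i] %in% nm
    }, logical(1))
    idx[keep]
  }
  bi <- pick(basicSpec, basicAtoms)
  ai <- pick(acidicSpec, acidicAtoms)
  if (!length(bi) || !length(ai))
    stop("no side-chain N/O atoms found in the basic/acidic selections")
  cm <- .coordMatrix(structure)
  bRes <- unique(data.frame(chain = at$chain[bi], resid = at$resid[bi],
                            resname = at$resname[bi],
                            stringsAsFactors = FALSE))
  aRes <- unique(data.frame(chain = at$chain[ai], resid = at$resid[ai],
                            resname = at$resname[ai],
                            stringsAsFactors = FALSE))
  rows <- list()
  for (p in seq_len(nrow(bRes))) {
    bAt <- bi[at$chain[bi] == bRes$chain[p] & at$resid[bi] == bRes$resid[p]]
    for (q in seq_len(nrow(aRes))) {
      aAt <- ai[at$chain[ai] == aRes$chain[q] & at$resid[ai] == aRes$resid[q]]
      d <- sqrt(pmax(outer(rowSums(cm[bAt, , drop = FALSE]^2),
                           rowSums(cm[aAt, , drop = FALSE]^2), `+`) -
                  2 * cm[bAt, , drop = FALSE] %*% t(cm[aAt, , drop = FALSE]),
                  0))
      dmin <- min(d)
      if (dmin <= cutoff) {
        side <- if (is.na(hcsZ)) "other" else
          if (mean(cm[aAt, 3]) > hcsZ) "ENC" else "INC"
        rows[[length(rows) + 1L]] <- data.frame(
          basicChain = bRes$chain[p], basicResid = bRes$resid[p],
          basicResname = bRes$resname[p], acidicChain = aRes$chain[q],
          acidicResid = aRes$resid[q], acidicResname = aRes$resname[q],
          minDistance = dmin, side = side, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(basicChain = character(0), basicResid = integer(0),
                      basicResname = character(0),
                      acidicChain = character(0), acidicResid = integer(0),
                      acidicResname = character(0),
                      minDistance = numeric(0), side = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Alpha versus 3-10 helix assignment
#'
#' Heavy-atom criterion robust to missing hydrogens: residue i is
#' \code{three_ten} when its carbonyl O sits within 3.5 Angstrom of the
#' backbone N of residue i+3 and that contact is shorter than the one to
#' i+4; \code{alpha} when the i+4 contact is within 3.5 Angstrom and
#' shorter; \code{other} otherwise (including terminal residues lacking
#' partners and residues with missing backbone atoms, which trigger a
#' warning).
#'
#' @param structure \code{MolecularSystem}.
#' @param residRange integer vector of author residue numbers to label.
#' @param chain optional chain restriction.
#' @param maxDist hydrogen-bond heavy-atom distance threshold, Angstrom.
#' @return data.frame with columns \code{chain}, \code{resid},
#'   \code{label} (\code{alpha}, \code{three_ten} or \code{other}).
#' @export
helixTypeAssignment <- function(structure, residRange, chain = NULL,
                                maxDist = 3.5) {
  at <- structure@atoms
  keep <- if (is.null(chain)) rep(TRUE, nrow(at)) else at$chain %in% chain
  getAtom <- function(resid, name) {
    i <- which(keep & at$resid == resid & at$name == name)
    if (length(i) != 1) return(NULL)
    c(at$x[i], at$y[i], at$z[i])
  }
  chains <- if (is.null(chain)) unique(at$chain[at$resid %in% residRange])
            else chain
  rows <- lapply(sort(unique(residRange)), function(r) {
    O <- getAtom(r, "O")
    bbOK <- !is.null(getAtom(r, "N")) && !is.null(getAtom(r, "CA")) &&
      !is.null(getAtom(r, "C")) && !is.null(O)
    if (!bbOK) {
      warning("residue ", r, ": missing backbone atoms; labelled 'other'")
      lbl <- "other"
    } else {
      N3 <- getAtom(r + 3L, "N")
      N4 <- getAtom(r + 4L, "N")
      if (is.null(N3) || is.null(N4)) {
        lbl <- "other"                     # terminal: partners missing
      } else {
        d3 <- sqrt(sum((O - N3)^2))
        d4 <- sqrt(sum((O - N4)^2))
        lbl <- if (d3 <= maxDist && d3 < d4) "three_ten"
               else if (d4 <= maxDist && d4 <= d3) "alpha"
               else "other"
      }
    }
    data.frame(chain = paste(chains, collapse = ","), resid = r,
               label = lbl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
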