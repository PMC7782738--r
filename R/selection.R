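# Atom selection mini-grammar.
#
# Grammar (case-insensitive keywords, whitespace-separated tokens):
#   expr    := term ('or' term)*
#   term    := factor ('and' factor)*
#   factor  := 'not' factor | '(' expr ')' | primitive
#   primitive :=
#     'name'    value+          atom names, e.g. name CA CB
#     'resname' value+          residue names, e.g. resname HOH TIP3
#     'chain'   value+          chain identifiers
#     'element' value+  (or 'elem')
#     'resid'   range+          residue numbers: 410, 410-413, 410:413,
#                               or comma lists 1,3,5
#     'water'                   recognised water residues (HOH, TIP3,
#                               SOL, WAT, TIP; case-insensitive)
#     'protein'                 standard amino-acid residues
#     'ion'                     recognised monatomic-ion residues
#     'all' | 'none'
# Values extend until the next keyword/operator/parenthesis.

.SEL_KEYWORDS <- c("name", "resname", "chain", "element", "elem", "resid",
                   "water", "protein", "ion", "all", "none", "and", "or",
                   "not", "(", ")")

.tokenizeSpec <- function(spec) {
  spec <- gsub("([()])", " \\1 ", spec)
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.parseResidValues <- function(values, pos) {
  out <- integer(0)
  for (v in values) {
    for (piece in strsplit(v, ",", fixed = TRUE)[[1]]) {
      m <- regmatches(piece, regexec("^([0-9]+)[-:]([0-9]+)$", piece))[[1]]
      if (length(m) == 3) {
        out <- c(out, seq(as.integer(m[2]), as.integer(m[3])))
      } else if (grepl("^-?[0-9]+$", piece)) {
        out <- c(out, as.integer(piece))
      } else {
        stop(sprintf("selection parse error at token %d: invalid residue range '%s'",
                     pos, piece), call. = FALSE)
      }
    }
  }
  out
}

# Recursive-descent parser; evaluates directly to a logical atom mask.
.parseSelection <- function(tokens, atoms) {
  i <- 0L
  n <- length(tokens)
  peek <- function() if (i < n) tolower(tokens[i + 1L]) else NA_character_
  advance <- function() {
    i <<- i + 1L
    tokens[i]
  }
  fail <- function(msg) {
    stop(sprintf("selection parse error at token %d ('%s'): %s",
                 i, if (i >= 1 && i <= n) tokens[i] else "<end>", msg),
         call. = FALSE)
  }
  takeValues <- function() {
    vals <- character(0)
    while (!is.na(peek()) && !(peek() %in% .SEL_KEYWORDS)) vals <- c(vals, advance())
    if (!length(vals)) fail("expected at least one value")
    vals
  }
  parsePrimitive <- function() {
    kw <- tolower(advance())
    switch(kw,
      name = atoms$name %in% takeValues(),
      resname = toupper(atoms$resname) %in% toupper(takeValues()),
      chain = atoms$chain %in% takeValues(),
      element = , elem = toupper(atoms$element) %in% toupper(takeValues()),
      resid = atoms$resid %in% .parseResidValues(takeValues(), i),
      water = .isWaterResname(atoms$resname),
      protein = toupper(atoms$resname) %in% .AA_RESNAMES,
      ion = toupper(atoms$resname) %in% .ION_RESNAMES,
      all = rep(TRUE, nrow(atoms)),
      none = rep(FALSE, nrow(atoms)),
      fail("expected a selection keyword"))
  }
  parseFactor <- function() {
    p <- peek()
    if (is.na(p)) fail("unexpected end of expression")
    if (p == "not") {
      advance()
      return(!parseFactor())
    }
    if (p == "(") {
      advance()
      v <- parseExpr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(v)
    }
    parsePrimitive()
  }
  parseTerm <- function() {
    v <- parseFactor()
    while (!is.na(peek()) && peek() == "and") {
      advance()
      v <- v & parseFactor()
    }
    v
  }
  parseExpr <- function() {
    v <- parseTerm()
    while (!is.na(peek()) && peek() == "or") {
      advance()
      v <- v | parseTerm()
    }
    v
  }
  mask <- parseExpr()
  if (i != n) fail("trailing tokens after complete expression")
  mask
}

#' Resolve an atom selection expression
#'
#' Evaluates the package's selection mini-grammar (see
#' \code{?selectAtoms} details) against a system's atom table and returns
#' the matching indices in topology order. An empty selection is legal.
#'
#' @param system \code{MolecularSystem} (or \code{FrameEnsemble}, whose
#'   topology is used).
#' @param spec selection expression string, e.g.
#'   \code{"name CA and resid 410-413"}; or an \code{AtomSelection},
#'   returned unchanged after a range check.
#' @return An \code{AtomSelection}.
#' @examples
#' sys <- newMolecularSystem(data.frame(
#'   name = "CA", resname = "ALA", resid = 410:413, chain = "A",
#'   x = 0, y = 0, z = 0))
#' length(selectAtoms(sys, "name CA and resid 410-413")@indices)
#' @export
selectAtoms <- function(system, spec) {
  if (is(system, "FrameEnsemble")) system <- system@topology
  stopifnot(is(system, "MolecularSystem"))
  if (is(spec, "AtomSelection")) {
    if (length(spec@indices) && max(spec@indices) > nAtoms(system))
      stop("selection indices out of range for this topology")
    return(spec)
  }
  tokens <- .tokenizeSpec(spec)
  if (!length(tokens)) stop("empty selection expression")
  mask <- .parseSelection(tokens, system@atoms)
  new("AtomSelection", indices = which(mask), spec = as.character(spec))
}
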