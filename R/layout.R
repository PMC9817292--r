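# Token <-> substructure correspondence: depiction layout, matched
# parentheses/brackets, ring-closure pairing, and the four hover semantics
# (atom, ring, group, branch) resolved into explicit HighlightSets.

#' Build the 2-D depiction layout for a SMILES string
#'
#' Parses the SMILES with the cheminformatics toolkit and returns heavy-atom
#' coordinates, bonds and rings. Atom i corresponds to the i-th ATOM token
#' of the string as written (the toolkit reads SMILES atoms in string
#' order). Rings are the smallest cycles through each ring bond, perceived
#' on the bond graph.
#'
#' @param smiles a single, valid SMILES string.
#' @return an [AtomLayout-class] object.
#' @examples
#' layout <- buildAtomLayout("C1CC1")
#' atomRings(layout)  # one ring: atoms 1, 2, 3
#' @export
buildAtomLayout <- function(smiles) {
  seq <- tokenizeSmiles(smiles)
  checkStructure(seq)
  mol <- obParseSmiles(smiles)
  if (mol$natoms != nAtoms(seq))
    stop("atom-count mismatch between lexer (", nAtoms(seq),
         ") and toolkit (", mol$natoms, ") for '", smiles, "'", call. = FALSE)
  new("AtomLayout", smiles = smiles, coords = mol$coords,
      bonds = mol$bonds, rings = .perceiveRings(mol$natoms, mol$bonds))
}

.bondGraph <- function(natoms, bonds) {
  g <- igraph::make_empty_graph(natoms, directed = FALSE)
  if (nrow(bonds))
    g <- igraph::add_edges(g, as.vector(t(bonds[, 1:2, drop = FALSE])))
  g
}

# smallest cycle through the bond (a, b): shortest a->b path after removing
# the edge; among equally short paths the one with the lowest atom-index sum
.smallestRingThroughBond <- function(g, a, b) {
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g2, from = a, to = b)$vpaths)
  if (!length(sp)) return(NULL)
  paths <- lapply(sp, as.integer)
  sums <- vapply(paths, sum, numeric(1))
  sort(paths[[which.min(sums)]])
}

.perceiveRings <- function(natoms, bonds) {
  if (!nrow(bonds)) return(list())
  g <- .bondGraph(natoms, bonds)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(bonds))) {
    r <- .smallestRingThroughBond(g, bonds[k, 1], bonds[k, 2])
    if (is.null(r)) next
    key <- paste(r, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- r
    }
  }
  rings
}

#' @describeIn AtomLayout-class source SMILES string.
#' @param x,object an \code{AtomLayout} object.
#' @export
setMethod("smiles", "AtomLayout", function(x) x@smiles)

#' @describeIn AtomLayout-class number of heavy atoms.
#' @export
setMethod("nAtoms", "AtomLayout", function(x) nrow(x@coords))

#' @describeIn AtomLayout-class n x 2 coordinate matrix (depiction units).
#' @export
setMethod("atomCoords", "AtomLayout", function(x) x@coords)

#' @describeIn AtomLayout-class bond matrix (from, to, order).
#' @export
setMethod("atomBonds", "AtomLayout", function(x) x@bonds)

#' @describeIn AtomLayout-class list of perceived ring atom sets.
#' @export
setMethod("atomRings", "AtomLayout", function(x) x@rings)

#' @describeIn AtomLayout-class compact display.
#' @export
setMethod("show", "AtomLayout", function(object) {
  cat(class(object), "for \"", object@smiles, "\":", nAtoms(object), "atoms,",
      nrow(object@bonds), "bonds,", length(object@rings), "rings\n")
})

.structError <- function(what, pos) {
  stop("structural error: ", what, " at token position ", pos, call. = FALSE)
}

# matched-pair tables for one token sequence: branch partner, bracket span,
# ring partner, and the attachment atom current before each token
.structTables <- function(seq) {
  tk <- seq@tokens
  nt <- nrow(tk)
  branchPartner <- rep(NA_integer_, nt)
  bracketOf <- rep(NA_integer_, nt)   # index of the BRACKET_OPEN covering token
  ringPartner <- rep(NA_integer_, nt)
  attachBefore <- rep(NA_integer_, nt)
  stack <- integer(0)
  openBracket <- NA_integer_
  ringOpen <- list()
  cur <- NA_integer_
  curStack <- integer(0)
  for (i in seq_len(nt)) {
    attachBefore[i] <- cur
    kind <- tk$kind[i]
    if (kind == "BRANCH_OPEN") {
      stack <- c(stack, i)
      curStack <- c(curStack, cur)
    } else if (kind == "BRANCH_CLOSE") {
      if (!length(stack)) .structError("unmatched ')'", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      branchPartner[i] <- j; branchPartner[j] <- i
      cur <- curStack[length(curStack)]
      curStack <- curStack[-length(curStack)]
    } else if (kind == "BRACKET_OPEN") {
      if (!is.na(openBracket)) .structError("nested '['", i)
      openBracket <- i
    } else if (kind == "BRACKET_CLOSE") {
      if (is.na(openBracket)) .structError("unmatched ']'", i)
      bracketOf[openBracket:i] <- openBracket
      openBracket <- NA_integer_
    } else if (kind == "RING_BOND") {
      lab <- sub("^%", "", tk$text[i])
      lab <- as.character(as.integer(lab))
      if (is.null(ringOpen[[lab]])) {
        ringOpen[[lab]] <- i
      } else {
        j <- ringOpen[[lab]]
        ringPartner[i] <- j; ringPartner[j] <- i
        ringOpen[[lab]] <- NULL
      }
    } else if (kind == "ATOM") {
      cur <- tk$atomIndex[i]
    } else if (kind == "DOT") {
      cur <- NA_integer_
    }
  }
  if (length(stack)) .structError("unmatched '('", stack[length(stack)])
  if (!is.na(openBracket)) .structError("unmatched '['", openBracket)
  open <- unlist(ringOpen, use.names = FALSE)
  if (length(open)) .structError("unpaired ring-closure digit", open[1])
  list(branchPartner = branchPartner, bracketOf = bracketOf,
       ringPartner = ringPartner, attachBefore = attachBefore)
}

#' Check bracket/parenthesis/ring-digit pairing of a tokenized SMILES
#'
#' Raises a structural error (naming the offending token position) on
#' unmatched parentheses, unmatched brackets or unpaired ring-closure
#' digits; returns the sequence invisibly when sound. The lexer itself is
#' intentionally lenient about balance, so callers that need a
#' structurally sound string run this check.
#'
#' @param seq a [SmilesTokens-class] object.
#' @return \code{seq}, invisibly.
#' @export
checkStructure <- function(seq) {
  stopifnot(is(seq, "SmilesTokens"))
  .structTables(seq)
  invisible(seq)
}

.highlight <- function(kind, tokens, atoms) {
  new("HighlightSet", kind = kind,
      tokenIndices = as.integer(sort(unique(tokens))),
      atomIndices = as.integer(sort(unique(atoms[!is.na(atoms)]))))
}

#' Resolve the hover semantics of one token
#'
#' Maps a hovered token to the tokens and atoms that light up, following
#' the four interaction semantics of the coordinated view: an atom token
#' highlights its atom; a parenthesis highlights the whole branch (matched
#' by nesting, nested branches included); a bracket token, or any token
#' inside a bracket group, highlights the group and its single atom; a
#' ring-closure digit highlights both partner digits and the smallest
#' perceived ring through the closure bond. Bond tokens highlight the two
#' atoms they join; a dot highlights only itself (it denotes a
#' disconnection, not a bond).
#'
#' @param seq a [SmilesTokens-class] object.
#' @param layout the matching [AtomLayout-class].
#' @param tokenIndex token position to resolve (1-based).
#' @return a [HighlightSet-class].
#' @examples
#' seq <- tokenizeSmiles("CC(C)O")
#' layout <- buildAtomLayout("CC(C)O")
#' resolveHover(seq, layout, 3L)  # the "(" -> branch "(C)", atom 3
#' @export
resolveHover <- function(seq, layout, tokenIndex) {
  stopifnot(is(seq, "SmilesTokens"), is(layout, "AtomLayout"))
  tk <- seq@tokens
  nt <- nrow(tk)
  tokenIndex <- as.integer(tokenIndex)
  if (length(tokenIndex) != 1L || is.na(tokenIndex) ||
      tokenIndex < 1L || tokenIndex > nt)
    stop("'tokenIndex' out of range (1..", nt, ")", call. = FALSE)
  st <- .structTables(seq)
  kind <- tk$kind[tokenIndex]

  br <- st$bracketOf[tokenIndex]
  if (!is.na(br)) {
    span <- br:(br + which(tk$kind[br:nt] == "BRACKET_CLOSE")[1] - 1L)
    atom <- tk$atomIndex[span][!is.na(tk$atomIndex[span])]
    return(.highlight("GROUP", span, atom))
  }
  if (kind == "ATOM")
    return(.highlight("ATOM", tokenIndex, tk$atomIndex[tokenIndex]))
  if (kind %in% c("BRANCH_OPEN", "BRANCH_CLOSE")) {
    p <- st$branchPartner[tokenIndex]
    if (is.na(p)) .structError("unmatched parenthesis", tokenIndex)
    span <- min(tokenIndex, p):max(tokenIndex, p)
    return(.highlight("BRANCH", span, tk$atomIndex[span]))
  }
  if (kind == "RING_BOND") {
    p <- st$ringPartner[tokenIndex]
    if (is.na(p)) .structError("unpaired ring-closure digit", tokenIndex)
    a1 <- st$attachBefore[min(tokenIndex, p)]
    a2 <- st$attachBefore[max(tokenIndex, p)]
    ring <- NULL
    if (!is.na(a1) && !is.na(a2) && nrow(layout@bonds))
      ring <- .smallestRingThroughBond(.bondGraph(nAtoms(layout), layout@bonds),
                                       a1, a2)
    if (is.null(ring)) ring <- c(a1, a2)
    return(.highlight("RING", c(tokenIndex, p), ring))
  }
  if (kind == "DOT")
    return(.highlight("BOND", tokenIndex, integer(0)))
  # BOND: joins the current attachment atom and the next atom (or the ring
  # partner's attachment atom when the bond decorates a ring closure)
  a1 <- st$attachBefore[tokenIndex]
  a2 <- NA_integer_
  j <- tokenIndex + 1L
  while (j <= nt) {
    if (tk$kind[j] == "ATOM") { a2 <- tk$atomIndex[j]; break }
    if (tk$kind[j] == "RING_BOND") {
      p <- st$ringPartner[j]
      if (is.na(p)) .structError("unpaired ring-closure digit", j)
      a2 <- st$attachBefore[min(j, p)]
      break
    }
    if (!tk$kind[j] %in% c("BOND", "BRANCH_OPEN")) break
    j <- j + 1L
  }
  .highlight("BOND", tokenIndex, c(a1, a2))
}

#' Resolve the hover semantics of one atom
#'
#' Inverse of [resolveHover()] for atom tokens: hovering atom k on the
#' diagram highlights the single ATOM token bound to it.
#'
#' @param seq a [SmilesTokens-class] object.
#' @param atomIndex atom index (1-based, 1..nAtoms).
#' @return a [HighlightSet-class] with one token and one atom.
#' @export
resolveAtomHover <- function(seq, atomIndex) {
  stopifnot(is(seq, "SmilesTokens"))
  atomIndex <- as.integer(atomIndex)
  na <- nAtoms(seq)
  if (length(atomIndex) != 1L || is.na(atomIndex) ||
      atomIndex < 1L || atomIndex > na)
    stop("'atomIndex' out of range (1..", na, ")", call. = FALSE)
  pos <- which(seq@tokens$atomIndex == atomIndex)
  .highlight("ATOM", pos, atomIndex)
}

#' Export the complete hover map of a molecule
#'
#' Resolves every token and every atom of a tokenized SMILES into the table
#' that drives the static hover behavior of rendered panels: one entry per
#' token (its [HighlightSet-class] as a plain list) and one entry per atom
#' (the position of its ATOM token). Structural errors in the string
#' propagate.
#'
#' @param seq a [SmilesTokens-class] object.
#' @param layout the matching [AtomLayout-class].
#' @return list with elements \code{tokens} (list of per-token highlight
#'   entries with fields \code{kind}, \code{tokens}, \code{atoms}) and
#'   \code{atoms} (integer vector mapping atom index to token position).
#'   All indices 1-based.
#' @export
exportHoverMap <- function(seq, layout) {
  stopifnot(is(seq, "SmilesTokens"), is(layout, "AtomLayout"))
  checkStructure(seq)
  tokenEntries <- lapply(seq_len(nTokens(seq)), function(i) {
    h <- resolveHover(seq, layout, i)
    list(kind = h@kind, tokens = h@tokenIndices, atoms = h@atomIndices)
  })
  atomMap <- vapply(seq_len(nAtoms(seq)),
                    function(a) resolveAtomHover(seq, a)@tokenIndices[1],
                    integer(1))
  list(tokens = tokenEntries, atoms = atomMap)
}

#' @describeIn HighlightSet-class the highlight kind.
#' @param x,object a \code{HighlightSet} object.
#' @export
setMethod("highlightKind", "HighlightSet", function(x) x@kind)

#' @describeIn HighlightSet-class highlighted token positions.
#' @export
setMethod("tokenIndices", "HighlightSet", function(x) x@tokenIndices)

#' @describeIn HighlightSet-class highlighted atom indices.
#' @export
setMethod("atomIndices", "HighlightSet", function(x) x@atomIndices)

#' @describeIn HighlightSet-class compact display.
#' @export
setMethod("show", "HighlightSet", function(object) {
  cat(class(object), object@kind,
      "tokens {", paste(object@tokenIndices, collapse = ","), "}",
      "atoms {", paste(object@atomIndices, collapse = ","), "}\n")
})
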