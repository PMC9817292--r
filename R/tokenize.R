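# SMILES lexer. The grammar is a declared convention (the formats in the
# wild never pin one down exactly): outside brackets the organic subset
# plus two-character halogens; inside a bracket group exactly one ATOM
# token (element or aromatic symbol), with isotope digits, chirality marks,
# H-counts and charges lexed as separate non-atom tokens so that the count
# of ATOM tokens always equals the molecule's heavy-atom count.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

.ORGANIC_SINGLE <- c("B", "C", "N", "O", "P", "S", "F", "I",
                     "b", "c", "n", "o", "p", "s", "*")
.AROMATIC_BRACKET <- c("b", "c", "n", "o", "p", "s", "se", "as")
.BOND_CHARS <- c("-", "=", "#", "$", ":", "/", "\\")

.lexError <- function(smiles, ch, pos) {
  stop("unrecognizable character '", ch, "' at position ", pos,
       " in SMILES '", smiles, "'", call. = FALSE)
}

.newTokenTable <- function() {
  data.frame(text = character(0), kind = character(0),
             charStart = integer(0), charEnd = integer(0),
             atomIndex = integer(0), stringsAsFactors = FALSE)
}

#' Tokenize a SMILES string
#'
#' Lexes a SMILES string into typed tokens, losslessly: concatenating the
#' token texts reproduces the input. Two-character organic-subset halogens
#' (\code{Cl}, \code{Br}) are single ATOM tokens; a bracket group such as
#' \code{[13CH3+]} yields one ATOM token (\code{C}) plus separate
#' \code{ISOTOPE}, \code{HCOUNT} and \code{CHARGE} tokens; ring-closure
#' digits and \code{\%nn} pairs are \code{RING_BOND} tokens; a charge group
#' (\code{+}, \code{-}, \code{+2}, \code{++}) is one \code{CHARGE} token.
#' As a consequence the number of ATOM tokens equals the heavy-atom count
#' of the molecule, which is what lets per-atom score vectors be spread
#' onto tokens (see [attachScores()]).
#'
#' The string is lexed exactly as given and never re-canonicalized
#' (re-canonicalizing would desynchronize any score vector bound to it).
#'
#' @param smiles a single SMILES string. The empty string yields an empty
#'   token sequence.
#' @return a [SmilesTokens-class] object.
#' @examples
#' tokenTable(tokenizeSmiles("[N+]"))   # 1 atom token, 3 non-atom tokens
#' tokenTable(tokenizeSmiles("C1CC1"))  # ring-closure digits as RING_BOND
#' @export
tokenizeSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("'smiles' must be a single string", call. = FALSE)
  n <- nchar(smiles)
  if (n == 0L)
    return(new("SmilesTokens", smiles = "", tokens = .newTokenTable()))
  ch <- strsplit(smiles, "", fixed = FALSE)[[1]]
  texts <- character(0); kinds <- character(0)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  inBracket <- FALSE
  bracketHasAtom <- FALSE
  emit <- function(text, kind) {
    texts[length(texts) + 1L] <<- text
    kinds[length(kinds) + 1L] <<- kind
    starts[length(starts) + 1L] <<- i
    ends[length(ends) + 1L] <<- i + nchar(text) - 1L
    i <<- i + nchar(text)
  }
  digitsFrom <- function(j) {
    k <- j
    while (k <= n && grepl("^[0-9]$", ch[k])) k <- k + 1L
    if (k == j) "" else paste(ch[j:(k - 1L)], collapse = "")
  }
  while (i <= n) {
    c1 <- ch[i]
    if (inBracket) {
      if (c1 == "]") {
        if (!bracketHasAtom) .lexError(smiles, c1, i)
        emit("]", "BRACKET_CLOSE"); inBracket <- FALSE
      } else if (!bracketHasAtom && grepl("^[0-9]$", c1)) {
        emit(digitsFrom(i), "ISOTOPE")
      } else if (!bracketHasAtom) {
        # the one atom of the group: element symbol, aromatic symbol or *
        two <- if (i < n) paste0(c1, ch[i + 1L]) else ""
        if (c1 == "*") {
          emit("*", "ATOM")
        } else if (nzchar(two) && two %in% .AROMATIC_BRACKET) {
          emit(two, "ATOM")
        } else if (c1 %in% .AROMATIC_BRACKET) {
          emit(c1, "ATOM")
        } else if (nzchar(two) && grepl("^[A-Z][a-z]$", two) &&
                   two %in% .ELEMENTS) {
          emit(two, "ATOM")
        } else if (grepl("^[A-Z]$", c1) && c1 %in% .ELEMENTS) {
          emit(c1, "ATOM")
        } else .lexError(smiles, c1, i)
        bracketHasAtom <- TRUE
      } else if (c1 == "H") {
        emit(paste0("H", digitsFrom(i + 1L)), "HCOUNT")
      } else if (c1 == "@") {
        if (i < n && ch[i + 1L] == "@") emit("@@", "CHIRALITY")
        else emit("@", "CHIRALITY")
      } else if (c1 %in% c("+", "-")) {
        j <- i + 1L
        while (j <= n && ch[j] == c1) j <- j + 1L
        sign <- paste(rep(c1, j - i), collapse = "")
        emit(paste0(sign, if (j - i == 1L) digitsFrom(j) else ""), "CHARGE")
      } else .lexError(smiles, c1, i)
    } else {
      two <- if (i < n) paste0(c1, ch[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        emit(two, "ATOM")
      } else if (c1 %in% .ORGANIC_SINGLE) {
        emit(c1, "ATOM")
      } else if (grepl("^[0-9]$", c1)) {
        emit(c1, "RING_BOND")
      } else if (c1 == "%") {
        if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(ch[i + 1L], ch[i + 2L])))
          .lexError(smiles, c1, i)
        emit(paste0("%", ch[i + 1L], ch[i + 2L]), "RING_BOND")
      } else if (c1 == "(") {
        emit("(", "BRANCH_OPEN")
      } else if (c1 == ")") {
        emit(")", "BRANCH_CLOSE")
      } else if (c1 == "[") {
        emit("[", "BRACKET_OPEN"); inBracket <- TRUE; bracketHasAtom <- FALSE
      } else if (c1 %in% .BOND_CHARS) {
        emit(c1, "BOND")
      } else if (c1 == ".") {
        emit(".", "DOT")
      } else .lexError(smiles, c1, i)
    }
  }
  atomIndex <- rep(NA_integer_, length(kinds))
  atomIndex[kinds == "ATOM"] <- seq_len(sum(kinds == "ATOM"))
  tk <- data.frame(text = texts, kind = kinds, charStart = starts,
                   charEnd = ends, atomIndex = atomIndex,
                   stringsAsFactors = FALSE)
  new("SmilesTokens", smiles = smiles, tokens = tk)
}

#' Positions of atom tokens
#'
#' Token positions (1-based) of the ATOM tokens of a tokenized SMILES, in
#' order of appearance. Its length equals the molecule's heavy-atom count;
#' element k is the token carrying atom k.
#'
#' @param seq a [SmilesTokens-class] object.
#' @return integer vector of token positions.
#' @examples
#' atomTokenPositions(tokenizeSmiles("C1CC1"))  # 1, 3, 4
#' @export
atomTokenPositions <- function(seq) {
  stopifnot(is(seq, "SmilesTokens"))
  which(seq@tokens$kind == "ATOM")
}

#' @describeIn SmilesTokens-class source SMILES string.
#' @param x,object a \code{SmilesTokens} object.
#' @export
setMethod("smiles", "SmilesTokens", function(x) x@smiles)

#' @describeIn SmilesTokens-class the token table (one row per token).
#' @export
setMethod("tokenTable", "SmilesTokens", function(x) x@tokens)

#' @describeIn SmilesTokens-class number of tokens.
#' @export
setMethod("nTokens", "SmilesTokens", function(x) nrow(x@tokens))

#' @describeIn SmilesTokens-class number of ATOM tokens (= heavy atoms).
#' @export
setMethod("nAtoms", "SmilesTokens", function(x) sum(x@tokens$kind == "ATOM"))

#' @describeIn SmilesTokens-class compact display.
#' @export
setMethod("show", "SmilesTokens", function(object) {
  cat(class(object), "of", nTokens(object), "tokens (", nAtoms(object),
      "atoms ) for \"", smiles(object), "\"\n")
  if (nTokens(object)) {
    kinds <- table(object@tokens$kind)
    cat("  kinds:", paste0(names(kinds), "=", kinds, collapse = " "), "\n")
  }
})
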