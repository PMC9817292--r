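# Central S4 containers. Token positions and atom indices are 1-based
# throughout, as usual in R.

.TOKEN_KINDS <- c("ATOM", "BOND", "RING_BOND", "BRANCH_OPEN", "BRANCH_CLOSE",
                  "BRACKET_OPEN", "BRACKET_CLOSE", "ISOTOPE", "CHIRALITY",
                  "HCOUNT", "CHARGE", "DOT")

#' Tokenized SMILES string
#'
#' Ordered, lossless lexical decomposition of one SMILES string. The token
#' table has columns \code{text}, \code{kind} (one of \code{ATOM},
#' \code{BOND}, \code{RING_BOND}, \code{BRANCH_OPEN}, \code{BRANCH_CLOSE},
#' \code{BRACKET_OPEN}, \code{BRACKET_CLOSE}, \code{ISOTOPE},
#' \code{CHIRALITY}, \code{HCOUNT}, \code{CHARGE}, \code{DOT}),
#' \code{charStart}/\code{charEnd} (1-based inclusive character span) and
#' \code{atomIndex} (1-based, \code{NA} for non-atom tokens). Concatenating
#' the \code{text} column reproduces the input string exactly, and the
#' number of \code{ATOM} tokens equals the heavy-atom count of the parsed
#' molecule, so per-atom score vectors align with atom tokens by position.
#'
#' @slot smiles the source SMILES string.
#' @slot tokens the token table described above.
#' @seealso [tokenizeSmiles()]
#' @export
setClass("SmilesTokens",
         representation(smiles = "character", tokens = "data.frame"))

setValidity("SmilesTokens", function(object) {
  tk <- object@tokens
  msg <- character()
  if (length(object@smiles) != 1L) msg <- c(msg, "'smiles' must be a single string")
  need <- c("text", "kind", "charStart", "charEnd", "atomIndex")
  if (!all(need %in% names(tk))) {
    return(paste("token table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(tk)) {
    if (!all(tk$kind %in% .TOKEN_KINDS)) msg <- c(msg, "unknown token kind")
    if (paste(tk$text, collapse = "") != object@smiles)
      msg <- c(msg, "token texts do not concatenate to the SMILES string")
    ai <- tk$atomIndex[!is.na(tk$atomIndex)]
    if (!identical(as.integer(ai), seq_along(ai)))
      msg <- c(msg, "atom indices must be 1..nAtoms in order of appearance")
    if (any(is.na(tk$atomIndex) & tk$kind == "ATOM") ||
        any(!is.na(tk$atomIndex) & tk$kind != "ATOM"))
      msg <- c(msg, "atomIndex must be present exactly for ATOM tokens")
  }
  if (length(msg)) msg else TRUE
})

#' Scored tokenized SMILES
#'
#' A [SmilesTokens-class] with one attribution score per token. When the
#' input vector was per-atom (\code{scoreMode() == "PER_ATOM"}), scores were
#' spread onto the atom tokens in order and every non-atom token carries
#' exactly 0.
#'
#' @slot scores numeric, one value per token.
#' @slot mode \code{"PER_ATOM"} or \code{"PER_TOKEN"} (length of the raw
#'   vector that was attached).
#' @seealso [attachScores()]
#' @export
setClass("ScoredSmiles", contains = "SmilesTokens",
         representation(scores = "numeric", mode = "character"))

setValidity("ScoredSmiles", function(object) {
  msg <- character()
  if (length(object@scores) != nrow(object@tokens))
    msg <- c(msg, "need exactly one score per token")
  if (!object@mode %in% c("PER_ATOM", "PER_TOKEN"))
    msg <- c(msg, "mode must be PER_ATOM or PER_TOKEN")
  if (identical(object@mode, "PER_ATOM")) {
    off <- object@scores[object@tokens$kind != "ATOM"]
    if (length(off) && any(off != 0))
      msg <- c(msg, "PER_ATOM scores must be 0 on non-atom tokens")
  }
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' 2-D depiction layout of a molecule
#'
#' Heavy-atom coordinates, bonds and rings of the molecule behind a SMILES
#' string, in the toolkit's depiction units. Atom i is the i-th ATOM token
#' of the SMILES as written (the input is never re-canonicalized, otherwise
#' attached score vectors would desynchronize).
#'
#' @slot smiles the source SMILES string.
#' @slot coords n x 2 matrix of atom positions.
#' @slot bonds m x 3 integer matrix: columns \code{from}, \code{to},
#'   \code{order} (1-based atom indices).
#' @slot rings list of integer vectors, each the atom set of a smallest ring
#'   through some ring bond.
#' @seealso [buildAtomLayout()]
#' @export
setClass("AtomLayout",
         representation(smiles = "character", coords = "matrix",
                        bonds = "matrix", rings = "list"))

setValidity("AtomLayout", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (nrow(object@bonds) && (ncol(object@bonds) != 3L ||
      any(object@bonds[, 1:2] < 1L) || any(object@bonds[, 1:2] > n)))
    msg <- c(msg, "bonds must reference valid atom indices")
  if (length(object@rings) &&
      any(vapply(object@rings, function(r) any(r < 1L | r > n), logical(1))))
    msg <- c(msg, "rings must reference valid atom indices")
  if (length(msg)) msg else TRUE
})

#' Resolved substructure highlight
#'
#' The hover semantics of one token (or atom), resolved to explicit data:
#' which tokens light up in the bar chart and which atoms light up on the
#' diagram. Kinds: \code{ATOM} (single atom token), \code{RING} (partner
#' ring-closure digits plus the smallest ring through the closure bond),
#' \code{GROUP} (a bracket-atom span), \code{BRANCH} (a parenthesized span
#' including nested branches), \code{BOND} (a bond or dot token and the
#' atoms it joins).
#'
#' @slot kind one of \code{ATOM}, \code{RING}, \code{GROUP}, \code{BRANCH},
#'   \code{BOND}.
#' @slot tokenIndices integer token positions (1-based).
#' @slot atomIndices integer atom indices (1-based); may be empty for DOT.
#' @seealso [resolveHover()]
#' @export
setClass("HighlightSet",
         representation(kind = "character", tokenIndices = "integer",
                        atomIndices = "integer"))

setValidity("HighlightSet", function(object) {
  msg <- character()
  if (!object@kind %in% c("ATOM", "RING", "GROUP", "BRANCH", "BOND"))
    msg <- c(msg, "unknown highlight kind")
  if (length(object@tokenIndices) == 0L)
    msg <- c(msg, "tokenIndices must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Visual configuration of a panel
#'
#' Palette, colormap domain, threshold list and geometry for one rendered
#' panel. The domain straddles zero; scores outside it clamp to the
#' endpoints (strongest color, full-height bar). Thresholds are fractions
#' of the domain maximum in [0, 1].
#'
#' @slot palette ordered color vector (diverging, odd length, neutral
#'   middle).
#' @slot paletteName name of the built-in palette, or "custom".
#' @slot domain numeric(0) for per-molecule automatic symmetric domain, or
#'   c(min, max) with min < 0 < max (a (min, 0, max) triple is accepted by
#'   the constructor and normalized to the pair).
#' @slot thresholds ascending fractions in [0, 1]; empty means no diagram
#'   highlight and default bar-chart guide lines at 0.5 and 1.
#' @slot showScoreLabels draw numeric per-atom score labels on the diagram.
#' @slot blackAtoms draw atom glyphs black instead of element-colored.
#' @slot geometry named list of drawing-unit constants (see
#'   [panelConfig()]).
#' @seealso [panelConfig()]
#' @export
setClass("PanelConfig",
         representation(palette = "character", paletteName = "character",
                        domain = "numeric", thresholds = "numeric",
                        showScoreLabels = "logical", blackAtoms = "logical",
                        geometry = "list"))

setValidity("PanelConfig", function(object) {
  msg <- character()
  np <- length(object@palette)
  if (np < 3L || np %% 2L == 0L)
    msg <- c(msg, "palette must be diverging: odd length >= 3 (neutral middle)")
  d <- object@domain
  if (length(d) && (length(d) != 2L || !(d[1] < 0 && d[2] > 0)))
    msg <- c(msg, "domain must be c(min, max) with min < 0 < max")
  th <- object@thresholds
  if (length(th) && (any(th < 0 | th > 1) || is.unsorted(th)))
    msg <- c(msg, "thresholds must be ascending fractions in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' One molecule record
#'
#' A SMILES string with its raw attribution-score vector (per-atom or
#' per-token length), optional ordered attribute rows displayed under the
#' bar chart, an optional per-record visual-config override and an id.
#'
#' @slot smiles SMILES string.
#' @slot scores raw numeric score vector (length = atom count or token
#'   count; may be empty for a score-less molecule).
#' @slot attributes named character vector, shown in input order.
#' @slot config named list of [panelConfig()] arguments overriding the
#'   gallery-level configuration for this record.
#' @slot id record identifier (auto-generated from the record index when
#'   absent in the input file).
#' @slot extra unknown input-file fields, preserved on round trip.
#' @seealso [loadRecords()], [makeFixtures()]
#' @export
setClass("SmilesRecord",
         representation(smiles = "character", scores = "numeric",
                        attributes = "character", config = "list",
                        id = "character", extra = "list"))

setValidity("SmilesRecord", function(object) {
  msg <- character()
  if (length(object@smiles) != 1L || !nzchar(object@smiles))
    msg <- c(msg, "'smiles' must be a non-empty string")
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (length(object@attributes) &&
      (is.null(names(object@attributes)) || any(!nzchar(names(object@attributes)))))
    msg <- c(msg, "'attributes' must be a named character vector")
  if (length(msg)) msg else TRUE
})

#' Black-box SMILES predictor
#'
#' Contract used by [substitutionAttribution()]: a deterministic vectorized
#' function from SMILES strings to real predictions (NA marks a rejected,
#' unparseable string) plus a finite token vocabulary used for
#' substitutions.
#'
#' @slot fun function(character vector) -> numeric vector (NA = rejected).
#' @slot vocabulary finite character vector of token texts.
#' @slot name human-readable label.
#' @seealso [smilesPredictor()], [logpPredictor()]
#' @export
setClass("SmilesPredictor",
         representation(fun = "function", vocabulary = "character",
                        name = "character"))

setValidity("SmilesPredictor", function(object) {
  if (length(object@name) != 1L) return("'name' must be a single string")
  TRUE
})
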