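# Cheminformatics toolkit bridges. OpenBabel (via ChemmineOB) is used
# in-process for SMILES parsing/validation, 2-D depiction coordinates and
# molecule-level Wildman-Crippen logP. Per-atom Crippen contributions come
# from RDKit through the system Python (see rdkitCrippenContribs below).
# OpenBabel reads SMILES atoms in string order, so atom i of the parsed
# molecule is the i-th ATOM token -- the alignment every downstream module
# relies on.

.backendCache <- new.env(parent = emptyenv())

.obConvert <- function(from, to, source, options = NULL) {
  ChemmineOB::convertFormat(from, to, source = source, options = options)
}

#' Parse a SMILES string with the cheminformatics toolkit
#'
#' Converts one SMILES to an SDF (V2000) block with generated 2-D
#' coordinates and reads back heavy-atom symbols, coordinates and bonds.
#' Atom order equals the order of ATOM tokens in the input string.
#'
#' @param smiles single SMILES string.
#' @return list with \code{natoms}, \code{symbols}, \code{coords} (n x 2),
#'   \code{bonds} (m x 3: from, to, order).
#' @keywords internal
obParseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  key <- paste0("mol:", smiles)
  hit <- .backendCache[[key]]
  if (!is.null(hit)) return(hit)
  sdf <- tryCatch(
    .obConvert("SMI", "SDF", paste0(smiles, "\n"),
               options = data.frame(names = "gen2D", args = "")),
    error = function(e) stop("SMILES not parseable by the toolkit: '", smiles,
                             "' (", conditionMessage(e), ")", call. = FALSE))
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L)
    stop("SMILES not parseable by the toolkit: '", smiles, "'", call. = FALSE)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || na < 1L)
    stop("SMILES not parseable by the toolkit: '", smiles, "'", call. = FALSE)
  atoml <- lines[4L + seq_len(na)]
  coords <- cbind(x = as.numeric(substr(atoml, 1, 10)),
                  y = as.numeric(substr(atoml, 11, 20)))
  symbols <- trimws(substr(atoml, 32, 34))
  bonds <- matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("from", "to", "order")))
  if (!is.na(nb) && nb > 0L) {
    bondl <- lines[4L + na + seq_len(nb)]
    bonds <- cbind(from = as.integer(substr(bondl, 1, 3)),
                   to = as.integer(substr(bondl, 4, 6)),
                   order = as.integer(substr(bondl, 7, 9)))
  }
  out <- list(natoms = na, symbols = symbols, coords = coords, bonds = bonds)
  assign(key, out, envir = .backendCache)
  out
}

#' Wildman-Crippen logP for a vector of SMILES
#'
#' Molecule-level logP from the toolkit's Wildman-Crippen model, vectorized.
#' Unparseable strings yield NA. Conversion is batched; because a batch
#' aborts at the first invalid entry, the remainder is resubmitted until
#' every input is accounted for.
#'
#' @param smiles character vector.
#' @return numeric vector, NA where the toolkit rejected the string.
#' @keywords internal
obLogP <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(numeric(0))
  res <- rep(NA_real_, n)
  bad <- !nzchar(smiles) | is.na(smiles)
  todo <- which(!bad)
  while (length(todo)) {
    inp <- paste0(smiles[todo], " t", todo, collapse = "\n")
    out <- tryCatch(
      .obConvert("SMI", "TXT", paste0(inp, "\n"),
                 options = data.frame(names = "append", args = "logP")),
      error = function(e) "")
    got <- integer(0)
    if (nzchar(out)) {
      ln <- strsplit(out, "\n", fixed = TRUE)[[1]]
      ln <- ln[grepl("^t[0-9]+[ \t]", ln)]
      if (length(ln)) {
        parts <- strsplit(ln, "[ \t]+")
        got <- as.integer(sub("^t", "", vapply(parts, `[`, "", 1L)))
        vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
        res[got] <- vals
      }
    }
    left <- todo[!todo %in% got]
    if (!length(left)) break
    # first unaccounted entry failed to parse; everything after it was
    # never attempted -- drop the failure, resubmit the rest
    todo <- left[-1L]
  }
  res
}

.pythonBin <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin))
    stop("no Python interpreter with RDKit found on PATH ",
         "(needed for per-atom Crippen contributions)", call. = FALSE)
  bin
}

.crippenPy <- '
import sys, json
from rdkit import Chem
from rdkit.Chem import rdMolDescriptors
from rdkit import RDLogger
RDLogger.DisableLog("rdApp.*")
out = []
with open(sys.argv[1]) as fh:
    for line in fh:
        s = line.rstrip("\\n")
        m = Chem.MolFromSmiles(s)
        if m is None:
            out.append(None)
            continue
        mh = Chem.AddHs(m)
        contribs = [c[0] for c in rdMolDescriptors._CalcCrippenContribs(mh)]
        res = [0.0] * m.GetNumAtoms()
        for a in mh.GetAtoms():
            i = a.GetIdx()
            if i < m.GetNumAtoms():
                res[i] += contribs[i]
            else:
                res[a.GetNeighbors()[0].GetIdx()] += contribs[i]
        out.append(res)
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'

#' Per-atom Wildman-Crippen logP contributions (RDKit)
#'
#' Batched call into the system RDKit. Hydrogen contributions are folded
#' into their heavy-atom neighbour, so each vector sums to the whole-
#' molecule Crippen logP. Values are in heavy-atom (= ATOM-token) order.
#'
#' @param smiles character vector.
#' @return list of numeric vectors; NULL elements mark rejected strings.
#' @keywords internal
rdkitCrippenContribs <- function(smiles) {
  if (!length(smiles)) return(list())
  py <- .pythonBin()
  script <- tempfile(fileext = ".py")
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(script, fin, fout)), add = TRUE)
  writeLines(.crippenPy, script)
  writeLines(smiles, fin)
  status <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout))
    stop("RDKit Crippen-contribution call failed (exit ", status, ")",
         call. = FALSE)
  out <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  lapply(out, function(x) if (is.null(x)) NULL else as.numeric(unlist(x)))
}
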