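# Attribution-score generation: the token-substitution sensitivity score
# for black-box SMILES predictors, per-atom Wildman-Crippen logP
# contributions as a ground-truth-style comparator, and the deterministic
# fixture generator built on both.

#' Construct a black-box SMILES predictor
#'
#' Wraps a prediction function and a token vocabulary into the contract
#' used by [substitutionAttribution()]. The function must be vectorized
#' over SMILES strings, deterministic, and return \code{NA} for strings it
#' rejects.
#'
#' @param fun function(character vector) -> numeric vector.
#' @param vocabulary non-empty character vector of token texts that may be
#'   substituted into a SMILES string.
#' @param name label used in attribute tables.
#' @return a [SmilesPredictor-class].
#' @export
smilesPredictor <- function(fun, vocabulary, name = "predictor") {
  new("SmilesPredictor", fun = fun, vocabulary = as.character(vocabulary),
      name = name)
}

#' Bundled toy predictor: Wildman-Crippen logP
#'
#' A deterministic, structure-symmetric predictor -- the toolkit's
#' molecule-level Wildman-Crippen logP of the input string -- bundled so
#' that realistic substitution attributions can be generated without any
#' trained model. Its default vocabulary is the uppercase organic-subset
#' atom tokens: substituting structural tokens (digits, parentheses,
#' brackets) almost always yields an unparseable string that the skip
#' policy drops anyway, so atom substitutions carry all the signal.
#'
#' @param vocabulary substitution vocabulary; defaults to the organic
#'   subset atoms.
#' @return a [SmilesPredictor-class].
#' @export
logpPredictor <- function(vocabulary = c("B", "C", "N", "O", "P", "S",
                                         "F", "Cl", "Br", "I")) {
  smilesPredictor(obLogP, vocabulary, name = "WildmanCrippenLogP")
}

#' Token-substitution sensitivity scores
#'
#' The occlusion-style attribution of one token is the difference between
#' the prediction for the original SMILES and the mean prediction over all
#' strings obtained by replacing that token's text with each vocabulary
#' entry (the original text is substituted too when it is in the
#' vocabulary). Substituted strings the predictor rejects are excluded
#' from the mean; if every substitution at a position is rejected the
#' token's score is 0 and a warning is logged. A positive score means the
#' prediction is expected to drop when the token is replaced.
#'
#' @param predictor a [SmilesPredictor-class].
#' @param smiles a single SMILES string accepted by the predictor.
#' @return a [ScoredSmiles-class] with one sensitivity score per token.
#' @examples
#' \donttest{
#' sc <- substitutionAttribution(logpPredictor(), "CCO")
#' scores(sc)
#' }
#' @export
substitutionAttribution <- function(predictor, smiles) {
  stopifnot(is(predictor, "SmilesPredictor"))
  vocab <- predictor@vocabulary
  if (!length(vocab))
    stop("the substitution vocabulary is empty", call. = FALSE)
  seq <- tokenizeSmiles(smiles)
  nt <- nTokens(seq)
  if (!nt) stop("cannot attribute an empty SMILES string", call. = FALSE)
  f0 <- predictor@fun(smiles)
  if (is.na(f0))
    stop("the predictor rejects the original SMILES '", smiles, "'",
         call. = FALSE)
  tk <- tokenTable(seq)
  # all candidate strings, then one deduplicated predictor call
  cand <- vector("list", nt)
  for (i in seq_len(nt)) {
    pre <- substr(smiles, 1, tk$charStart[i] - 1L)
    post <- substr(smiles, tk$charEnd[i] + 1L, nchar(smiles))
    cand[[i]] <- paste0(pre, vocab, post)
  }
  all <- unique(unlist(cand))
  pred <- predictor@fun(all)
  names(pred) <- all
  dropped <- 0L
  scoresOut <- vapply(cand, function(cs) {
    p <- pred[cs]
    p <- p[!is.na(p)]
    if (!length(p)) { dropped <<- dropped + 1L; return(0) }
    f0 - mean(p)
  }, numeric(1))
  if (dropped > 0L)
    warning(dropped, " token position(s) had every substitution rejected; ",
            "their scores are 0", call. = FALSE)
  attachScores(seq, scoresOut)
}

#' Per-atom Wildman-Crippen logP contributions
#'
#' The additive atomic decomposition of the Wildman-Crippen logP model, in
#' atom (= ATOM-token) order, with hydrogen contributions folded into
#' their heavy-atom neighbours so that the vector sums to the molecule's
#' Crippen logP. These contributions are the customary ground-truth-style
#' comparator for learned logP attributions.
#'
#' @param smiles a single valid SMILES string.
#' @return numeric vector, one contribution per heavy atom.
#' @examples
#' \donttest{
#' sum(crippenScores("CCO"))  # equals the molecule-level Crippen logP
#' }
#' @export
crippenScores <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- rdkitCrippenContribs(smiles)[[1]]
  if (is.null(out))
    stop("SMILES not parseable for Crippen contributions: '", smiles, "'",
         call. = FALSE)
  out
}

# fixed built-in list of drug-like / feature-covering SMILES used by the
# fixture generator (brackets, rings, fused rings, nested branches,
# charges, isotopes, aromatics, two-letter halogens, stereo bonds)
.FIXTURE_SMILES <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                  # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",             # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",                     # paracetamol
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",             # caffeine
  "NC(=O)c1ccc[nH]1",                       # pyrrole amide
  "Brc1c(Br)c(Br)c(Br)c(Br)c1Br",           # hexabromobenzene
  "C=CCN(CC=C)CC=C",                        # triallylamine
  "OC(=O)CC(O)(CC(=O)O)C(=O)O",             # citric acid
  "C1CCC2(CC1)CCCCC2",                      # spiro ring system
  "c1ccc2ccccc2c1",                         # naphthalene
  "CC(C)(C)OC(=O)N1CCC(CC1)N",              # Boc piperidine
  "OCC1OC(O)C(O)C(O)C1O",                   # glucose (open anomeric)
  "CN1CCC[C@H]1c1cccnc1",                   # nicotine (chiral)
  "C[N+](C)(C)CCO",                         # choline cation
  "[O-]C(=O)c1ccccc1",                      # benzoate anion
  "O=[N+]([O-])c1ccc(Cl)cc1",               # chloronitrobenzene
  "C/C=C/c1ccccc1",                         # trans-propenylbenzene
  "CC(Cl)Br",                               # both two-letter halogens
  "FC(F)(F)c1ccccc1",                       # trifluorotoluene
  "[13CH4]",                                # isotope-labelled methane
  "S=C=S",                                  # carbon disulfide
  "CCOC(=O)c1ccc(N)cc1",                    # benzocaine
  "c1ccsc1",                                # thiophene
  "O=C1CCCCC1",                             # cyclohexanone
  "CC12CCC(CC1)C(C)(C)O2",                  # eucalyptol (bridged)
  "N#Cc1ccccc1")                            # benzonitrile

#' Built-in fixture SMILES list
#'
#' The fixed list of drug-like, feature-covering SMILES strings the
#' fixture generator draws from.
#'
#' @return character vector.
#' @export
fixtureSmiles <- function() .FIXTURE_SMILES

.recordSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2011 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Generate deterministic demonstration records
#'
#' Draws \code{n} molecules (cyclically) from the built-in SMILES list and
#' equips each with attribution scores by the requested method:
#' \code{"crippen"} (per-atom Wildman-Crippen contributions),
#' \code{"substitution"} (token-substitution sensitivity scores against
#' the bundled [logpPredictor()]) or \code{"random"} (seeded standard-
#' normal per-token scores). Records also carry an attribute table naming
#' the method and the molecule-level Crippen logP. Output is fully
#' deterministic for a fixed seed, and record i does not depend on
#' \code{n}, so growing a fixture set keeps its prefix.
#'
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @param method one of \code{"crippen"}, \code{"substitution"},
#'   \code{"random"}.
#' @return list of [SmilesRecord-class] objects.
#' @examples
#' \donttest{
#' recs <- makeFixtures(3, seed = 7, method = "random")
#' }
#' @export
makeFixtures <- function(n, seed = 1L,
                         method = c("crippen", "substitution", "random")) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  smi <- .FIXTURE_SMILES[(seq_len(n) - 1L) %% length(.FIXTURE_SMILES) + 1L]
  logp <- obLogP(smi)
  scoreSets <- switch(method,
    crippen = rdkitCrippenContribs(smi),
    substitution = lapply(smi, function(s)
      scores(substitutionAttribution(logpPredictor(), s))),
    random = lapply(seq_len(n), function(i) {
      nt <- nTokens(tokenizeSmiles(smi[i]))
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(.recordSeed(seed, i))
      stats::rnorm(nt)
    }))
  lapply(seq_len(n), function(i) {
    sc <- scoreSets[[i]]
    if (is.null(sc))
      stop("fixture SMILES rejected by the toolkit: ", smi[i], call. = FALSE)
    new("SmilesRecord", smiles = smi[i], scores = as.numeric(sc),
        attributes = c(method = method,
                       logP = formatC(logp[i], format = "f", digits = 4)),
        config = list(),
        id = sprintf("fix%03d-%s", i, method), extra = list())
  })
}

#' @describeIn SmilesRecord-class the SMILES string.
#' @param x,object a \code{SmilesRecord} object.
#' @export
setMethod("smiles", "SmilesRecord", function(x) x@smiles)

#' @describeIn SmilesRecord-class the raw score vector.
#' @export
setMethod("scores", "SmilesRecord", function(x) x@scores)

#' @describeIn SmilesRecord-class the record id.
#' @export
setMethod("recordId", "SmilesRecord", function(x) x@id)

#' @describeIn SmilesRecord-class the ordered attribute rows.
#' @export
setMethod("recordAttributes", "SmilesRecord", function(x) x@attributes)

#' @describeIn SmilesRecord-class compact display.
#' @export
setMethod("show", "SmilesRecord", function(object) {
  cat(class(object), "'", object@id, "' \"", object@smiles, "\" with ",
      length(object@scores), " scores\n", sep = "")
})
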