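# Score binding, colormap-domain normalization, threshold highlighting and
# diverging-palette color mapping.

#' Attach a raw score vector to a tokenized SMILES
#'
#' A score vector may come in two admissible lengths: one value per atom
#' (the common XAI output for atom-level methods) or one value per token.
#' Per-atom vectors are spread onto the ATOM tokens in order, with 0.0
#' assigned to every non-atom token; per-token vectors map positionally.
#' Any other length is a shape error naming both admissible lengths.
#'
#' @param seq a [SmilesTokens-class] object.
#' @param raw numeric vector of length \code{nAtoms(seq)} or
#'   \code{nTokens(seq)}.
#' @return a [ScoredSmiles-class] object.
#' @examples
#' s <- attachScores(tokenizeSmiles("C1CC1"), c(0.1, 0.2, 0.3))
#' scores(s)  # 0.1 0.0 0.2 0.3 0.0
#' @export
attachScores <- function(seq, raw) {
  stopifnot(is(seq, "SmilesTokens"))
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)))
    stop("scores must be finite numbers", call. = FALSE)
  nt <- nTokens(seq)
  na <- nAtoms(seq)
  if (length(raw) == nt && nt > 0L) {
    mode <- "PER_TOKEN"
    sc <- raw
  } else if (length(raw) == na && na > 0L) {
    mode <- "PER_ATOM"
    sc <- rep(0, nt)
    sc[atomTokenPositions(seq)] <- raw
  } else {
    stop("score vector of length ", length(raw), " cannot be attached to '",
         smiles(seq), "': admissible lengths are ", na, " (per atom) or ",
         nt, " (per token)", call. = FALSE)
  }
  new("ScoredSmiles", seq, scores = sc, mode = mode)
}

#' @describeIn ScoredSmiles-class per-token score vector.
#' @param x,object a \code{ScoredSmiles} object.
#' @export
setMethod("scores", "ScoredSmiles", function(x) x@scores)

#' @describeIn ScoredSmiles-class \code{"PER_ATOM"} or \code{"PER_TOKEN"}.
#' @export
setMethod("scoreMode", "ScoredSmiles", function(x) x@mode)

#' @describeIn ScoredSmiles-class compact display.
#' @export
setMethod("show", "ScoredSmiles", function(object) {
  cat(class(object), "(", object@mode, ") for \"", smiles(object), "\":",
      nTokens(object), "tokens, score range [",
      format(min(object@scores)), ",", format(max(object@scores)), "]\n")
})

.asDomain <- function(domain) {
  domain <- as.numeric(domain)
  if (length(domain) == 3L) {
    if (domain[2] != 0)
      stop("a domain triple must have 0 as its midpoint", call. = FALSE)
    domain <- domain[c(1L, 3L)]
  }
  if (length(domain) != 2L || !is.finite(domain[1]) || !is.finite(domain[2]) ||
      !(domain[1] < 0 && domain[2] > 0))
    stop("colormap domain must be c(min, max) with min < 0 < max",
         call. = FALSE)
  domain
}

#' Default colormap domain for a scored molecule
#'
#' The per-molecule automatic domain is symmetric around zero with its
#' maximum at the largest absolute attribution of the molecule, so the
#' strongest palette colors are reached exactly by the strongest score.
#' When every score is zero there is nothing to scale against and the
#' fallback domain (-1, 1) is returned with a warning.
#'
#' @param scored a [ScoredSmiles-class] object (or a bare numeric vector).
#' @return numeric c(min, max), symmetric.
#' @examples
#' defaultDomain(attachScores(tokenizeSmiles("CCO"), c(0.2, -0.6, 0.4)))
#' @export
defaultDomain <- function(scored) {
  sc <- if (is(scored, "ScoredSmiles")) scored@scores else as.numeric(scored)
  m <- max(abs(sc), 0)
  if (m == 0) {
    warning("all scores are zero; falling back to colormap domain (-1, 1)",
            call. = FALSE)
    return(c(-1, 1))
  }
  c(-m, m)
}

#' Normalize scores against a colormap domain
#'
#' Positive scores are divided by the domain maximum and negative scores by
#' the absolute domain minimum, then clamped to [-1, 1]: every value at or
#' beyond a domain endpoint maps to a full-height bar and the strongest
#' palette color. Bar height and color intensity downstream are functions
#' of this value only.
#'
#' @param score numeric vector of raw scores.
#' @param domain colormap domain, c(min, max) or c(min, 0, max).
#' @return numeric vector in [-1, 1].
#' @examples
#' normalizeScore(c(0.6, -0.165, 0), c(-0.33, 0.33))  # 1, -0.5, 0
#' @export
normalizeScore <- function(score, domain) {
  domain <- .asDomain(domain)
  v <- ifelse(score >= 0, score / domain[2], score / abs(domain[1]))
  pmin(1, pmax(-1, v))
}

#' Absolute highlight cutoffs from threshold fractions
#'
#' Thresholds are fractions in [0, 1] of the colormap domain's maximum;
#' each becomes the absolute attribution cutoff at which atoms start to be
#' highlighted (symmetrically on the negative side via |score|). With the
#' domain (-0.5, 0, 0.5), a threshold of 0.5 yields the cutoff 0.25, i.e.
#' scores >= 0.25 or <= -0.25 are highlighted. An empty threshold list
#' yields no cutoffs (no diagram highlight; the bar chart then falls back
#' to guide lines at fractions 0.5 and 1).
#'
#' @param thresholds numeric vector of fractions in [0, 1].
#' @param domain colormap domain, c(min, max) or c(min, 0, max).
#' @return numeric vector of absolute cutoffs, same length as
#'   \code{thresholds}.
#' @examples
#' thresholdCutoffs(0.5, c(-0.5, 0, 0.5))  # 0.25
#' @export
thresholdCutoffs <- function(thresholds, domain) {
  domain <- .asDomain(domain)
  thresholds <- as.numeric(thresholds)
  if (!length(thresholds)) return(numeric(0))
  if (any(!is.finite(thresholds)) || any(thresholds < 0 | thresholds > 1))
    stop("thresholds must be fractions in [0, 1]", call. = FALSE)
  thresholds * domain[2]
}

#' Atoms highlighted at each cutoff
#'
#' For each absolute cutoff c, the set of atoms whose |score| >= c (atoms
#' with score exactly zero are never highlighted, so a cutoff of 0 selects
#' every atom with a nonzero score). Sets are nested: a larger cutoff
#' selects a subset of a smaller one.
#'
#' @param scored a [ScoredSmiles-class] object.
#' @param cutoffs numeric vector of absolute cutoffs (from
#'   [thresholdCutoffs()]).
#' @return list (one element per cutoff) of integer atom-index vectors.
#' @export
highlightedAtoms <- function(scored, cutoffs) {
  stopifnot(is(scored, "ScoredSmiles"))
  pos <- atomTokenPositions(scored)
  atomScore <- scored@scores[pos]
  lapply(as.numeric(cutoffs), function(cc) {
    which(abs(atomScore) >= cc & atomScore != 0)
  })
}

# --- diverging palettes -----------------------------------------------------

# 5-class colorblind-safe diverging schemes after the Color Brewer families;
# ordered negative endpoint -> neutral middle -> positive endpoint
.PALETTES <- list(
  RdBu = c("#CA0020", "#F4A582", "#F7F7F7", "#92C5DE", "#0571B0"),
  PiYG = c("#D01C8B", "#F1B6DA", "#F7F7F7", "#B8E186", "#4DAC26"),
  PuOr = c("#E66101", "#FDB863", "#F7F7F7", "#B2ABD2", "#5E3C99"),
  BrBG = c("#A6611A", "#DFC27D", "#F5F5F5", "#80CDC1", "#018571"))

#' Built-in diverging palettes
#'
#' Named list of the built-in colorblind-friendly diverging palettes
#' (derived from Color Brewer 5-class schemes), each ordered from the
#' negative endpoint through the neutral middle to the positive endpoint.
#'
#' @return named list of hex color vectors.
#' @export
divergingPalettes <- function() .PALETTES

.resolvePalette <- function(palette) {
  if (length(palette) == 1L && palette %in% names(.PALETTES))
    return(structure(.PALETTES[[palette]], name = palette))
  if (length(palette) == 1L && grepl("\\.json$", palette)) {
    if (!file.exists(palette))
      stop("palette file does not exist: '", palette, "'", call. = FALSE)
    palette <- as.character(unlist(jsonlite::fromJSON(palette)))
  }
  if (length(palette) < 3L || length(palette) %% 2L == 0L)
    stop("a custom palette must be diverging: odd length >= 3 with a ",
         "neutral middle color", call. = FALSE)
  m <- tryCatch(grDevices::col2rgb(palette) / 255,
                error = function(e) stop("invalid palette colors",
                                         call. = FALSE))
  structure(grDevices::rgb(m[1, ], m[2, ], m[3, ]), name = "custom")
}

.hex <- function(rgbRow) {
  grDevices::rgb(rgbRow[1], rgbRow[2], rgbRow[3], maxColorValue = 1)
}

.toLab <- function(hex) {
  grDevices::convertColor(t(grDevices::col2rgb(hex)) / 255,
                          from = "sRGB", to = "Lab")
}

.fromLab <- function(lab) {
  m <- matrix(pmin(1, pmax(0, grDevices::convertColor(
    lab, from = "Lab", to = "sRGB"))), ncol = 3)
  grDevices::rgb(m[, 1], m[, 2], m[, 3])
}

#' Lightness of a color (CIE L*)
#'
#' @param hex hex color string(s).
#' @return numeric CIE L* values in [0, 100].
#' @keywords internal
colorLightness <- function(hex) .toLab(hex)[, 1]

# interpolate within one half of a diverging palette at strength t in [0,1]:
# piecewise-linear in CIELAB for hue/chroma, with the L channel replaced by
# a linear ramp from the neutral middle's L to the endpoint's L, so color
# lightness is monotone in |score| by construction (the palettes' own
# lightness correction)
.halfColor <- function(anchors, t) {
  lab <- .toLab(anchors)
  k <- nrow(lab)
  posn <- t * (k - 1)
  i0 <- pmin(floor(posn), k - 2)
  f <- posn - i0
  out <- lab[i0 + 1, , drop = FALSE] * (1 - f) +
         lab[i0 + 2, , drop = FALSE] * f
  out[, 1] <- lab[1, 1] + (lab[k, 1] - lab[1, 1]) * t
  .fromLab(out)
}

#' Map scores to diverging-palette colors
#'
#' Normalizes each score against the colormap domain and interpolates the
#' corresponding half of the diverging palette in an approximately
#' perceptually uniform space (CIELAB), with lightness corrected to
#' decrease monotonically from the neutral middle toward either endpoint.
#' A score of zero maps exactly to the middle color; scores at or beyond a
#' domain endpoint map exactly to that endpoint color.
#'
#' @param score numeric vector of raw scores.
#' @param domain colormap domain, c(min, max) or c(min, 0, max).
#' @param palette a built-in palette name (see [divergingPalettes()]) or a
#'   custom odd-length diverging color vector.
#' @return character vector of hex colors.
#' @examples
#' scoreToColor(c(-0.6, 0, 0.6), c(-0.6, 0.6), "RdBu")
#' @export
scoreToColor <- function(score, domain, palette = "RdBu") {
  pal <- .resolvePalette(palette)
  domain <- .asDomain(domain)
  v <- normalizeScore(score, domain)
  mid <- (length(pal) + 1L) %/% 2L
  out <- character(length(v))
  out[v == 0] <- pal[mid]
  out[v == 1] <- pal[length(pal)]
  out[v == -1] <- pal[1]
  rest <- which(out == "")
  for (i in rest) {
    anchors <- if (v[i] > 0) pal[mid:length(pal)] else pal[mid:1]
    out[i] <- .halfColor(anchors, abs(v[i]))
  }
  out
}
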